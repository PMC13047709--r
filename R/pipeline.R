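# End-to-end orchestration: a run configuration whose defaults mirror the
# standard ensemble-SDM protocol (1 km thinning, 2 x 1000 pseudo-absences,
# prevalence 0.5, 75/25 splits x 10 repetitions, contribution/correlation
# screening at 0.5% and |r| 0.8, RM x FC tuning under AICc, AUC 0.90 / TSS
# 0.80 ensemble gate, grade breakpoints 0.3/0.6/0.85), plus a runner that
# executes every stage in order and writes its artifact tree.

#' Run configuration
#'
#' Collects every tunable of the pipeline with protocol defaults. The
#' configuration round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param thin_radius_km Thinning radius (km, or map units on abstract
#'   grids).
#' @param thin_distance `"euclidean"` or `"great-circle"`.
#' @param pa_n_points,pa_n_sets Pseudo-absence points per set, and number of
#'   sets.
#' @param prevalence Weighting prevalence (0.5 equalizes class weight sums).
#' @param n_reps Train/test repetitions.
#' @param train_frac Training fraction per class.
#' @param screen_c_min Minimum contribution percentage retained.
#' @param screen_r_max Collinearity threshold on |r|.
#' @param learners Algorithm names to fit (subset of [learner_registry()]).
#' @param tune_rm_grid,tune_fc_grid RM and FC grids for maxent-style tuning.
#' @param n_hinge_knots,n_threshold_knots Feature knot counts.
#' @param gate_auc,gate_tss Ensemble member gate (strict inequalities).
#' @param ensemble_weighting `"tss"` or `"auc"`.
#' @param grade_breaks Suitability breakpoints (unsuitable/low/moderate/high).
#' @param binary_cut Presence/absence cutoff.
#' @param change_classes `"moderate_high"` (change analysis on grades >= 3)
#'   or `"suitable"` (grades >= 2, i.e. P > binary cut).
#' @param area_mode,cell_area_km2 Area model settings.
#' @param sim Named list of [simulate_landscape()] overrides (synthetic
#'   runs).
#' @return A `run_config` (named list).
#' @export
run_config <- function(seed = 1,
                       thin_radius_km = 1.0,
                       thin_distance = "euclidean",
                       pa_n_points = 1000, pa_n_sets = 2,
                       prevalence = 0.5, n_reps = 10, train_frac = 0.75,
                       screen_c_min = 0.5, screen_r_max = 0.8,
                       learners = learner_registry(),
                       tune_rm_grid = seq(0.5, 4, by = 0.5),
                       tune_fc_grid = c("L", "LQ", "LQH", "H", "LQHP", "LQHPT"),
                       n_hinge_knots = 50, n_threshold_knots = 50,
                       gate_auc = 0.90, gate_tss = 0.80,
                       ensemble_weighting = "tss",
                       grade_breaks = c(0.3, 0.6, 0.85),
                       binary_cut = 0.3,
                       change_classes = "moderate_high",
                       area_mode = "constant", cell_area_km2 = 1,
                       sim = list()) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$thin_radius_km > 0, cfg$pa_n_points >= 1, cfg$pa_n_sets >= 1,
    cfg$prevalence > 0, cfg$prevalence < 1,
    cfg$train_frac > 0, cfg$train_frac < 1,
    cfg$screen_c_min >= 0, cfg$screen_r_max > 0, cfg$screen_r_max <= 1,
    cfg$gate_auc >= 0, cfg$gate_auc <= 1, cfg$gate_tss >= -1, cfg$gate_tss <= 1,
    length(cfg$grade_breaks) == 3, !is.unsorted(cfg$grade_breaks),
    cfg$change_classes %in% c("moderate_high", "suitable")
  )
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_run_config()] (missing keys take
#'   the defaults).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

log_line <- function(log, stage, message) {
  entry <- sprintf("[%s] %s", stage, message)
  c(log, entry)
}

#' Run the full ensemble-SDM workflow on a synthetic landscape
#'
#' Executes every stage in protocol order: simulate -> thin -> screen ->
#' tune -> fit/evaluate -> gate/ensemble -> project per scenario -> classify
#' -> change + transition accounting -> MESS/MoD, and (when `outdir` is
#' given) writes the artifact tree (CSV tables, ASCII grids, JSON manifest,
#' plain-text log). With the same configuration and master seed the run is
#' fully reproducible.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (`NULL` = in-memory only).
#' @return List with elements `presences`, `screen_log`, `variables`,
#'   `tuning`, `members`, `member_summary`, `ensemble`, `ensemble_scores`,
#'   `maps` (per scenario: suitability/grade/binary maps), `area_tables`,
#'   `change`, `transitions`, `mess`, `log`, `manifest`.
#' @export
run_sdm_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log <- character(0)
  amodel <- area_model(config$area_mode, cell_area_km2 = config$cell_area_km2)

  # -- simulate ---------------------------------------------------------
  sim <- do.call(simulate_landscape,
                 c(list(seed = derive_seed(seed, "sim")), config$sim))
  stack <- sim$stack
  log <- log_line(log, "simulate",
                  sprintf("stack %dx%d, %d layers, %d presences, %d future scenario(s)",
                          stack$spec$n_rows, stack$spec$n_cols,
                          length(stack$layers), nrow(sim$presences),
                          length(sim$future)))

  # -- thin -------------------------------------------------------------
  pres <- thin_occurrences(sim$presences, radius_km = config$thin_radius_km,
                           seed = derive_seed(seed, "thin"),
                           distance = config$thin_distance)
  log <- log_line(log, "thin", sprintf("%d -> %d records (radius %g)",
                                       nrow(sim$presences), nrow(pres),
                                       config$thin_radius_km))

  # -- screen -----------------------------------------------------------
  pa <- sample_pseudo_absences(stack, pres, n_points = config$pa_n_points,
                               n_sets = config$pa_n_sets,
                               seed = derive_seed(seed, "pa"))
  full <- assemble_datasets(stack, pres, pa, prevalence = config$prevalence,
                            n_reps = 1, train_frac = config$train_frac,
                            seed = derive_seed(seed, "prescreen"))[[1]]
  prelim <- fit_learner("GBM", full$X, full$y, full$w,
                        seed = derive_seed(seed, "prelim"))
  imp <- permutation_importance(prelim, full$X,
                                seed = derive_seed(seed, "importance"))
  cors <- pearson_matrix(stack)
  screen_log <- screen_variables(imp, cors, c_min = config$screen_c_min,
                                 r_max = config$screen_r_max)
  vars <- screened_variables(screen_log)
  if (length(vars) == 0) {
    abort_sdm("screening retained no variables", "sdmflow_screen_error")
  }
  log <- log_line(log, "screen",
                  sprintf("%d of %d variables retained: %s", length(vars),
                          nrow(screen_log), paste(vars, collapse = ", ")))

  # -- assemble + tune --------------------------------------------------
  datasets <- assemble_datasets(stack, pres, pa, layers = vars,
                                prevalence = config$prevalence,
                                n_reps = config$n_reps,
                                train_frac = config$train_frac,
                                seed = derive_seed(seed, "assemble"))
  tuning <- NULL
  specs <- lapply(config$learners, learner_spec)
  if ("MAXNET" %in% config$learners) {
    ds1 <- datasets[[1]]
    tuning <- tune_maxnet(
      ds1$X[ds1$y == 1, , drop = FALSE], ds1$X[ds1$y == 0, , drop = FALSE],
      rm_grid = config$tune_rm_grid, fc_grid = config$tune_fc_grid,
      n_hinge_knots = config$n_hinge_knots,
      n_threshold_knots = config$n_threshold_knots,
      seed = derive_seed(seed, "tunemax")
    )
    specs <- lapply(specs, function(s) {
      if (s$name == "MAXNET") {
        learner_spec("MAXNET", fc = tuning$chosen$fc, rm = tuning$chosen$rm,
                     n_hinge_knots = config$n_hinge_knots,
                     n_threshold_knots = config$n_threshold_knots)
      } else s
    })
    log <- log_line(log, "tune",
                    sprintf("%d combinations; chosen RM=%g FC=%s",
                            nrow(tuning$grid), tuning$chosen$rm,
                            tuning$chosen$fc))
  }

  # -- fit + evaluate ---------------------------------------------------
  members <- run_protocol(datasets, specs, seed = derive_seed(seed, "protocol"))
  msum <- summarize_members(members)
  n_failed <- sum(members$status != "ok")
  if (n_failed > 0) {
    failed_algs <- unique(members$algorithm[members$status != "ok"])
    log <- log_line(log, "fit", sprintf("%d failed run(s): %s", n_failed,
                                        paste(failed_algs, collapse = ", ")))
  }
  log <- log_line(log, "fit", sprintf("%d member records (%d ok)",
                                      nrow(members), sum(members$status == "ok")))

  # -- gate + ensemble --------------------------------------------------
  sel <- select_members(members, auc_min = config$gate_auc,
                        tss_min = config$gate_tss)
  em <- build_ensemble(sel, weighting = config$ensemble_weighting)
  em_scores <- evaluate_ensemble(em, datasets)
  log <- log_line(log, "ensemble",
                  sprintf("%d members from %d algorithm(s); mean AUC %.3f, mean TSS %.3f",
                          nrow(em$members),
                          dplyr::n_distinct(em$members$algorithm),
                          mean(em_scores$auc), mean(em_scores$tss)))

  # -- project + classify per scenario ----------------------------------
  scenarios <- c(list(current = stack), sim$future)
  maps <- lapply(scenarios, function(s) {
    P <- project_suitability(em, s, layers = vars)
    g <- classify_suitability(P, breaks = config$grade_breaks)
    b <- binarize_suitability(P, cut = config$binary_cut)
    list(suitability = P, grade = g, binary = b)
  })
  area_tables <- purrr::map_dfr(maps, function(m) grade_areas(m$grade, amodel))
  log <- log_line(log, "project", sprintf("%d scenario(s) projected",
                                          length(scenarios)))

  # -- change + transitions ---------------------------------------------
  change_bin <- function(m) {
    if (config$change_classes == "moderate_high") {
      hi <- m$grade
      v <- matrix(NA_integer_, nrow(hi$values), ncol(hi$values))
      ok <- !is.na(hi$values)
      v[ok] <- as.integer(hi$values[ok] >= 3L)
      new_map(hi$spec, v, hi$scenario_id, "binary_map")
    } else {
      m$binary
    }
  }
  cur_bin <- change_bin(maps$current)
  future_names <- setdiff(names(maps), "current")
  change <- lapply(future_names, function(nm) {
    cm <- change_map(cur_bin, change_bin(maps[[nm]]), amodel)
    a <- setNames(cm$areas$area_km2, cm$areas$category)
    cm$rates <- change_rates(a["gain"], a["loss"], a["retained"])
    cm
  })
  names(change) <- future_names
  transitions <- lapply(future_names, function(nm) {
    transition_map(maps$current$grade, maps[[nm]]$grade, amodel)
  })
  names(transitions) <- future_names
  log <- log_line(log, "change", sprintf("change + transition maps for %d scenario(s)",
                                         length(future_names)))

  # -- MESS / MoD -------------------------------------------------------
  ref_idx <- datasets[[1]]
  reference <- ref_idx$X  # calibration points: presences + PA set 1
  mess <- lapply(future_names, function(nm) {
    mess_map(reference, scenarios[[nm]], variables = vars)
  })
  names(mess) <- future_names
  log <- log_line(log, "mess", sprintf("MESS/MoD for %d scenario(s)",
                                       length(future_names)))

  result <- list(
    config = config, presences = pres, screen_log = screen_log,
    variables = vars, tuning = tuning, members = members,
    member_summary = msum, ensemble = em, ensemble_scores = em_scores,
    maps = maps, area_tables = area_tables, change = change,
    transitions = transitions, mess = mess, truth_map = sim$truth_map,
    log = log
  )
  if (!is.null(outdir)) {
    result$manifest <- write_run_artifacts(result, outdir)
  }
  result
}

# Write the artifact tree of a completed run; returns the manifest.
write_run_artifacts <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  put_asc <- function(map, name) {
    p <- file.path(outdir, name)
    v <- map$values
    if (is.character(v)) stop("cannot write character map")
    write_asc(v + 0, map$spec, p)
    files <<- c(files, name)
  }
  put_csv(result$presences, "occurrences_thinned.csv")
  put_csv(result$screen_log, "screening.csv")
  if (!is.null(result$tuning)) put_csv(result$tuning$grid, "tuning.csv")
  put_csv(result$members[, setdiff(names(result$members), "model")],
          "members.csv")
  put_csv(result$member_summary, "member_summary.csv")
  put_csv(result$ensemble_scores, "ensemble_scores.csv")
  put_csv(round2(report_area_table(result)), "area_table.csv")
  put_csv(round2(report_change_table(result)), "change_table.csv")
  for (nm in names(result$maps)) {
    put_asc(result$maps[[nm]]$suitability, sprintf("suitability_%s.asc", nm))
    put_asc(result$maps[[nm]]$grade, sprintf("grade_%s.asc", nm))
  }
  for (nm in names(result$transitions)) {
    put_asc(result$transitions[[nm]], sprintf("transition_%s.asc", nm))
    tm <- result$transitions[[nm]]$area_matrix / 1e4
    put_csv(data.frame(previous = rownames(tm), round(tm, 2)),
            sprintf("transition_matrix_%s.csv", nm))
  }
  for (nm in names(result$mess)) {
    m <- result$mess[[nm]]
    put_asc(new_map(m$spec, m$S, nm, "suitability_map"),
            sprintf("mess_S_%s.asc", nm))
    put_asc(new_map(m$spec, m$mod + 0, nm, "suitability_map"),
            sprintf("mess_mod_%s.asc", nm))
    put_csv(tibble::tibble(index = seq_along(m$variables),
                           variable = m$variables),
            sprintf("mess_mod_legend_%s.csv", nm))
  }
  writeLines(result$log, file.path(outdir, "run.log"))
  files <- c(files, "run.log")
  manifest <- list(
    package = "sdmflow",
    version = as.character(utils::packageVersion("sdmflow")),
    seed = result$config$seed,
    variables = result$variables,
    files = files
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

round2 <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)
  df
}

#' Per-scenario area table of a completed run
#'
#' One row per scenario: per-grade areas and the suitable total, in
#' 1e4 km2 (full precision; the written CSV rounds to 2 decimals).
#'
#' @param result Output of [run_sdm_pipeline()].
#' @return Tibble with columns `scenario`, `unsuitable`, `low`, `moderate`,
#'   `high`, `total_suitable`.
#' @export
report_area_table <- function(result) {
  result$area_tables |>
    dplyr::select("scenario", "class", "area_1e4_km2") |>
    tidyr::pivot_wider(names_from = "class", values_from = "area_1e4_km2") |>
    dplyr::mutate(total_suitable = .data$low + .data$moderate + .data$high)
}

#' Per-scenario change table of a completed run
#'
#' One row per future scenario: retained / contraction / expansion areas
#' (1e4 km2) and the contraction/expansion rates relative to the
#' previous-period suitable area (`retained + contraction`).
#'
#' @param result Output of [run_sdm_pipeline()].
#' @return Tibble with columns `scenario`, `total`, `retained`,
#'   `contraction`, `contraction_rate`, `expansion`, `expansion_rate`.
#' @export
report_change_table <- function(result) {
  purrr::map_dfr(names(result$change), function(nm) {
    a <- setNames(result$change[[nm]]$areas$area_km2,
                  result$change[[nm]]$areas$category)
    r <- result$change[[nm]]$rates
    tibble::tibble(
      scenario = nm,
      total = (a[["gain"]] + a[["retained"]]) / 1e4,
      retained = a[["retained"]] / 1e4,
      contraction = a[["loss"]] / 1e4,
      contraction_rate = r$contraction_rate,
      expansion = a[["gain"]] / 1e4,
      expansion_rate = r$expansion_rate
    )
  })
}
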