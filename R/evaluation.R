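#' Rank-based ROC AUC
#'
#' Mann-Whitney form: the probability that a randomly chosen presence scores
#' above a randomly chosen absence, with ties contributing one half.
#'
#' @param labels 0/1 labels (1 = presence).
#' @param scores Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
eval_auc <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort_sdm("AUC undefined: both classes must be present",
              "sdmflow_score_error")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic with threshold optimization
#'
#' Sweeps candidate thresholds (the midpoints of consecutive sorted unique
#' scores, plus 0 and 1; a point scores presence when its score is strictly
#' above the threshold) and returns the maximum of
#' `sensitivity + specificity - 1` together with the smallest threshold
#' attaining it.
#'
#' @inheritParams eval_auc
#' @return List with `tss` and `threshold`.
#' @export
eval_tss <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort_sdm("TSS undefined: both classes must be present",
              "sdmflow_score_error")
  }
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2)))
  tss_at <- vapply(cand, function(t) {
    pred <- scores > t
    sens <- sum(pred & pos) / n1
    spec <- sum(!pred & !pos) / n0
    sens + spec - 1
  }, numeric(1))
  best <- which.max(tss_at)
  list(tss = tss_at[best], threshold = cand[best])
}

#' Run the fit/evaluate repetition protocol
#'
#' For every algorithm x pseudo-absence set x repetition, fits the learner
#' on the training fold and scores the test fold with AUC and max-TSS
#' (test-fold scoring is unweighted; weights affect fitting only). Fit
#' failures are recorded as `status = "failed"` rows, never raised, so a
#' missing backend simply drops out of the member table.
#'
#' @param datasets List of `modeling_dataset` objects from
#'   [assemble_datasets()].
#' @param specs List of [learner_spec()] objects (or algorithm names).
#' @param seed Integer master seed for stochastic learners.
#' @return Tibble member table: `algorithm`, `pa_set`, `rep`, `status`,
#'   `auc`, `tss`, `tss_threshold`, and a `model` list-column.
#' @export
run_protocol <- function(datasets, specs, seed = 1) {
  stopifnot(length(datasets) >= 1, length(specs) >= 1)
  specs <- lapply(specs, function(s) if (is.character(s)) learner_spec(s) else s)
  rows <- list()
  for (spec in specs) {
    for (ds in datasets) {
      for (r in seq_along(ds$reps)) {
        train <- ds$reps[[r]]
        fit_seed <- derive_seed(seed, paste0("fit_", spec$name),
                                ds$pa_set * 1000L + r)
        fit <- tryCatch(
          fit_learner(spec, ds$X[train, , drop = FALSE], ds$y[train],
                      ds$w[train], seed = fit_seed),
          error = function(e) NULL
        )
        if (is.null(fit)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            algorithm = spec$name, pa_set = ds$pa_set, rep = r,
            status = "failed", auc = NA_real_, tss = NA_real_,
            tss_threshold = NA_real_, model = list(NULL)
          )
          next
        }
        scores <- predict(fit, ds$X[!train, , drop = FALSE])
        labels <- ds$y[!train]
        auc <- eval_auc(labels, scores)
        ts <- eval_tss(labels, scores)
        rows[[length(rows) + 1]] <- tibble::tibble(
          algorithm = spec$name, pa_set = ds$pa_set, rep = r, status = "ok",
          auc = auc, tss = ts$tss, tss_threshold = ts$threshold,
          model = list(fit)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-algorithm performance summary of a member table
#'
#' @param members Member table from [run_protocol()].
#' @return Tibble with per-algorithm `n_ok`, `n_failed`, `mean_auc`,
#'   `mean_tss`.
#' @export
summarize_members <- function(members) {
  members |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      n_ok = sum(.data$status == "ok"),
      n_failed = sum(.data$status != "ok"),
      mean_auc = mean(.data$auc[.data$status == "ok"]),
      mean_tss = mean(.data$tss[.data$status == "ok"]),
      .groups = "drop"
    )
}
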