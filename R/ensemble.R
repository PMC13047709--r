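#' Gate member models on skill
#'
#' At the default `"algorithm"` level an algorithm passes iff its mean test
#' AUC and mean test TSS (over successful runs) strictly exceed the gate
#' thresholds; all its successful runs then become ensemble members. At
#' `"run"` level the gate is applied per individual run.
#'
#' @param members Member table from [run_protocol()].
#' @param auc_min,tss_min Gate thresholds (strict inequalities; defaults
#'   0.90 and 0.80).
#' @param level `"algorithm"` or `"run"`.
#' @return The subset of `members` selected for ensembling.
#' @export
select_members <- function(members, auc_min = 0.90, tss_min = 0.80,
                           level = c("algorithm", "run")) {
  level <- match.arg(level)
  ok <- members[members$status == "ok", ]
  if (level == "algorithm") {
    s <- summarize_members(ok)
    pass <- s$algorithm[s$mean_auc > auc_min & s$mean_tss > tss_min]
    sel <- ok[ok$algorithm %in% pass, ]
  } else {
    sel <- ok[ok$auc > auc_min & ok$tss > tss_min, ]
  }
  if (nrow(sel) == 0) {
    abort_sdm(
      "no member passed the skill gate; consider relaxing auc_min/tss_min",
      "sdmflow_ensemble_error"
    )
  }
  sel
}

#' Build a TSS-weighted ensemble
#'
#' Member weights are proportional to each member's test TSS (no decay
#' exponent), renormalized to sum to one.
#'
#' @param members Gate-passing member table (from [select_members()]).
#' @param weighting `"tss"` (default) or `"auc"`.
#' @return An `sdm_ensemble`.
#' @export
build_ensemble <- function(members, weighting = c("tss", "auc")) {
  weighting <- match.arg(weighting)
  stopifnot(nrow(members) >= 1)
  wraw <- members[[weighting]]
  if (any(wraw < 0)) wraw <- pmax(wraw, 0)
  if (sum(wraw) == 0) wraw <- rep(1, length(wraw))
  members$weight <- wraw / sum(wraw)
  structure(
    list(members = members, weighting = weighting),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  algs <- table(x$members$algorithm)
  cat(sprintf("<sdm_ensemble> %d members (%s-weighted): %s\n",
              nrow(x$members), x$weighting,
              paste(sprintf("%s x%d", names(algs), algs), collapse = ", ")))
  invisible(x)
}

#' Predict ensemble suitability
#'
#' The weighted average of member suitabilities. A member whose prediction
#' fails is dropped with a warning and the remaining weights renormalized.
#'
#' @param object An `sdm_ensemble`.
#' @param newdata Predictor matrix.
#' @param ... Unused.
#' @return Suitability scores in \[0, 1\].
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- lapply(seq_len(nrow(object$members)), function(i) {
    tryCatch(predict(object$members$model[[i]], newdata),
             error = function(e) NULL)
  })
  okm <- !vapply(preds, is.null, logical(1))
  if (!all(okm)) {
    warning(sprintf("%d member prediction(s) failed; weights renormalized",
                    sum(!okm)))
  }
  w <- object$members$weight[okm]
  w <- w / sum(w)
  out <- numeric(nrow(newdata))
  ks <- which(okm)
  for (i in seq_along(ks)) out <- out + w[i] * preds[[ks[i]]]
  clamp01(out)
}

#' Evaluate an ensemble over the repetition test folds
#'
#' @param em An `sdm_ensemble`.
#' @param datasets List of `modeling_dataset` objects.
#' @return Tibble with one row per pseudo-absence set x repetition
#'   (`pa_set`, `rep`, `auc`, `tss`) and attributes-free means accessible via
#'   [glance()].
#' @export
evaluate_ensemble <- function(em, datasets) {
  purrr::map_dfr(datasets, function(ds) {
    purrr::map_dfr(seq_along(ds$reps), function(r) {
      test <- !ds$reps[[r]]
      scores <- predict(em, ds$X[test, , drop = FALSE])
      ts <- eval_tss(ds$y[test], scores)
      tibble::tibble(pa_set = ds$pa_set, rep = r,
                     auc = eval_auc(ds$y[test], scores), tss = ts$tss)
    })
  })
}

#' Ensemble response curve for one variable
#'
#' Evaluation-strip method: the target variable is varied across its
#' observed range over valid cells at `n_points` evenly spaced values while
#' every other variable is held at its median over valid cells.
#'
#' @param em An `sdm_ensemble` (or any `sdm_fit`).
#' @param stack The calibration [env_stack()].
#' @param variable Layer name to profile.
#' @param n_points Grid resolution (default 100).
#' @param layers Predictor layers the model expects (default: all stack
#'   layers).
#' @return Tibble with columns `variable`, `value`, `suitability`.
#' @export
response_curve <- function(em, stack, variable, n_points = 100, layers = NULL) {
  layers <- layers %||% names(stack$layers)
  if (!variable %in% layers) {
    abort_sdm(sprintf("unknown variable '%s'", variable), "sdmflow_lookup_error")
  }
  vals <- stack_values(stack, layers)
  med <- apply(vals, 2, median)
  grid <- seq(min(vals[, variable]), max(vals[, variable]),
              length.out = n_points)
  X <- matrix(rep(med, each = n_points), nrow = n_points,
              dimnames = list(NULL, layers))
  X[, variable] <- grid
  tibble::tibble(variable = variable, value = grid,
                 suitability = predict(em, X))
}

#' @exportS3Method generics::tidy
tidy.sdm_ensemble <- function(x, ...) {
  x$members[, c("algorithm", "pa_set", "rep", "auc", "tss", "weight")]
}

#' @exportS3Method generics::glance
glance.sdm_ensemble <- function(x, ...) {
  tibble::tibble(
    n_members = nrow(x$members),
    n_algorithms = dplyr::n_distinct(x$members$algorithm),
    weighting = x$weighting,
    mean_member_auc = mean(x$members$auc),
    mean_member_tss = mean(x$members$tss)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.sdm_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$weight)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$algorithm), show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Ensemble weight")
}

#' Plot one or more response curves
#'
#' @param curves Tibble from [response_curve()] (rows from several variables
#'   may be bound together).
#' @return A ggplot.
#' @export
plot_response_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$value, y = .data$suitability)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Variable value", y = "Ensemble suitability")
}
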