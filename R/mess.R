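#' Univariate environmental similarity
#'
#' Similarity of query values `p` to a reference sample for one variable.
#' With `f` the percentage of reference values strictly below `p`:
#' `f = 0` gives `S = 100 * (p - min) / (max - min)` (negative below the
#' range), `0 < f <= 50` gives `S = 2 f`, `50 <= f < 100` gives
#' `S = 2 (100 - f)`, and `f = 100` gives `S = 100 * (max - p) / (max - min)`
#' (negative above the range). `S = 100` only at the reference median;
#' `S <= 0` iff `p` lies outside the reference range.
#'
#' @param reference Numeric reference sample (>= 2 distinct values).
#' @param p Numeric query values.
#' @return Similarity values (same length as `p`), each <= 100.
#' @export
mess_similarity <- function(reference, p) {
  reference <- sort(reference[is.finite(reference)])
  n <- length(reference)
  mn <- reference[1]; mx <- reference[n]
  if (n < 2 || mx == mn) {
    abort_sdm("degenerate reference: need >= 2 distinct values",
              "sdmflow_domain_error")
  }
  f <- 100 * findInterval(p, reference, left.open = TRUE) / n
  s <- numeric(length(p))
  s[f == 0] <- 100 * (p[f == 0] - mn) / (mx - mn)
  mid_lo <- f > 0 & f <= 50
  s[mid_lo] <- 2 * f[mid_lo]
  mid_hi <- f > 50 & f < 100
  s[mid_hi] <- 2 * (100 - f[mid_hi])
  s[f == 100] <- 100 * (mx - p[f == 100]) / (mx - mn)
  s
}

#' Multivariate environmental similarity surface (MESS) and MoD
#'
#' For every valid cell of a projection stack, computes the per-variable
#' similarity to the reference sample (typically the environmental values at
#' the calibration points) and takes the minimum across variables; the
#' variable attaining the minimum (smallest index on ties) is the
#' most-dissimilar variable (MoD). Cells with `S <= 0` extrapolate beyond
#' the reference range in at least one variable.
#'
#' @param reference Matrix of reference values (rows = calibration points,
#'   named columns), e.g. the predictors extracted at presences +
#'   pseudo-absences.
#' @param projection An [env_stack()] containing every reference variable.
#' @param variables Variables to use (default: the reference columns).
#' @return A `mess_result`: `S` (matrix of minimum similarity), `mod`
#'   (matrix of MoD variable indices), `variables`, and `per_variable`
#'   (list of per-variable similarity matrices).
#' @export
mess_map <- function(reference, projection, variables = NULL) {
  reference <- as.matrix(reference)
  variables <- variables %||% colnames(reference)
  missing <- setdiff(variables, names(projection$layers))
  if (length(missing)) {
    abort_sdm(paste0("projection stack lacks variable(s): ",
                     paste(missing, collapse = ", ")),
              "sdmflow_lookup_error")
  }
  vals <- stack_values(projection, variables)
  idx <- attr(vals, "cells")
  smat <- vapply(variables, function(v) {
    mess_similarity(reference[, v], vals[, v])
  }, numeric(nrow(vals)))
  smat <- matrix(smat, nrow = nrow(vals), dimnames = list(NULL, variables))
  mins <- apply(smat, 1, min)
  which_min <- apply(smat, 1, which.min)  # smallest index on ties
  spec <- projection$spec
  S <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  S[idx] <- mins
  mod <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  mod[idx] <- as.integer(which_min)
  per_var <- lapply(seq_along(variables), function(j) {
    m <- matrix(NA_real_, spec$n_rows, spec$n_cols)
    m[idx] <- smat[, j]
    m
  })
  names(per_var) <- variables
  structure(
    list(S = S, mod = mod, variables = variables, per_variable = per_var,
         spec = spec, scenario_id = projection$scenario_id),
    class = "mess_result"
  )
}

#' @export
print.mess_result <- function(x, ...) {
  s <- x$S[!is.na(x$S)]
  cat(sprintf(
    "<mess_result> '%s': %d cells, S range [%.2f, %.2f], %.1f%% extrapolating (S <= 0)\n",
    x$scenario_id, length(s), min(s), max(s), 100 * mean(s <= 0)
  ))
  invisible(x)
}

#' Summarize a MESS result into anomaly bands
#'
#' Reporting bands: `extreme` (S < 0, beyond-range extrapolation),
#' `anomalous` (0 <= S < 10) and `similar` (S >= 10), plus the MoD
#' frequency per variable.
#'
#' @param mess A `mess_result`.
#' @return List of tibbles `bands` (band, n_cells, fraction) and `mod`
#'   (variable, n_cells, fraction).
#' @export
summarize_mess <- function(mess) {
  s <- mess$S[!is.na(mess$S)]
  bands <- tibble::tibble(
    band = c("extreme", "anomalous", "similar"),
    n_cells = c(sum(s < 0), sum(s >= 0 & s < 10), sum(s >= 10))
  )
  bands$fraction <- bands$n_cells / length(s)
  m <- mess$mod[!is.na(mess$mod)]
  mod <- tibble::tibble(
    variable = mess$variables,
    n_cells = vapply(seq_along(mess$variables),
                     function(j) sum(m == j), numeric(1))
  )
  mod$fraction <- mod$n_cells / length(m)
  list(bands = bands, mod = dplyr::arrange(mod, dplyr::desc(.data$n_cells)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.mess_result <- function(object, ...) {
  d <- map_to_tibble(new_map(object$spec, object$S, object$scenario_id,
                             "suitability_map"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "MESS S",
                  title = object$scenario_id)
}
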