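#' Permutation-based variable contributions
#'
#' Contribution of each predictor to a fitted model, by the prediction-
#' permutation method standard in ensemble SDM practice: for each variable,
#' permute its column, re-predict, and take one minus the Pearson
#' correlation between the reference and permuted predictions; the mean over
#' shuffles is clipped at zero and the vector is normalized to percentages
#' summing to 100.
#'
#' @param model A fitted model honouring the [predict()] contract
#'   (`predict(model, X)` returns suitability scores).
#' @param X Predictor matrix (rows = points, named columns).
#' @param n_shuffles Number of permutations per variable (default 5).
#' @param seed Integer seed.
#' @return Tibble with columns `variable`, `contribution` (percent).
#' @export
permutation_importance <- function(model, X, n_shuffles = 5, seed = 1) {
  stopifnot(nrow(X) >= 3)
  ref <- predict(model, X)
  if (sd(ref) == 0) {
    warning("reference predictions are constant; all contributions set to 0")
    return(tibble::tibble(variable = colnames(X), contribution = 0))
  }
  raw <- vapply(seq_len(ncol(X)), function(j) {
    drops <- vapply(seq_len(n_shuffles), function(s) {
      Xp <- X
      Xp[, j] <- withr_seed(derive_seed(seed, "permimp", j * 1000L + s),
                            sample(Xp[, j]))
      pred <- predict(model, Xp)
      if (sd(pred) == 0) return(1)
      1 - cor(ref, pred)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  raw <- pmax(raw, 0)
  pct <- if (sum(raw) > 0) 100 * raw / sum(raw) else raw
  tibble::tibble(variable = colnames(X), contribution = pct)
}

#' Pearson correlation matrix of predictors
#'
#' Product-moment correlations between layers over all jointly valid cells
#' (or between columns of a plain matrix). Zero-variance variables yield
#' undefined correlations, reported as 0 with a warning.
#'
#' @param x An [env_stack()] or a numeric matrix with named columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x) {
  m <- if (inherits(x, "env_stack")) stack_values(x) else as.matrix(x)
  stopifnot(nrow(m) >= 3)
  zv <- apply(m, 2, function(v) stats::var(v, na.rm = TRUE)) == 0
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (any(zv) || anyNA(r)) {
    warning("zero-variance variable(s): undefined correlations reported as 0")
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

#' Screen predictors by contribution and collinearity
#'
#' Applies the two screening rules jointly and greedily: variables are
#' visited in decreasing contribution order (ties broken alphabetically); a
#' variable is dropped if its contribution falls below `c_min` percent, or
#' if its absolute Pearson correlation with any already-retained variable
#' reaches `r_max` (in which case the retained partner, having the higher
#' contribution, wins). A contribution exactly at `c_min` is retained; such
#' boundary cases are flagged in the decision log.
#'
#' @param importance Tibble from [permutation_importance()]
#'   (`variable`, `contribution`).
#' @param cors Correlation matrix from [pearson_matrix()] covering the same
#'   variables.
#' @param c_min Minimum contribution percentage (default 0.5; strictly lower
#'   values are dropped).
#' @param r_max Collinearity threshold on |r| (default 0.8; reached or
#'   exceeded means dropped).
#' @return Tibble decision log with columns `variable`, `contribution`,
#'   `retained`, `reason` (`"low_contribution"`, `"correlated"`, or `NA`),
#'   `partner`, `boundary`. Use [screened_variables()] for just the names.
#' @export
screen_variables <- function(importance, cors, c_min = 0.5, r_max = 0.8) {
  vars <- importance$variable
  if (!all(vars %in% colnames(cors))) {
    abort_sdm("importance and correlation matrix cover different variables",
              "sdmflow_lookup_error")
  }
  ord <- order(-importance$contribution, importance$variable)
  retained <- character(0)
  log <- importance[ord, ]
  log$retained <- NA
  log$reason <- NA_character_
  log$partner <- NA_character_
  log$boundary <- abs(log$contribution - c_min) < 1e-12
  for (i in seq_len(nrow(log))) {
    v <- log$variable[i]
    if (log$contribution[i] < c_min) {
      log$retained[i] <- FALSE
      log$reason[i] <- "low_contribution"
      next
    }
    hit <- retained[abs(cors[v, retained]) >= r_max]
    if (length(hit)) {
      log$retained[i] <- FALSE
      log$reason[i] <- "correlated"
      log$partner[i] <- hit[1]
    } else {
      log$retained[i] <- TRUE
      retained <- c(retained, v)
    }
  }
  tibble::as_tibble(log)
}

#' Retained variable names from a screening log
#' @param screen_log Output of [screen_variables()].
#' @return Character vector of retained variables, in screening order.
#' @export
screened_variables <- function(screen_log) {
  screen_log$variable[screen_log$retained]
}
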