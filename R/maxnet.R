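#' Feature-class specification for the maxent-style learner
#'
#' @param fc Feature-combination string over the classes `L` (linear), `Q`
#'   (quadratic), `H` (hinge), `P` (product), `T` (threshold), e.g. `"LQ"`.
#' @param rm Regularization multiplier (> 0).
#' @param n_hinge_knots,n_threshold_knots Knots per variable for hinge /
#'   threshold features (evenly spaced interior knots on the scaled \[0, 1\]
#'   range).
#' @return A `maxnet_feature_spec`.
#' @export
maxnet_feature_spec <- function(fc = "LQ", rm = 1,
                                n_hinge_knots = 50, n_threshold_knots = 50) {
  fc <- toupper(fc)
  chars <- strsplit(fc, "")[[1]]
  if (length(chars) == 0 || !all(chars %in% c("L", "Q", "H", "P", "T"))) {
    abort_sdm("FC must be a non-empty string over {L, Q, H, P, T}",
              "sdmflow_parameter_error")
  }
  stopifnot(rm > 0, n_hinge_knots >= 1, n_threshold_knots >= 1)
  structure(
    list(fc = fc, rm = rm, n_hinge_knots = as.integer(n_hinge_knots),
         n_threshold_knots = as.integer(n_threshold_knots)),
    class = "maxnet_feature_spec"
  )
}

# Background min/max scaling statistics, dropping degenerate variables.
make_scaling <- function(X) {
  X <- as.matrix(X)
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  degen <- mx - mn <= 0
  if (any(degen)) {
    warning(sprintf("degenerate variable(s) skipped: %s",
                    paste(colnames(X)[degen], collapse = ", ")))
  }
  list(min = mn[!degen], max = mx[!degen], vars = colnames(X)[!degen])
}

# Per-feature-class base regularization constants. The overall penalty for a
# feature is rm * base(class) / sqrt(n_presence): simpler classes are
# penalized lightly, data-hungry hinge/threshold classes heavily.
maxnet_base_penalty <- c(L = 0.05, Q = 0.05, P = 0.05, H = 0.5, T = 1.0)

#' Expand predictors into maxent-style features
#'
#' Variables are min-max scaled to `\[0, 1\]` using background statistics
#' (supplied via `scaling`, or computed from `X` when absent and returned
#' for reuse at projection time; projection values are clamped into the
#' scaling range). Classes: `L` gives `x`; `Q` gives `x^2`; `P` gives all
#' pairwise products; `H` gives forward hinges `max(0, (x - k)/(1 - k))` and
#' reverse hinges `max(0, (k - x)/k)` at interior knots `k`; `T` gives
#' indicators `x > k`.
#'
#' @param X Predictor matrix with named columns.
#' @param spec A [maxnet_feature_spec()].
#' @param scaling Optional list with `min`/`max` per variable (from a
#'   previous call).
#' @return List: `F` (feature matrix), `classes` (feature class per column),
#'   `scaling`.
#' @export
build_features <- function(X, spec, scaling = NULL) {
  X <- as.matrix(X)
  if (is.null(scaling)) scaling <- make_scaling(X)
  vars <- scaling$vars
  Z <- vapply(vars, function(v) {
    clamp01((X[, v] - scaling$min[[v]]) / (scaling$max[[v]] - scaling$min[[v]]))
  }, numeric(nrow(X)))
  Z <- matrix(Z, nrow = nrow(X), dimnames = list(NULL, vars))
  chars <- strsplit(spec$fc, "")[[1]]
  cols <- list(); classes <- character(0)
  add <- function(m, cl) {
    cols[[length(cols) + 1]] <<- m
    classes <<- c(classes, rep(cl, ncol(m)))
  }
  if ("L" %in% chars) {
    add(`colnames<-`(Z, paste0("L_", vars)), "L")
  }
  if ("Q" %in% chars) {
    add(`colnames<-`(Z^2, paste0("Q_", vars)), "Q")
  }
  if ("H" %in% chars) {
    k <- seq(0, 1, length.out = spec$n_hinge_knots + 2)[-c(1, spec$n_hinge_knots + 2)]
    for (v in vars) {
      fwd <- outer(Z[, v], k, function(x, kk) pmax(0, (x - kk) / (1 - kk)))
      rev <- outer(Z[, v], k, function(x, kk) pmax(0, (kk - x) / kk))
      colnames(fwd) <- sprintf("Hf_%s_%02d", v, seq_along(k))
      colnames(rev) <- sprintf("Hr_%s_%02d", v, seq_along(k))
      add(fwd, "H"); add(rev, "H")
    }
  }
  if ("P" %in% chars && length(vars) >= 2) {
    pairs <- utils::combn(vars, 2)
    pm <- apply(pairs, 2, function(p) Z[, p[1]] * Z[, p[2]])
    pm <- matrix(pm, nrow = nrow(X))
    colnames(pm) <- apply(pairs, 2, paste, collapse = "_x_")
    colnames(pm) <- paste0("P_", colnames(pm))
    add(pm, "P")
  }
  if ("T" %in% chars) {
    k <- seq(0, 1, length.out = spec$n_threshold_knots + 2)[-c(1, spec$n_threshold_knots + 2)]
    for (v in vars) {
      tm <- outer(Z[, v], k, function(x, kk) as.numeric(x > kk))
      colnames(tm) <- sprintf("T_%s_%02d", v, seq_along(k))
      add(tm, "T")
    }
  }
  F <- do.call(cbind, cols)
  list(F = F, classes = classes, scaling = scaling)
}

#' Closed-form feature count for a feature specification
#'
#' `L` and `Q` contribute one feature per variable, `H` contributes
#' `2 * n_hinge_knots` per variable (forward + reverse), `T` contributes
#' `n_threshold_knots` per variable, and `P` contributes `choose(v, 2)`.
#'
#' @param n_vars Number of (non-degenerate) variables.
#' @param spec A [maxnet_feature_spec()].
#' @return Integer feature count.
#' @export
count_features <- function(n_vars, spec) {
  chars <- strsplit(spec$fc, "")[[1]]
  n <- 0L
  if ("L" %in% chars) n <- n + n_vars
  if ("Q" %in% chars) n <- n + n_vars
  if ("H" %in% chars) n <- n + 2L * spec$n_hinge_knots * n_vars
  if ("P" %in% chars) n <- n + choose(n_vars, 2)
  if ("T" %in% chars) n <- n + spec$n_threshold_knots * n_vars
  as.integer(n)
}

#' Fit the penalized maxent-style presence/background learner
#'
#' An L1-penalized logistic regression of presence vs background on the
#' expanded feature set, with per-feature penalty proportional to
#' `rm * base(class)` (relative class weighting via glmnet's penalty
#' factors) and overall penalty strength `rm * mean(base) / sqrt(n_presence)`
#' (the sample-size rule). Predictions are plain logistic outputs in
#' `\[0, 1\]`; the raw linear score (without intercept) is retained for AICc.
#'
#' @param X_presence,X_background Predictor matrices with the same named
#'   columns.
#' @param spec A [maxnet_feature_spec()].
#' @param weights Optional per-row weights, presences first.
#' @return A fitted model of class `sdm_fit` (subclass `maxnet_fit`).
#' @export
fit_maxnet <- function(X_presence, X_background, spec = maxnet_feature_spec(),
                       weights = NULL) {
  X_presence <- as.matrix(X_presence); X_background <- as.matrix(X_background)
  n_p <- nrow(X_presence); n_b <- nrow(X_background)
  X <- rbind(X_presence, X_background)
  y <- c(rep(1, n_p), rep(0, n_b))
  if (is.null(weights)) weights <- rep(1, n_p + n_b)
  feats <- build_features(X, spec, scaling = make_scaling(X_background))
  base <- maxnet_base_penalty[feats$classes]
  padded <- ncol(feats$F) == 1
  if (padded) {
    # glmnet needs >= 2 columns; a zero dummy never earns a coefficient
    feats$F <- cbind(feats$F, .pad = 0)
    base <- c(base, 1)
  }
  lambda_target <- spec$rm * mean(base) / sqrt(n_p)
  lambda_seq <- lambda_target * 10^seq(3, 0, length.out = 40)
  fit <- tryCatch(
    glmnet::glmnet(
      feats$F, y, family = "binomial", weights = weights,
      penalty.factor = base, lambda = lambda_seq, standardize = FALSE,
      maxit = 1e5
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    abort_sdm("maxnet fit failed to converge", "sdmflow_fit_error")
  }
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  b0 <- fit$a0[length(fit$a0)]
  if (padded) {
    beta <- beta[-length(beta)]
    feats$F <- feats$F[, -ncol(feats$F), drop = FALSE]
  }
  structure(
    list(
      algorithm = "MAXNET", spec = spec, beta = beta, intercept = b0,
      feature_names = colnames(feats$F), classes = feats$classes,
      scaling = feats$scaling, n_presence = n_p,
      n_nonzero = sum(beta != 0)
    ),
    class = c("maxnet_fit", "sdm_fit")
  )
}

# Linear score (intercept excluded) of a maxnet fit on new data.
maxnet_raw_score <- function(object, X) {
  feats <- build_features(as.matrix(X), object$spec, scaling = object$scaling)
  as.numeric(feats$F %*% object$beta)
}

#' @export
predict.maxnet_fit <- function(object, newdata, ...) {
  clamp01(plogis(object$intercept + maxnet_raw_score(object, newdata)))
}

#' Small-sample AIC of a maxent-style fit
#'
#' The raw exponential scores `exp(eta)` are normalized over the combined
#' presence + background sample so they sum to one; the log-likelihood is
#' the sum of log normalized scores at the presences. With `k` the number of
#' nonzero coefficients and `n` the number of presences,
#' `AICc = 2k - 2 lnL + 2k(k + 1)/(n - k - 1)`; it is undefined (NA) when
#' `n - k - 1 <= 0`, and such models are excluded from tuning.
#'
#' @param model A `maxnet_fit`.
#' @param X_presence,X_background Predictor matrices (the landscape sample).
#' @return Scalar AICc (NA when undefined).
#' @export
maxnet_aicc <- function(model, X_presence, X_background) {
  n <- nrow(X_presence)
  k <- model$n_nonzero
  if (n - k - 1 <= 0) return(NA_real_)
  eta <- maxnet_raw_score(model, rbind(as.matrix(X_presence),
                                       as.matrix(X_background)))
  eta <- eta - max(eta)  # overflow guard; cancels in normalization
  p <- exp(eta) / sum(exp(eta))
  lnL <- sum(log(p[seq_len(n)]))
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Tune the maxent-style learner over an RM x FC grid
#'
#' Fits every combination of regularization multiplier and feature
#' combination, computes AICc on the full presence/background sample and AUC
#' on a held-out fraction of the presences, and selects the combination with
#' `delta_AICc = 0`; ties go to higher AUC, then smaller RM, then shorter FC
#' string. Combinations with undefined AICc are marked invalid and never
#' chosen. The `delta_AICc < 2` set is flagged `reliable`.
#'
#' @param X_presence,X_background Predictor matrices.
#' @param rm_grid Regularization multipliers (default 0.5 to 4 by 0.5: 8
#'   values).
#' @param fc_grid Feature combinations (default `L, LQ, LQH, H, LQHP,
#'   LQHPT`: 6 strings, for 48 grid points).
#' @param n_hinge_knots,n_threshold_knots Knot counts passed to
#'   [maxnet_feature_spec()].
#' @param test_frac Presence fraction held out for the AUC column.
#' @param seed Integer seed for the held-out split.
#' @return A `maxnet_tuning` object: tibble `grid` (columns `rm`, `fc`,
#'   `aicc`, `delta_aicc`, `auc`, `n_nonzero`, `valid`, `reliable`) plus
#'   `chosen` (a [maxnet_feature_spec()]).
#' @export
tune_maxnet <- function(X_presence, X_background,
                        rm_grid = seq(0.5, 4, by = 0.5),
                        fc_grid = c("L", "LQ", "LQH", "H", "LQHP", "LQHPT"),
                        n_hinge_knots = 50, n_threshold_knots = 50,
                        test_frac = 0.25, seed = 1) {
  stopifnot(length(rm_grid) >= 1, length(fc_grid) >= 1)
  n_p <- nrow(X_presence)
  n_test <- max(1L, floor(test_frac * n_p))
  test_idx <- withr_seed(derive_seed(seed, "tune"), sample.int(n_p, n_test))
  Xp_tr <- X_presence[-test_idx, , drop = FALSE]
  Xp_te <- X_presence[test_idx, , drop = FALSE]
  grid <- tidyr::expand_grid(fc = fc_grid, rm = rm_grid)
  res <- purrr::pmap_dfr(grid, function(fc, rm) {
    spec <- maxnet_feature_spec(fc, rm, n_hinge_knots, n_threshold_knots)
    fit <- tryCatch(fit_maxnet(Xp_tr, X_background, spec), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(rm = rm, fc = fc, aicc = NA_real_, auc = NA_real_,
                            n_nonzero = NA_integer_, valid = FALSE))
    }
    a <- maxnet_aicc(fit, Xp_tr, X_background)
    scores <- c(predict(fit, Xp_te), predict(fit, X_background))
    labels <- c(rep(1, nrow(Xp_te)), rep(0, nrow(X_background)))
    auc <- tryCatch(eval_auc(labels, scores), error = function(e) NA_real_)
    tibble::tibble(rm = rm, fc = fc, aicc = a, auc = auc,
                   n_nonzero = fit$n_nonzero, valid = is.finite(a))
  })
  if (!any(res$valid)) {
    abort_sdm("all RM x FC combinations invalid", "sdmflow_tuning_error")
  }
  res$delta_aicc <- res$aicc - min(res$aicc[res$valid])
  res$reliable <- res$valid & res$delta_aicc < 2
  cand <- res[res$valid & res$delta_aicc == 0, ]
  cand <- cand[order(-cand$auc, cand$rm, nchar(cand$fc), cand$fc), ]
  chosen <- maxnet_feature_spec(cand$fc[1], cand$rm[1],
                                n_hinge_knots, n_threshold_knots)
  structure(
    list(grid = res[, c("rm", "fc", "aicc", "delta_aicc", "auc",
                        "n_nonzero", "valid", "reliable")],
         chosen = chosen),
    class = "maxnet_tuning"
  )
}

#' @export
print.maxnet_tuning <- function(x, ...) {
  cat(sprintf("<maxnet_tuning> %d combinations; chosen RM = %g, FC = %s\n",
              nrow(x$grid), x$chosen$rm, x$chosen$fc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.maxnet_tuning <- function(x, ...) x$grid

#' @exportS3Method ggplot2::autoplot
autoplot.maxnet_tuning <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$rm, y = .data$delta_aicc,
                               colour = .data$fc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = "Regularization multiplier",
                  y = expression(Delta * "AICc"),
                  colour = "Feature\ncombination")
}
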