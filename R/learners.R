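# The algorithm registry. Every learner is fitted through fit_learner() and
# scored through predict(), which always returns finite suitabilities in
# [0, 1]. FDA and MARS are registered but have no backing implementation
# here; requesting them yields a fit error that the protocol records as a
# failed member rather than raising.

#' Names of the registered algorithms
#' @return Character vector of the 12 registry names.
#' @export
learner_registry <- function() {
  c("ANN", "CTA", "FDA", "GAM", "GBM", "GLM", "MAXENT", "MARS", "MAXNET",
    "RF", "XGBOOST", "SRE")
}

#' Learner specification
#'
#' @param name Registry name (see [learner_registry()]).
#' @param ... Learner hyperparameters. Unknown names are rejected.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(name, ...) {
  name <- toupper(name)
  if (!name %in% learner_registry()) {
    abort_sdm(sprintf("unknown learner '%s'", name), "sdmflow_parameter_error")
  }
  hp <- list(...)
  allowed <- switch(name,
    ANN = c("size", "decay", "maxit"),
    CTA = c("minsplit", "cp"),
    GAM = c("k", "select"),
    GBM = c("nrounds", "eta", "max_depth"),
    GLM = character(0),
    MAXENT = c("fc", "rm", "n_hinge_knots", "n_threshold_knots"),
    MAXNET = c("fc", "rm", "n_hinge_knots", "n_threshold_knots"),
    RF = c("ntree", "mtry"),
    XGBOOST = c("nrounds", "eta", "max_depth"),
    SRE = c("q"),
    character(0)
  )
  bad <- setdiff(names(hp), allowed)
  if (length(bad)) {
    abort_sdm(sprintf("unknown hyperparameter(s) for %s: %s", name,
                      paste(bad, collapse = ", ")),
              "sdmflow_parameter_error")
  }
  structure(list(name = name, hyperparams = hp), class = "learner_spec")
}

#' Fit a surface range envelope (SRE) model
#'
#' BIOCLIM-style rectangular envelope: a point scores 1 iff every variable
#' lies within the presence quantile interval `[q, 1 - q]`, else 0.
#'
#' @param X_presence Presence predictor matrix.
#' @param q Tail quantile trimmed per side (default 0.025; must be < 0.5).
#' @return An `sdm_fit` (subclass `sre_fit`) with binary predictions.
#' @export
fit_sre <- function(X_presence, q = 0.025) {
  if (q >= 0.5 || q < 0) {
    abort_sdm("SRE quantile q must lie in [0, 0.5)", "sdmflow_parameter_error")
  }
  X_presence <- as.matrix(X_presence)
  stopifnot(nrow(X_presence) >= 2)
  lo <- apply(X_presence, 2, quantile, probs = q, names = FALSE)
  hi <- apply(X_presence, 2, quantile, probs = 1 - q, names = FALSE)
  structure(
    list(algorithm = "SRE", lower = lo, upper = hi, q = q,
         vars = colnames(X_presence)),
    class = c("sre_fit", "sdm_fit")
  )
}

#' @export
predict.sre_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$vars, drop = FALSE]
  inside <- rep(TRUE, nrow(X))
  for (j in seq_along(object$vars)) {
    inside <- inside & X[, j] >= object$lower[j] & X[, j] <= object$upper[j]
  }
  as.numeric(inside)
}

#' Fit a registered learner under the uniform contract
#'
#' Fits `spec` on the given rows of a modelling dataset. Per-point weights
#' are honoured where the backend supports them (GLM, GAM, CTA, GBM,
#' XGBOOST, ANN, MAXENT/MAXNET); random forests are fitted unweighted.
#' Fit failures and unavailable backends raise a condition of class
#' `sdmflow_fit_error`, which [run_protocol()] converts into a "failed"
#' member record.
#'
#' @param spec A [learner_spec()] or algorithm name.
#' @param X Predictor matrix (named columns).
#' @param y 0/1 labels (1 = presence).
#' @param w Per-point weights.
#' @param seed Integer seed (learners with stochastic fitting are seeded
#'   deterministically from it).
#' @return An `sdm_fit`; `predict(fit, X)` returns suitabilities in \[0, 1\].
#' @export
fit_learner <- function(spec, X, y, w = rep(1, length(y)), seed = 1) {
  if (is.character(spec)) spec <- learner_spec(spec)
  X <- as.matrix(X)
  hp <- spec$hyperparams
  df <- data.frame(X, check.names = FALSE)
  fit <- switch(spec$name,
    GLM = {
      d <- df; d$.y <- y
      m <- suppressWarnings(stats::glm(
        .y ~ ., data = d, family = binomial(), weights = w
      ))
      wrap_fit("GLM", m, function(m, nd) {
        as.numeric(predict(m, newdata = data.frame(nd, check.names = FALSE),
                           type = "response"))
      })
    },
    GAM = {
      d <- df; d$.y <- y
      k <- hp$k %||% 4
      terms <- vapply(colnames(X), function(v) {
        if (length(unique(X[, v])) > k) sprintf("s(`%s`, k = %d)", v, k)
        else sprintf("`%s`", v)
      }, character(1))
      f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      m <- mgcv::gam(f, data = d, family = binomial(), weights = w,
                     select = hp$select %||% TRUE, method = "REML")
      wrap_fit("GAM", m, function(m, nd) {
        as.numeric(predict(m, newdata = data.frame(nd, check.names = FALSE),
                           type = "response"))
      })
    },
    CTA = {
      d <- df; d$.y <- factor(y, levels = c(0, 1))
      m <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = rpart::rpart.control(
                          minsplit = hp$minsplit %||% 5, cp = hp$cp %||% 0.001))
      wrap_fit("CTA", m, function(m, nd) {
        predict(m, newdata = data.frame(nd, check.names = FALSE))[, "1"]
      })
    },
    RF = {
      m <- withr_seed(seed, randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = hp$ntree %||% 500,
        mtry = hp$mtry %||% max(1, floor(sqrt(ncol(X))))
      ))
      wrap_fit("RF", m, function(m, nd) {
        predict(m, newdata = nd, type = "prob")[, "1"]
      })
    },
    GBM = fit_xgb("GBM", X, y, w, seed,
                  nrounds = hp$nrounds %||% 250, eta = hp$eta %||% 0.05,
                  max_depth = hp$max_depth %||% 3),
    XGBOOST = fit_xgb("XGBOOST", X, y, w, seed,
                      nrounds = hp$nrounds %||% 60, eta = hp$eta %||% 0.3,
                      max_depth = hp$max_depth %||% 6),
    ANN = {
      m <- withr_seed(seed, nnet::nnet(
        x = X, y = y, weights = w, size = hp$size %||% 5,
        decay = hp$decay %||% 0.01, maxit = hp$maxit %||% 200,
        entropy = TRUE, trace = FALSE
      ))
      wrap_fit("ANN", m, function(m, nd) as.numeric(predict(m, nd)))
    },
    MAXENT = ,
    MAXNET = {
      fs <- maxnet_feature_spec(
        fc = hp$fc %||% if (spec$name == "MAXENT") "LQHPT" else "LQ",
        rm = hp$rm %||% 1,
        n_hinge_knots = hp$n_hinge_knots %||% 50,
        n_threshold_knots = hp$n_threshold_knots %||% 50
      )
      m <- fit_maxnet(X[y == 1, , drop = FALSE], X[y == 0, , drop = FALSE],
                      fs, weights = c(w[y == 1], w[y == 0]))
      m$algorithm <- spec$name
      m
    },
    SRE = fit_sre(X[y == 1, , drop = FALSE], q = hp$q %||% 0.025),
    abort_sdm(sprintf("no backend available for learner '%s'", spec$name),
              "sdmflow_fit_error")
  )
  fit
}

fit_xgb <- function(name, X, y, w, seed, nrounds, eta, max_depth) {
  d <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
  m <- withr_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta,
                  max_depth = max_depth, nthread = 1,
                  seed = derive_seed(seed, "xgb")),
    data = d, nrounds = nrounds, verbose = 0
  ))
  wrap_fit(name, m, function(m, nd) as.numeric(predict(m, nd)))
}

wrap_fit <- function(algorithm, fit, predict_fun) {
  structure(
    list(algorithm = algorithm, fit = fit, predict_fun = predict_fun),
    class = c("wrapped_fit", "sdm_fit")
  )
}

#' @export
predict.wrapped_fit <- function(object, newdata, ...) {
  p <- object$predict_fun(object$fit, as.matrix(newdata))
  p[!is.finite(p)] <- 0
  clamp01(p)
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s\n", x$algorithm))
  invisible(x)
}
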