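test_that("the surface range envelope matches order-statistics quantiles", {
  set.seed(3)
  X <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))

  # q = 0: min-max box membership
  sre0 <- fit_sre(X, q = 0)
  inside <- c(mean(X[, 1]), mean(X[, 2]))
  outside <- c(max(X[, 1]) + 0.1, mean(X[, 2]))
  expect_equal(predict(sre0, rbind(inside, outside) |>
                         `colnames<-`(c("a", "b"))), c(1, 0))

  # q = 0.025 bounds against a hand-rolled interpolation oracle:
  # position 1 + q (n - 1) between the sorted values
  sre <- fit_sre(X, q = 0.025)
  for (j in 1:2) {
    s <- sort(X[, j])
    h <- 1 + 0.025 * (100 - 1)
    lo <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
    h2 <- 1 + 0.975 * (100 - 1)
    hi <- s[floor(h2)] + (h2 - floor(h2)) * (s[floor(h2) + 1] - s[floor(h2)])
    expect_equal(unname(sre$lower[j]), lo)
    expect_equal(unname(sre$upper[j]), hi)
  }

  # predictions are strictly binary, and q >= 0.5 is rejected
  p <- predict(sre, X)
  expect_true(all(p %in% c(0, 1)))
  expect_error(fit_sre(X, q = 0.5), class = "sdmflow_parameter_error")
})

test_that("feature expansion counts follow the closed-form formula", {
  set.seed(5)
  X <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(ncol(build_features(X, maxnet_feature_spec("L"))$F), 3)
  expect_equal(ncol(build_features(X, maxnet_feature_spec("LQ"))$F), 6)
  # LQHP with 3 vars and 50 hinge knots: 3 + 3 + 3*2*50 + 3 = 309
  f <- build_features(X, maxnet_feature_spec("LQHP", n_hinge_knots = 50))
  expect_equal(ncol(f$F), 309)
  # the counting formula matches the built matrix for every default FC
  for (fc in c("L", "LQ", "LQH", "H", "LQHP", "LQHPT")) {
    for (nv in 2:4) {
      Xn <- matrix(runif(20 * nv), 20,
                   dimnames = list(NULL, paste0("x", 1:nv)))
      spec <- maxnet_feature_spec(fc, n_hinge_knots = 7, n_threshold_knots = 5)
      expect_equal(ncol(build_features(Xn, spec)$F), count_features(nv, spec))
    }
  }
  # degenerate (constant) variables are skipped with a warning
  Xd <- cbind(X, d = rep(0.5, 20))
  expect_warning(fd <- build_features(Xd, maxnet_feature_spec("L")), "degenerate")
  expect_equal(ncol(fd$F), 3)
})

test_that("the penalized presence/background learner behaves at the RM limits", {
  set.seed(11)
  n <- 200
  x1 <- c(rnorm(n, 2), rnorm(n, -2))
  X <- cbind(x1 = x1, x2 = rnorm(2 * n))
  Xp <- X[1:n, ]; Xb <- X[(n + 1):(2 * n), ]

  # separable limit: near-zero RM gives training AUC ~ 1
  m_lo <- fit_maxnet(Xp, Xb, maxnet_feature_spec("L", rm = 1e-4))
  auc_lo <- eval_auc(c(rep(1, n), rep(0, n)), predict(m_lo, X))
  expect_gt(auc_lo, 0.99)

  # heavy-penalty limit: all coefficients 0, predictions constant
  m_hi <- fit_maxnet(Xp, Xb, maxnet_feature_spec("L", rm = 1e6))
  expect_equal(m_hi$n_nonzero, 0)
  expect_equal(sd(predict(m_hi, X)), 0)
})

test_that("maxnet recovers the coefficients of a known logistic truth", {
  # presences kept rare (low baseline rate) so the presence/background
  # log-density ratio is the truth's linear predictor up to a constant
  set.seed(21)
  N <- 40000
  X <- cbind(x1 = runif(N), x2 = runif(N))
  p <- plogis(4 * X[, "x1"] - 2 * X[, "x2"] - 6)
  pres <- which(runif(N) < p)
  Xp <- X[pres[1:500], ]
  Xb <- X[sample(N, 500), ]
  m <- fit_maxnet(Xp, Xb, maxnet_feature_spec("L", rm = 0.1))
  b <- setNames(m$beta, m$feature_names)
  # features are scaled by the background range, so unscale before comparing
  rng <- m$scaling$max - m$scaling$min
  b1 <- b[["L_x1"]] / rng[["x1"]]
  b2 <- b[["L_x2"]] / rng[["x2"]]
  expect_gt(b1, 0)
  expect_lt(b2, 0)
  expect_equal(abs(b1 / b2), 2, tolerance = 0.3)
})

test_that("AICc follows the small-sample formula and its guard", {
  set.seed(31)
  X <- cbind(x = rnorm(100))
  Xp <- X[1:40, , drop = FALSE]; Xb <- X[41:100, , drop = FALSE]

  # all-zero coefficients (huge RM): k = 0, every point gets probability
  # 1/N, so AICc = -2 * n_presence * log(1/N) exactly
  m0 <- fit_maxnet(Xp, Xb, maxnet_feature_spec("L", rm = 1e6))
  expect_equal(maxnet_aicc(m0, Xp, Xb), -2 * 40 * log(1 / 100))

  # direct arithmetic of the penalty: with k = 3, n = 10, lnL = -25 the
  # formula gives 6 + 50 + 24/6 = 60; monotone in k at equal likelihood
  aicc_formula <- function(k, n, lnL) 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(aicc_formula(3, 10, -25), 60)
  expect_lt(aicc_formula(2, 30, -25), aicc_formula(4, 30, -25))

  # n - k - 1 <= 0 renders the criterion undefined
  m_bad <- m0
  m_bad$n_nonzero <- 39
  expect_true(is.na(maxnet_aicc(m_bad, Xp, Xb)))
})

test_that("RM x FC tuning enumerates the grid and breaks ties deterministically", {
  set.seed(41)
  n <- 60
  X <- cbind(x1 = c(rnorm(n, 1.5), rnorm(n, -1.5)), x2 = rnorm(2 * n))
  Xp <- X[1:n, ]; Xb <- X[(n + 1):(2 * n), ]
  tun <- tune_maxnet(Xp, Xb, n_hinge_knots = 5, n_threshold_knots = 5,
                     seed = 2)
  # the default grids: 8 RM values x 6 FC strings = 48 combinations
  expect_equal(nrow(tun$grid), 48)
  expect_equal(dplyr::n_distinct(tun$grid$rm), 8)
  expect_equal(dplyr::n_distinct(tun$grid$fc), 6)
  expect_true(all(tun$grid$delta_aicc[tun$grid$valid] >= 0))
  chosen_row <- tun$grid[tun$grid$rm == tun$chosen$rm &
                           tun$grid$fc == tun$chosen$fc, ]
  expect_equal(chosen_row$delta_aicc, 0)
  expect_true(all(tun$grid$reliable == (tun$grid$valid & tun$grid$delta_aicc < 2)))

  # a single-combination grid is chosen trivially
  tun1 <- tune_maxnet(Xp, Xb, rm_grid = 1, fc_grid = "LQ", seed = 2)
  expect_equal(nrow(tun1$grid), 1)
  expect_equal(tun1$chosen$fc, "LQ")
  expect_equal(tun1$grid$delta_aicc, 0)
})

test_that("AICc tuning does not over-select complex feature classes", {
  # truth is linear-only; the chosen FC should be L or LQ in most replicates
  hits <- 0
  for (s in 1:5) {
    set.seed(500 + s)
    N <- 2000
    X <- cbind(x1 = runif(N), x2 = runif(N))
    p <- plogis(6 * X[, "x1"] - 3)
    pres <- which(runif(N) < p)
    Xp <- X[pres[1:80], ]
    Xb <- X[sample(N, 200), ]
    tun <- tune_maxnet(Xp, Xb, n_hinge_knots = 5, n_threshold_knots = 5,
                       seed = s)
    if (tun$chosen$fc %in% c("L", "LQ")) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("standard learners honour the uniform predict contract", {
  sim <- small_sim()
  pres <- thin_occurrences(sim$presences, 1, seed = 1, distance = "euclidean")
  pa <- sample_pseudo_absences(sim$stack, pres, n_points = 150, n_sets = 1,
                               seed = 2)
  ds <- assemble_datasets(sim$stack, pres, pa,
                          layers = c("env01", "env02", "env03"),
                          n_reps = 1, seed = 3)[[1]]
  for (alg in c("GLM", "GAM", "CTA", "RF", "GBM", "ANN", "XGBOOST", "SRE")) {
    fit <- fit_learner(alg, ds$X, ds$y, ds$w, seed = 5)
    p <- predict(fit, ds$X)
    expect_true(all(is.finite(p)), info = alg)
    expect_true(all(p >= 0 & p <= 1), info = alg)
  }
  # learners without a backend raise the fit-error condition
  expect_error(fit_learner("FDA", ds$X, ds$y, ds$w), class = "sdmflow_fit_error")
  expect_error(fit_learner("MARS", ds$X, ds$y, ds$w), class = "sdmflow_fit_error")
  # unknown hyperparameters are rejected up front
  expect_error(learner_spec("RF", bogus = 1), class = "sdmflow_parameter_error")
})

test_that("GLM recovers the signs of the synthetic truth", {
  set.seed(61)
  N <- 600
  X <- cbind(a = rnorm(N), b = rnorm(N))
  y <- as.integer(runif(N) < plogis(1.5 * X[, "a"] - 1 * X[, "b"]))
  fit <- fit_learner("GLM", X, y)
  cf <- stats::coef(fit$fit)
  expect_gt(cf[["a"]], 0)
  expect_lt(cf[["b"]], 0)
  # RF separates a linearly separable toy problem perfectly in-sample
  ysep <- as.integer(X[, "a"] > 0)
  rf <- fit_learner("RF", X, ysep, seed = 3)
  expect_equal(eval_auc(ysep, predict(rf, X)), 1)
})
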