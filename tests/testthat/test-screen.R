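test_that("permutation importance isolates the variables a model uses", {
  set.seed(8)
  X <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))

  # model ignoring every variable -> constant predictions, all zero + warning
  expect_warning(
    imp0 <- permutation_importance(const_model(0.4), X, seed = 1),
    "constant"
  )
  expect_equal(imp0$contribution, c(0, 0, 0))

  # single-variable model -> that variable carries 100%
  m1 <- toy_model(function(X) plogis(X[, "b"]))
  imp1 <- permutation_importance(m1, X, seed = 1)
  expect_equal(imp1$contribution[imp1$variable == "b"], 100)
  expect_equal(sum(imp1$contribution), 100)

  # linear score 2a + c on independent standardized columns: a dominates,
  # and a 5-shuffle estimate agrees with a high-replicate run of the same
  # estimator within a few percent
  m2 <- toy_model(function(X) plogis(2 * X[, "a"] + X[, "c"]))
  imp5 <- permutation_importance(m2, X, n_shuffles = 5, seed = 2)
  imp_hi <- permutation_importance(m2, X, n_shuffles = 400, seed = 3)
  expect_gt(imp5$contribution[imp5$variable == "a"],
            imp5$contribution[imp5$variable == "c"])
  expect_equal(imp5$contribution, imp_hi$contribution, tolerance = 0.15)
  expect_equal(imp_hi$contribution[imp_hi$variable == "b"], 0,
               tolerance = 0.02)
})

test_that("pearson_matrix reproduces direct product-moment correlations", {
  st <- small_sim()$stack
  r <- pearson_matrix(st)
  expect_equal(diag(r), setNames(rep(1, 12), stack_layers(st)))
  expect_true(all(abs(r) <= 1 + 1e-12))
  expect_equal(r, t(r))

  # direct covariance-formula oracle for one pair
  v <- stack_values(st, c("env05", "env06"))
  x <- v[, 1]; y <- v[, 2]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["env05", "env06"], r_direct)
  # independent smooth layers are nearly uncorrelated
  expect_lt(abs(r["env05", "env06"]), 0.3)

  # negation gives exactly -1; engineered near-duplicates are ~0.95
  m <- cbind(a = x, b = -x)
  expect_equal(pearson_matrix(m)["a", "b"], -1)
  expect_gt(abs(r["env01", "env11"]), 0.9)

  # zero-variance column: flagged warning, correlation reported as 0
  expect_warning(rz <- pearson_matrix(cbind(a = x, z = rep(1, length(x)))),
                 "zero-variance")
  expect_equal(rz["a", "z"], 0)
})

test_that("screening applies the contribution and collinearity rules greedily", {
  imp <- tibble::tibble(variable = c("a", "b", "c"),
                        contribution = c(40, 35, 0.3))
  cors <- diag(3); dimnames(cors) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cors["a", "b"] <- cors["b", "a"] <- 0.9
  log <- screen_variables(imp, cors)
  expect_equal(screened_variables(log), "a")
  expect_equal(log$reason[log$variable == "b"], "correlated")
  expect_equal(log$partner[log$variable == "b"], "a")
  expect_equal(log$reason[log$variable == "c"], "low_contribution")

  # nothing to drop -> everything retained
  imp2 <- tibble::tibble(variable = c("a", "b"), contribution = c(60, 40))
  cors2 <- diag(2); dimnames(cors2) <- list(c("a", "b"), c("a", "b"))
  expect_equal(screened_variables(screen_variables(imp2, cors2)), c("a", "b"))

  # an exact duplicate (r = 1) with lower contribution loses to the original
  imp3 <- tibble::tibble(variable = c("x", "x_copy"), contribution = c(55, 45))
  cors3 <- matrix(1, 2, 2, dimnames = list(c("x", "x_copy"), c("x", "x_copy")))
  log3 <- screen_variables(imp3, cors3)
  expect_equal(screened_variables(log3), "x")
  expect_equal(log3$partner[log3$variable == "x_copy"], "x")

  # a contribution exactly at the threshold is retained and flagged boundary
  imp4 <- tibble::tibble(variable = c("a", "b"), contribution = c(99.5, 0.5))
  log4 <- screen_variables(imp4, cors2 |> `dimnames<-`(list(c("a", "b"), c("a", "b"))))
  expect_true("b" %in% screened_variables(log4))
  expect_true(log4$boundary[log4$variable == "b"])
  # ... and strictly below it is dropped
  imp5 <- tibble::tibble(variable = c("a", "b"), contribution = c(99.51, 0.49))
  expect_false("b" %in% screened_variables(screen_variables(imp5, cors2 |>
    `dimnames<-`(list(c("a", "b"), c("a", "b"))))))
})

test_that("retained sets are always correlation-feasible (property)", {
  for (s in 1:10) {
    set.seed(s)
    n <- 8
    vars <- paste0("v", 1:n)
    # random correlation matrix from random data, random contributions
    X <- matrix(rnorm(50 * n), 50, n, dimnames = list(NULL, vars))
    X[, 4] <- X[, 2] + rnorm(50, sd = 0.05)  # engineered near-duplicate
    cors <- pearson_matrix(X)
    imp <- tibble::tibble(variable = vars,
                          contribution = as.numeric(rmultinom(1, 1000, rep(1, n))) / 10)
    kept <- screened_variables(screen_variables(imp, cors))
    if (length(kept) > 1) {
      sub <- abs(cors[kept, kept]); diag(sub) <- 0
      expect_lt(max(sub), 0.8)
    }
    # at most one of the near-duplicate pair survives
    expect_lte(sum(c("v2", "v4") %in% kept), 1)
  }
})
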