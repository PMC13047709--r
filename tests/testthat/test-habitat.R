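# Grades, binary maps, change/transition accounting. Constant 1 km2 cells
# make areas equal cell counts throughout.

suit <- function(values, nr = 1, scenario = "current") {
  suitability_map(grid_spec(nr, length(values) / nr),
                  matrix(values, nr), scenario)
}

test_that("grade breakpoints put boundaries in the lower class", {
  g <- classify_suitability(suit(c(0, 0.3, 0.31, 0.6, 0.61, 0.85, 0.86, 1)))
  expect_equal(as.vector(g$values), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_error(classify_suitability(suit(c(0.5, 1.2))),
               class = "sdmflow_domain_error")
})

test_that("binarization uses a strict cutoff with 0.3 mapping to absence", {
  b <- binarize_suitability(suit(c(0, 0.29, 0.30, 0.31, 1)))
  expect_equal(as.vector(b$values), c(0, 0, 0, 1, 1))
  b0 <- binarize_suitability(suit(rep(0, 5)))
  expect_equal(sum(b0$values), 0)
})

test_that("per-class area shares reproduce the printed-arithmetic fixture", {
  # 100 cells of 1 km2: 40 low, 10 moderate
  P <- c(rep(0.1, 50), rep(0.5, 40), rep(0.7, 10))
  t1 <- grade_areas(classify_suitability(suit(P)))
  expect_equal(t1$area_km2[t1$class == "low"], 40)
  expect_equal(t1$area_km2[t1$class == "moderate"], 10)
  expect_equal(t1$area_km2[t1$class == "high"], 0)
  expect_equal(t1$pct_of_suitable[t1$class == "high"], 0)

  # component areas proportional to 38.98 / 23.61 / 1.30 (x 1e4 km2)
  # yield suitable-total shares 61.01% / 36.95% / 2.03%
  P2 <- c(rep(0.5, 3898), rep(0.7, 2361), rep(0.9, 130))
  t2 <- grade_areas(classify_suitability(suit(P2)))
  shares <- round(t2$pct_of_suitable[t2$code > 1], 2)
  expect_equal(shares, c(61.01, 36.95, 2.03))
  # class areas always sum to the total valid area
  expect_equal(sum(t2$area_km2), 6389)
})

test_that("change maps partition the domain and conserve area", {
  sp <- grid_spec(8, 8)
  prev <- binarize_suitability(suitability_map(sp, matrix(0.5, 8, 8), "a"))
  nxt <- binarize_suitability(suitability_map(sp, matrix(0.5, 8, 8), "b"))

  # identical maps: no gain, no loss
  cm_same <- change_map(prev, nxt)
  a <- setNames(cm_same$areas$area_km2, cm_same$areas$category)
  expect_equal(a[["gain"]], 0)
  expect_equal(a[["loss"]], 0)
  expect_equal(a[["retained"]], 64)

  # all-absent to all-present: gain equals the whole valid area
  prev0 <- binarize_suitability(suitability_map(sp, matrix(0.1, 8, 8), "a"))
  cm_gain <- change_map(prev0, nxt)
  expect_equal(setNames(cm_gain$areas$area_km2,
                        cm_gain$areas$category)[["gain"]], 64)

  # checkerboard vs its inverse: half gain, half loss
  cb <- matrix(rep(c(0.1, 0.9), 32), 8, 8)
  cm_cb <- change_map(
    binarize_suitability(suitability_map(sp, cb, "a")),
    binarize_suitability(suitability_map(sp, 1 - cb, "b"))
  )
  acb <- setNames(cm_cb$areas$area_km2, cm_cb$areas$category)
  expect_equal(acb[["gain"]], 32)
  expect_equal(acb[["loss"]], 32)

  # conservation on random masked maps: the four categories tile the
  # jointly valid area exactly
  for (s in 1:5) {
    set.seed(s)
    v1 <- matrix(runif(64), 8, 8); v1[sample(64, 6)] <- NA
    v2 <- matrix(runif(64), 8, 8); v2[sample(64, 6)] <- NA
    cm <- change_map(binarize_suitability(suitability_map(sp, v1, "a")),
                     binarize_suitability(suitability_map(sp, v2, "b")))
    expect_equal(sum(cm$areas$area_km2), sum(!is.na(v1) & !is.na(v2)))
  }

  # misaligned grids are refused
  prev_bad <- binarize_suitability(
    suitability_map(grid_spec(8, 8, x_origin = 0.01), matrix(0.5, 8, 8), "a"))
  expect_error(change_map(prev_bad, nxt), class = "sdmflow_alignment_error")
})

test_that("expansion/contraction rates reproduce the reported identities", {
  # gain 10.75, retained 22.37, loss 2.08 -> baseline 24.45,
  # expansion 43.97%, contraction 8.51%
  r <- change_rates(gain = 10.75, loss = 2.08, retained = 22.37)
  expect_equal(round(r$expansion_rate, 2), 43.97)
  expect_equal(round(r$contraction_rate, 2), 8.51)
  # loss 7.31 on the same baseline -> contraction 29.90%
  r2 <- change_rates(gain = 2.25, loss = 7.31, retained = 17.14)
  expect_equal(round(r2$contraction_rate, 2), 29.90)
  # no gain -> zero expansion; zero baseline -> domain error
  expect_equal(change_rates(0, 1, 9)$expansion_rate, 0)
  expect_error(change_rates(1, 0, 0), class = "sdmflow_domain_error")
})

test_that("transition codes are A*10+B and the matrix margins match grade areas", {
  sp <- grid_spec(2, 2)
  gp <- classify_suitability(suitability_map(sp, matrix(0.7, 2, 2), "a"))
  gn <- classify_suitability(suitability_map(sp, matrix(0.5, 2, 2), "b"))
  tm <- transition_map(gp, gn)
  expect_equal(unique(as.vector(tm$values)), 32L)
  expect_equal(tm$area_matrix["moderate", "low"], 4)

  # equal maps populate only the diagonal
  tm_same <- transition_map(gp, gp)
  expect_equal(sum(tm_same$area_matrix) - sum(diag(tm_same$area_matrix)), 0)

  # uniform unsuitable -> low on half the cells
  half <- matrix(c(0.1, 0.1, 0.5, 0.5), 2, 2)
  tm_half <- transition_map(
    classify_suitability(suitability_map(sp, matrix(0.1, 2, 2), "a")),
    classify_suitability(suitability_map(sp, half, "b"))
  )
  expect_equal(tm_half$area_matrix["unsuitable", "low"], 2)

  # margins: row sums = previous grade areas, column sums = subsequent
  for (s in 1:5) {
    set.seed(10 + s)
    sp8 <- grid_spec(8, 8)
    v1 <- matrix(runif(64), 8, 8); v1[sample(64, 5)] <- NA
    v2 <- matrix(runif(64), 8, 8)
    g1 <- classify_suitability(suitability_map(sp8, v1, "a"))
    g2 <- classify_suitability(suitability_map(sp8, v2, "b"))
    tmx <- transition_map(g1, g2)
    joint <- !is.na(v1)
    g1m <- g1; g1m$values[!joint] <- NA
    g2m <- g2; g2m$values[!joint] <- NA
    expect_equal(unname(rowSums(tmx$area_matrix)),
                 grade_areas(g1m)$area_km2)
    expect_equal(unname(colSums(tmx$area_matrix)),
                 grade_areas(g2m)$area_km2)
  }
})

test_that("profiles bin habitat area along latitude and elevation", {
  # single-row grid: all area in one occupied latitude bin
  g1 <- classify_suitability(suit(c(0.5, 0.5, 0.7), nr = 1))
  st1 <- env_stack(g1$spec, list(elev = matrix(c(100, 200, 300), 1)))
  pr <- habitat_profiles(g1, st1, "latitude", n_bins = 4)
  occupied <- pr |> dplyr::group_by(bin) |>
    dplyr::summarise(a = sum(area_km2))
  expect_equal(sum(occupied$a > 0), 1)
  expect_equal(sum(pr$area_km2), 3)
  # a grade absent everywhere yields an all-zero row
  expect_equal(sum(pr$area_km2[pr$grade == 4]), 0)

  # suitability decreasing with elevation: the modal suitable bin sits in
  # the lower half of the elevation range
  set.seed(3)
  n <- 30
  elev <- matrix(seq(0, 3000, length.out = n * n), n, n)
  P <- plogis(3 - elev / 600)
  g <- classify_suitability(suitability_map(grid_spec(n, n), P))
  st <- env_stack(grid_spec(n, n), list(elev = elev))
  pe <- habitat_profiles(g, st, "elevation", n_bins = 10)
  suit_by_bin <- pe |> dplyr::filter(grade >= 2) |>
    dplyr::group_by(bin) |> dplyr::summarise(a = sum(area_km2))
  expect_lt(suit_by_bin$bin[which.max(suit_by_bin$a)], 5.5)

  expect_error(habitat_profiles(g1, env_stack(g1$spec,
    list(x = matrix(1, 1, 3))), "elevation"), class = "sdmflow_lookup_error")
})
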