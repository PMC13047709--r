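test_that("thinning removes neighbours within the radius and keeps the rest", {
  # two records 0.5 km apart -> one survives a 1 km radius
  close_pair <- points_km_apart(0.5)
  expect_equal(nrow(thin_occurrences(close_pair, 1, seed = 1)), 1)
  # two records 1.5 km apart -> both survive
  far_pair <- points_km_apart(1.5)
  expect_equal(nrow(thin_occurrences(far_pair, 1, seed = 1)), 2)
  # five records on a 0.4 km segment are mutually conflicting: one survives
  seg <- tibble::tibble(species = "t", longitude = 100,
                        latitude = 25 + seq(0, 0.4, length.out = 5) / 111.32,
                        source = NA)
  expect_equal(nrow(thin_occurrences(seg, 1, seed = 3)), 1)
  # a single record returns itself
  expect_equal(nrow(thin_occurrences(seg[1, ], 1, seed = 1)), 1)
})

test_that("thinned sets satisfy the pairwise-distance property (oracle check)", {
  for (s in 1:5) {
    set.seed(100 + s)
    occ <- tibble::tibble(species = "t",
                          longitude = runif(60, 0, 10),
                          latitude = runif(60, 0, 10), source = NA)
    kept <- thin_occurrences(occ, radius_km = 2, seed = s,
                             distance = "euclidean")
    # exhaustive pairwise check of the retained records
    d <- as.matrix(stats::dist(cbind(kept$longitude, kept$latitude)))
    diag(d) <- Inf
    expect_gt(min(d), 2)
    # greedy maximality: every dropped record conflicts with a kept one
    dropped <- dplyr::anti_join(occ, kept, by = c("longitude", "latitude"))
    if (nrow(dropped) > 0) {
      dmin <- apply(
        outer(dropped$longitude, kept$longitude, "-")^2 +
          outer(dropped$latitude, kept$latitude, "-")^2, 1,
        function(r) sqrt(min(r))
      )
      expect_true(all(dmin <= 2))
    }
  }
})

test_that("pseudo-absence sampling is uniform over eligible cells, seeded and sized", {
  st <- tiny_stack(10)  # one masked cell -> 99 valid
  pres <- tibble::tibble(longitude = c(0.5, 1.5), latitude = c(0.5, 0.5))
  pa <- sample_pseudo_absences(st, pres, n_points = 50, n_sets = 2, seed = 7)
  expect_equal(nrow(pa), 100)
  for (k in 1:2) {
    pk <- pa[pa$pa_set == k, ]
    cells <- paste(pk$longitude, pk$latitude)
    expect_equal(length(unique(cells)), 50)    # without replacement
    expect_false(any(pk$longitude %in% c(0.5, 1.5) & pk$latitude == 0.5))
  }
  # the two sets are differently seeded
  expect_false(identical(pa[pa$pa_set == 1, 1:2], pa[pa$pa_set == 2, 1:2]))
  # same seed -> identical draw
  pa2 <- sample_pseudo_absences(st, pres, n_points = 50, n_sets = 2, seed = 7)
  expect_identical(pa, pa2)
  # requesting exactly all eligible cells returns all of them
  all_pa <- sample_pseudo_absences(st, pres, n_points = 97, n_sets = 1, seed = 1)
  expect_equal(nrow(all_pa), 97)
  # oversized requests are a sizing error with counts in the message
  expect_error(sample_pseudo_absences(st, pres, n_points = 98, seed = 1),
               class = "sdmflow_sizing_error")
})

test_that("prevalence weighting equalizes class weight sums at 0.5", {
  st <- tiny_stack(40, hole = c(2, 2))
  # 59 presences vs 1000 pseudo-absences: the protocol's canonical counts
  set.seed(1)
  idx <- sample(which(st$mask), 59)
  pres <- tibble::tibble(
    longitude = ((idx - 1) %/% 40) + 0.5,
    latitude = 40 - ((idx - 1) %% 40) - 0.5
  )
  pa <- sample_pseudo_absences(st, pres, n_points = 1000, n_sets = 1, seed = 2)
  ds <- assemble_datasets(st, pres, pa, prevalence = 0.5, n_reps = 2,
                          seed = 3)[[1]]
  expect_equal(unique(ds$w[ds$y == 0]), 0.059)
  expect_equal(sum(ds$w[ds$y == 1]), sum(ds$w[ds$y == 0]))
  expect_equal(sum(ds$w[ds$y == 1]), 59)

  # equal counts at prevalence 0.5 -> unit weights everywhere
  pa_eq <- sample_pseudo_absences(st, pres, n_points = 59, n_sets = 1, seed = 4)
  ds_eq <- assemble_datasets(st, pres, pa_eq, n_reps = 1, seed = 3)[[1]]
  expect_true(all(ds_eq$w == 1))

  # conservation holds for arbitrary counts when prevalence = 0.5
  for (npa in c(13, 101, 350)) {
    pa_n <- sample_pseudo_absences(st, pres, n_points = npa, n_sets = 1,
                                   seed = npa)
    ds_n <- assemble_datasets(st, pres, pa_n, n_reps = 1, seed = 3)[[1]]
    expect_equal(sum(ds_n$w[ds_n$y == 1]), sum(ds_n$w[ds_n$y == 0]))
  }
})

test_that("train/test splits are stratified, sized by the floor/ceil rule and reproducible", {
  st <- tiny_stack(12, hole = c(1, 2))
  set.seed(2)
  idx <- sample(which(st$mask), 8)
  pres <- tibble::tibble(
    longitude = ((idx - 1) %/% 12) + 0.5,
    latitude = 12 - ((idx - 1) %% 12) - 0.5
  )
  pa <- sample_pseudo_absences(st, pres, n_points = 20, n_sets = 1, seed = 5)
  ds <- assemble_datasets(st, pres, pa, n_reps = 10, train_frac = 0.75,
                          seed = 11)[[1]]
  for (r in seq_along(ds$reps)) {
    train <- ds$reps[[r]]
    # 8 presences -> 6 train / 2 test; 20 PA -> 15 train / 5 test
    expect_equal(sum(train & ds$y == 1), 6)
    expect_equal(sum(!train & ds$y == 1), 2)
    expect_equal(sum(train & ds$y == 0), 15)
    expect_equal(sum(!train & ds$y == 0), 5)
  }
  ds2 <- assemble_datasets(st, pres, pa, n_reps = 10, train_frac = 0.75,
                           seed = 11)[[1]]
  expect_identical(ds$reps, ds2$reps)
  # under 4 presences the split is refused
  expect_error(
    assemble_datasets(st, pres[1:3, ], pa, n_reps = 2, seed = 1),
    class = "sdmflow_split_error"
  )
})
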