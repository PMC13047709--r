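#' Read an occurrence CSV
#'
#' Expects a header `species,longitude,latitude[,source]` with coordinates in
#' decimal degrees (WGS84) for geographic grids, or map units otherwise.
#' Records with non-finite coordinates are dropped with a message.
#'
#' @param path CSV path.
#' @return Tibble with columns `species`, `longitude`, `latitude`, `source`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df))) {
    abort_sdm("occurrence CSV must have columns species, longitude, latitude",
              "sdmflow_io_error")
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  df <- tibble::as_tibble(df[, c("species", "longitude", "latitude", "source")])
  keep <- is.finite(df$longitude) & is.finite(df$latitude)
  if (any(!keep)) {
    message(sprintf("dropped %d record(s) with non-finite coordinates", sum(!keep)))
  }
  df[keep, ]
}

# Pairwise distance from one point to many, in the units thinning uses
# (km for great-circle, coordinate units for euclidean).
point_distances <- function(x0, y0, x, y, mode) {
  if (mode == "great-circle") {
    geosphere::distHaversine(c(x0, y0), cbind(x, y)) / 1000
  } else {
    sqrt((x - x0)^2 + (y - y0)^2)
  }
}

#' Spatially thin occurrence records
#'
#' Greedy minimum-distance filter against spatial sampling autocorrelation:
#' records are shuffled by `seed`, then scanned once, keeping a record iff
#' its distance to every already-kept record exceeds `radius_km`. The result
#' therefore depends on the shuffle order, which is why the seed is part of
#' the contract; the retained set always satisfies the pairwise-distance
#' property regardless of order.
#'
#' @param occ Data frame with `longitude`/`latitude` columns.
#' @param radius_km Exclusion radius. Interpreted in km for
#'   `distance = "great-circle"` and in coordinate units for `"euclidean"`.
#' @param seed Integer seed for the shuffle.
#' @param distance `"great-circle"` (haversine on lon/lat degrees) or
#'   `"euclidean"`.
#' @return The retained subset of `occ` (original row order).
#' @export
thin_occurrences <- function(occ, radius_km = 1, seed = 1,
                             distance = c("great-circle", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(radius_km > 0, nrow(occ) >= 1)
  ord <- withr_seed(seed, sample.int(nrow(occ)))
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L) {
      kept <- i
      next
    }
    d <- point_distances(occ$longitude[i], occ$latitude[i],
                         occ$longitude[kept], occ$latitude[kept], distance)
    if (all(d > radius_km)) kept <- c(kept, i)
  }
  occ[sort(kept), , drop = FALSE]
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Sample pseudo-absence point sets
#'
#' Draws `n_sets` independent sets of `n_points` background ("pseudo-
#' absence") points, uniformly without replacement over valid cells that do
#' not contain a presence record (when `exclude_presence_cells`). Points are
#' placed at cell centres. Set `k` is seeded with `seed + k` so the sets are
#' disjointly seeded and individually reproducible.
#'
#' @param stack An [env_stack()].
#' @param presences Data frame with `longitude`/`latitude` columns.
#' @param n_points Points per set (default 1000).
#' @param n_sets Number of sets (default 2).
#' @param seed Integer base seed.
#' @param exclude_presence_cells Exclude cells holding a presence record.
#' @return Tibble with columns `longitude`, `latitude`, `pa_set`.
#' @export
sample_pseudo_absences <- function(stack, presences, n_points = 1000,
                                   n_sets = 2, seed = 1,
                                   exclude_presence_cells = TRUE) {
  spec <- stack$spec
  eligible <- which(stack$mask)
  if (exclude_presence_cells && nrow(presences) > 0) {
    pc <- point_to_cell(spec, presences$longitude, presences$latitude)
    ok <- !pc$out_of_bounds
    pres_idx <- unique((pc$col[ok] - 1L) * spec$n_rows + pc$row[ok])
    eligible <- setdiff(eligible, pres_idx)
  }
  if (n_points > length(eligible)) {
    abort_sdm(sprintf("requested %d pseudo-absences but only %d eligible cells",
                      n_points, length(eligible)),
              "sdmflow_sizing_error")
  }
  xs <- col_centres(spec); ys <- row_centres(spec)
  out <- purrr::map_dfr(seq_len(n_sets), function(k) {
    cells <- withr_seed(seed + k, sample(eligible, n_points))
    row <- ((cells - 1L) %% spec$n_rows) + 1L
    col <- ((cells - 1L) %/% spec$n_rows) + 1L
    tibble::tibble(longitude = xs[col], latitude = ys[row], pa_set = k)
  })
  out
}

#' Assemble modelling datasets
#'
#' Builds one presence/pseudo-absence dataset per pseudo-absence set:
#' predictors extracted from the stack, labels (presence 1, pseudo-absence
#' 0), prevalence weights, and the stratified train/test replicate structure.
#'
#' Weights: presences weigh 1; each pseudo-absence weighs
#' `(n_presence / n_pa) * (prevalence / (1 - prevalence))`, so at prevalence
#' 0.5 the weighted sums of the two classes are equal regardless of counts.
#'
#' Splits: for each of `n_reps` repetitions, `round(train_frac * n)` points
#' of each class train (reduced by one when that would leave an empty test
#' fold), the remainder test.
#'
#' @param stack An [env_stack()].
#' @param presences Data frame of presence points (`longitude`/`latitude`).
#' @param pa_points Output of [sample_pseudo_absences()] (`pa_set` column).
#' @param layers Predictor layers to extract (default: all).
#' @param prevalence Target presence prevalence (default 0.5).
#' @param n_reps Number of train/test repetitions (default 10).
#' @param train_frac Training fraction per class (default 0.75).
#' @param seed Integer seed for the splits.
#' @return List of `modeling_dataset` objects (one per pseudo-absence set),
#'   each with elements `X`, `y`, `w`, `pa_set`, `reps` (list of logical
#'   train-membership vectors) and `prevalence`.
#' @export
assemble_datasets <- function(stack, presences, pa_points, layers = NULL,
                              prevalence = 0.5, n_reps = 10,
                              train_frac = 0.75, seed = 1) {
  layers <- layers %||% names(stack$layers)
  pres_x <- extract_predictors(stack, presences, layers)
  pres_x <- pres_x[pres_x$.valid, layers, drop = FALSE]
  if (nrow(pres_x) < 4) {
    abort_sdm("fewer than 4 extractable presences: cannot split",
              "sdmflow_split_error")
  }
  purrr::map(sort(unique(pa_points$pa_set)), function(k) {
    pa <- pa_points[pa_points$pa_set == k, ]
    pa_x <- extract_predictors(stack, pa, layers)
    pa_x <- pa_x[pa_x$.valid, layers, drop = FALSE]
    n_p <- nrow(pres_x); n_a <- nrow(pa_x)
    w_pa <- (n_p / n_a) * (prevalence / (1 - prevalence))
    X <- as.matrix(rbind(pres_x, pa_x))
    y <- c(rep(1L, n_p), rep(0L, n_a))
    w <- c(rep(1, n_p), rep(w_pa, n_a))
    reps <- purrr::map(seq_len(n_reps), function(r) {
      s <- derive_seed(seed, "split", k * 1000L + r)
      train <- rep(FALSE, n_p + n_a)
      train[withr_seed(s, sample.int(n_p, train_count(n_p, train_frac)))] <- TRUE
      train[n_p + withr_seed(s + 1L, sample.int(n_a, train_count(n_a, train_frac)))] <- TRUE
      train
    })
    structure(
      list(X = X, y = y, w = w, pa_set = k, reps = reps,
           prevalence = prevalence, n_presence = n_p, n_absence = n_a),
      class = "modeling_dataset"
    )
  })
}

# Training-fold size: round(frac * n), reduced so the test fold keeps >= 1.
train_count <- function(n, frac) {
  k <- floor(frac * n + 0.5)
  if (k >= n) k <- n - 1L
  max(k, 1L)
}

#' @export
print.modeling_dataset <- function(x, ...) {
  cat(sprintf(
    "<modeling_dataset> PA set %d: %d presences + %d pseudo-absences, %d predictors, %d repetitions\n",
    x$pa_set, x$n_presence, x$n_absence, ncol(x$X), length(x$reps)
  ))
  invisible(x)
}
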