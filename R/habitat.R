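# Habitat products: the cascade suitability -> grades -> binary ->
# change/transition maps, with area accounting in units of 1e4 km2 at the
# reporting layer (full precision internally).

grade_labels <- c("unsuitable", "low", "moderate", "high")

new_map <- function(spec, values, scenario_id, class) {
  structure(list(spec = spec, values = values, scenario_id = scenario_id),
            class = c(class, "sdm_map"))
}

#' @export
print.sdm_map <- function(x, ...) {
  cat(sprintf("<%s> '%s' on %d x %d grid (%d valid cells)\n", class(x)[1],
              x$scenario_id, x$spec$n_rows, x$spec$n_cols,
              sum(!is.na(x$values))))
  invisible(x)
}

#' Project an ensemble (or single model) over a stack
#'
#' Scores every valid cell of the scenario stack and returns a suitability
#' map aligned with it.
#'
#' @param model An `sdm_ensemble` or `sdm_fit`.
#' @param stack An [env_stack()].
#' @param layers Predictor layers the model expects (default: all).
#' @return A `suitability_map`.
#' @export
project_suitability <- function(model, stack, layers = NULL) {
  vals <- stack_values(stack, layers)
  P <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  P[attr(vals, "cells")] <- predict(model, vals)
  new_map(stack$spec, P, stack$scenario_id, "suitability_map")
}

#' Wrap a suitability matrix as a map
#'
#' @param spec A [grid_spec()].
#' @param values Matrix of suitabilities in \[0, 1\] (`NA` = nodata).
#' @param scenario_id Scenario label.
#' @return A `suitability_map`.
#' @export
suitability_map <- function(spec, values, scenario_id = "current") {
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort_sdm("suitability values must lie in [0, 1]", "sdmflow_domain_error")
  }
  new_map(spec, values, scenario_id, "suitability_map")
}

#' Classify suitability into habitat grades
#'
#' Fixed breakpoints with half-open intervals: unsuitable
#' (0 <= P <= 0.3, code 1), low (0.3 < P <= 0.6, code 2), moderate
#' (0.6 < P <= 0.85, code 3), high (0.85 < P <= 1, code 4). The boundary
#' values 0.3, 0.6 and 0.85 belong to the lower grade.
#'
#' @param map A `suitability_map`.
#' @param breaks The three interior breakpoints (default `c(0.3, 0.6, 0.85)`).
#' @return A `grade_map` with integer codes 1-4.
#' @export
classify_suitability <- function(map, breaks = c(0.3, 0.6, 0.85)) {
  P <- map$values
  rng <- range(P, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort_sdm("suitability values must lie in [0, 1]", "sdmflow_domain_error")
  }
  g <- matrix(NA_integer_, nrow(P), ncol(P))
  ok <- !is.na(P)
  g[ok] <- 1L + (P[ok] > breaks[1]) + (P[ok] > breaks[2]) + (P[ok] > breaks[3])
  new_map(map$spec, g, map$scenario_id, "grade_map")
}

#' Binarize suitability into presence/absence
#'
#' Presence (1) iff `P > cut`; a cell exactly at the cutoff is absence,
#' consistent with the grading rule that places `P = 0.3` in the unsuitable
#' class.
#'
#' @param map A `suitability_map`.
#' @param cut Cutoff (default 0.3).
#' @return A `binary_map` with values 0/1.
#' @export
binarize_suitability <- function(map, cut = 0.3) {
  b <- matrix(NA_integer_, nrow(map$values), ncol(map$values))
  ok <- !is.na(map$values)
  b[ok] <- as.integer(map$values[ok] > cut)
  new_map(map$spec, b, map$scenario_id, "binary_map")
}

# Sum of cell areas over the cells where `sel` (logical matrix) is TRUE.
area_of <- function(sel, spec, model) {
  row_area <- cell_areas(spec, model)
  sel[is.na(sel)] <- FALSE
  sum(rowSums(sel) * row_area)
}

#' Area accounting per habitat grade
#'
#' @param grade_map A `grade_map` (or `binary_map`, in which case classes
#'   are absence/presence).
#' @param model An [area_model()].
#' @return Tibble with per-class `area_km2`, `area_1e4_km2`, `pct_of_suitable`
#'   (share of the suitable total; NA for the unsuitable class) and
#'   `pct_of_domain` (share of total valid area). Percentages and 1e4 km2
#'   columns are full precision; round at the reporting layer.
#' @export
grade_areas <- function(grade_map, model = area_model()) {
  codes <- if (inherits(grade_map, "binary_map")) 0:1 else 1:4
  labels <- if (inherits(grade_map, "binary_map")) {
    c("absence", "presence")
  } else {
    grade_labels
  }
  a <- vapply(codes, function(k) {
    area_of(grade_map$values == k, grade_map$spec, model)
  }, numeric(1))
  total <- sum(a)
  suitable <- sum(a[codes > min(codes)])
  pct_suit <- if (suitable > 0) 100 * a / suitable else rep(0, length(a))
  pct_suit[codes == min(codes)] <- NA
  tibble::tibble(
    scenario = grade_map$scenario_id,
    code = codes, class = labels, area_km2 = a,
    area_1e4_km2 = a / 1e4,
    pct_of_suitable = pct_suit,
    pct_of_domain = if (total > 0) 100 * a / total else rep(0, length(a))
  )
}

#' Change map between two binary habitat maps
#'
#' Per-cell transition categories between a previous and a subsequent
#' presence/absence map: `gain` (0 to 1), `loss` (1 to 0), `retained`
#' (1 to 1), `absent` (0 to 0), plus the four area sums. Cells masked in
#' either map are excluded.
#'
#' @param bin_prev,bin_next Aligned `binary_map`s.
#' @param model An [area_model()].
#' @return A `change_map` whose `areas` element is a tibble of category
#'   areas (km2 and 1e4 km2).
#' @export
change_map <- function(bin_prev, bin_next, model = area_model()) {
  if (!grids_aligned(bin_prev$spec, bin_next$spec)) {
    abort_sdm("change_map: grids are not aligned", "sdmflow_alignment_error")
  }
  a <- bin_prev$values; b <- bin_next$values
  ok <- !is.na(a) & !is.na(b)
  cat_m <- matrix(NA_character_, nrow(a), ncol(a))
  cat_m[ok & a == 0 & b == 1] <- "gain"
  cat_m[ok & a == 1 & b == 0] <- "loss"
  cat_m[ok & a == 1 & b == 1] <- "retained"
  cat_m[ok & a == 0 & b == 0] <- "absent"
  areas <- tibble::tibble(
    category = c("gain", "loss", "retained", "absent"),
    area_km2 = vapply(c("gain", "loss", "retained", "absent"), function(k) {
      area_of(cat_m == k, bin_prev$spec, model)
    }, numeric(1))
  )
  areas$area_1e4_km2 <- areas$area_km2 / 1e4
  out <- new_map(bin_prev$spec, cat_m,
                 paste0(bin_prev$scenario_id, "->", bin_next$scenario_id),
                 "change_map")
  out$areas <- areas
  out
}

#' Expansion and contraction rates
#'
#' Rates are expressed relative to the previous-period suitable area, which
#' by construction equals `retained + loss`:
#' `expansion = 100 * gain / (retained + loss)` and
#' `contraction = 100 * loss / (retained + loss)`.
#'
#' @param gain,loss,retained Category areas (any consistent unit).
#' @return Tibble with `expansion_rate` and `contraction_rate` (percent,
#'   full precision).
#' @export
change_rates <- function(gain, loss, retained) {
  baseline <- retained + loss
  if (baseline <= 0) {
    abort_sdm("undefined rates: previous-period suitable area is zero",
              "sdmflow_domain_error")
  }
  tibble::tibble(
    expansion_rate = 100 * gain / baseline,
    contraction_rate = 100 * loss / baseline
  )
}

#' Grade-transition coding between two periods
#'
#' Each cell gets the code `X = A * 10 + B` where `A` is its grade (1-4) in
#' the previous period and `B` in the subsequent one, together with the
#' 4 x 4 cross-tabulated area matrix (rows = previous grade, columns =
#' subsequent grade).
#'
#' @param grade_prev,grade_next Aligned `grade_map`s.
#' @param model An [area_model()].
#' @return A `transition_map` with elements `values` (X codes) and
#'   `area_matrix` (4 x 4, km2).
#' @export
transition_map <- function(grade_prev, grade_next, model = area_model()) {
  if (!grids_aligned(grade_prev$spec, grade_next$spec)) {
    abort_sdm("transition_map: grids are not aligned", "sdmflow_alignment_error")
  }
  a <- grade_prev$values; b <- grade_next$values
  ok <- !is.na(a) & !is.na(b)
  if (any(!(a[ok] %in% 1:4)) || any(!(b[ok] %in% 1:4))) {
    abort_sdm("grade codes must lie in 1..4", "sdmflow_domain_error")
  }
  X <- matrix(NA_integer_, nrow(a), ncol(a))
  X[ok] <- a[ok] * 10L + b[ok]
  am <- matrix(0, 4, 4, dimnames = list(previous = grade_labels,
                                        subsequent = grade_labels))
  for (i in 1:4) for (j in 1:4) {
    am[i, j] <- area_of(ok & a == i & b == j, grade_prev$spec, model)
  }
  out <- new_map(grade_prev$spec, X,
                 paste0(grade_prev$scenario_id, "->", grade_next$scenario_id),
                 "transition_map")
  out$area_matrix <- am
  out
}

#' Habitat-area profiles along latitude, longitude or elevation
#'
#' Sums cell areas per grade within equal-width bins of the chosen axis
#' (row-centre y for latitude, column-centre x for longitude, or the values
#' of an `elev` layer).
#'
#' @param grade_map A `grade_map`.
#' @param stack The matching [env_stack()] (needed for the elevation axis).
#' @param axis `"latitude"`, `"longitude"` or `"elevation"`.
#' @param n_bins Number of equal-width bins (default 20).
#' @param model An [area_model()].
#' @return Tibble with `axis`, `bin_mid`, `grade`, `class`, `area_km2`.
#' @export
habitat_profiles <- function(grade_map, stack, axis = c("latitude", "longitude",
                                                        "elevation"),
                             n_bins = 20, model = area_model()) {
  axis <- match.arg(axis)
  spec <- grade_map$spec
  ok <- !is.na(grade_map$values)
  idx <- which(ok)
  row <- ((idx - 1L) %% spec$n_rows) + 1L
  col <- ((idx - 1L) %/% spec$n_rows) + 1L
  ax_val <- switch(axis,
    latitude = row_centres(spec)[row],
    longitude = col_centres(spec)[col],
    elevation = {
      if (!"elev" %in% names(stack$layers)) {
        abort_sdm("elevation profile requires an 'elev' layer",
                  "sdmflow_lookup_error")
      }
      stack$layers[["elev"]][idx]
    }
  )
  keep <- is.finite(ax_val)
  idx <- idx[keep]; row <- row[keep]; ax_val <- ax_val[keep]
  rng <- range(ax_val)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cell_bin <- pmin(pmax(findInterval(ax_val, brk, rightmost.closed = TRUE), 1L),
                   n_bins)
  cell_area <- cell_areas(spec, model)[row]
  cell_grade <- grade_map$values[idx]
  mids <- (head(brk, -1) + tail(brk, -1)) / 2
  tidyr::expand_grid(bin = seq_len(n_bins), grade = 1:4) |>
    dplyr::mutate(
      axis = axis,
      bin_mid = mids[.data$bin],
      class = grade_labels[.data$grade],
      area_km2 = purrr::map2_dbl(.data$bin, .data$grade, function(b, g) {
        sum(cell_area[cell_bin == b & cell_grade == g])
      })
    ) |>
    dplyr::select("axis", "bin", "bin_mid", "grade", "class", "area_km2")
}

#' @exportS3Method ggplot2::autoplot
autoplot.suitability_map <- function(object, ...) plot_map_values(object, "Suitability")

#' @exportS3Method ggplot2::autoplot
autoplot.grade_map <- function(object, ...) {
  d <- map_to_tibble(object)
  d$class <- factor(grade_labels[d$value], levels = grade_labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Grade",
                  title = object$scenario_id)
}

map_to_tibble <- function(map) {
  spec <- map$spec
  idx <- which(!is.na(map$values))
  row <- ((idx - 1L) %% spec$n_rows) + 1L
  col <- ((idx - 1L) %/% spec$n_rows) + 1L
  tibble::tibble(x = col_centres(spec)[col], y = row_centres(spec)[row],
                 value = map$values[idx])
}

plot_map_values <- function(map, legend) {
  d <- map_to_tibble(map)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = legend, title = map$scenario_id)
}
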