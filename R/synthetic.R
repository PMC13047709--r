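# Synthetic-landscape generator: smooth correlated environmental layers, a
# known logistic truth surface, presences sampled from it, and deterministic
# "future" shifts. This is the test bed for the whole pipeline; it emulates
# the statistical structure of a bioclimatic stack (spatial smoothness,
# inter-layer correlation, a species responding to a few layers), not any
# real geography.

# Smooth standardized Gaussian random field via separable kernel smoothing
# of white noise (kernel sd = `smoothness` cells; edges renormalized).
smooth_field <- function(n_rows, n_cols, smoothness, seed) {
  noise <- withr_seed(seed, matrix(rnorm(n_rows * n_cols), n_rows, n_cols))
  if (smoothness <= 0) return(scale_field(noise))
  K <- function(n) {
    k <- outer(seq_len(n), seq_len(n),
               function(i, j) stats::dnorm(j - i, sd = smoothness))
    k / rowSums(k)
  }
  scale_field(K(n_rows) %*% noise %*% t(K(n_cols)))
}

scale_field <- function(m) {
  s <- sd(m)
  if (s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

#' Generate a synthetic environmental stack
#'
#' Each layer is a spatially smooth standardized random field. Optional
#' `correlation_pairs` re-mix a target layer with a source layer (weights
#' r and sqrt(1 - r^2)) so the pair's correlation is approximately the
#' target r, injecting near-duplicate layers that exercise collinearity
#' screening.
#'
#' @param spec A [grid_spec()] (default 120 x 120 abstract grid with 1-unit
#'   cells).
#' @param n_vars Number of layers (named `env01`, `env02`, ...).
#' @param smoothness Smoothing kernel standard deviation in cells.
#' @param correlation_pairs List of `list(source =, target =, r =)` entries
#'   (layer indices).
#' @param seed Integer seed; regeneration with the same arguments is
#'   bit-identical.
#' @return An [env_stack()] with `scenario_id = "current"`.
#' @export
gen_stack <- function(spec = grid_spec(120, 120), n_vars = 12, smoothness = 6,
                      correlation_pairs = list(), seed = 1) {
  stopifnot(n_vars >= 1)
  fields <- lapply(seq_len(n_vars), function(j) {
    smooth_field(spec$n_rows, spec$n_cols, smoothness,
                 derive_seed(seed, "field", j))
  })
  for (p in correlation_pairs) {
    s <- p$source; t <- p$target; r <- p$r
    stopifnot(s <= n_vars, t <= n_vars, abs(r) <= 1)
    fields[[t]] <- scale_field(r * fields[[s]] + sqrt(1 - r^2) * fields[[t]])
  }
  names(fields) <- sprintf("env%02d", seq_len(n_vars))
  env_stack(spec, fields, scenario_id = "current")
}

#' Truth specification for the synthetic species
#'
#' The true suitability is `plogis(b0 + sum(beta_j * z_j) +
#' sum(gamma_j * z_j^2))` over the standardized active layers, so it always
#' lies strictly inside (0, 1).
#'
#' @param active Names of the active layers.
#' @param beta Linear coefficients (same length as `active`).
#' @param gamma Quadratic coefficients (same length; 0 = none).
#' @param intercept Intercept `b0`.
#' @return A `truth_spec`.
#' @export
truth_spec <- function(active = c("env01", "env02", "env03"),
                       beta = c(14, -10, 8),
                       gamma = c(-5, 0, 0),
                       intercept = -18) {
  stopifnot(length(beta) == length(active), length(gamma) == length(active))
  if (all(beta == 0) && all(gamma == 0)) {
    abort_sdm("truth needs at least one nonzero coefficient",
              "sdmflow_parameter_error")
  }
  structure(list(active = active, beta = beta, gamma = gamma,
                 intercept = intercept),
            class = "truth_spec")
}

#' Evaluate the truth suitability surface on a stack
#'
#' @param stack An [env_stack()] containing every active layer.
#' @param truth A [truth_spec()].
#' @param reference Stack supplying the standardization statistics (mean/sd
#'   per active layer). Defaults to `stack`; pass the calibration-period
#'   stack when re-scoring the truth on a shifted scenario, so that shifts
#'   actually move cells along the response surface.
#' @return A `suitability_map` of the true suitability.
#' @export
true_suitability <- function(stack, truth = truth_spec(), reference = stack) {
  missing <- setdiff(truth$active, names(stack$layers))
  if (length(missing)) {
    abort_sdm(paste0("stack lacks active layer(s): ",
                     paste(missing, collapse = ", ")),
              "sdmflow_lookup_error")
  }
  eta <- matrix(truth$intercept, stack$spec$n_rows, stack$spec$n_cols)
  for (j in seq_along(truth$active)) {
    x <- stack$layers[[truth$active[j]]]
    xr <- reference$layers[[truth$active[j]]]
    mu <- mean(xr, na.rm = TRUE); s <- sd(xr, na.rm = TRUE)
    z <- if (s > 0) (x - mu) / s else x - mu
    eta <- eta + truth$beta[j] * z + truth$gamma[j] * z^2
  }
  eta[!stack$mask] <- NA_real_
  new_map(stack$spec, plogis(eta), stack$scenario_id, "suitability_map")
}

#' Sample presence points from a truth surface
#'
#' Cells are drawn without replacement with probability proportional to the
#' suitability; points are placed at the cell centre plus a seeded sub-cell
#' jitter (uniform within 45% of the cell on each side), which keeps each
#' point inside its cell while exercising distance-based thinning.
#'
#' @param truth_map A `suitability_map` (the truth surface).
#' @param n Number of presences.
#' @param seed Integer seed.
#' @param species Species label for the output.
#' @return Occurrence tibble (`species`, `longitude`, `latitude`, `source`).
#' @export
sample_presences <- function(truth_map, n, seed = 1, species = "synthetic") {
  spec <- truth_map$spec
  idx <- which(!is.na(truth_map$values))
  if (n > length(idx)) {
    abort_sdm(sprintf("requested %d presences from %d valid cells", n,
                      length(idx)),
              "sdmflow_sizing_error")
  }
  p <- truth_map$values[idx]
  cells <- withr_seed(derive_seed(seed, "presence_cells"),
                      sample(idx, n, prob = p))
  row <- ((cells - 1L) %% spec$n_rows) + 1L
  col <- ((cells - 1L) %/% spec$n_rows) + 1L
  jit <- withr_seed(derive_seed(seed, "presence_jitter"),
                    matrix(runif(2 * n, -0.45, 0.45), ncol = 2))
  tibble::tibble(
    species = species,
    longitude = col_centres(spec)[col] + jit[, 1] * spec$cell_size,
    latitude = row_centres(spec)[row] + jit[, 2] * spec$cell_size,
    source = "sim"
  )
}

#' Deterministic scenario shift
#'
#' @param label Scenario label for the shifted stack.
#' @param offsets Named numeric vector of additive offsets per layer.
#' @param scales Named numeric vector of multiplicative scalings per layer.
#' @return A `scenario_shift`.
#' @export
scenario_shift <- function(label, offsets = numeric(0), scales = numeric(0)) {
  structure(list(label = label, offsets = offsets, scales = scales),
            class = "scenario_shift")
}

#' Apply a scenario shift to a stack
#'
#' Each named layer is transformed `x -> scale * x + offset`; the identity
#' shift reproduces the input stack exactly.
#'
#' @param stack An [env_stack()].
#' @param shift A [scenario_shift()].
#' @return A new [env_stack()] labelled with the shift's `label`.
#' @export
future_stack <- function(stack, shift) {
  touched <- union(names(shift$offsets), names(shift$scales))
  missing <- setdiff(touched, names(stack$layers))
  if (length(missing)) {
    abort_sdm(paste0("shift names unknown layer(s): ",
                     paste(missing, collapse = ", ")),
              "sdmflow_lookup_error")
  }
  layers <- stack$layers
  for (l in touched) {
    sc <- if (l %in% names(shift$scales)) shift$scales[[l]] else 1
    of <- if (l %in% names(shift$offsets)) shift$offsets[[l]] else 0
    layers[[l]] <- sc * layers[[l]] + of
  }
  env_stack(stack$spec, layers, scenario_id = shift$label)
}

#' Simulate a complete synthetic study system
#'
#' The default fixture used throughout the test-suite and examples: a
#' 120 x 120 abstract grid (1 km2 cells) with 12 smooth layers, two
#' engineered near-duplicate layer pairs (`env11 ~ env01`, `env12 ~ env04`,
#' target r = 0.95), a three-variable logistic truth, 300 presences, and
#' two deterministic future scenarios (a shift toward the truth optimum and
#' an extreme beyond-range shift of `env01`).
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_rows,n_cols Grid dimensions.
#' @param n_vars Number of layers.
#' @param n_presences Number of presence points.
#' @param smoothness Field smoothness (cells).
#' @param truth A [truth_spec()].
#' @param correlation_pairs Engineered near-duplicate pairs.
#' @param future_shifts List of [scenario_shift()]s applied to the current
#'   stack (set `list()` to skip).
#' @return List with `stack`, `truth`, `truth_map`, `presences`, and
#'   `future` (named list of shifted stacks).
#' @export
simulate_landscape <- function(seed = 1, n_rows = 120, n_cols = 120,
                               n_vars = 12, n_presences = 300, smoothness = 6,
                               truth = truth_spec(),
                               correlation_pairs = list(
                                 list(source = 1, target = 11, r = 0.95),
                                 list(source = 4, target = 12, r = 0.95)
                               ),
                               future_shifts = default_shifts()) {
  spec <- grid_spec(n_rows, n_cols)
  stack <- gen_stack(spec, n_vars = n_vars, smoothness = smoothness,
                     correlation_pairs = correlation_pairs,
                     seed = derive_seed(seed, "stack"))
  tmap <- true_suitability(stack, truth)
  pres <- sample_presences(tmap, n_presences,
                           seed = derive_seed(seed, "presences"))
  future <- lapply(future_shifts, function(s) future_stack(stack, s))
  names(future) <- vapply(future_shifts, `[[`, character(1), "label")
  list(stack = stack, truth = truth, truth_map = tmap, presences = pres,
       future = future)
}

#' Default future scenario shifts of the synthetic system
#'
#' `warm-mild` nudges the positively weighted truth layer toward its
#' optimum; `warm-extreme` pushes `env01` and its engineered near-duplicate
#' `env11` far beyond the reference range (correlated layers shift
#' together), so MESS flags beyond-range extrapolation whichever of the
#' pair survives screening.
#'
#' @return List of [scenario_shift()]s.
#' @export
default_shifts <- function() {
  list(
    scenario_shift("warm-mild", offsets = c(env01 = 0.5)),
    scenario_shift("warm-extreme", offsets = c(env01 = 8, env11 = 8))
  )
}
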