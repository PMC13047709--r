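# Shared fixtures and toy model machinery for the suite. Everything is
# generated in code; nothing is read from disk.

# A deterministic "model" whose predictions are a fixed function of the
# predictor matrix; used to probe importance, ensembling and evaluation
# without a real fit.
toy_model <- function(fun) structure(list(fun = fun), class = "toy_model")
predict.toy_model <- function(object, newdata, ...) {
  object$fun(as.matrix(newdata))
}
registerS3method("predict", "toy_model", predict.toy_model)

# Constant-prediction toy model.
const_model <- function(value) toy_model(function(X) rep(value, nrow(X)))

# Small aligned two-layer stack with a hand-placed nodata hole.
tiny_stack <- function(n = 10, hole = c(3, 4)) {
  a <- matrix(seq_len(n * n) / (n * n), n, n)
  b <- matrix(rev(seq_len(n * n)) / (n * n), n, n)
  a[hole[1], hole[2]] <- NA
  env_stack(grid_spec(n, n), list(la = a, lb = b))
}

# Member-table row with an attached constant model, for ensemble tests.
member_row <- function(algorithm, auc, tss, value = auc, pa_set = 1, rep = 1,
                       model = const_model(value)) {
  tibble::tibble(algorithm = algorithm, pa_set = pa_set, rep = rep,
                 status = "ok", auc = auc, tss = tss, tss_threshold = 0.5,
                 model = list(model))
}

# Cached small synthetic system shared by the heavier tests (built once per
# test run).
local_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(local_sim_cache$sim)) {
    local_sim_cache$sim <- simulate_landscape(
      seed = 99, n_rows = 60, n_cols = 60, n_presences = 150
    )
  }
  local_sim_cache$sim
}

# Great-circle helper: a pair of lon/lat points separated by `km`
# kilometres along a meridian.
points_km_apart <- function(km, lon = 100, lat = 25) {
  dlat <- km / 111.32
  tibble::tibble(species = "t", longitude = c(lon, lon),
                 latitude = c(lat, lat + dlat), source = NA_character_)
}
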