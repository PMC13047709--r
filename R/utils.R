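# Internal helpers shared across modules.

# Derive a reproducible stage seed from a master seed and a stage label.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 1000003 + h * 7919 + index * 104729) %% 2147483629)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_sdm <- function(msg, class) {
  stop(structure(
    class = c(class, "sdmflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
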