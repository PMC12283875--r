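# Internal helpers shared across modules.

# Deterministic seed fan-out: one root seed, named substreams, so stages
# (simulation, fold planning, stage-1/stage-2 forests) draw from independent
# reproducible streams. Result always in [1, 2^31 - 2].
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483645 + 1)
}

# Polynomial rolling hash of a serialised object, for provenance stamps.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kneecast <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "kneecast_error")))
}
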