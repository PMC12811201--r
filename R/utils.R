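# Internal helpers shared across modules.

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_crc <- function(msg, class, ...) {
  stop(rlang::error_cnd(c(class, "crcscreen_error"), message = msg, ...))
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_crc(sprintf("`%s` must be a probability in [0, 1].", name),
             "crcscreen_validation_error")
  }
  invisible(x)
}

# Deterministic substream seed for a labelled simulation arm: the global seed
# plus a polynomial hash of the label, folded into the 32-bit integer range.
# Keyed by arm identity so adding arms never perturbs existing arms.
arm_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147480009
  as.integer((seed %% 2147480009 + h) %% 2147480009) + 1L
}
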