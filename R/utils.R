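## Small internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic substream seed for (master seed, index); kept well below
## .Machine$integer.max so set.seed() always accepts it.
deriveSeed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 100000) * 10007 + i * 97 + 11)
}

## stopifnot-style check with a formatted message
assertThat <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
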