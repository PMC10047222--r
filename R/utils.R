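# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Generator kinds are pinned so that identical seeds give identical
# draws across platforms and R versions.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Deterministic sub-stream seed from a parent seed and a string label.
# djb2-style string hash folded with the parent seed, kept within 32-bit
# signed range. Adding a new label never perturbs the stream of another.
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- 5381
  for (code in utf8ToInt(label)) h <- (h * 33 + code) %% m
  as.integer((h + (as.numeric(seed) %% m) * 69069) %% (m - 1) + 1)
}

# Polynomial rolling hash over a character representation; used for config
# provenance fingerprints (collision resistance is not a requirement).
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  m <- 2^31 - 1
  h <- 17
  for (code in utf8ToInt(txt)) h <- (h * 131 + code) %% m
  sprintf("%08x", as.integer(h))
}

stop_if_not_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      abs(x - round(x)) > 1e-8) {
    stop(what, " must be a single non-negative integer, got ",
         deparse(substitute(x)), " = ", format(x), call. = FALSE)
  }
  invisible(as.integer(round(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
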