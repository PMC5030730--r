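# Internal helpers shared across modules.

# Run code with a temporarily fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a well-behaved 32-bit sub-seed from a base seed and stream indices.
derive_seed <- function(seed, a, b = 0L) {
  (as.double(seed) * 2654435.0 + a * 97003.0 + b * 131.0) %% 2147483587
}

# Pad a matrix with a constant border of width w.
pad_matrix <- function(m, w, value = 0) {
  out <- matrix(value, nrow(m) + 2L * w, ncol(m) + 2L * w)
  out[(w + 1L):(w + nrow(m)), (w + 1L):(w + ncol(m))] <- m
  out
}

unpad_matrix <- function(m, w, nr, nc) {
  m[(w + 1L):(w + nr), (w + 1L):(w + nc)]
}

# Population standard deviation (divide by n).
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
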