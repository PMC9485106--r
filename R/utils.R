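# Internal helpers shared across modules.

#' @importFrom stats fft rnorm runif median mad sd qnorm
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All package randomness flows through this so
# that a fixed seed gives byte-identical output regardless of ambient state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, staying inside
# 32-bit integer range. Keeps per-session / per-component streams independent
# so adding a component does not perturb unrelated draws.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 2147480000
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480000) + 1L
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Linear convolution of a long signal with FIR taps via FFT, returning the
# "full" convolution (length n + length(taps) - 1).
fft_convolve <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  m <- next_pow2(n + L - 1)
  y <- Re(fft(fft(c(x, rep(0, m - n))) * fft(c(taps, rep(0, m - L))),
              inverse = TRUE)) / m
  y[seq_len(n + L - 1)]
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}
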