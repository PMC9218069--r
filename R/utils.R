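#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed for a named stage so stages are independently seeded.
child_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

# Zero-phase band-pass via FFT bin masking. Ends of the band are inclusive.
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  if (n < 4L) return(x)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  f <- pmin(f, fs - f)               # folded (two-sided) frequency axis
  keep <- f >= f_lo & f <= f_hi
  X[!keep] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Hann window (periodic form, suited to Welch averaging).
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

# 3-point quadratic interpolation of an extremum location; returns fractional
# offset in [-0.5, 0.5] relative to the centre sample.
quad_peak_offset <- function(y_m1, y_0, y_p1) {
  denom <- y_m1 - 2 * y_0 + y_p1
  if (abs(denom) < .Machine$double.eps) return(0)
  d <- 0.5 * (y_m1 - y_p1) / denom
  max(-0.5, min(0.5, d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
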