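#' Welch amplitude spectral density
#'
#' Averaged Hann-windowed periodogram reported as amplitude spectral density
#' in uV/sqrt(Hz) (the square root of the one-sided power density), the
#' field's axis convention for chronic-sensing LFP displays. Defaults give a
#' 0.25 Hz grid (4 s segments, 50\% overlap), enough to resolve a 4-5 Hz
#' theta peak.
#'
#' @param rec a \code{recording}.
#' @param channel channel label, or a numeric vector (with \code{fs}).
#' @param segment_s Welch segment length, s.
#' @param overlap fractional overlap in [0, 1).
#' @param fs sampling rate, only when \code{rec} is a bare numeric vector.
#' @return a \code{spectral_estimate}: \code{freqs} (Hz, 0..fs/2),
#'   \code{density} (uV/sqrt(Hz)), \code{df}, \code{window},
#'   \code{n_segments}.
#' @export
power_spectral_density <- function(rec, channel = NULL, segment_s = 4,
                                   overlap = 0.5, fs = NULL) {
  if (is.numeric(rec)) {
    stopifnot(!is.null(fs))
    x <- rec
  } else {
    x <- rec_channel(rec, channel)
    fs <- rec$fs
  }
  nseg <- as.integer(round(segment_s * fs))
  if (length(x) < nseg)
    stop(sprintf("recording too short: need >= %.3g s (%d samples), have %d",
                 segment_s, nseg, length(x)), call. = FALSE)
  stopifnot(overlap >= 0, overlap < 1)
  hop <- max(1L, as.integer(round(nseg * (1 - overlap))))
  w <- hann(nseg)
  scale <- 2 / (fs * sum(w^2))          # one-sided power density scaling
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    X <- stats::fft(x[s:(s + nseg - 1L)] * w)
    p <- scale * Mod(X[seq_len(nf)])^2
    p[1L] <- p[1L] / 2                   # DC not doubled
    if (nseg %% 2L == 0L) p[nf] <- p[nf] / 2   # Nyquist not doubled
    acc <- acc + p
  }
  pwr <- acc / length(starts)
  structure(list(freqs = seq(0, fs / 2, length.out = nf),
                 density = sqrt(pwr), df = fs / nseg,
                 window = "hann", n_segments = length(starts)),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> df = %g Hz, %d segment(s), %s window\n",
              x$df, x$n_segments, x$window))
  invisible(x)
}

#' Short-time (Hann) spectrogram in dB
#'
#' Power values are 10*log10(power density) re 1 uV^2/Hz; for display export
#' values are clipped to \code{[max - dynamic_range, max]}, matching the
#' 40 dB logarithmic-intensity convention.
#'
#' @inheritParams power_spectral_density
#' @param dynamic_range display dynamic range in dB.
#' @return a \code{spectrogram}: \code{times} (bin centres, s), \code{freqs}
#'   (Hz), \code{values} (dB, freq x time), \code{dynamic_range}.
#' @export
spectrogram <- function(rec, channel = NULL, segment_s = 2, overlap = 0.5,
                        dynamic_range = 40, fs = NULL) {
  if (is.numeric(rec)) {
    stopifnot(!is.null(fs)); x <- rec
  } else {
    x <- rec_channel(rec, channel); fs <- rec$fs
  }
  nseg <- as.integer(round(segment_s * fs))
  if (length(x) < nseg)
    stop(sprintf("recording too short: need >= %.3g s", segment_s),
         call. = FALSE)
  hop <- max(1L, as.integer(round(nseg * (1 - overlap))))
  w <- hann(nseg)
  scale <- 2 / (fs * sum(w^2))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  nf <- nseg %/% 2L + 1L
  vals <- matrix(0, nf, length(starts))
  for (j in seq_along(starts)) {
    X <- stats::fft(x[starts[j]:(starts[j] + nseg - 1L)] * w)
    p <- scale * Mod(X[seq_len(nf)])^2
    p[1L] <- p[1L] / 2
    if (nseg %% 2L == 0L) p[nf] <- p[nf] / 2
    vals[, j] <- 10 * log10(pmax(p, 1e-12))
  }
  structure(list(times = (starts - 1L + nseg / 2) / fs,
                 freqs = seq(0, fs / 2, length.out = nf),
                 values = vals, dynamic_range = dynamic_range),
            class = "spectrogram")
}

#' Clip spectrogram values to the display dynamic range
#' @param sg a \code{spectrogram}.
#' @return the spectrogram with \code{values} clipped to
#'   \code{[max - dynamic_range, max]}.
#' @export
clip_spectrogram <- function(sg) {
  top <- max(sg$values)
  sg$values <- pmax(sg$values, top - sg$dynamic_range)
  sg
}

#' Band power from an amplitude spectral density
#'
#' Trapezoidal integral of density^2 (uV^2/Hz) over the band, in uV^2.
#' Additive over disjoint band unions.
#'
#' @param est a \code{spectral_estimate}.
#' @param band numeric \code{c(f_lo, f_hi)} in Hz, within [0, fs/2].
#' @return band power in uV^2.
#' @export
band_power <- function(est, band) {
  stopifnot(inherits(est, "spectral_estimate"), length(band) == 2L)
  if (band[1] < 0 || band[2] <= band[1] || band[2] > max(est$freqs) + est$df / 2)
    stop("invalid band [", band[1], ", ", band[2], "] Hz", call. = FALSE)
  f <- est$freqs; p <- est$density^2
  # integrate on the union of grid points inside the band plus the exact
  # (interpolated) band edges, so adjacent bands tile exactly
  edges <- stats::approx(f, p, xout = pmin(pmax(band, min(f)), max(f)))$y
  inside <- f > band[1] & f < band[2]
  xs <- c(band[1], f[inside], band[2])
  ys <- c(edges[1], p[inside], edges[2])
  trapz(xs, ys)
}

#' Peak frequency of a spectral estimate within a search band
#'
#' Frequency of the maximum density inside the band; exact ties broken
#' toward the lower frequency.
#'
#' @param est a \code{spectral_estimate}.
#' @param search_band numeric \code{c(f_lo, f_hi)} in Hz.
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(est, search_band = c(2, 12)) {
  stopifnot(inherits(est, "spectral_estimate"))
  sel <- which(est$freqs >= search_band[1] & est$freqs <= search_band[2])
  if (!length(sel))
    stop("empty search band after gridding (df = ", est$df, " Hz)",
         call. = FALSE)
  est$freqs[sel[which.max(est$density[sel])]]
}
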