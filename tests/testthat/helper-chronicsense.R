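# Shared fixtures and independent oracles, built in code at test time.

quiet_params <- function(seed = 1L, ...) gen_params(seed = seed, ...)

# Independent brute-force normalized cross-correlation oracle: explicit
# loops, no shared code path with estimate_lag/xcorr_window.
oracle_best_lag <- function(xs, xt, centre, half, max_lag) {
  best_val <- -Inf
  best_lag <- NA_integer_
  for (l in -max_lag:max_lag) {
    num <- 0; ss <- 0; st <- 0; ms <- 0; mt <- 0
    idx <- (centre - half):(centre + half)
    for (i in idx) { ms <- ms + xs[i]; mt <- mt + xt[i + l] }
    ms <- ms / length(idx); mt <- mt / length(idx)
    for (i in idx) {
      a <- xs[i] - ms; b <- xt[i + l] - mt
      num <- num + a * b; ss <- ss + a^2; st <- st + b^2
    }
    v <- if (ss == 0 || st == 0) 0 else num / sqrt(ss * st)
    if (v > best_val + 1e-12 ||
        (abs(v - best_val) <= 1e-12 && abs(l) < abs(best_lag))) {
      best_val <- v; best_lag <- l
    }
  }
  list(lag = best_lag, corr = best_val)
}

# Hand Pearson correlation (oracle for rank_concordance).
oracle_pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  num <- sum((a - mean(a)) * (b - mean(b)))
  num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Draw a parameter uniformly from an interval using an isolated seed.
seeded_unif <- function(seed, lo, hi) {
  chronicsense:::with_seed(seed, stats::runif(1, lo, hi))
}

# Single-channel recording wrapper around a bare numeric vector.
vec_recording <- function(x, fs = 250, label = "HC_E0-E3") {
  parts <- strsplit(label, "_|-")[[1]]
  new_recording(matrix(x, nrow = 1),
                fs = fs,
                channels = data.frame(label = label, lead = parts[1],
                                      anode = parts[2], cathode = parts[3],
                                      valid = TRUE, stringsAsFactors = FALSE))
}
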