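#' Generator parameters for the synthetic chronic-sensing cohort
#'
#' Houses every tunable of the phenomenological signal model: a theta-dominant
#' hippocampal LFP (narrowband 4-5 Hz oscillation over 1/f background),
#' sharp-wave transients that propagate to the thalamus with a 30-40 ms lag,
#' sleep-state K-complexes seen as zero-lag far-field events at the
#' hippocampal site, thalamo-hippocampal evoked potentials with a 35-40 ms
#' main peak, amplitude-dependent suppression (0.6 V) and after-discharge
#' (1 V) thresholds for direct hippocampal stimulation, directional segment
#' gain asymmetry, and impedance stabilization with scheduled lead breakage.
#'
#' @param seed integer RNG seed; identical seed + params give bit-identical
#'   output.
#' @param theta_f0 theta peak frequency, Hz, must lie in [4, 5].
#' @param theta_amp theta oscillation amplitude, uV.
#' @param noise_sd 1/f background noise standard deviation, uV.
#' @param one_over_f_exponent spectral slope alpha of the background.
#' @param state_dwell named mean dwell times (s) for the behavioural states
#'   \code{theta}, \code{sharp_wave}, \code{sleep}.
#' @param sw_rate sharp-wave event rate during sharp-wave state, events/s.
#' @param sw_amp median sharp-wave peak amplitude, uV (lognormal jitter,
#'   sdlog 0.3).
#' @param ep_latency evoked-potential main-peak latency, ms.
#' @param ep_amp_max saturating EP amplitude, uV; response is sigmoidal in
#'   stimulation voltage with half-max at \code{ep_threshold}.
#' @param ep_threshold stimulation amplitude (V) of half-maximal EP.
#' @param net_lag hippocampus-to-thalamus propagation lag, ms, in [30, 40].
#' @param prop_ratio thalamic/hippocampal amplitude ratio of propagated
#'   sharp waves.
#' @param farfield_ratio hippocampal/thalamic amplitude ratio of far-field
#'   K-complexes (< 1, zero lag).
#' @param kc_rate K-complex rate during sleep state, events/s.
#' @param kc_amp K-complex amplitude at the thalamic site, uV.
#' @param theta_supp inhibitory (suppression) threshold, V.
#' @param theta_ad after-discharge threshold, V; must exceed
#'   \code{theta_supp}.
#' @param supp_factor post-burst LFP power attenuation factor.
#' @param ad_duration after-discharge duration, s.
#' @param segment_gains named gains in (0, 1] for the six segmented contacts
#'   of a 1-3-3-1 lead; ring contacts have gain 1.
#' @param impedance_base sense-only contact plateau impedance, Ohm.
#' @param stim_contacts contact names treated as chronically stimulated
#'   (lower impedance plateau by the stimulated-contact factor).
#' @param stim_impedance_factor plateau ratio sense-only / stimulated.
#' @param breakage_schedule list of \code{list(lead=, contact=, month=)}
#'   entries; from that month the contact reads open-circuit and its channels
#'   are flat.
#' @return a validated \code{gen_params} list.
#' @export
gen_params <- function(seed = 1L,
                       theta_f0 = 4.5, theta_amp = 40, noise_sd = 10,
                       one_over_f_exponent = 1,
                       state_dwell = c(theta = 20, sharp_wave = 20, sleep = 20),
                       sw_rate = 0.5, sw_amp = 150,
                       ep_latency = 37, ep_amp_max = 60, ep_threshold = 3,
                       net_lag = 36, prop_ratio = 0.6,
                       farfield_ratio = 0.15, kc_rate = 0.1, kc_amp = 200,
                       theta_supp = 0.6, theta_ad = 1.0,
                       supp_factor = 0.25, ad_duration = 4,
                       segment_gains = c(E1a = 0.70, E1b = 0.55, E1c = 0.45,
                                         E2a = 0.80, E2b = 1.00, E2c = 0.60),
                       impedance_base = 1200,
                       stim_contacts = "E1",
                       stim_impedance_factor = 2.5,
                       breakage_schedule = list()) {
  p <- as.list(environment())
  stopifnot(theta_f0 >= 4, theta_f0 <= 5,
            net_lag >= 30, net_lag <= 40,
            theta_supp < theta_ad,
            all(segment_gains > 0), all(segment_gains <= 1),
            farfield_ratio < 1,
            all(c("theta", "sharp_wave", "sleep") %in% names(state_dwell)))
  class(p) <- "gen_params"
  p
}

#' Default lead set: 4-contact hippocampal and thalamic leads
#' @export
default_leads <- function() {
  list(HC = build_lead("3387"), AN = build_lead("3389"))
}

# ---- internal signal primitives ------------------------------------------

# Gaussian white noise shaped to 1/f^alpha by frequency-domain filtering,
# rescaled to standard deviation `sd`.
one_over_f_noise <- function(n, fs, alpha, sd) {
  if (sd <= 0 || n < 4) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1L)[1:n]
  f <- pmin(f, fs - f)
  shape <- c(0, f[-1]^(-alpha / 2))     # kill DC; HP hardware stage follows
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# Biexponential sharp-wave kernel, unit peak, rise 5 ms / decay 40 ms.
sw_kernel <- function(fs, tau_r = 0.005, tau_d = 0.040) {
  tt <- seq(0, 8 * tau_d, by = 1 / fs)
  k <- exp(-tt / tau_d) - exp(-tt / tau_r)
  k / max(k)
}

# K-complex kernel: large biphasic transient of ~0.7 s, unit peak.
kc_kernel <- function(fs, width = 0.7) {
  tt <- seq(0, width, by = 1 / fs)
  k <- -sin(2 * pi * tt / width) * sin(pi * tt / width)
  k / max(abs(k))
}

# Add `kernel * amp` into x starting at sample index i0 (1-based), clipped.
add_transient <- function(x, i0, kernel, amp) {
  n <- length(x)
  if (i0 > n || i0 + length(kernel) - 1L < 1L) return(x)
  src <- max(1L, 2L - i0):min(length(kernel), n - i0 + 1L)
  dst <- (i0 + src - 1L)
  x[dst] <- x[dst] + amp * kernel[src]
  x
}

# Behavioural state sequence: 1 = theta, 2 = sharp_wave, 3 = sleep.
# Exponential dwells with the configured means; next state uniform among the
# other two. A fixed `state` returns a constant sequence.
sim_states <- function(params, n, fs, state) {
  codes <- c(theta = 1L, sharp_wave = 2L, sleep = 3L)
  if (state != "markov") return(rep(codes[[state]], n))
  dwell <- params$state_dwell[c("theta", "sharp_wave", "sleep")]
  out <- integer(0)
  s <- sample(1:3, 1L)
  while (length(out) < n) {
    len <- max(1L, round(stats::rexp(1, 1 / dwell[s]) * fs))
    out <- c(out, rep(s, len))
    s <- sample(setdiff(1:3, s), 1L)
  }
  out[seq_len(n)]
}

# Poisson event onsets (sample indices) within the runs where mask is TRUE.
poisson_onsets <- function(mask, rate, fs) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- integer(0)
  for (j in which(r$values)) {
    span <- r$lengths[j] / fs
    k <- stats::rpois(1, rate * span)
    if (k > 0)
      onsets <- c(onsets, starts[j] + sort(sample.int(r$lengths[j], k,
                                                      replace = TRUE)) - 1L)
  }
  onsets
}

# Role of a lead id in the circuit model: thalamic ids start with AN,
# everything else (HC, FX) carries the hippocampal-like source.
lead_role <- function(id) if (grepl("^AN", id)) "AN" else "HC"

# Default sense channels for a lead: the 15-pair montage on directional
# leads; on 4-contact leads the distal-proximal E0-E3 pair plus E1-E3 (the
# alternative pair clinical sessions fall back from when a contact breaks).
lead_channels <- function(lead) {
  if (length(lead$contacts) == 8L) enumerate_montage(lead)
  else list(bipolar_pair(lead, "E0", "E3"), bipolar_pair(lead, "E1", "E3"))
}

# Gain of a contact: segmented contacts from params, ring contacts 1.
contact_gain <- function(params, lead, contact) {
  if (lead$segment_angle[[contact]] == "ring") return(1)
  g <- params$segment_gains[[contact]]
  if (is.null(g)) 1 else g
}

# ---- generate_lfp ---------------------------------------------------------

#' Generate a spontaneous multichannel LFP recording
#'
#' Hippocampal-like channels alternate between a theta state (amplitude
#' modulated narrowband oscillation at \code{theta_f0} over 1/f background),
#' a sharp-wave state (biexponential transients at \code{sw_rate}), and a
#' sleep state, under a Markov dwell process. Thalamic channels carry the
#' background plus coupled activity: sharp waves arrive \code{net_lag} ms
#' after the hippocampal event at ratio \code{prop_ratio}; during sleep,
#' K-complexes appear at the thalamic site with a zero-lag far-field copy
#' (ratio \code{farfield_ratio}) at the hippocampal site. Directional-lead
#' channels are scaled by the mean gain of their two contacts. A hardware
#' band-pass (hp/lp corner metadata) is applied last.
#'
#' @param params a \code{gen_params} object.
#' @param duration length in seconds, > 0.
#' @param fs sampling rate in Hz (default 250).
#' @param leads named list of \code{lead_geometry}; names are lead ids
#'   (\code{HC}, \code{AN}, \code{FX_L}, ...).
#' @param state \code{"markov"} or a fixed state for the whole record.
#' @param condition recording condition metadata.
#' @return a \code{recording}; ground-truth event times and states are
#'   attached as the \code{sim_truth} element.
#' @export
generate_lfp <- function(params, duration, fs = 250, leads = default_leads(),
                         state = c("markov", "theta", "sharp_wave", "sleep"),
                         condition = "free_roaming") {
  state <- match.arg(state)
  stopifnot(inherits(params, "gen_params"))
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  with_seed(params$seed, {
    n <- as.integer(round(duration * fs))
    tt <- (seq_len(n) - 1) / fs
    states <- sim_states(params, n, fs, state)

    # shared sources per role
    bg_hc <- one_over_f_noise(n, fs, params$one_over_f_exponent, params$noise_sd)
    bg_an <- one_over_f_noise(n, fs, params$one_over_f_exponent, params$noise_sd)

    phi <- stats::runif(2, 0, 2 * pi)
    am <- 1 + 0.3 * sin(2 * pi * 0.2 * tt + phi[2])   # modulation depth 0.3
    theta_wave <- params$theta_amp * am * sin(2 * pi * params$theta_f0 * tt + phi[1])
    hc <- bg_hc + theta_wave * (states == 1L)

    an <- bg_an
    # sharp waves: generated in HC, propagated to AN with net_lag
    ksw <- sw_kernel(fs)
    pk <- which.max(ksw) - 1L                 # samples from onset to peak
    sw_on <- poisson_onsets(states == 2L, params$sw_rate, fs)
    sw_amp <- stats::rlnorm(length(sw_on), log(params$sw_amp), 0.3)
    lag_smp <- as.integer(round(params$net_lag / 1000 * fs))
    for (j in seq_along(sw_on)) {
      hc <- add_transient(hc, sw_on[j], ksw, sw_amp[j])
      an <- add_transient(an, sw_on[j] + lag_smp, ksw, params$prop_ratio * sw_amp[j])
    }
    # K-complexes: AN-local during sleep, zero-lag far field on HC
    kkc <- kc_kernel(fs)
    kc_on <- poisson_onsets(states == 3L, params$kc_rate, fs)
    for (j in seq_along(kc_on)) {
      an <- add_transient(an, kc_on[j], kkc, params$kc_amp)
      hc <- add_transient(hc, kc_on[j], kkc, params$farfield_ratio * params$kc_amp)
    }
    src <- list(HC = hc, AN = an)

    rows <- list(); meta <- list()
    for (id in names(leads)) {
      lead <- leads[[id]]
      base <- src[[lead_role(id)]]
      for (pr in lead_channels(lead)) {
        g <- mean(c(contact_gain(params, lead, pr$anode),
                    contact_gain(params, lead, pr$cathode)))
        ch <- base * g + stats::rnorm(n, sd = 0.3 * params$noise_sd)
        ch <- fft_bandpass(ch, fs, 0.5, min(100, fs / 2 * 0.98))
        rows[[length(rows) + 1L]] <- ch
        meta[[length(meta) + 1L]] <- data.frame(
          label = paste0(id, "_", pr$label), lead = id,
          anode = pr$anode, cathode = pr$cathode, valid = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    rec <- new_recording(do.call(rbind, rows), fs, do.call(rbind, meta),
                         condition = condition)
    rec$sim_truth <- list(
      states = states,
      sw_times = (sw_on - 1L + pk) / fs, sw_amps = sw_amp,
      kc_times = (kc_on - 1L + which.max(abs(kkc)) - 1L) / fs,
      net_lag_ms = lag_smp / fs * 1000)
    rec
  })
}

# ---- generate_stim_session ------------------------------------------------

# Continuous EP template (uV) as a function of time since pulse (s); main
# positive peak at `latency_ms`, smaller opposite lobe 25 ms later.
ep_template <- function(t_s, latency_ms, amp) {
  tm <- t_s * 1000
  amp * (exp(-(tm - latency_ms)^2 / (2 * 6^2)) -
           0.4 * exp(-(tm - latency_ms - 25)^2 / (2 * 10^2))) * (tm >= 0)
}

# Sigmoidal EP amplitude in stimulation voltage, half-max at ep_threshold.
ep_amplitude <- function(params, volts) {
  params$ep_amp_max / (1 + exp(-(volts - params$ep_threshold) / 0.8))
}

# Vector of one-sample biphasic stimulus artifacts (+amp then -amp) at the
# given onset sample indices; amp may be scalar or per-pulse.
artifact_vector <- function(n, idx, amp) {
  v <- numeric(n)
  amp <- rep_len(amp, length(idx))
  ok <- idx >= 1L & idx <= n
  v[idx[ok]] <- v[idx[ok]] + amp[ok]
  ok2 <- idx + 1L >= 1L & idx + 1L <= n
  v[idx[ok2] + 1L] <- v[idx[ok2] + 1L] - amp[ok2]
  v
}

#' Generate a stimulation session with ground-truth events
#'
#' Three protocols: \code{ep_train} (pulse train with stimulus artifacts and
#' sigmoidally scaled evoked potentials on hippocampal channels),
#' \code{burst_ramp} (a series of increasing-amplitude 50 Hz bursts; above
#' the inhibitory threshold post-burst LFP power is attenuated, above the
#' after-discharge threshold a large 2-8 Hz transient follows the burst),
#' and \code{directional_sweep} (monopolar stimulation of each segmented
#' contact in seeded random order, 20 s pre-baseline, post-stimulation
#' suppression depth proportional to that contact's segment gain).
#'
#' @param params a \code{gen_params}.
#' @param setting a \code{stim_setting}; \code{amplitude = 0} is a sham (no
#'   artifacts, no responses).
#' @param protocol one of \code{"ep_train"}, \code{"burst_ramp"},
#'   \code{"directional_sweep"}.
#' @param fs sampling rate, Hz.
#' @param leads named lead list; \code{directional_sweep} requires a
#'   directional lead.
#' @param amplitudes burst amplitudes (V) for \code{burst_ramp}.
#' @param post_s post-stimulation observation window per sweep step, s.
#' @param supp_minutes duration of full suppression in the sweep, min.
#' @param sweep_contacts optional subset of segmented contacts to sweep.
#' @return \code{list(recording=, events=)} where events is a list of
#'   \code{stim_event}.
#' @export
generate_stim_session <- function(params, setting,
                                  protocol = c("ep_train", "burst_ramp",
                                               "directional_sweep"),
                                  fs = 250, leads = NULL,
                                  amplitudes = c(0.4, 0.6, 0.8, 1.0),
                                  post_s = 360, supp_minutes = 3,
                                  sweep_contacts = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(params, "gen_params"), inherits(setting, "stim_setting"))
  switch(protocol,
    ep_train = sim_ep_train(params, setting, fs,
                            leads %||% default_leads()),
    burst_ramp = sim_burst_ramp(params, setting, fs,
                                leads %||% list(HC = build_lead("3387")),
                                amplitudes),
    directional_sweep = sim_directional_sweep(
      params, setting, fs, leads %||% list(HC = build_lead("1-3-3-1")),
      post_s, supp_minutes, sweep_contacts))
}

sim_ep_train <- function(params, setting, fs, leads) {
  pre <- 5; post <- 5
  dur <- pre + setting$duration_s + post
  p2 <- params; p2$seed <- child_seed(params$seed, "ep_base")
  rec <- generate_lfp(p2, dur, fs, leads, state = "theta", condition = "sling")
  n <- ncol(rec$samples)
  npulse <- as.integer(round(setting$rate * setting$duration_s))
  pt <- pre + (seq_len(npulse) - 1L) / setting$rate
  events <- lapply(pt, function(o) stim_event(setting, o, o + 1 / fs))
  if (setting$amplitude > 0) {
    tt <- (seq_len(n) - 1) / fs
    hc_rows <- which(vapply(rec$channels$lead, lead_role, "") == "HC")
    i0 <- as.integer(round(pt * fs)) + 1L
    art <- artifact_vector(n, i0, 10 * params$theta_amp)
    amp <- ep_amplitude(params, setting$amplitude)
    epv <- numeric(n)
    for (o in pt) {
      idx <- (as.integer(round(o * fs)) + 1L):min(n, as.integer(round(o * fs)) +
                                                    1L + as.integer(0.12 * fs))
      epv[idx] <- epv[idx] + ep_template(tt[idx] - o, params$ep_latency, amp)
    }
    for (r in seq_len(nrow(rec$samples))) {
      rec$samples[r, ] <- rec$samples[r, ] + art
      if (r %in% hc_rows) rec$samples[r, ] <- rec$samples[r, ] + epv
    }
  }
  list(recording = rec, events = events)
}

sim_burst_ramp <- function(params, setting, fs, leads, amplitudes) {
  pre <- 15; rest <- 20
  bdur <- setting$duration_s
  dur <- pre + length(amplitudes) * (bdur + rest)
  p2 <- params; p2$seed <- child_seed(params$seed, "burst_base")
  rec <- generate_lfp(p2, dur, fs, leads, state = "theta", condition = "sling")
  n <- ncol(rec$samples)
  onsets <- pre + (seq_along(amplitudes) - 1L) * (bdur + rest)
  events <- list()
  env <- rep(1, n)
  ad <- rep(0, n)
  tt <- (seq_len(n) - 1) / fs
  for (j in seq_along(amplitudes)) {
    v <- amplitudes[j]
    s <- setting; s$amplitude <- v
    events[[j]] <- stim_event(s, onsets[j], onsets[j] + bdur)
    if (v <= 0) next
    if (v >= params$theta_supp) {
      supp_dur <- 5 + 10 * (v - params$theta_supp)
      i1 <- as.integer(round((onsets[j] + bdur) * fs)) + 1L
      i2 <- min(n, i1 + as.integer(supp_dur * fs))
      env[i1:i2] <- pmin(env[i1:i2], sqrt(params$supp_factor))
      ramp <- i2 + seq_len(as.integer(2 * fs))
      ramp <- ramp[ramp <= n]
      env[ramp] <- pmin(env[ramp],
                        sqrt(params$supp_factor) +
                          (1 - sqrt(params$supp_factor)) *
                          seq_along(ramp) / length(ramp))
    }
    if (v >= params$theta_ad) {
      i1 <- as.integer(round((onsets[j] + bdur) * fs)) + 1L
      idx <- i1:min(n, i1 + as.integer(params$ad_duration * fs))
      tl <- (idx - i1) / fs
      ad[idx] <- ad[idx] + 6 * params$theta_amp *
        sin(2 * pi * 4 * tl) * sin(pi * tl / params$ad_duration)^2
    }
  }
  aidx <- integer(0); aamp <- numeric(0)
  for (j in seq_along(amplitudes)) {
    v <- amplitudes[j]
    if (v <= 0) next
    pt <- seq(onsets[j], onsets[j] + bdur - 1 / setting$rate,
              by = 1 / setting$rate)
    aidx <- c(aidx, as.integer(round(pt * fs)) + 1L)
    aamp <- c(aamp, rep(10 * params$theta_amp * v, length(pt)))
  }
  art <- artifact_vector(n, aidx, aamp)
  for (r in seq_len(nrow(rec$samples)))
    rec$samples[r, ] <- rec$samples[r, ] * env + ad + art
  list(recording = rec, events = events)
}

sim_directional_sweep <- function(params, setting, fs, leads, post_s,
                                  supp_minutes, sweep_contacts) {
  id <- names(leads)[1]
  lead <- leads[[id]]
  if (length(lead$contacts) != 8L)
    stop("directional_sweep needs a 1-3-3-1 lead", call. = FALSE)
  segs <- sweep_contacts %||% segmented_contacts(lead)
  stopifnot(all(segs %in% segmented_contacts(lead)))
  pre <- 20; sdur <- setting$duration_s
  # block must outlast suppression + the 60 s recovery ramp so one step's
  # after-effects never contaminate the next step's baseline
  block <- pre + sdur + max(post_s, supp_minutes * 60 + 70)
  dur <- block * length(segs)
  p2 <- params; p2$seed <- child_seed(params$seed, "sweep_base")
  rec <- generate_lfp(p2, dur, fs, leads, state = "theta", condition = "sling")
  order_seed <- child_seed(params$seed, "sweep_order")
  segs <- with_seed(order_seed, sample(segs))
  n <- ncol(rec$samples)
  env <- rep(1, n)
  events <- list()
  for (j in seq_along(segs)) {
    o <- (j - 1L) * block + pre
    s <- setting; s$cathode <- segs[j]; s$anode <- "case"
    events[[j]] <- stim_event(s, o, o + sdur)
    if (setting$amplitude <= 0) next
    g <- contact_gain(params, lead, segs[j])
    pfac <- 1 - (1 - params$supp_factor) * g      # post/pre power factor
    i1 <- as.integer(round((o + sdur) * fs)) + 1L
    i2 <- min(n, i1 + as.integer(supp_minutes * 60 * fs))
    env[i1:i2] <- pmin(env[i1:i2], sqrt(pfac))
    ramp <- i2 + seq_len(as.integer(60 * fs))
    ramp <- ramp[ramp <= n]
    env[ramp] <- pmin(env[ramp],
                      sqrt(pfac) + (1 - sqrt(pfac)) *
                        seq_along(ramp) / length(ramp))
  }
  aidx <- integer(0)
  if (setting$amplitude > 0) {
    for (j in seq_along(segs)) {
      o <- (j - 1L) * block + pre
      pt <- seq(o, o + sdur - 1 / setting$rate, by = 1 / setting$rate)
      aidx <- c(aidx, as.integer(round(pt * fs)) + 1L)
    }
  }
  art <- artifact_vector(n, aidx, 10 * params$theta_amp)
  for (r in seq_len(nrow(rec$samples)))
    rec$samples[r, ] <- rec$samples[r, ] * env + art
  list(recording = rec, events = events)
}

# ---- generate_cohort_timeline --------------------------------------------

# Impedance trajectory for one contact: exponential stabilization over ~6
# weeks (time constant 1.5 months) from 1.8x toward the plateau, with
# lognormal measurement noise; open circuit (1e6 Ohm) after breakage.
impedance_series <- function(plateau, months, noise_sdlog = 0.03,
                             break_month = Inf) {
  m <- seq_len(months)
  z <- plateau * (1 + 0.8 * exp(-m / 1.5)) *
    exp(stats::rnorm(months, 0, noise_sdlog))
  z[m >= break_month] <- 1e6
  z
}

#' Generate a multi-month synthetic cohort timeline
#'
#' Emits one session per month (alternating sling / free-roaming) with a
#' spontaneous LFP recording and a per-contact impedance table. After a
#' scheduled breakage month the broken contact reads open circuit and every
#' channel containing it is flat amplifier noise and flagged invalid.
#'
#' @param params a \code{gen_params}; breakage via
#'   \code{params$breakage_schedule}.
#' @param months number of monthly sessions, >= 1.
#' @param fs sampling rate, Hz.
#' @param session_s duration of each monthly recording, s.
#' @param leads named lead list.
#' @return list of sessions, each \code{list(month, condition, recording,
#'   impedance)}; \code{impedance} is a data.frame with columns lead,
#'   contact, month, ohms, usage, broken.
#' @export
generate_cohort_timeline <- function(params, months, fs = 250, session_s = 30,
                                     leads = default_leads()) {
  stopifnot(months >= 1)
  for (b in params$breakage_schedule) {
    if (is.null(leads[[b$lead]]) || !(b$contact %in% leads[[b$lead]]$contacts))
      stop("breakage contact ", b$contact, " not on lead ", b$lead,
           call. = FALSE)
  }
  break_month <- function(id, contact) {
    for (b in params$breakage_schedule)
      if (b$lead == id && b$contact == contact) return(b$month)
    Inf
  }
  # impedance trajectories drawn once so months are consistent
  imp <- with_seed(child_seed(params$seed, "impedance"), {
    out <- list()
    for (id in names(leads)) {
      lead <- leads[[id]]
      for (ct in lead$contacts) {
        usage <- if (ct %in% params$stim_contacts) "stimulated" else "sense_only"
        plateau <- if (usage == "stimulated")
          params$impedance_base / params$stim_impedance_factor
        else params$impedance_base
        z <- impedance_series(plateau, months,
                              break_month = break_month(id, ct))
        out[[length(out) + 1L]] <- data.frame(
          lead = id, contact = ct, month = seq_len(months), ohms = z,
          usage = usage, broken = seq_len(months) >= break_month(id, ct),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  sessions <- vector("list", months)
  for (m in seq_len(months)) {
    pm <- params; pm$seed <- child_seed(params$seed, paste0("month", m))
    cond <- if (m %% 2 == 1) "sling" else "free_roaming"
    rec <- generate_lfp(pm, session_s, fs, leads, state = "markov",
                        condition = cond)
    for (r in seq_len(nrow(rec$channels))) {
      ch <- rec$channels[r, ]
      bm <- min(break_month(ch$lead, ch$anode), break_month(ch$lead, ch$cathode))
      if (m >= bm) {
        rec$samples[r, ] <- with_seed(
          child_seed(pm$seed, paste0("broken", r)),
          stats::rnorm(ncol(rec$samples), sd = 2))
        rec$channels$valid[r] <- FALSE
      }
    }
    sessions[[m]] <- list(month = m, condition = cond, recording = rec,
                          impedance = imp[imp$month == m, ])
  }
  sessions
}
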