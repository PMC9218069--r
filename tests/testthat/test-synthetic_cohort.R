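test_that("generation is deterministic under a fixed seed", {
  p <- quiet_params(seed = 123)
  a <- generate_lfp(p, 5)
  b <- generate_lfp(p, 5)
  expect_identical(a$samples, b$samples)
  p2 <- quiet_params(seed = 124)
  expect_false(identical(generate_lfp(p2, 5)$samples, a$samples))
  sa <- generate_stim_session(p, stim_setting(4, "V", 5, 120, 30), "ep_train")
  sb <- generate_stim_session(p, stim_setting(4, "V", 5, 120, 30), "ep_train")
  expect_identical(sa$recording$samples, sb$recording$samples)
})

test_that("a pure theta state puts the PSD peak at theta_f0", {
  p <- quiet_params(seed = 5, theta_f0 = 4.4)
  rec <- generate_lfp(p, 30, state = "theta")
  est <- power_spectral_density(rec, "HC_E0-E3")
  expect_lte(abs(peak_frequency(est, c(2, 12)) - 4.4), est$df)
})

test_that("sharp-wave counts follow the configured Poisson rate", {
  # 60 s of sharp-wave state at 0.5 events/s: detected count inside the
  # Poisson 99% interval around 30 (oracle: exact Poisson quantiles)
  p <- quiet_params(seed = 9, sw_rate = 0.5)
  rec <- generate_lfp(p, 60, state = "sharp_wave")
  ev <- detect_spike_events(rec, "HC_E0-E3")
  lo <- qpois(0.005, 30); hi <- qpois(0.995, 30)
  expect_gte(nrow(ev), lo)
  expect_lte(nrow(ev), hi)
  expect_gte(length(rec$sim_truth$sw_times), lo)
  expect_lte(length(rec$sim_truth$sw_times), hi)
})

test_that("invalid durations and protocols are rejected", {
  p <- quiet_params()
  expect_error(generate_lfp(p, 0), "duration")
  expect_error(generate_lfp(p, 10, fs = -1), "fs")
  expect_error(generate_stim_session(p, stim_setting(1, "V", 5, 120, 30),
                                     protocol = "nope"))
})

test_that("ep_train emits one event per pulse and a sham emits no artifacts", {
  p <- quiet_params(seed = 2)
  ses <- generate_stim_session(p, stim_setting(4, "V", 5, 120, 30), "ep_train")
  expect_length(ses$events, 150L)
  sham <- generate_stim_session(p, stim_setting(0, "V", 5, 120, 30), "ep_train")
  expect_length(detect_stim_artifacts(sham$recording, "HC_E0-E3"), 0L)
  # a sham session is exactly the seeded spontaneous background
  p2 <- p; p2$seed <- chronicsense:::child_seed(p$seed, "ep_base")
  base <- generate_lfp(p2, 40, leads = default_leads(), state = "theta",
                       condition = "sling")
  expect_identical(sham$recording$samples, base$samples)
})

test_that("burst_ramp responses cross the two thresholds in order", {
  p <- quiet_params(seed = 3)
  br <- generate_stim_session(p, stim_setting(1, "V", 50, 120, 10),
                              "burst_ramp", amplitudes = c(0.4, 0.6, 0.8, 1.0))
  cls <- classify_burst_responses(br$recording, br$events)
  expect_identical(cls$responses$label,
                   c("none", "suppression", "suppression", "after_discharge"))
})

test_that("averaged EP amplitude is non-decreasing in stimulation voltage", {
  p <- quiet_params(seed = 4)
  amps <- vapply(c(1, 3, 5, 7), function(v) {
    ses <- generate_stim_session(p, stim_setting(v, "V", 5, 120, 30),
                                 "ep_train")
    tr <- detect_stim_artifacts(ses$recording, "HC_E0-E3")
    average_epochs(ses$recording, tr, "HC_E0-E3",
                   align_to_peak = TRUE)$amplitude
  }, numeric(1))
  expect_true(all(diff(amps) >= 0))
})

test_that("segment gains order expected channel power", {
  # direct construction check: gain_i > gain_j implies theta band power i > j
  p <- quiet_params(seed = 6, segment_gains = c(E1a = 0.9, E1b = 0.5,
                                                E1c = 0.3, E2a = 0.9,
                                                E2b = 0.5, E2c = 0.3))
  dl <- list(HC = build_lead("1-3-3-1"))
  rec <- generate_lfp(p, 30, leads = dl, state = "theta")
  bp <- vapply(c("HC_E1a-E2a", "HC_E1b-E2b", "HC_E1c-E2c"), function(ch)
    band_power(power_spectral_density(rec, ch), c(3, 8)), numeric(1))
  expect_true(bp[1] > bp[2] && bp[2] > bp[3])
})

test_that("cohort timeline propagates breakage and keeps its schedule", {
  p <- quiet_params(seed = 7,
                    breakage_schedule = list(list(lead = "HC", contact = "E1",
                                                  month = 4)))
  tl <- generate_cohort_timeline(p, 6, session_s = 2)
  expect_length(tl, 6L)
  ch <- tl[[1]]$recording$channels
  before <- tl[[3]]$recording$channels$valid
  after <- tl[[4]]$recording$channels$valid
  has_e1 <- ch$lead == "HC" & (ch$anode == "E1" | ch$cathode == "E1")
  expect_true(all(before))
  expect_identical(after, !has_e1)
  expect_true(all(tl[[5]]$impedance$ohms[tl[[5]]$impedance$lead == "HC" &
                                           tl[[5]]$impedance$contact == "E1"] > 5e4))
  # no breakage: always valid
  tl0 <- generate_cohort_timeline(quiet_params(seed = 7), 3, session_s = 2)
  expect_true(all(vapply(tl0, function(s) all(s$recording$channels$valid),
                         logical(1))))
  # different seeds: different samples, identical schedule
  tlA <- generate_cohort_timeline(quiet_params(seed = 1), 3, session_s = 2)
  tlB <- generate_cohort_timeline(quiet_params(seed = 2), 3, session_s = 2)
  expect_false(identical(tlA[[1]]$recording$samples,
                         tlB[[1]]$recording$samples))
  expect_identical(vapply(tlA, `[[`, "", "condition"),
                   vapply(tlB, `[[`, "", "condition"))
  expect_error(generate_cohort_timeline(
    quiet_params(breakage_schedule = list(list(lead = "HC", contact = "E9",
                                               month = 2))), 3),
    "not on lead")
})
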