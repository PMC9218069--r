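test_that("artifact triggers recover the pulse train", {
  p <- quiet_params(seed = 31)
  ses <- generate_stim_session(p, stim_setting(4, "V", 5, 120, 30), "ep_train")
  tr <- detect_stim_artifacts(ses$recording, "HC_E0-E3")
  expect_length(tr, 150L)
  iti <- diff(tr) * 1000
  expect_true(all(abs(iti - 200) <= 4))
  # stimulation-free recording: no triggers
  rec0 <- generate_lfp(p, 20, state = "theta")
  expect_length(detect_stim_artifacts(rec0, "HC_E0-E3"), 0L)
})

test_that("pulses inside the refractory period collapse to one trigger", {
  fs <- 250
  x <- rnorm(5 * fs, sd = 1)
  for (t0 in c(2.0, 2.02)) {            # 20 ms apart, refractory 50 ms
    i <- round(t0 * fs) + 1
    x[i] <- x[i] + 400; x[i + 1] <- x[i + 1] - 400
  }
  expect_length(detect_stim_artifacts(vec_recording(x), "HC_E0-E3"), 1L)
})

test_that("epoch averaging reduces noise by 1/sqrt(N)", {
  # residual RMS is itself noisy (few dozen samples), so the law is checked
  # on the mean RMS over independent repetitions
  fs <- 250; sigma <- 10
  tmpl_fun <- function(tms) 40 * exp(-(tms - 37)^2 / (2 * 6^2))
  for (N in c(4, 25, 100)) {
    set.seed(N)
    rms <- vapply(1:6, function(rep) {
      trig <- (seq_len(N) - 1) * 0.5 + 1
      n <- round((max(trig) + 1) * fs)
      x <- rnorm(n, sd = sigma)
      tt <- (0:(n - 1)) / fs
      for (tr in trig) x <- x + tmpl_fun((tt - tr) * 1000) * (tt >= tr)
      ep <- average_epochs(vec_recording(x), trig, "HC_E0-E3")
      stopifnot(ep$n_epochs == N)
      keep <- ep$times >= 6               # outside the blanked artifact span
      sqrt(mean((ep$waveform[keep] - tmpl_fun(ep$times[keep]))^2))
    }, numeric(1))
    expect_lt(abs(mean(rms) - sigma / sqrt(N)) / (sigma / sqrt(N)), 0.2)
  }
})

test_that("a single noise-free epoch is returned verbatim", {
  fs <- 250
  x <- sin(2 * pi * 3 * (0:(2 * fs - 1)) / fs)
  ep <- average_epochs(vec_recording(x), 1.0, "HC_E0-E3")
  idx <- round(1.0 * fs) + 1 + round(ep$times / 1000 * fs)
  keep <- ep$times >= 6 | ep$times < 0
  expect_equal(ep$waveform[keep], x[idx][keep], tolerance = 1e-12)
  expect_error(average_epochs(vec_recording(x), 100, "HC_E0-E3"),
               "zero usable epochs")
})

test_that("ep_metrics finds the main peak with sign and sub-sample latency", {
  fs <- 250
  trig <- seq(1, 20, by = 0.5)
  n <- 22 * fs
  tt <- (0:(n - 1)) / fs
  x <- numeric(n)
  for (tr in trig) x <- x + 40 * exp(-((tt - tr) * 1000 - 37)^2 / 72)
  ep <- average_epochs(vec_recording(x), trig, "HC_E0-E3")
  expect_lt(abs(ep$latency - 37), 0.5)
  expect_lt(abs(ep$amplitude - 40), 1)
  expect_identical(ep$polarity, 1)
  epi <- average_epochs(vec_recording(-x), trig, "HC_E0-E3")
  expect_lt(abs(epi$latency - 37), 0.5)
  expect_identical(epi$polarity, -1)
  expect_error(ep_metrics(ep, c(0, 3)), "blanked")
})

test_that("EP latency is recovered within 1 ms and is gain invariant", {
  for (s in c(101, 202, 303)) {
    p <- quiet_params(seed = s)                # ep_latency default 37 ms
    ses <- generate_stim_session(p, stim_setting(4, "V", 5, 120, 30),
                                 "ep_train")
    tr <- detect_stim_artifacts(ses$recording, "HC_E0-E3")
    expect_gte(length(tr), 50)
    ep <- average_epochs(ses$recording, tr, "HC_E0-E3", align_to_peak = TRUE)
    expect_lt(abs(ep$latency - p$ep_latency), 1)
    expect_gte(ep$latency, 35); expect_lte(ep$latency, 40)
    # overall gain rescaling leaves the latency untouched
    sc <- ses$recording; sc$samples <- sc$samples * 10
    tr2 <- detect_stim_artifacts(sc, "HC_E0-E3")
    ep2 <- average_epochs(sc, tr2, "HC_E0-E3", align_to_peak = TRUE)
    expect_equal(ep2$latency, ep$latency, tolerance = 1e-9)
  }
})

test_that("trigger count equals pulse count across 50 seeded sessions", {
  counts <- vapply(1:50, function(s) {
    ses <- generate_stim_session(quiet_params(seed = s),
                                 stim_setting(4, "V", 5, 120, 30), "ep_train")
    length(detect_stim_artifacts(ses$recording, "HC_E0-E3"))
  }, numeric(1))
  expect_true(all(counts == 150))
})

test_that("burst classifier applies strict thresholds and handles shams", {
  p <- quiet_params(seed = 41)
  br <- generate_stim_session(p, stim_setting(1, "V", 50, 120, 10),
                              "burst_ramp", amplitudes = c(0.4, 0.6, 0.8, 1.0))
  cls <- classify_burst_responses(br$recording, br$events)
  expect_identical(cls$responses$label,
                   c("none", "suppression", "suppression", "after_discharge"))
  expect_identical(cls$theta_inh, 0.6)
  expect_identical(cls$theta_ad, 1.0)
  expect_true(all(cls$responses$post_pre_power_ratio[
    cls$responses$label == "suppression"] < 1))
  expect_gt(cls$responses$ad_ratio[cls$responses$label == "after_discharge"], 1)
  # all-sham ramp: everything "none"
  sham <- generate_stim_session(p, stim_setting(1, "V", 50, 120, 10),
                                "burst_ramp", amplitudes = c(0, 0, 0))
  cls0 <- classify_burst_responses(sham$recording, sham$events)
  expect_true(all(cls0$responses$label == "none"))
  expect_true(is.na(cls0$theta_inh) && is.na(cls0$theta_ad))
  # bursts packed tighter than the required clean windows are rejected
  fake <- lapply(c(1, 7), function(o)
    chronicsense:::stim_event(stim_setting(1, "V", 50, 120, 2), o, o + 2))
  expect_error(classify_burst_responses(br$recording, fake, pre_s = 5,
                                        post_s = 5), "too close")
})

test_that("the suppression criterion is a strict inequality at r_supp", {
  fs <- 250
  n <- 20 * fs
  tone <- 15 * sin(2 * pi * 4 * (0:(n - 1)) / fs)
  ev <- chronicsense:::stim_event(stim_setting(0.5, "V", 50, 120, 0.5),
                                  10, 10.5)
  scale_post <- function(fac) {
    x <- tone
    post <- (round(10.5 * fs) + 1):n
    x[post] <- x[post] * sqrt(fac)
    vec_recording(x)
  }
  just_above <- classify_burst_responses(scale_post(0.7 + 1e-6), list(ev))
  just_below <- classify_burst_responses(scale_post(0.7 - 1e-6), list(ev))
  expect_identical(just_above$responses$label, "none")
  expect_identical(just_below$responses$label, "suppression")
})
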