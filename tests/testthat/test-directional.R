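test_that("the directional montage is the canonical 15-pair set", {
  lead <- build_lead("1-3-3-1")
  mg <- enumerate_montage(lead)
  labels <- vapply(mg, `[[`, "", "label")
  expect_length(labels, 15L)
  expect_length(unique(labels), 15L)
  expect_setequal(labels, c(
    "E0-E1a", "E0-E1b", "E0-E1c",
    "E1a-E1b", "E1a-E1c", "E1b-E1c",
    "E2a-E2b", "E2a-E2c", "E2b-E2c",
    "E1a-E2a", "E1b-E2b", "E1c-E2c",
    "E2a-E3", "E2b-E3", "E2c-E3"))
  # 4-contact lead: all C(4,2) = 6 unordered pairs
  expect_length(enumerate_montage(build_lead("3389")), 6L)
  bad <- build_lead("1-3-3-1"); bad$contacts <- bad$contacts[1:5]
  expect_error(enumerate_montage(bad), "unsupported lead geometry")
  # scheduling: three 5-pair groups recorded 40 s each, 2 min total
  gr <- montage_groups(mg)
  expect_length(gr$groups, 3L)
  expect_true(all(vapply(gr$groups, length, 0L) == 5L))
  expect_identical(gr$total_s, 120)
})

test_that("radial spectra follow the configured direction gains", {
  p <- quiet_params(seed = 51, segment_gains = c(E1a = 1.0, E1b = 0.6,
                                                 E1c = 0.3, E2a = 1.0,
                                                 E2b = 0.6, E2c = 0.3))
  dl <- list(HC = build_lead("1-3-3-1"))
  rec <- generate_lfp(p, 30, leads = dl, state = "theta")
  rs <- radial_spectra(rec, "HC")
  bp <- vapply(rs, band_power, numeric(1), band = c(3, 8))
  expect_true(bp[["a"]] > bp[["b"]] && bp[["b"]] > bp[["c"]])
  # a broken pair drops its direction, the others survive
  rec$channels$valid[rec$channels$label == "HC_E1b-E2b"] <- FALSE
  rs2 <- radial_spectra(rec, "HC")
  expect_setequal(names(rs2), c("a", "c"))
  # missing pair entirely is a hard error naming the pair
  rec$channels$label[rec$channels$label == "HC_E1a-E2a"] <- "HC_E0-E1a"
  expect_error(radial_spectra(rec, "HC"), "HC_E1a-E2a")
})

test_that("noise-free distinct gains rank exactly by gain", {
  p <- quiet_params(seed = 52, noise_sd = 0,
                    segment_gains = c(E1a = 0.4, E1b = 0.9, E1c = 0.5,
                                      E2a = 0.7, E2b = 0.95, E2c = 0.6))
  dl <- list(HC = build_lead("1-3-3-1"))
  rec <- generate_lfp(p, 10, leads = dl, state = "theta")
  rk <- rank_segments(rec, dl$HC)
  expect_identical(rk$contact[order(rk$rank)],
                   c("E2b", "E1b", "E2a", "E2c", "E1c", "E1a"))
  expect_setequal(rk$rank, 1:6)
})

test_that("equal gains leave the top rank uniform across seeds", {
  g <- c(E1a = 0.7, E1b = 0.7, E1c = 0.7, E2a = 0.7, E2b = 0.7, E2c = 0.7)
  dl <- list(HC = build_lead("1-3-3-1"))
  tops <- vapply(1:240, function(s) {
    rec <- generate_lfp(quiet_params(seed = s, segment_gains = g), 10,
                        leads = dl, state = "theta")
    rk <- rank_segments(rec, dl$HC)
    rk$contact[rk$rank == 1]
  }, "")
  tab <- table(factor(tops, levels = names(g)))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("suppression profiles recover the generator's depth and recovery", {
  p <- quiet_params(seed = 53)
  dl <- list(HC = build_lead("1-3-3-1"))
  sw <- generate_stim_session(p, stim_setting(1, "mA", 100, 300, 10),
                              "directional_sweep", leads = dl,
                              post_s = 360, supp_minutes = 3,
                              sweep_contacts = "E2b")   # gain 1: depth 0.75
  pr <- suppression_response(sw$recording, sw$events[[1]], max_minutes = 6)
  expect_identical(pr$stimulated_contact, "E2b")
  expect_lt(abs(pr$normalized[1] - 0.25), 0.1)
  expect_lt(abs(pr$normalized[5] - 1), 0.15)
  expect_lt(abs(pr$normalized[6] - 1), 0.15)
  expect_gt(pr$baseline_power, 0)
  expect_length(pr$normalized, 6L)
  # sham stimulation: normalized stays near 1 throughout
  sham <- generate_stim_session(p, stim_setting(0, "mA", 100, 300, 10),
                                "directional_sweep", leads = dl,
                                post_s = 120, sweep_contacts = "E2b")
  ps <- suppression_response(sham$recording, sham$events[[1]],
                             max_minutes = 2)
  expect_true(all(abs(ps$normalized - 1) < 2 * ps$dispersion / ps$baseline_power + 0.15))
  # shortened baseline is rejected
  expect_error(suppression_response(sw$recording, sw$events[[1]],
                                    baseline_s = 10), "20 s")
  early <- chronicsense:::stim_event(sw$events[[1]]$setting, 5, 15)
  expect_error(suppression_response(sw$recording, early), "pre-stimulus")
})

test_that("rank concordance matches the hand Pearson oracle", {
  a <- c(E1a = 1, E1b = 2, E1c = 3)
  expect_identical(rank_concordance(a, a)$r_squared, 1)
  b <- c(E1a = 1, E1b = 3, E1c = 2)
  r_oracle <- oracle_pearson(a, b[names(a)])
  cc <- rank_concordance(a, b)
  expect_equal(cc$r_squared, r_oracle^2, tolerance = 1e-12)
  expect_equal(cc$r_squared, 0.25, tolerance = 1e-12)
  rev <- c(E1a = 3, E1b = 2, E1c = 1)
  crev <- rank_concordance(a, rev)
  expect_equal(crev$r_squared, 1, tolerance = 1e-12)   # direction blind
  expect_equal(crev$r, -1, tolerance = 1e-12)          # signed r disambiguates
  expect_error(rank_concordance(a, c(E2a = 1, E2b = 2, E2c = 3)), "identical")
  expect_error(rank_concordance(a[1:2], a[1:2]), ">= 3")
})

test_that("rank concordance is invariant under contact relabeling", {
  a <- c(E1a = 2, E1b = 1, E1c = 4, E2a = 3)
  b <- c(E1a = 1, E1b = 2, E1c = 3, E2a = 4)
  base <- rank_concordance(a, b)
  relab <- c(E1a = "S1", E1b = "S2", E1c = "S3", E2a = "S4")
  a2 <- a; names(a2) <- relab[names(a)]
  b2 <- b; names(b2) <- relab[names(b)]
  expect_equal(rank_concordance(a2, b2)$r_squared, base$r_squared,
               tolerance = 1e-12)
})
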