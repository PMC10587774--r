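# The synthetic cohort generator: determinism, marginal statistics and
# the structure the downstream analyses assume.

test_that("identical seeds give bit-identical cohorts", {
  cfg <- synth_config(n_patients = 1L, n_contacts = 2L,
                      recording_minutes = 0.5, seed = 9)
  a <- gen_ieeg(cfg)
  b <- gen_ieeg(cfg)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$recordings[[1]]$samples, b$recordings[[1]]$samples)
  u1 <- gen_unit_trains(cfg, a$truth)
  u2 <- gen_unit_trains(cfg, b$truth)
  expect_identical(u1$units[[1]]$ap_times_ms, u2$units[[1]]$ap_times_ms)
})

test_that("zero spike rate produces no spike-class events", {
  cfg <- tiny_cfg(rate_spike = 0, p_prime = 0.5)
  tru <- gen_ground_truth(cfg)
  expect_false(any(tru$events$class %in% c("fRonS", "RonS", "SharpSpike")))
  # priming needs spikes, so no primed events either
  expect_false(any(tru$events$primed == 1L))
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(fs_ieeg = 1000), "1200")
  expect_error(synth_config(rate_fRonO = -1), "non-negative")
  expect_error(synth_config(p_prime = 1.5), "p_prime")
})

test_that("event counts per channel are Poisson with the configured rate", {
  # placement before gap-thinning is homogeneous Poisson; use gap 0
  counts <- vapply(1:20, function(s) {
    cfg <- synth_config(n_patients = 1L, n_contacts = 1L,
                        recording_minutes = 10, rate_fRonO = 2,
                        rate_spike = 0, rate_RonO = 0, soz_fraction = 0,
                        soz_rate_factor = 1, min_event_gap_s = 0, seed = s)
    sum(gen_ground_truth(cfg)$events$class == "fRonO")
  }, 0)
  lambda <- 2 * 10
  se <- sqrt(lambda / 20)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("events lie inside epochs with strictly increasing onsets", {
  tru <- gen_ground_truth(tiny_cfg(p_prime = 0.4, seed = 3))
  for (ch in unique(tru$events$channel)) {
    on <- tru$events$onset_s[tru$events$channel == ch]
    expect_true(all(diff(on) > 0))
  }
  t_end <- tru$epochs$end_s[1]
  expect_true(all(tru$events$onset_s > 0 & tru$events$offset_s < t_end))
})

test_that("injected fast-ripple bursts concentrate power in 200-600 Hz", {
  set.seed(4)
  fs <- 2000
  for (i in 1:10) {
    cf <- runif(1, 210, 590)
    dur <- runif(1, 0.02, 0.1)
    b <- hfoprime:::hfo_burst(dur, cf, fs)
    b <- c(numeric(200), b, numeric(200))
    sp <- Mod(fft(b))^2
    f <- (seq_along(sp) - 1) * fs / length(sp)
    keep <- f <= fs / 2
    inband <- sum(sp[keep & f >= 200 & f <= 600])
    expect_gt(inband / sum(sp[keep]), 0.8)
  }
})

test_that("unit trains follow the configured baseline rate and gain", {
  # no events on a unit's contact: homogeneous Poisson at the base rate
  cfg <- synth_config(n_patients = 1L, n_contacts = 2L,
                      recording_minutes = 1, unit_base_rate = 5,
                      n_units_per_contact = 1L, rate_spike = 0,
                      rate_RonO = 0, rate_fRonO = 10, soz_fraction = 0.5,
                      soz_rate_factor = 1, seed = 2)
  counts <- vapply(1:20, function(s) {
    tru <- gen_ground_truth(cfg, seed = s)
    # pick a contact, strip its events so the unit sees none
    ch <- tru$electrodes$channel[1]
    tru$events <- tru$events[tru$events$channel != ch, , drop = FALSE]
    tr <- gen_unit_trains(cfg, tru, seed = s + 500L)
    u <- Filter(function(u) u$contact == ch, tr$units)[[1]]
    length(u$ap_times_ms)
  }, 0)
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300 / 20))

  # zero gain: rate inside events equals rate outside (Poisson error)
  cfg0 <- synth_config(n_patients = 1L, n_contacts = 1L,
                       recording_minutes = 10, unit_base_rate = 5,
                       unit_gain_per_log10power = 0,
                       n_units_per_contact = 1L, soz_fraction = 0,
                       seed = 11)
  tru <- gen_ground_truth(cfg0)
  tr <- gen_unit_trains(cfg0, tru)
  ap <- tr$units[[1]]$ap_times_ms / 1000
  ev <- tru$events
  inside <- vapply(ap, function(t)
    any(t >= ev$onset_s & t < ev$offset_s), TRUE)
  t_in <- sum(ev$offset_s - ev$onset_s)
  t_out <- 600 - t_in
  r_in <- sum(inside) / t_in
  r_out <- sum(!inside) / t_out
  expect_lt(abs(r_in - r_out), 3 * sqrt(5 / t_in))
  tru0 <- tru
  tru0$events <- tru0$events[0, ]
  expect_error(gen_unit_trains(cfg0, tru0), "no events")
})

test_that("uniform priming placement matches the SOZ fraction", {
  # enrichment 1: the fraction of pre-spike fRonO on SOZ contacts matches
  # the SOZ share of events, which is soz_fraction weighted by the SOZ
  # rate factor
  cfg <- synth_config(n_patients = 1L, n_contacts = 16L,
                      recording_minutes = 10, p_prime = 0.5,
                      prime_soz_enrichment = 1, soz_rate_factor = 1,
                      seed = 21)
  frac <- vapply(1:10, function(s) {
    tru <- gen_ground_truth(cfg, seed = s)
    soz_ch <- tru$electrodes$channel[tru$electrodes$soz == 1L]
    pr <- tru$events[tru$events$primed == 1L, ]
    mean(pr$channel %in% soz_ch)
  }, 0)
  expect_lt(abs(mean(frac) - 0.25), 0.05)
})
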