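# HFO->spike latencies, coincidence flags and the surrogate null.

test_that("minimum positive latency is strict and handles edge cases", {
  expect_equal(min_positive_latency(10.0, c(9.5, 10.2, 10.5)), 200)
  # a spike exactly at the HFO onset is skipped (strictly positive)
  expect_equal(min_positive_latency(10.0, c(10.0, 10.4)), 400)
  expect_true(is.na(min_positive_latency(10.0, c(9.0, 9.9))))
  expect_equal(length(min_positive_latency(numeric(0), 1)), 0L)
  expect_true(all(is.na(min_positive_latency(c(1, 2), numeric(0)))))
})

test_that("latency operator matches the brute force on random instances", {
  set.seed(42)
  for (i in 1:25) {
    h <- sort(runif(sample(1:30, 1), 0, 100))
    s <- sort(runif(sample(0:30, 1), 0, 100))
    expect_equal(min_positive_latency(h, s), latency_bruteforce(h, s))
  }
})

test_that("coincidence flags respect the strict 300 ms window", {
  # window bound chosen exactly representable in binary (0.3125 s) so the
  # boundary case is a true equality
  ev <- data.frame(channel = "C1",
                   class = c("fRonO", "fRonS", "fRonO", "RonS", "RonO",
                             "SharpSpike", "fRonO"),
                   onset_s = c(1.00, 1.25, 5.0000, 5.3125, 9.00, 9.10,
                               20.0),
                   stringsAsFactors = FALSE)
  fl <- flag_coincidence(ev, window_ms = 312.5)
  expect_equal(fl$prespike[1], 1L)               # 250 ms before the fRonS
  expect_equal(fl$followed_fRonO[2], 1L)
  expect_equal(fl$prespike[3], 0L)               # exactly at the bound: strict <
  expect_equal(fl$followed_fRonO[4], 0L)
  expect_equal(fl$prespike[5], 1L)               # sharp spikes count too
  expect_equal(fl$latency_to_spike_ms[5], 100, tolerance = 1e-9)
  expect_equal(fl$prespike[7], 0L)               # no later spike
  expect_true(is.na(fl$latency_to_spike_ms[7]))
})

test_that("surrogate null is reproducible and shift-invariant", {
  cfg <- tiny_cfg(p_prime = 0.4, seed = 6)
  tru <- gen_ground_truth(cfg)
  ev <- truth_events_table(tru)
  s1 <- surrogate_null(ev, tru$epochs, n = 200, seed = 99)
  s2 <- surrogate_null(ev, tru$epochs, n = 200, seed = 99)
  expect_identical(s1$z, s2$z)
  expect_equal(length(s1$surrogate_counts), 200L)
  # global time shift of events and epochs leaves z unchanged
  ev3 <- ev; ev3$onset_s <- ev3$onset_s + 1000
  epo3 <- tru$epochs
  epo3$start_s <- epo3$start_s + 1000; epo3$end_s <- epo3$end_s + 1000
  s3 <- surrogate_null(ev3, epo3, n = 200, seed = 99)
  expect_equal(s3$z, s1$z, tolerance = 1e-9)
  expect_equal(s3$observed, s1$observed)
})

test_that("primed generators give large positive pooled z", {
  cfg <- tiny_cfg(p_prime = 0.5, seed = 31)
  tru <- gen_ground_truth(cfg)
  sr <- surrogate_null(truth_events_table(tru), tru$epochs, n = 300,
                       seed = 7)
  expect_gt(sr$z, 3)
  expect_lt(sr$empirical_p, 0.05)
})

test_that("cumulative spike:fRonO ratios behave as documented", {
  on_f <- seq(30, 570, length.out = 10)       # 10 fRonO over 10 min
  on_s <- seq(60, 540, length.out = 5)        # 5 fRonS
  ev <- data.frame(channel = "C1",
                   class = c(rep("fRonO", 10), rep("fRonS", 5)),
                   onset_s = c(on_f, on_s), stringsAsFactors = FALSE)
  rt <- ratio_timeseries(ev, bin_s = 60, t_end = 600)
  expect_equal(tail(rt$ratio_fRonS_fRonO, 1), 0.5)
  # no fRonO: all missing
  ev2 <- ev[ev$class == "fRonS", ]
  rt2 <- ratio_timeseries(ev2, bin_s = 60, t_end = 600)
  expect_true(all(is.na(rt2$ratio_fRonS_fRonO)))
  # generator with RonS outnumbering fRonO: terminal RonS ratio above 1
  cfg <- tiny_cfg(rate_fRonO = 1, rate_spike = 4, seed = 12)
  tru <- gen_ground_truth(cfg)
  rt3 <- ratio_timeseries(tru$events, bin_s = 60,
                          t_end = tru$epochs$end_s[1])
  term <- rt3$ratio_RonS_fRonO[rt3$t_s == max(rt3$t_s)]
  expect_gt(mean(term, na.rm = TRUE), 1)
})

test_that("latency histogram is normalized and matches the surrogate z", {
  # all latencies at 150 ms: unit mass in the first bin
  ev <- data.frame(channel = "C1",
                   class = c("fRonO", "fRonS"),
                   onset_s = c(1.0, 1.15), stringsAsFactors = FALSE)
  ep <- data.frame(channel = "C1", start_s = 0, end_s = 10)
  lh <- latency_histogram(ev, ep, breaks = c(0, 300, 600), n = 20, seed = 1)
  expect_equal(lh$observed, c(1, 0))
  # uniform latencies on (0, 3 s): first 300 ms bin holds ~10% of the mass
  set.seed(5)
  on_h <- sort(600 - runif(400, 0, 3))
  ev3 <- data.frame(channel = "C1",
                    class = c(rep("fRonO", 400), "fRonS"),
                    onset_s = c(on_h, 600), stringsAsFactors = FALSE)
  ep3 <- data.frame(channel = "C1", start_s = 0, end_s = 601)
  lh3 <- latency_histogram(ev3, ep3, breaks = seq(0, 3000, 300), n = 20,
                           seed = 2)
  expect_lt(abs(lh3$observed[1] - 0.1), 0.06)
  # internal consistency: first-bin z equals the surrogate test z under
  # the same seed
  cfg <- tiny_cfg(p_prime = 0.3, seed = 44)
  tru <- gen_ground_truth(cfg)
  evt <- truth_events_table(tru)
  lh4 <- latency_histogram(evt, tru$epochs, breaks = seq(0, 3000, 300),
                           n = 200, seed = 77)
  sr4 <- surrogate_null(evt, tru$epochs, n = 200, seed = 77)
  expect_equal(lh4$z_first_bin, sr4$z, tolerance = 1e-9)
})
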