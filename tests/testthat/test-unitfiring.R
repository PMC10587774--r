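# Peri-event firing: smoothing, trial construction, firing statistics,
# unit inclusion, effect sizes.

test_that("Gaussian smoothing has the analytic peak and conserves count", {
  r <- integer(2000); r[1000] <- 1L
  s <- smooth_rate(r, full = TRUE)
  # unit-area 100 ms Gaussian peaks at 1/(sigma*sqrt(2*pi)) ~ 3.99 Hz
  expect_equal(max(attr(s, "full")), 1 / (0.1 * sqrt(2 * pi)),
               tolerance = 1e-3)
  expect_equal(sum(attr(s, "full")) * 0.001, 1, tolerance = 1e-12)
  r2 <- integer(2000); r2[c(3, 500, 1999)] <- 1L
  s2 <- smooth_rate(r2, full = TRUE)
  expect_equal(sum(attr(s2, "full")) * 0.001, 3, tolerance = 1e-12)
  expect_true(all(smooth_rate(integer(2000)) == 0))
  expect_length(smooth_rate(integer(2000)), 80L)
})

test_that("long homogeneous trains recover their rate after smoothing", {
  set.seed(9)
  means <- replicate(10, {
    r <- as.integer(runif(2000) < 0.010)   # 10 Hz at 1 ms bins
    mean(smooth_rate(r))
  })
  expect_lt(abs(mean(means) - 10), 0.7)
})

test_that("trials pair events with same-bundle units only", {
  ev <- data.frame(patient_id = "P01", channel = "C1",
                   class = "fRonO", onset_s = c(5, 8, 11),
                   offset_s = c(5.05, 8.05, 11.05), peak_freq_hz = 300,
                   log10_power = 3, duration_ms = 50, prespike = 0L,
                   followed_fRonO = 0L, followed_RonO = 0L,
                   stringsAsFactors = FALSE)
  units <- list(
    unit_spike_train("U1", "P01", "C1", "single", c(4000, 5010, 8020)),
    unit_spike_train("U2", "P01", "C1", "multi", c(100, 9000)),
    unit_spike_train("U3", "P01", "C2", "single", c(5000, 8000)))
  tr <- build_trials(ev, units, rec_duration_s = 60)
  expect_equal(nrow(tr), 6L)                 # 3 events x 2 same-bundle units
  expect_false("U3" %in% tr$unit_id)
  # an event too close to the recording start is dropped
  ev2 <- ev; ev2$onset_s[1] <- 0.5
  tr2 <- build_trials(ev2, units, rec_duration_s = 60)
  expect_equal(nrow(tr2), 4L)
  # raster has the APs in the right 1 ms bins
  ras <- attr(tr, "rasters")
  i <- which(tr$unit_id == "U1" & tr$onset_s == 5)
  expect_equal(which(ras[i, ] == 1L), c(1, 1011))  # 4000ms -> bin 1; 5010 -> 1011
})

test_that("trial firing statistics follow their definitions", {
  times <- seq(-1000, 975, by = 25)
  const <- rep(5, 80)
  expect_equal(unname(trial_rates(const, times, 40)), c(5, 5, 0))
  # 30 ms event: max over samples at 0 and 25 ms only
  x <- rep(1, 80)
  x[times == 0] <- 4; x[times == 25] <- 7; x[times == 50] <- 50
  tr <- trial_rates(x, times, 30)
  expect_equal(unname(tr["hfo_fr"]), 7)
  expect_warning(trial_rates(x, times, 3000), "clamp")
  expect_true(all(trial_rates(abs(x), times, 100)[1:2] >= 0))
})

test_that("Holm step-down inclusion matches the brute force exactly", {
  expect_equal(holm_include(c(1e-4, 0.5), alpha = 0.001), c(TRUE, FALSE))
  set.seed(77)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:6, 1)
    a <- c(0.001, 0.05)[sample(1:2, 1)]
    expect_identical(holm_include(p, a), holm_bruteforce(p, a))
  }
})

test_that("unit inclusion keeps responsive units and drops silent ones", {
  set.seed(3)
  mk_trials <- function(uid, gain, n = 200) {
    bl <- rnorm(n, 5, 1)
    data.frame(unit_id = uid, class = "fRonO", bl_fr = bl,
               hfo_fr = pmax(0, rnorm(n, 5 * gain, 1.5)),
               stringsAsFactors = FALSE)
  }
  tr <- rbind(mk_trials("U_resp", 3), mk_trials("U_flat", 1))
  inc <- unit_inclusion_test(tr, classes = "fRonO")
  expect_true(inc$included[inc$unit_id == "U_resp"])
  expect_false(inc$included[inc$unit_id == "U_flat"])
  # degenerate zero-variance differences are excluded
  tr0 <- data.frame(unit_id = "U0", class = "fRonO", bl_fr = rep(2, 10),
                    hfo_fr = rep(2, 10), stringsAsFactors = FALSE)
  inc0 <- unit_inclusion_test(tr0, classes = "fRonO")
  expect_false(inc0$included)
  expect_equal(inc0$p, 1)
})

test_that("grand averages and peak-time histograms work on trials", {
  ev <- data.frame(patient_id = "P01", channel = "C1", class = "fRonO",
                   onset_s = c(5, 8), offset_s = c(5.05, 8.05),
                   peak_freq_hz = 300, log10_power = 3, duration_ms = 50,
                   prespike = c(0L, 1L), followed_fRonO = 0L,
                   followed_RonO = 0L, stringsAsFactors = FALSE)
  u <- unit_spike_train("U1", "P01", "C1", "single", c(5010, 8010))
  tr <- build_trials(ev, list(u), rec_duration_s = 60)
  ga <- grand_average(tr, groups = c("a", "a"))
  expect_equal(ga$a$n, 2L)
  # identical trials: zero-width confidence band
  expect_equal(ga$a$lo, ga$a$hi, tolerance = 1e-9)
  pk <- peak_time_histogram(tr, breaks = seq(-1000, 1000, 20))
  expect_equal(sum(pk$counts), 2L)
  expect_true(all(pk$peak_times_ms >= 0 & pk$peak_times_ms <= 25))
  # flat series: argmax tie resolves to the earliest sample
  flat <- tr
  attr(flat, "rates") <- matrix(1, 2, 80)
  pk2 <- peak_time_histogram(flat)
  expect_true(all(pk2$peak_times_ms == -1000))
})

test_that("Cohen's d follows the pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0, 2); b <- c(1, 3)    # pooled sd = sqrt(2), diff = -1
  expect_equal(cohens_d(a, b), -1 / sqrt(2))
  set.seed(10)
  x <- rnorm(40); y <- rnorm(30, 0.4)
  sp <- sqrt(((39) * var(x) + 29 * var(y)) / 68)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("pre-spike power stratification respects half-open bins", {
  ev <- data.frame(class = "fRonO", prespike = 1L,
                   latency_to_spike_ms = c(5, 10, 150, 299.9),
                   log10_power = c(4, 3, 2, 1), stringsAsFactors = FALSE)
  pb <- power_by_latency(ev)
  expect_equal(pb$n, c(1L, 3L))               # 10 ms belongs to [10, 300)
  expect_equal(pb$mean_log10_power, c(4, 2))
  single <- power_by_latency(ev[1, ])
  expect_equal(single$mean_log10_power, c(4, NA))
})
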