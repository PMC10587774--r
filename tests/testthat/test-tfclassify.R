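# Stage-2: wavelet maps, the isopower contour threshold, contour topology
# and the CLC/OLC classification rules.

# blob in (time, log-frequency); returns freqs x times power field
blob_field <- function(freqs, times, f0, t0, amp = 10, sf = 0.12,
                       st = 0.02) {
  outer(exp(-(log(freqs) - log(f0))^2 / (2 * sf^2)),
        exp(-(times - t0)^2 / (2 * st^2))) * amp
}

# broadband spike signature: low-frequency-rooted ridge, open at the map
# bottom (centre frequency below the 60 Hz floor)
spike_field <- function(freqs, times, t0, amp = 12, st = 0.02) {
  outer(exp(-(log(freqs) - log(35))^2 / (2 * 0.45^2)),
        exp(-(times - t0)^2 / (2 * st^2))) * amp
}

grid_tf <- function(power) {
  make_tf_map(power, tfr_freq_grid(n = 48, lo = 60, hi = 800),
              seq(0, 0.8, length.out = 200))
}

test_that("wavelet map localizes a pure tone and scales quadratically", {
  fs <- 2000
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 150 * t)
  tf <- wavelet_tfr(x, fs, whiten = FALSE)
  prof <- rowMeans(tf$power)
  fhat <- tf$freqs[which.max(prof)]
  step <- tf$freqs[2] / tf$freqs[1]
  expect_lt(abs(log(fhat / 150)), log(step) * 1.0001)
  tf2 <- wavelet_tfr(2 * x, fs, whiten = FALSE)
  expect_equal(tf2$power, 4 * tf$power, tolerance = 1e-10)
  # determinism
  set.seed(1); w <- rnorm(fs)
  expect_identical(wavelet_tfr(w, fs)$power, wavelet_tfr(w, fs)$power)
})

test_that("contour threshold follows 0.2 * (max - min) + min", {
  m <- matrix(c(5, 1, 2, 3), 2)
  expect_equal(contour_threshold(m), 0.2 * (5 - 1) + 1)
  expect_equal(contour_threshold(m * 10), 10 * contour_threshold(m))
  const <- grid_tf(matrix(2, 48, 200))
  expect_equal(contour_threshold(const), 2)
  expect_equal(nrow(extract_contours(const)$contours), 0L)
})

test_that("contour topology: closed blobs, truncated blobs, grouping", {
  fr <- tfr_freq_grid(n = 48, lo = 60, hi = 800)
  ts <- seq(0, 0.8, length.out = 200)
  # single interior blob: at least one closed contour, one group
  tf1 <- grid_tf(blob_field(fr, ts, 250, 0.4) + 0.01)
  cs1 <- extract_contours(tf1)
  expect_gte(sum(cs1$contours$closed), 1L)
  expect_equal(length(unique(cs1$contours$group[cs1$contours$closed])), 1L)
  # blob truncated by the time edge: outermost contour open
  tf2 <- grid_tf(blob_field(fr, ts, 250, 0.01) + 0.01)
  cs2 <- extract_contours(tf2)
  outer2 <- cs2$contours[which.min(cs2$contours$level), ]
  expect_false(outer2$closed)
  # two separated blobs: two groups, matching the flood-fill oracle
  tf3 <- grid_tf(blob_field(fr, ts, 120, 0.25) +
                   blob_field(fr, ts, 420, 0.6, amp = 6) + 0.01)
  cs3 <- extract_contours(tf3)
  expect_equal(length(unique(cs3$contours$group[cs3$contours$closed])), 2L)
  lab <- flood_fill_components(tf3$power >= contour_threshold(tf3))
  expect_equal(max(lab), 2L)
})

test_that("every contour label matches the first==last vertex check", {
  for (s in 1:10) {
    rb <- random_blob_map(s)
    cs <- extract_contours(rb$tf)
    for (i in seq_len(nrow(cs$contours))) {
      v <- cs$vertices[[i]]
      expect_identical(cs$contours$closed[i],
                       v[1, 1] == v[nrow(v), 1] && v[1, 2] == v[nrow(v), 2])
    }
  }
})

test_that("classification rules distinguish the five event classes", {
  fr <- tfr_freq_grid(n = 48, lo = 60, hi = 800)
  ts <- seq(0, 0.8, length.out = 200)
  # CLC group at 250 Hz, no OLC -> fRonO
  ev <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 250, 0.4) + 0.01)))
  expect_equal(ev$class, "fRonO")
  expect_lt(abs(ev$peak_freq_hz - 250), 25)
  # ripple CLC with a spike OLC starting 40 ms earlier -> RonS
  ev2 <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 120, 0.44) + spike_field(fr, ts, 0.42) + 0.01)))
  expect_equal(ev2$class, "RonS")
  # fast-ripple CLC on a spike -> fRonS
  ev3 <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 350, 0.44) + spike_field(fr, ts, 0.42) + 0.01)))
  expect_equal(ev3$class, "fRonS")
  # OLC only -> SharpSpike
  ev4 <- classify_event(extract_contours(grid_tf(
    spike_field(fr, ts, 0.4) + 0.01)))
  expect_equal(ev4$class, "SharpSpike")
  # spike OLC later than the CLC onset -> still an HFO on oscillation
  ev5 <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 350, 0.3) + spike_field(fr, ts, 0.55) + 0.01)))
  expect_equal(ev5$class, "fRonO")
})

test_that("the ripple/fast-ripple boundary sits at 200 Hz", {
  fr <- tfr_freq_grid(n = 48, lo = 60, hi = 800)
  ts <- seq(0, 0.8, length.out = 200)
  lo <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 180, 0.4) + 0.01)))
  hi <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 222, 0.4) + 0.01)))
  expect_equal(lo$class, "RonO")
  expect_equal(hi$class, "fRonO")
})

test_that("stronger events report larger log10 power", {
  fr <- tfr_freq_grid(n = 48, lo = 60, hi = 800)
  ts <- seq(0, 0.8, length.out = 200)
  p1 <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 300, 0.4, amp = 5) + 0.01)))$log10_power
  p2 <- classify_event(extract_contours(grid_tf(
    blob_field(fr, ts, 300, 0.4, amp = 20) + 0.01)))$log10_power
  expect_gt(p2, p1)
})

test_that("classify_all handles empty candidate sets and real cohorts", {
  rec <- ieeg_recording(matrix(rnorm(2000 * 5), 1), 2000, "C1")
  empty <- classify_all(rec, data.frame(channel = character(0),
                                        band = character(0),
                                        onset_s = numeric(0),
                                        offset_s = numeric(0),
                                        peak_z = numeric(0)))
  expect_equal(nrow(empty), 0L)
  # small synthetic cohort: majority of fRonS truth assigned fRonS
  cfg <- synth_config(n_patients = 1L, n_contacts = 2L,
                      recording_minutes = 2,
                      spike_mix = c(fRonS = 0.8, RonS = 0.1,
                                    SharpSpike = 0.1), seed = 17)
  sim <- gen_ieeg(cfg)
  ev <- run_pipeline(sim$recordings[[1]])
  acc <- classification_accuracy(ev, sim$truth$events)
  m <- acc$matches
  frs <- m[m$truth_class == "fRonS" & !is.na(m$detected_class), ]
  expect_gt(mean(frs$detected_class == "fRonS"), 0.5)
  expect_gt(acc$accuracy, 0.75)
})
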