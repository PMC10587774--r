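# SOZ/resection ratios and the fast-ripple rate-distance radius.

mk_el <- function(n, soz = integer(n), resected = integer(n), pid = "P01") {
  data.frame(patient_id = pid, channel = sprintf("%s_C%02d", pid, 1:n),
             x_mm = seq(0, by = 10, length.out = n), y_mm = 0, z_mm = 0,
             soz = soz, resected = resected, stringsAsFactors = FALSE)
}

mk_ev <- function(channels, class = "fRonO", freq = 400, pid = "P01") {
  n <- length(channels)
  data.frame(patient_id = pid, channel = channels, class = class,
             onset_s = seq_len(n), offset_s = seq_len(n) + 0.05,
             peak_freq_hz = freq, log10_power = 3, duration_ms = 50,
             prespike = 0L, followed_fRonO = 0L, followed_RonO = 0L,
             stringsAsFactors = FALSE)
}

test_that("event ratios count flagged contacts correctly", {
  el <- mk_el(4, soz = c(1L, 0L, 0L, 0L), resected = c(1L, 1L, 0L, 0L))
  ev <- mk_ev(el$channel[c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4, 4, 4)])
  expect_equal(event_ratios(ev, el, "fRonO", "soz"), 3 / 12)
  expect_equal(event_ratios(ev, el, "fRonO", "resected"), 5 / 12)
  expect_true(is.na(event_ratios(ev, el, "RonS", "soz")))
  all_res <- mk_ev(el$channel[c(1, 2)])
  expect_equal(event_ratios(all_res, el, "fRonO", "resected"), 1)
  # complement property: soz + non-soz shares sum to one
  el2 <- el; el2$soz <- 1L - el2$soz
  expect_equal(event_ratios(ev, el, "fRonO", "soz") +
                 event_ratios(ev, el2, "fRonO", "soz"), 1)
})

test_that("rate-distance weights follow mean-rate times distance", {
  el <- mk_el(2)
  # rates 2 and 4 events/min over 1 minute, 10 mm apart -> weight 30
  ev <- mk_ev(rep(el$channel, c(2, 4)))
  g <- rate_distance_matrix(ev, el, "all", minutes = 1)
  expect_equal(unname(g$weights[1, 2]), (2 + 4) / 2 * 10)
  expect_equal(g$weights, t(g$weights))
  expect_true(all(diag(g$weights) == 0))
  # scaling coordinates doubles every weight
  el2 <- el; el2$x_mm <- el2$x_mm * 2
  g2 <- rate_distance_matrix(ev, el2, "all", minutes = 1)
  expect_equal(g2$weights, 2 * g$weights)
  # zero-rate contacts are not generator sites
  el3 <- mk_el(3)
  ev3 <- mk_ev(rep(el3$channel[c(1, 3)], c(2, 4)))
  g3 <- rate_distance_matrix(ev3, el3, "all", minutes = 1)
  expect_equal(dim(g3$weights), c(2L, 2L))
  expect_false(el3$channel[2] %in% rownames(g3$weights))
  expect_error(rate_distance_matrix(mk_ev(el3$channel[1]), el3, "all", 1),
               "generator sites")
  # the frequency cut keeps only fast fRonO and any fRonS
  ev4 <- rbind(mk_ev(el$channel[1], freq = 300),
               mk_ev(el$channel[2], class = "fRonS", freq = NA))
  expect_error(rate_distance_matrix(ev4[1, ], el, "all", 1),
               "generator sites")  # 300 Hz fRonO is below the 350 Hz cut
  g4 <- rate_distance_matrix(ev4, el, "all", 1, freq_cut_hz = 250)
  expect_equal(dim(g4$weights), c(2L, 2L))
})

test_that("graph radius equals the minimum eccentricity", {
  expect_equal(graph_radius(matrix(c(0, 3, 3, 0), 2)), 3)
  w <- matrix(c(0, 1, 5, 1, 0, 2, 5, 2, 0), 3)
  expect_equal(graph_radius(w), 2)         # eccentricities 5, 2, 5
  # permutation invariance
  p <- c(3, 1, 2)
  expect_equal(graph_radius(w[p, p]), 2)
  # isolated node excluded with a warning
  w2 <- matrix(c(0, 2, NA, 2, 0, NA, NA, NA, 0), 3)
  expect_warning(r2 <- graph_radius(w2), "isolated")
  expect_equal(r2, 2)
  expect_error(graph_radius(matrix(c(0, NA, NA, 0), 2)), "no finite")
})

test_that("graph radius matches the brute force on random graphs", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    w <- matrix(runif(n * n, 0, 10), n)
    w <- (w + t(w)) / 2; diag(w) <- 0
    w[w < 2 & row(w) != col(w)] <- NA
    oracle <- radius_bruteforce(w)
    got <- tryCatch(suppressWarnings(graph_radius(w)),
                    error = function(e) NA_real_)
    expect_identical(is.na(got), is.na(oracle))
    if (!is.na(got)) expect_equal(got, oracle)
  }
})

test_that("radius difference takes the root or flags the sign", {
  expect_equal(radius_difference(5, 4), 1)
  expect_equal(radius_difference(7, 7), 0)
  rd <- radius_difference(3, 4)
  expect_true(is.na(rd))
  expect_true(attr(rd, "negative_argument"))
})

test_that("cohort reports stratify metrics by outcome", {
  cfg <- synth_config(n_patients = 6L, n_contacts = 16L,
                      recording_minutes = 5, p_prime = 0.4,
                      prime_soz_enrichment = 4, simulate_outcomes = TRUE,
                      szfree_fraction = 0.5, seed = 14)
  tru <- gen_ground_truth(cfg)
  ev <- truth_events_table(tru)
  met <- localization_metrics(ev, tru$electrodes, minutes = 5)
  expect_equal(nrow(met), 6L)
  expect_true(all(met$soz_ratio_fRonO >= 0 & met$soz_ratio_fRonO <= 1,
                  na.rm = TRUE))
  rep <- cohort_report(met, tru$outcomes)
  expect_true(is.finite(rep$ranksum$radius_difference$p) ||
                is.na(rep$ranksum$radius_difference$p))
  expect_error(cohort_report(met[1:3, ],
                             tru$outcomes[tru$outcomes$patient_id %in%
                                            met$patient_id[1:3], ]),
               "2 patients")
})
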