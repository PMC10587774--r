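# Event-aligned unit firing: 2 s / 1 ms rasters around each HFO/spike
# event, Gaussian-smoothed rates at 40 Hz, baseline vs in-event firing and
# the Holm-Bonferroni unit-inclusion test.

#' Gaussian-smoothed firing rate of a 1 ms raster
#'
#' Convolves a binary 1 ms raster with a unit-area Gaussian kernel
#' (\code{sigma_ms} SD, truncated at 4 SD) and samples the result at 40 Hz
#' (every 25th millisecond value; no averaging).  Rates are in Hz.  The
#' full-resolution convolution conserves spike count: its integral equals
#' the number of spikes in the raster.
#'
#' @param raster binary (0/1) vector, 1 ms bins; bin i covers
#'   \code{[i-1, i)} ms from the window start.
#' @param sigma_ms Gaussian kernel SD in ms (default 100).
#' @param step_ms decimation step in ms (default 25, i.e. 40 Hz).
#' @param full also return the full-support 1 kHz convolution (attribute
#'   \code{"full"}, length \code{length(raster) + 8 * sigma_ms}), whose
#'   integral equals the spike count exactly.
#' @return numeric rate series in Hz, sampled at times
#'   \code{0, step, 2*step, ...} ms from the window start; attribute
#'   \code{"times_ms"} holds the sample times.
#' @export
smooth_rate <- function(raster, sigma_ms = 100, step_ms = 25, full = FALSE) {
  n <- length(raster)
  half <- 4 * sigma_ms
  tk <- (-half):half
  kern <- exp(-tk^2 / (2 * sigma_ms^2))
  kern <- kern / (sum(kern) * 0.001)           # unit area in seconds -> Hz
  yfull <- numeric(n + 2 * half)               # full convolution support
  sp <- which(raster != 0)
  for (s in sp) {
    idx <- s:(s + 2L * half)                   # s - half .. s + half, shifted
    yfull[idx] <- yfull[idx] + raster[s] * kern
  }
  y <- yfull[(half + 1L):(half + n)]
  idx <- seq(1L, n, by = step_ms)
  out <- y[idx]
  attr(out, "times_ms") <- idx - 1
  if (full) attr(out, "full") <- yfull
  out
}

#' Build event-unit trials
#'
#' One trial per (event, unit) pair where the unit's microwire bundle sits
#' on the event's macroelectrode contact (comparisons are within a depth
#' electrode, never across).  Each trial is a 2 s raster of 1 ms bins
#' centred on the event onset; trials whose window crosses a recording edge
#' are dropped.
#'
#' @param events classified (and flagged) events data frame.
#' @param units list of \code{\link{unit_spike_train}}.
#' @param window_ms trial window length (default 2000).
#' @param rec_duration_s recording duration used for edge dropping
#'   (default \code{Inf}, i.e. only the left edge is enforced).
#' @param smooth compute the smoothed rate series and firing statistics
#'   (default TRUE).
#' @return data frame of class \code{event_unit_trials}, one row per trial:
#'   ids, event class, flags, log10_power, duration, bl_fr, hfo_fr,
#'   hfodiff_fr; rasters and rate series in attributes \code{"rasters"} and
#'   \code{"rates"} (matrices, one row per trial).
#' @export
build_trials <- function(events, units, window_ms = 2000,
                         rec_duration_s = Inf, smooth = TRUE) {
  half_s <- window_ms / 2000
  rows <- list(); rasters <- list(); rates <- list()
  for (u in units) {
    ev <- events[events$channel == u$contact, , drop = FALSE]
    if (!nrow(ev)) next
    ap <- u$ap_times_ms
    for (j in seq_len(nrow(ev))) {
      on <- ev$onset_s[j]
      if (on - half_s < 0 || on + half_s > rec_duration_s) next
      rel <- ap - on * 1000 + window_ms / 2       # ms from window start
      bins <- floor(rel) + 1L
      bins <- bins[bins >= 1L & bins <= window_ms]
      raster <- integer(window_ms)
      raster[bins] <- 1L                           # binary raster
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u$unit_id, contact = u$contact, patient_id = u$patient_id,
        unit_type = u$unit_type, class = ev$class[j], onset_s = on,
        duration_ms = ev$duration_ms[j], log10_power = ev$log10_power[j],
        prespike = ev$prespike[j] %||% 0L,
        followed_fRonO = ev$followed_fRonO[j] %||% 0L,
        followed_RonO = ev$followed_RonO[j] %||% 0L,
        stringsAsFactors = FALSE)
      rasters[[length(rasters) + 1L]] <- raster
    }
  }
  if (!length(rows)) {
    df <- data.frame(unit_id = character(0), contact = character(0),
                     patient_id = character(0), unit_type = character(0),
                     class = character(0), onset_s = numeric(0),
                     duration_ms = numeric(0), log10_power = numeric(0),
                     prespike = integer(0), followed_fRonO = integer(0),
                     followed_RonO = integer(0))
    attr(df, "rasters") <- matrix(0L, 0, window_ms)
    attr(df, "rates") <- matrix(0, 0, window_ms / 25)
    class(df) <- c("event_unit_trials", class(df))
    return(df)
  }
  df <- do.call(rbind, rows)
  rmat <- do.call(rbind, rasters)
  df$bl_fr <- NA_real_; df$hfo_fr <- NA_real_; df$hfodiff_fr <- NA_real_
  if (smooth) {
    smat <- t(apply(rmat, 1, smooth_rate))
    times <- attr(smooth_rate(rmat[1, ]), "times_ms") - window_ms / 2
    for (i in seq_len(nrow(df))) {
      tr <- trial_rates(smat[i, ], times, df$duration_ms[i])
      df$bl_fr[i] <- tr[1]; df$hfo_fr[i] <- tr[2]; df$hfodiff_fr[i] <- tr[3]
    }
    attr(df, "rates") <- smat
    attr(df, "rate_times_ms") <- times
  }
  attr(df, "rasters") <- rmat
  class(df) <- c("event_unit_trials", class(df))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline, peak and difference firing rates of one trial
#'
#' \code{bl_fr} is the mean smoothed rate over [-750, 0) ms before event
#' onset; \code{hfo_fr} the maximum over [0, duration] ms (clamped to the
#' window end, with a warning, if the event outlasts the window);
#' \code{hfodiff_fr = hfo_fr - bl_fr}.
#'
#' @param rate_series smoothed rate samples (Hz).
#' @param times_ms sample times in ms relative to event onset.
#' @param duration_ms event duration in ms.
#' @param baseline_ms baseline extent before onset (default 750).
#' @return numeric c(bl_fr, hfo_fr, hfodiff_fr).
#' @export
trial_rates <- function(rate_series, times_ms, duration_ms,
                        baseline_ms = 750) {
  bl <- mean(rate_series[times_ms >= -baseline_ms & times_ms < 0])
  if (is.na(duration_ms)) duration_ms <- 0
  if (duration_ms > max(times_ms)) {
    warning("event duration exceeds trial window; clamping")
    duration_ms <- max(times_ms)
  }
  hf <- max(rate_series[times_ms >= 0 & times_ms <= duration_ms])
  c(bl_fr = bl, hfo_fr = hf, hfodiff_fr = hf - bl)
}

#' Holm-Bonferroni step-down inclusion decisions
#'
#' Returns which hypotheses survive the Holm step-down procedure at
#' family-wise level \code{alpha}.
#'
#' @param p vector of p-values.
#' @param alpha family-wise level.
#' @return logical vector: TRUE where the Holm-adjusted p is at most
#'   \code{alpha}.
#' @export
holm_include <- function(p, alpha = 0.001) {
  p.adjust(p, method = "holm") <= alpha
}

#' Holm-Bonferroni unit-inclusion test
#'
#' For each unit and event class, a paired t-test of bl_fr against hfo_fr
#' across that unit's trials; units whose Holm-adjusted p exceeds
#' \code{alpha} (default 0.001) are excluded from the mixed-model input.
#' The step-down correction runs across units within each class.
#'
#' @param trials an \code{event_unit_trials} data frame.
#' @param classes event classes to test (default: each class present).
#' @param alpha family-wise level (default 0.001).
#' @return data frame: unit_id, class, n_trials, t, p, p_holm, included.
#' @export
unit_inclusion_test <- function(trials, classes = NULL, alpha = 0.001) {
  if (is.null(classes)) classes <- unique(trials$class)
  out <- list()
  for (cl in classes) {
    sub <- trials[trials$class == cl, , drop = FALSE]
    uids <- unique(sub$unit_id)
    res <- lapply(uids, function(u) {
      s <- sub[sub$unit_id == u, ]
      if (nrow(s) < 2L || sd(s$hfo_fr - s$bl_fr) == 0)
        return(data.frame(unit_id = u, class = cl, n_trials = nrow(s),
                          t = NA_real_, p = 1, stringsAsFactors = FALSE))
      tt <- t.test(s$hfo_fr, s$bl_fr, paired = TRUE)
      data.frame(unit_id = u, class = cl, n_trials = nrow(s),
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_holm <- p.adjust(res$p, method = "holm")
    res$included <- holm_include(res$p, alpha)
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}

#' Grand-average smoothed firing rate by trial group
#'
#' Pointwise mean and normal-approximation 95 percent confidence interval
#' of the smoothed rate series across the trials of each group.
#'
#' @param trials an \code{event_unit_trials} data frame (with rates).
#' @param groups factor/character vector, one label per trial row.
#' @return list per group: \code{times_ms}, \code{mean}, \code{lo},
#'   \code{hi}, \code{n}.
#' @export
grand_average <- function(trials, groups) {
  rates <- attr(trials, "rates")
  times <- attr(trials, "rate_times_ms")
  stopifnot(!is.null(rates), length(groups) == nrow(rates))
  out <- list()
  for (g in unique(groups)) {
    m <- rates[groups == g, , drop = FALSE]
    if (!nrow(m)) stop("empty trial group: ", g)
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(nrow(m))
    se[is.na(se)] <- 0
    out[[as.character(g)]] <- list(times_ms = times, mean = mu,
                                   lo = mu - 1.96 * se, hi = mu + 1.96 * se,
                                   n = nrow(m))
  }
  out
}

#' Histogram of peak-firing times relative to event onset
#'
#' Per trial, the time of the maximum smoothed rate (earliest sample on
#' ties); returns the histogram over the given bins.
#'
#' @param trials an \code{event_unit_trials} data frame (with rates).
#' @param breaks bin edges in ms relative to onset.
#' @return list with \code{breaks}, \code{counts}, \code{peak_times_ms}.
#' @export
peak_time_histogram <- function(trials,
                                breaks = seq(-1000, 1000, by = 20)) {
  rates <- attr(trials, "rates")
  times <- attr(trials, "rate_times_ms")
  pk <- times[apply(rates, 1, which.max)]   # which.max takes the first tie
  counts <- tabulate(findInterval(pk, breaks), nbins = length(breaks) - 1)
  list(breaks = breaks, counts = counts, peak_times_ms = pk)
}

#' Cohen's d effect size
#'
#' Mean difference divided by the pooled standard deviation.
#'
#' @param a,b numeric samples (each of length at least 2).
#' @return scalar d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least 2 observations per sample")
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

#' Mean pre-spike HFO power stratified by latency to the spike
#'
#' @param events flagged events (rows with \code{prespike == 1} are used).
#' @param breaks latency bin edges in ms, half-open \code{[lo, hi)}
#'   (default bins: under 10 ms and 10-300 ms).
#' @param class event class to stratify (default fRonO).
#' @return data frame: bin label, n, mean log10_power (\code{NA} for empty
#'   bins).
#' @export
power_by_latency <- function(events, breaks = c(0, 10, 300),
                             class = "fRonO") {
  ev <- events[events$class == class & events$prespike == 1 &
                 !is.na(events$latency_to_spike_ms), , drop = FALSE]
  nb <- length(breaks) - 1L
  bin <- findInterval(ev$latency_to_spike_ms, breaks)
  out <- data.frame(
    bin = sprintf("[%g,%g)", breaks[-(nb + 1L)], breaks[-1]),
    lo_ms = breaks[-(nb + 1L)], hi_ms = breaks[-1],
    n = tabulate(bin[bin >= 1 & bin <= nb], nbins = nb))
  out$mean_log10_power <- vapply(seq_len(nb), function(k) {
    v <- ev$log10_power[bin == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  out
}
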