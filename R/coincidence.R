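# HFO -> spike latencies, pre-spike/followed-by flags and the
# uniform-resampling surrogate null for the <300 ms coincidence count.
# All coincidence arithmetic is within-channel.

#' Minimum positive latency from each HFO onset to the next spike onset
#'
#' For each HFO onset, the smallest strictly positive difference
#' (spike onset minus HFO onset), in milliseconds.  A spike exactly at the
#' HFO onset does not count; an HFO with no later spike gets \code{NA}.
#'
#' @param hfo_onsets numeric vector of HFO onsets (seconds), one channel.
#' @param spike_onsets numeric vector of spike onsets (seconds), same channel.
#' @return numeric vector of latencies in ms (\code{NA} where undefined).
#' @export
min_positive_latency <- function(hfo_onsets, spike_onsets) {
  if (!length(hfo_onsets)) return(numeric(0))
  if (!length(spike_onsets)) return(rep(NA_real_, length(hfo_onsets)))
  sp <- sort(spike_onsets)
  # findInterval counts spikes <= onset, so idx points at the first spike
  # strictly after the onset (a spike exactly at the onset is stepped over)
  idx <- findInterval(hfo_onsets, sp) + 1L
  lat <- ifelse(idx <= length(sp), (sp[pmin(idx, length(sp))] - hfo_onsets),
                NA_real_)
  lat[lat <= 0] <- NA_real_   # safety; strictly positive by construction
  lat * 1000
}

#' Flag pre-spike HFOs and HFO-spikes preceded by a fRonO/RonO
#'
#' Within each channel, a fRonO/RonO is \code{prespike} when its minimum
#' positive latency to any spike (fRonS, RonS or sharp spike) is under
#' 300 ms; a fRonS/RonS is \code{followed_fRonO}/\code{followed_RonO} when a
#' fRonO/RonO onset lies in the 300 ms window before its onset.  Events not
#' so paired are solitary.  The window bound is strict (a latency of exactly
#' 300 ms is not flagged).
#'
#' @param events classified events data frame (\code{channel}, \code{class},
#'   \code{onset_s}).
#' @param window_ms coincidence window, default 300.
#' @return \code{events} with \code{prespike}, \code{latency_to_spike_ms},
#'   \code{followed_fRonO} and \code{followed_RonO} columns filled.
#' @export
flag_coincidence <- function(events, window_ms = 300) {
  n <- nrow(events)
  events$prespike <- integer(n)
  events$latency_to_spike_ms <- rep(NA_real_, n)
  events$followed_fRonO <- integer(n)
  events$followed_RonO <- integer(n)
  if (!n) return(events)
  for (ch in unique(events$channel)) {
    ix <- which(events$channel == ch)
    cls <- events$class[ix]
    on <- events$onset_s[ix]
    sp <- on[cls %in% SPIKE_CLASSES]
    ono <- cls %in% c("fRonO", "RonO")
    if (any(ono)) {
      lat <- min_positive_latency(on[ono], sp)
      events$latency_to_spike_ms[ix[ono]] <- lat
      events$prespike[ix[ono]] <- as.integer(!is.na(lat) & lat < window_ms)
    }
    for (hc in c("fRonO", "RonO")) {
      h_on <- on[cls == hc]
      if (!length(h_on)) next
      tgt <- which(cls %in% c("fRonS", "RonS"))
      if (!length(tgt)) next
      flag <- vapply(on[tgt], function(t0)
        any(h_on > t0 - window_ms / 1000 & h_on < t0), TRUE)
      col <- paste0("followed_", hc)
      events[[col]][ix[tgt]] <- as.integer(flag)
    }
  }
  events
}

count_coincidence <- function(hfo_on, spike_on, window_ms) {
  lat <- min_positive_latency(hfo_on, spike_on)
  sum(!is.na(lat) & lat < window_ms)
}

#' Surrogate null for the HFO-before-spike coincidence count
#'
#' Holds spike onsets fixed and redraws each channel's HFO onsets uniformly
#' within that channel's artifact-free epochs, \code{n} times; the observed
#' number of HFOs preceding a spike by less than \code{window_ms} is
#' compared with the surrogate distribution.  The pooled statistic sums
#' per-channel counts, with surrogates resampled independently per channel.
#'
#' @param events flagged events data frame for one patient (or any pooled
#'   set of channels).
#' @param epochs data frame with \code{channel}, \code{start_s}, \code{end_s}
#'   artifact-free intervals.
#' @param hfo_class HFO-on-oscillation class whose onsets are resampled
#'   (\code{"fRonO"} or \code{"RonO"}).
#' @param spike_subset which after-going spikes count: \code{"all"} (fRonS,
#'   RonS and sharp spikes), \code{"fRonS"}, \code{"RonS"}, or
#'   \code{"hfospike"} (fRonS or RonS).
#' @param channels optional subset of channels (e.g. SOZ contacts).
#' @param n number of surrogate resamples.
#' @param window_ms coincidence window in ms.
#' @param seed integer seed for the resampling.
#' @return object of class \code{surrogate_result}: observed count, the
#'   surrogate counts, z-score, two-sided empirical p (with +1 correction)
#'   and the settings used.  \code{z} is \code{NA} (flagged) when the
#'   surrogate SD is zero.
#' @export
surrogate_null <- function(events, epochs, hfo_class = "fRonO",
                           spike_subset = c("all", "fRonS", "RonS",
                                            "hfospike"),
                           channels = NULL, n = 500, window_ms = 300,
                           seed = 1L) {
  spike_subset <- match.arg(spike_subset)
  spk_cls <- switch(spike_subset,
                    all = SPIKE_CLASSES,
                    fRonS = "fRonS", RonS = "RonS",
                    hfospike = c("fRonS", "RonS"))
  if (is.null(channels)) channels <- unique(events$channel)
  set.seed(seed)
  obs <- 0
  surr <- numeric(n)
  for (ch in channels) {
    ix <- events$channel == ch
    h_on <- events$onset_s[ix & events$class == hfo_class]
    s_on <- events$onset_s[ix & events$class %in% spk_cls]
    ep <- epochs[epochs$channel == ch, , drop = FALSE]
    if (!nrow(ep)) stop("no artifact-free epochs for channel ", ch)
    epm <- cbind(ep$start_s, ep$end_s)
    if (epoch_length(epm) <= 0) stop("empty epochs for channel ", ch)
    obs <- obs + count_coincidence(h_on, s_on, window_ms)
    m <- length(h_on)
    if (m == 0L || !length(s_on)) next
    draws <- matrix(runif_in_epochs(m * n, epm), nrow = n)
    sp <- sort(s_on)
    idx <- matrix(findInterval(draws, sp) + 1L, nrow = n)
    lat <- ifelse(idx <= length(sp), sp[pmin(idx, length(sp))] - draws,
                  NA_real_)
    hit <- !is.na(lat) & lat > 0 & lat < window_ms / 1000
    surr <- surr + rowSums(matrix(hit, nrow = n))
  }
  s <- sd(surr)
  z <- if (s > 0) (obs - mean(surr)) / s else NA_real_
  p_emp <- (1 + sum(abs(surr - mean(surr)) >= abs(obs - mean(surr)))) / (n + 1)
  structure(list(observed = obs, surrogate_counts = surr, z = z,
                 empirical_p = p_emp, n = n, window_ms = window_ms,
                 hfo_class = hfo_class, spike_subset = spike_subset,
                 channels = channels, sd_zero = s == 0),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf(paste0("<surrogate_result> %s before %s spikes (<%g ms): ",
                     "observed %d vs %.2f +/- %.2f surrogate ",
                     "(n=%d); z=%.2f, p=%.4g\n"),
              x$hfo_class, x$spike_subset, x$window_ms, x$observed,
              mean(x$surrogate_counts), sd(x$surrogate_counts), x$n,
              x$z, x$empirical_p))
  invisible(x)
}

#' Cumulative spike-to-fRonO occurrence ratios in 1-minute bins
#'
#' Per channel, the cumulative count of fRonS (and RonS) divided by the
#' cumulative count of fRonO at the end of each bin.  Bins whose fRonO
#' denominator is still zero yield \code{NA}.
#'
#' @param events classified events data frame.
#' @param bin_s bin width in seconds (default 60).
#' @param t_end end of the recording in seconds (defaults to the last event).
#' @return data frame with \code{channel}, \code{t_s} (bin end),
#'   \code{ratio_fRonS_fRonO}, \code{ratio_RonS_fRonO}.
#' @export
ratio_timeseries <- function(events, bin_s = 60, t_end = NULL) {
  if (is.null(t_end)) t_end <- max(events$onset_s, 0)
  breaks <- seq(0, ceiling(t_end / bin_s) * bin_s, by = bin_s)
  out <- list()
  for (ch in unique(events$channel)) {
    e <- events[events$channel == ch, ]
    cum <- function(cls) {
      on <- sort(e$onset_s[e$class == cls])
      vapply(breaks[-1], function(b) sum(on < b), 0L)
    }
    den <- cum("fRonO")
    out[[length(out) + 1L]] <- data.frame(
      channel = ch, t_s = breaks[-1],
      ratio_fRonS_fRonO = ifelse(den > 0, cum("fRonS") / den, NA_real_),
      ratio_RonS_fRonO = ifelse(den > 0, cum("RonS") / den, NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Normalized latency histogram with surrogate overlay
#'
#' Histogram (unit mass) of HFO-to-spike latencies, with the per-bin mean
#' and SD of the same histogram under the uniform-resampling surrogate.
#'
#' @param events flagged events data frame.
#' @param epochs artifact-free epochs data frame (as in
#'   \code{\link{surrogate_null}}).
#' @param breaks latency bin edges in ms (half-open \code{[lo, hi)}).
#' @param hfo_class,spike_subset,channels,n,seed as in
#'   \code{\link{surrogate_null}}.
#' @return list with \code{breaks}, \code{observed} (normalized masses),
#'   \code{surrogate_mean}, \code{surrogate_sd} and the first-bin z-score.
#' @export
latency_histogram <- function(events, epochs, breaks = seq(0, 3000, 300),
                              hfo_class = "fRonO", spike_subset = "all",
                              channels = NULL, n = 500, seed = 1L) {
  spk_cls <- switch(spike_subset, all = SPIKE_CLASSES,
                    fRonS = "fRonS", RonS = "RonS",
                    hfospike = c("fRonS", "RonS"))
  if (is.null(channels)) channels <- unique(events$channel)
  set.seed(seed)
  nb <- length(breaks) - 1L
  bin_counts <- function(lat) {
    lat <- lat[!is.na(lat) & lat >= breaks[1] & lat < breaks[nb + 1L]]
    tabulate(findInterval(lat, breaks), nbins = nb)
  }
  obs <- numeric(nb)
  surr <- matrix(0, n, nb)
  for (ch in channels) {
    ix <- events$channel == ch
    h_on <- events$onset_s[ix & events$class == hfo_class]
    s_on <- sort(events$onset_s[ix & events$class %in% spk_cls])
    if (!length(h_on)) next
    obs <- obs + bin_counts(min_positive_latency(h_on, s_on))
    ep <- epochs[epochs$channel == ch, , drop = FALSE]
    epm <- cbind(ep$start_s, ep$end_s)
    if (!length(s_on)) next
    # drawn exactly as in surrogate_null so that, under the same seed, the
    # first-bin z reproduces the surrogate test on the same data
    draws <- matrix(runif_in_epochs(length(h_on) * n, epm), nrow = n)
    for (r in seq_len(n))
      surr[r, ] <- surr[r, ] + bin_counts(min_positive_latency(draws[r, ],
                                                               s_on))
  }
  tot <- sum(obs)
  norm <- if (tot > 0) obs / tot else obs
  sm <- colMeans(surr)
  ssd <- apply(surr, 2, sd)
  z1 <- if (ssd[1] > 0) (obs[1] - sm[1]) / ssd[1] else NA_real_
  list(breaks = breaks, observed = norm, counts = obs,
       surrogate_mean = sm, surrogate_sd = ssd, z_first_bin = z1)
}
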