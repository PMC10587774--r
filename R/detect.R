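# Stage-1 candidate detection: transient elevations of the band-limited
# analytic envelope, with broadband artifact masking.  Filtering is
# zero-phase (real, symmetric frequency response with raised-cosine edges),
# so candidate onsets are not biased in time.

band_edges <- function(band) {
  switch(band,
         ripple = c(80, 200),
         fr = c(200, 600),
         spike = c(20, 80),
         stop("unknown band: ", band))
}

# Analytic band-limited signal via a one-sided frequency mask with
# raised-cosine transitions; Mod() of the result is the band envelope.
band_analytic <- function(x, fs, lo, hi, trans_frac = 0.15) {
  n <- length(x)
  if (hi >= fs / 2) stop("band edge at or above Nyquist")
  X <- fft(x)
  fax <- (seq_len(n) - 1) * fs / n
  tw_lo <- trans_frac * lo
  tw_hi <- trans_frac * hi
  H <- numeric(n)
  pos <- fax <= fs / 2
  f <- fax[pos]
  g <- rep(0, length(f))
  g[f >= lo & f <= hi] <- 1
  rise <- f > lo - tw_lo & f < lo
  g[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / tw_lo))
  fall <- f > hi & f < hi + tw_hi
  g[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / tw_hi))
  H[pos] <- 2 * g
  H[1] <- 0
  fft(X * H, inverse = TRUE) / n
}

#' Artifact masking of an iEEG recording
#'
#' Flags broadband transients (mechanical/muscle artifact) while sparing
#' physiological events: a sample is flagged when the analytic envelope in
#' a supra-physiological band (0.8-0.95 of Nyquist, well above the 600 Hz
#' fast-ripple edge and the spectral spread of brief bursts) exceeds
#' \code{z_art} robust z-units, or the sample-to-sample derivative exceeds
#' \code{slew_z} robust z-units (square edges and steps; the bound is high
#' because fast-ripple oscillations themselves carry large sample-to-sample
#' slew).  Flags are expanded by a guard interval and removed from the
#' channel's artifact-free epochs.  A flat (all-equal) channel is treated
#' as saturated and loses all its epochs.  Recordings sampled too slowly
#' for a supra-physiological band (Nyquist under 850 Hz) use only the slew
#' and flatline criteria.
#'
#' @param rec an \code{\link{ieeg_recording}}.
#' @param z_art high-band envelope threshold (robust z), default 8.
#' @param slew_z derivative threshold (robust z), default 150.
#' @param guard_ms guard padding around flagged samples, default 50 ms.
#' @return named list of per-channel epoch matrices (start, end in seconds).
#' @export
artifact_mask <- function(rec, z_art = 8, slew_z = 150, guard_ms = 50) {
  stopifnot(inherits(rec, "ieeg_recording"))
  out <- list()
  art_band <- c(0.8, 0.95) * rec$fs / 2
  for (ci in seq_len(nrow(rec$samples))) {
    ch <- rec$channel_labels[ci]
    x <- rec$samples[ci, ]
    ep <- rec$epochs[[ch]]
    if (is.null(ep)) ep <- cbind(start = 0, end = rec$duration_s)
    if (mad(x) == 0 && sd(x) == 0) {     # saturated/flat channel
      out[[ch]] <- matrix(numeric(0), ncol = 2,
                          dimnames = list(NULL, c("start", "end")))
      next
    }
    bad <- rep(FALSE, length(x))
    if (art_band[1] > 650) {
      env_hi <- Mod(band_analytic(x, rec$fs, art_band[1], art_band[2],
                                  trans_frac = 0.03))
      bad <- robust_z(env_hi) > z_art
    }
    dx <- c(0, diff(x))
    bad <- bad | abs(robust_z(dx)) > slew_z
    if (any(bad)) {
      runs <- logical_runs(bad)
      g <- guard_ms / 1000
      iv <- cbind((runs[, 1] - 1) / rec$fs - g, runs[, 2] / rec$fs + g)
      iv[iv < 0] <- 0
      ep <- subtract_intervals(ep, iv)
    }
    out[[ch]] <- ep
  }
  out
}

#' Detect transient band-envelope elevations (stage 1)
#'
#' Computes the analytic envelope of the zero-phase band-filtered signal,
#' converts it to a robust z-score against the median/MAD of the envelope
#' within the artifact-free epochs, and keeps contiguous runs above a low
#' threshold \code{z_lo} that reach \code{z_hi} at their peak, last at least
#' \code{min_cycles} cycles of the band centre frequency and lie inside an
#' artifact-free epoch.  Runs separated by less than \code{merge_gap_ms}
#' are merged first.
#'
#' @param rec an \code{\link{ieeg_recording}}.
#' @param band \code{"ripple"} (80-200 Hz), \code{"fr"} (200-600 Hz) or
#'   \code{"spike"} (20-80 Hz broadband spike scan).
#' @param epochs per-channel artifact-free epochs (default from
#'   \code{\link{artifact_mask}}).
#' @param z_hi peak threshold in robust z-units (default 8).
#' @param z_lo boundary threshold defining candidate extent (default 4).
#' @param min_cycles minimum duration in cycles of the band geometric-mean
#'   frequency (default 2; the spike scan uses 1).
#' @param merge_gap_ms gap below which candidates merge (default 10 ms).
#' @return data frame: channel, band, onset_s, offset_s, peak_z.
#' @export
band_envelope_detect <- function(rec, band = c("ripple", "fr", "spike"),
                                 epochs = NULL, z_hi = 8, z_lo = 4,
                                 min_cycles = NULL, merge_gap_ms = 10) {
  band <- match.arg(band)
  stopifnot(inherits(rec, "ieeg_recording"))
  edges <- band_edges(band)
  if (edges[2] >= rec$fs / 2) stop("band upper edge at or above Nyquist")
  if (is.null(min_cycles)) min_cycles <- if (band == "spike") 1 else 2
  if (is.null(epochs)) epochs <- artifact_mask(rec)
  fc <- sqrt(prod(edges))
  min_dur <- min_cycles / fc
  out <- list()
  for (ci in seq_len(nrow(rec$samples))) {
    ch <- rec$channel_labels[ci]
    ep <- epochs[[ch]]
    if (is.null(ep) || nrow(ep) == 0L) next
    env <- Mod(band_analytic(rec$samples[ci, ], rec$fs, edges[1], edges[2]))
    tt <- (seq_along(env) - 1) / rec$fs
    in_ep <- rep(FALSE, length(env))
    for (k in seq_len(nrow(ep)))
      in_ep[tt >= ep[k, 1] & tt < ep[k, 2]] <- TRUE
    if (!any(in_ep)) next
    z <- robust_z(env, env[in_ep])
    z[!in_ep] <- -Inf
    runs <- logical_runs(z > z_lo)
    if (!nrow(runs)) next
    # merge runs separated by less than the gap
    cand <- merge_runs(runs, gap = merge_gap_ms / 1000 * rec$fs)
    on <- (cand[, 1] - 1) / rec$fs
    off <- cand[, 2] / rec$fs
    pk <- vapply(seq_len(nrow(cand)),
                 function(i) max(z[cand[i, 1]:cand[i, 2]]), 0)
    ok <- pk >= z_hi & (off - on) >= min_dur
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      channel = ch, band = band, onset_s = on[ok], offset_s = off[ok],
      peak_z = pk[ok], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(channel = character(0), band = character(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      peak_z = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1L) return(runs)
  keep <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    last <- nrow(keep)
    if (runs[i, 1] - keep[last, 2] <= gap) keep[last, 2] <- runs[i, 2]
    else keep <- rbind(keep, runs[i, ])
  }
  keep
}

#' Merge nearby candidate events
#'
#' Candidates of the same channel and band that overlap or are separated by
#' at most \code{gap_ms} are merged into one.  Idempotent; the candidate
#' count never increases.
#'
#' @param cands candidate data frame (channel, band, onset_s, offset_s,
#'   peak_z).
#' @param gap_ms merge gap in ms.
#' @return merged candidate data frame.
#' @export
merge_events <- function(cands, gap_ms = 10) {
  if (nrow(cands) <= 1L) return(cands)
  out <- list()
  for (key in unique(paste(cands$channel, cands$band))) {
    e <- cands[paste(cands$channel, cands$band) == key, , drop = FALSE]
    e <- e[order(e$onset_s), , drop = FALSE]
    cur <- e[1, ]
    for (i in seq_len(nrow(e))[-1]) {
      if (e$onset_s[i] - cur$offset_s <= gap_ms / 1000) {
        cur$offset_s <- max(cur$offset_s, e$offset_s[i])
        cur$peak_z <- max(cur$peak_z, e$peak_z[i])
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- e[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$channel, res$band, res$onset_s), ]
  rownames(res) <- NULL
  res
}

#' Run the full stage-1 scan
#'
#' Artifact masking followed by candidate detection in the ripple,
#' fast-ripple and spike bands.
#'
#' @param rec an \code{\link{ieeg_recording}}.
#' @param bands which bands to scan.
#' @param epochs optional precomputed artifact-free epochs.
#' @param ... forwarded to \code{\link{band_envelope_detect}}.
#' @return list with \code{candidates} (data frame) and \code{epochs}.
#' @export
detect_candidates <- function(rec, bands = c("ripple", "fr", "spike"),
                              epochs = NULL, ...) {
  if (is.null(epochs)) epochs <- artifact_mask(rec)
  cands <- do.call(rbind, lapply(bands, function(b)
    band_envelope_detect(rec, b, epochs = epochs, ...)))
  list(candidates = cands, epochs = epochs)
}
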