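# Stage-2 classification: decide RonO / fRonO / RonS / fRonS / SharpSpike
# from the topology of the isopower contours of a candidate's wavelet map.

# Summarise CLC groups and qualifying spike OLCs, and classify every HFO
# group in the window (one row per group) plus a sharp-spike row when only
# open contours qualify.  Closed-contour groups whose mean frequency falls
# below hfo_min_freq belong to the broadband spike signature (HFO classes
# are only defined from 80 Hz up) and are not emitted as HFOs.
classify_groups <- function(cs, boundary_hz = 200, hfo_min_freq = 80,
                            spike_max_freq = 80, spike_level_frac = 0.1,
                            spike_min_width_s = 0.015, overlap_pad_s = 0.1) {
  df <- cs$contours
  if (!nrow(df)) stop("empty contour set")
  lev_bar <- cs$threshold + spike_level_frac * (cs$max_power - cs$threshold)
  olc <- df[!df$closed &
              df$min_f <= spike_max_freq &
              (df$max_t - df$min_t) >= spike_min_width_s &
              df$level >= lev_bar, , drop = FALSE]
  groups <- unique(df$group[df$closed])
  rows <- list()
  if (length(groups)) {
    for (g in groups) {
      gc <- df[df$closed & df$group == g, , drop = FALSE]
      outer <- gc[which.min(gc$level), ]
      top <- gc[which.max(gc$level), ]
      if (outer$mean_freq < hfo_min_freq) next
      ripple <- outer$mean_freq < boundary_hz
      sp <- olc[olc$max_t >= outer$min_t - overlap_pad_s &
                  olc$min_t <= outer$max_t + overlap_pad_s, , drop = FALSE]
      on_spike <- nrow(sp) > 0 && min(sp$min_t) < outer$min_t
      cls <- if (on_spike) (if (ripple) "RonS" else "fRonS")
             else (if (ripple) "RonO" else "fRonO")
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, onset_s = outer$min_t, offset_s = outer$max_t,
        peak_freq_hz = top$peak_f, log10_power = log10(max(gc$peak_power)),
        duration_ms = (outer$max_t - outer$min_t) * 1000,
        mean_freq_hz = outer$mean_freq, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows) && nrow(olc)) {
    rows[[1L]] <- data.frame(
      class = "SharpSpike", onset_s = min(olc$min_t),
      offset_s = max(olc$max_t), peak_freq_hz = NA_real_,
      log10_power = log10(cs$max_power),
      duration_ms = (max(olc$max_t) - min(olc$min_t)) * 1000,
      mean_freq_hz = NA_real_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Classify one candidate window from its contour set
#'
#' Classification rules:
#' \itemize{
#'   \item a closed-loop contour (CLC) group with no qualifying earlier open
#'     contour is an HFO on the background oscillation (RonO/fRonO);
#'   \item a CLC group whose outermost contour starts later than the onset
#'     of a qualifying outermost open-loop contour (OLC, the broadband spike
#'     signature) is an HFO on a spike (RonS/fRonS);
#'   \item open contours with no CLC group are a sharp spike.
#' }
#' Ripples and fast ripples are separated at 200 Hz by the mean frequency of
#' the CLC group (power-weighted geometric mean over the enclosed cells);
#' peak frequency and power come from the largest isopower contour in the
#' group, duration from the outermost contour's extent.  An OLC only
#' qualifies as a spike signature when it extends below
#' \code{spike_max_freq} (spikes are broadband and low-frequency rooted,
#' which keeps edge-truncated HFOs from being read as spikes), is at least
#' \code{spike_min_width_s} wide, reaches \code{spike_level_frac} of the
#' suprathreshold power range, and overlaps the CLC group in time.
#' Closed-contour groups with mean frequency below \code{hfo_min_freq} are
#' part of the spike's broadband signature, not HFOs.
#'
#' When several CLC groups qualify, groups overlapping
#' \code{cand_interval} are preferred and the largest-power one is
#' returned (see \code{\link{classify_all}} for per-group emission).
#'
#' @param cs a \code{\link{extract_contours}} result.
#' @param cand_interval optional c(onset, offset) of the stage-1 candidate
#'   (seconds, same clock as the map).
#' @param boundary_hz ripple/fast-ripple boundary (default 200; ripple is
#'   [80, 200), fast ripple [200, 600]).
#' @param hfo_min_freq minimum mean frequency of an HFO group (default 80).
#' @param spike_max_freq OLCs must extend below this frequency to count as
#'   a spike signature (default 80 Hz).
#' @param spike_level_frac minimum OLC ladder height as a fraction of
#'   (max - threshold) (default 0.1).
#' @param spike_min_width_s minimum OLC time width (default 0.015 s).
#' @param overlap_pad_s padding when testing group/candidate and group/OLC
#'   overlap (default 0.1 s).
#' @return one-row data frame (class, onset_s, offset_s, peak_freq_hz,
#'   log10_power, duration_ms) with times relative to the map, or NULL when
#'   nothing is classifiable.
#' @export
classify_event <- function(cs, cand_interval = NULL, boundary_hz = 200,
                           hfo_min_freq = 80, spike_max_freq = 80,
                           spike_level_frac = 0.1,
                           spike_min_width_s = 0.015, overlap_pad_s = 0.1) {
  stopifnot(inherits(cs, "contour_set"))
  rows <- classify_groups(cs, boundary_hz, hfo_min_freq, spike_max_freq,
                          spike_level_frac, spike_min_width_s,
                          overlap_pad_s)
  if (is.null(rows)) return(NULL)
  if (!is.null(cand_interval) && nrow(rows) > 1L) {
    ov <- rows$offset_s >= cand_interval[1] - overlap_pad_s &
      rows$onset_s <= cand_interval[2] + overlap_pad_s
    if (any(ov)) rows <- rows[ov, , drop = FALSE]
  }
  rows <- rows[which.max(rows$log10_power), , drop = FALSE]
  rows$mean_freq_hz <- NULL
  rownames(rows) <- NULL
  rows
}

#' Classify all stage-1 candidates of a recording
#'
#' Windows each candidate, computes its whitened wavelet map, extracts and
#' labels isopower contours and emits one classified event per closed-loop
#' contour group overlapping the candidate (so a priming fRonO and the
#' HFO-on-spike it precedes, caught in one window, both survive), plus
#' sharp spikes from open-contour-only windows.  Candidates from the
#' spike-band scan let sharp spikes without an HFO be represented.
#' Near-coincident classifications of the same event from different
#' candidates/bands are deduplicated, keeping the contour-rich (CLC)
#' classification with the largest power.
#'
#' @param rec an \code{\link{ieeg_recording}}.
#' @param candidates data frame from \code{\link{detect_candidates}}.
#' @param window_s half-window around the candidate onset (default 0.5 s);
#'   the wavelet transform is computed over this window, while the
#'   contour threshold and topology are evaluated on the candidate's own
#'   support padded by \code{sub_pad_s}, so a high-power neighbour inside
#'   the window does not set the isopower floor for a weaker event.
#' @param sub_pad_s padding around the candidate support for the
#'   thresholded sub-map (default 0.15 s).
#' @param freqs,n_cycles,n_levels forwarded to the wavelet/contour stage.
#' @param dedup_ms onset separation under which two classifications are
#'   considered the same event (default 25 ms).
#' @param ... forwarded to the classification rules (see
#'   \code{\link{classify_event}}).
#' @return events data frame (patient_id, channel, class, onset_s, offset_s,
#'   peak_freq_hz, log10_power, duration_ms), coincidence flags unfilled.
#' @export
classify_all <- function(rec, candidates, window_s = 0.5, sub_pad_s = 0.15,
                         freqs = tfr_freq_grid(), n_cycles = 7,
                         n_levels = 10, dedup_ms = 25, ...) {
  stopifnot(inherits(rec, "ieeg_recording"))
  out <- list()
  if (nrow(candidates)) {
    for (i in seq_len(nrow(candidates))) {
      ch <- candidates$channel[i]
      ci <- match(ch, rec$channel_labels)
      if (is.na(ci)) next
      on <- candidates$onset_s[i]
      t0 <- on - window_s
      t1 <- on + window_s
      if (t0 < 0 || t1 > rec$duration_s) next
      i0 <- floor(t0 * rec$fs) + 1L
      i1 <- min(ncol(rec$samples), i0 + round(2 * window_s * rec$fs))
      seg <- rec$samples[ci, i0:i1]
      tf <- wavelet_tfr(seg, rec$fs, freqs = freqs, n_cycles = n_cycles)
      t_off <- (i0 - 1L) / rec$fs
      tf <- tf_subset(tf, on - sub_pad_s - t_off,
                      candidates$offset_s[i] + sub_pad_s - t_off)
      thr <- contour_threshold(tf)
      cs <- extract_contours(tf, thr, n_levels = n_levels)
      if (!nrow(cs$contours)) next
      rows <- classify_groups(cs, ...)
      if (is.null(rows)) next
      # keep groups overlapping the candidate's own support
      ov <- rows$offset_s + t_off >= on - 0.05 &
        rows$onset_s + t_off <= candidates$offset_s[i] + 0.05
      if (!any(ov)) next
      rows <- rows[ov, , drop = FALSE]
      rows$onset_s <- rows$onset_s + t_off
      rows$offset_s <- rows$offset_s + t_off
      rows$patient_id <- rec$patient_id
      rows$channel <- ch
      out[[length(out) + 1L]] <- rows
    }
  }
  cols <- c("patient_id", "channel", "class", "onset_s", "offset_s",
            "peak_freq_hz", "log10_power", "duration_ms")
  if (!length(out)) {
    return(data.frame(patient_id = character(0), channel = character(0),
                      class = character(0), onset_s = numeric(0),
                      offset_s = numeric(0), peak_freq_hz = numeric(0),
                      log10_power = numeric(0), duration_ms = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, out)[, cols]
  dedup_events(ev, dedup_ms)
}

# Collapse near-coincident classifications (onsets within dedup_ms on one
# channel) to a single event, preferring CLC-backed classes (anything but
# SharpSpike) and, within those, the largest power.
dedup_events <- function(ev, dedup_ms = 25) {
  keep <- list()
  for (ch in unique(ev$channel)) {
    e <- ev[ev$channel == ch, , drop = FALSE]
    e <- e[order(e$onset_s), , drop = FALSE]
    grp <- cumsum(c(1, diff(e$onset_s) > dedup_ms / 1000))
    for (g in unique(grp)) {
      sub <- e[grp == g, , drop = FALSE]
      hfo <- sub$class != "SharpSpike"
      pick <- if (any(hfo)) {
        cand <- sub[hfo, , drop = FALSE]
        cand[which.max(cand$log10_power), ]
      } else sub[1L, ]
      keep[[length(keep) + 1L]] <- pick
    }
  }
  res <- do.call(rbind, keep)
  res <- res[order(res$channel, res$onset_s), ]
  rownames(res) <- NULL
  res
}
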