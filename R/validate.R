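# Scoring detected/classified events against synthetic ground truth.

#' Match detected events to ground-truth events
#'
#' Greedy nearest-onset matching within a channel: each truth event is
#' paired with the unmatched detected event whose onset is closest and
#' within \code{tol_s}.
#'
#' @param detected classified events data frame.
#' @param truth ground-truth events (a \code{synth_truth$events} table or
#'   \code{\link{truth_events_table}} output).
#' @param tol_s onset tolerance in seconds (default 0.1).
#' @return data frame, one row per truth event: truth class, matched
#'   detected class (\code{NA} if missed), onset error in seconds.
#' @export
match_events <- function(detected, truth, tol_s = 0.1) {
  out <- list()
  for (ch in unique(truth$channel)) {
    tr <- truth[truth$channel == ch, , drop = FALSE]
    de <- detected[detected$channel == ch, , drop = FALSE]
    used <- rep(FALSE, nrow(de))
    for (i in order(tr$onset_s)) {
      err <- abs(de$onset_s - tr$onset_s[i])
      err[used] <- Inf
      j <- if (nrow(de)) which.min(err) else integer(0)
      hit <- length(j) == 1L && is.finite(err[j]) && err[j] <= tol_s
      if (hit) used[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, truth_class = tr$class[i], onset_s = tr$onset_s[i],
        detected_class = if (hit) de$class[j] else NA_character_,
        onset_error_s = if (hit) de$onset_s[j] - tr$onset_s[i] else NA_real_,
        truth_freq_hz = tr$freq_hz[i],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classification accuracy against ground truth
#'
#' Overall accuracy (missed truth events count as errors), the confusion
#' table, detection recall, and the subset of ripple/fast-ripple band
#' confusions with the truth centre frequency (to verify that band errors
#' only happen near the 200 Hz boundary).
#'
#' @param detected classified events data frame.
#' @param truth ground-truth events table.
#' @param tol_s matching tolerance in seconds.
#' @return list: \code{accuracy}, \code{recall}, \code{confusion},
#'   \code{band_confusions} (truth frequencies of R/FR mix-ups),
#'   \code{matches}.
#' @export
classification_accuracy <- function(detected, truth, tol_s = 0.1) {
  m <- match_events(detected, truth, tol_s)
  correct <- !is.na(m$detected_class) & m$detected_class == m$truth_class
  band_of <- function(cl) ifelse(cl %in% c("RonO", "RonS"), "R",
                                 ifelse(cl %in% c("fRonO", "fRonS"), "FR",
                                        "S"))
  mism <- !is.na(m$detected_class) & m$detected_class != m$truth_class
  band_mix <- mism & band_of(m$detected_class) != band_of(m$truth_class) &
    band_of(m$truth_class) %in% c("R", "FR") &
    band_of(m$detected_class) %in% c("R", "FR")
  list(accuracy = mean(correct),
       recall = mean(!is.na(m$detected_class)),
       confusion = table(truth = m$truth_class,
                         detected = ifelse(is.na(m$detected_class), "miss",
                                           m$detected_class)),
       band_confusions = m$truth_freq_hz[band_mix],
       matches = m)
}

#' Run detection and classification on one recording
#'
#' Convenience wrapper: artifact mask, stage-1 candidate scan in all three
#' bands, stage-2 classification and coincidence flagging.
#'
#' @param rec an \code{\link{ieeg_recording}}.
#' @param ... forwarded to \code{\link{classify_all}}.
#' @return flagged events data frame.
#' @export
run_pipeline <- function(rec, ...) {
  det <- detect_candidates(rec)
  ev <- classify_all(rec, det$candidates, ...)
  flag_coincidence(ev)
}
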