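# On-disk synthetic cohorts: EDF recordings plus the CSV tables the
# pipeline reads back (electrodes, units, epochs, ground-truth events).

#' Write a complete synthetic cohort to disk
#'
#' Generates recordings, ground truth and unit trains and writes one EDF per
#' patient plus \code{electrodes.csv}, \code{units.csv}, \code{epochs.csv},
#' \code{events_truth.csv} and a plain-text \code{config.txt}.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param dir output directory (created if needed).
#' @param seed optional integer overriding \code{cfg$seed}.
#' @return invisibly, a list with the \code{synth_ieeg} object, the unit
#'   trains and the paths written.
#' @export
gen_cohort <- function(cfg, dir, seed = cfg$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- gen_ieeg(cfg, seed = seed)
  tr <- gen_unit_trains(cfg, sim$truth)
  paths <- character(0)
  for (pid in names(sim$recordings)) {
    p <- file.path(dir, paste0(pid, ".edf"))
    write_edf(sim$recordings[[pid]], p)
    paths <- c(paths, p)
  }
  el <- sim$truth$electrodes
  write.csv(el, file.path(dir, "electrodes.csv"), row.names = FALSE,
            quote = FALSE)
  ev <- sim$truth$events
  ev_out <- data.frame(patient_id = ev$patient_id, channel = ev$channel,
                       class = ev$class, onset_s = round(ev$onset_s, 6),
                       offset_s = round(ev$offset_s, 6),
                       freq_hz = round(ev$freq_hz, 3),
                       stringsAsFactors = FALSE)
  write.csv(ev_out, file.path(dir, "events_truth.csv"), row.names = FALSE,
            quote = FALSE)
  urows <- lapply(tr$units, function(u)
    if (length(u$ap_times_ms)) data.frame(
      patient_id = u$patient_id, unit_id = u$unit_id, contact = u$contact,
      unit_type = u$unit_type, spike_time_ms = round(u$ap_times_ms, 3),
      stringsAsFactors = FALSE))
  ut <- do.call(rbind, urows)
  if (is.null(ut))
    ut <- data.frame(patient_id = character(0), unit_id = character(0),
                     contact = character(0), unit_type = character(0),
                     spike_time_ms = numeric(0))
  write.csv(ut, file.path(dir, "units.csv"), row.names = FALSE, quote = FALSE)
  write.csv(sim$truth$epochs, file.path(dir, "epochs.csv"),
            row.names = FALSE, quote = FALSE)
  write_run_config(c(cfg, analysis_config()), file.path(dir, "config.txt"))
  invisible(list(sim = sim, units = tr,
                 paths = c(paths, file.path(dir, c(
                   "electrodes.csv", "events_truth.csv", "units.csv",
                   "epochs.csv", "config.txt")))))
}
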