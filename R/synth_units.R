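# Inhomogeneous-Poisson unit spike trains whose in-event rate gain scales
# with the log10 spectral power of the iEEG event on the unit's contact.

#' Generate unit spike trains for a ground-truth cohort
#'
#' Each contact bundle carries \code{n_units_per_contact} units.  A unit
#' fires as a Poisson process at \code{unit_base_rate} Hz outside events
#' and at \code{base * (1 + unit_gain_per_log10power * log10(power))}
#' inside the window of any event on its contact (floored at zero), where
#' \code{log10(power)} is the event's ground-truth whitened log power.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param truth a \code{synth_truth} from \code{\link{gen_ground_truth}}.
#' @param seed integer seed (default derived from the config seed).
#' @return list with \code{units} (list of \code{\link{unit_spike_train}})
#'   and \code{unit_truth} (data frame of true base rate and gain per unit).
#' @export
gen_unit_trains <- function(cfg, truth, seed = cfg$seed + 1000L) {
  stopifnot(inherits(truth, "synth_truth"))
  if (nrow(truth$events) == 0L) stop("ground truth contains no events")
  set.seed(seed)
  t_end <- cfg$recording_minutes * 60
  units <- list(); utruth <- list()
  uct <- 0L
  for (i in seq_len(nrow(truth$electrodes))) {
    el <- truth$electrodes[i, ]
    ev <- truth$events[truth$events$channel == el$channel, , drop = FALSE]
    lp <- truth_log10_power(ev, cfg)
    gain_fac <- pmax(0, 1 + cfg$unit_gain_per_log10power * lp)
    for (u in seq_len(cfg$n_units_per_contact)) {
      uct <- uct + 1L
      base <- cfg$unit_base_rate
      ap <- runif(rpois(1, base * t_end), 0, t_end)
      if (nrow(ev)) for (j in seq_len(nrow(ev))) {
        r_in <- base * gain_fac[j]
        dur <- ev$offset_s[j] - ev$onset_s[j]
        if (r_in > base) {
          extra <- runif(rpois(1, (r_in - base) * dur),
                         ev$onset_s[j], ev$offset_s[j])
          ap <- c(ap, extra)
        } else if (r_in < base) {
          inside <- ap >= ev$onset_s[j] & ap < ev$offset_s[j]
          drop <- inside & runif(length(ap)) > r_in / base
          ap <- ap[!drop]
        }
      }
      uid <- sprintf("%s_U%03d", el$patient_id, uct)
      units[[length(units) + 1L]] <- unit_spike_train(
        unit_id = uid, patient_id = el$patient_id, contact = el$channel,
        unit_type = if (u %% 2 == 0) "multi" else "single",
        ap_times_ms = sort(ap) * 1000)
      utruth[[length(utruth) + 1L]] <- data.frame(
        unit_id = uid, patient_id = el$patient_id, contact = el$channel,
        true_base_hz = base, true_gain = cfg$unit_gain_per_log10power,
        stringsAsFactors = FALSE)
    }
  }
  list(units = units, unit_truth = do.call(rbind, utruth))
}
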