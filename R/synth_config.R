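#' Configuration for the synthetic iEEG cohort generator
#'
#' Collects every tunable of the synthetic-data model: cohort size, event
#' rates, the spike-priming probability, amplitude calibration, unit-firing
#' parameters and clinical-flag assignment.  Defaults describe a plausible
#' inter-ictal non-REM recording from a depth-electrode implant; all rates
#' are per contact.
#'
#' @param n_patients number of patients in the cohort.
#' @param n_contacts macroelectrode contacts per patient.
#' @param recording_minutes recording duration per patient (minutes).
#' @param fs_ieeg sampling rate in Hz (at least 1200 so that 600 Hz content
#'   is below Nyquist).
#' @param rate_fRonO,rate_RonO background HFO-on-oscillation rates
#'   (events/min per contact).
#' @param rate_spike total inter-ictal spike rate (events/min per contact),
#'   split into fRonS/RonS/sharp-spike by \code{spike_mix}.
#' @param spike_mix named proportions for the three spike types.
#' @param p_prime probability that a spike is preceded by a dedicated fRonO
#'   at a latency drawn on (0, 300] ms.
#' @param prime_latency_mode \code{"uniform"} for latencies uniform on
#'   (0, 300] ms or \code{"spikelocked"} for latencies under 10 ms.
#' @param prime_soz_enrichment spatial concentration of priming: the
#'   priming probability is \code{p_prime * e} on seizure-onset-zone
#'   contacts and \code{p_prime / e} elsewhere (1 = uniform placement).
#' @param p_suppress_nonsoz probability that a background fRonO falling
#'   within 300 ms before a spike on a non-SOZ contact is removed, emulating
#'   below-chance coincidence outside the SOZ.
#' @param power_gain_prespike multiplicative spectral-power factor applied
#'   to priming fRonO (amplitude is scaled by its square root).
#' @param unit_base_rate baseline unit firing rate (Hz).
#' @param unit_gain_per_log10power dimensionless slope of the in-event rate
#'   gain per unit log10 event power.
#' @param n_units_per_contact microwire units simulated per contact bundle.
#' @param snr_db event-to-background amplitude ratio in dB: peak event
#'   amplitude over the channel's realized broadband background SD
#'   (calibrated empirically per seed; see \code{\link{gen_ieeg}}).
#' @param spike_amp_db additional amplitude (dB) of epileptiform spike
#'   transients over \code{snr_db}; inter-ictal spikes are the
#'   largest-amplitude inter-ictal events.
#' @param base_uV microvolts per background-SD unit when rendering signals.
#' @param amp_sd_log10 standard deviation of per-event log10 relative
#'   amplitude (lognormal amplitude spread).
#' @param soz_fraction,resected_fraction proportions of contacts flagged as
#'   seizure-onset-zone and as resected.
#' @param soz_rate_factor rate multiplier on SOZ contacts (epileptiform
#'   events concentrate in the SOZ).
#' @param simulate_outcomes if \code{TRUE}, assign an Engel-1 (seizure-free)
#'   outcome to a fraction of patients and scale fast-ripple rates on their
#'   non-resected contacts by \code{residual_fr_factor_szfree} (seizure-free
#'   patients harbour little residual fast-ripple-generating tissue).
#' @param szfree_fraction fraction of patients with an Engel-1 outcome.
#' @param residual_fr_factor_szfree,residual_fr_factor_nonfree fast-ripple
#'   rate multipliers outside the resection for the two outcome groups.
#' @param min_event_gap_s minimum spacing enforced within each background
#'   event stream (spikes, fRonO, RonO separately; cross-stream spacing is
#'   never constrained, preserving independence between streams).
#' @param edge_margin_s events are kept away from the recording edges by
#'   this margin so that peri-event windows are complete.
#' @param slow_wave_amp slow-wave amplitude in units of background noise SD.
#' @param rate_artifact rate of broadband artifact transients (events/min);
#'   0 disables them.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a validated list of class \code{synth_config}.
#' @export
synth_config <- function(n_patients = 1L,
                         n_contacts = 16L,
                         recording_minutes = 10,
                         fs_ieeg = 2000,
                         rate_fRonO = 2,
                         rate_RonO = 3,
                         rate_spike = 3,
                         spike_mix = c(fRonS = 0.198, RonS = 0.715,
                                       SharpSpike = 0.087),
                         p_prime = 0.2,
                         prime_latency_mode = c("uniform", "spikelocked"),
                         prime_soz_enrichment = 1,
                         p_suppress_nonsoz = 0,
                         power_gain_prespike = 2,
                         unit_base_rate = 2,
                         unit_gain_per_log10power = 0.5,
                         n_units_per_contact = 2L,
                         snr_db = 15,
                         spike_amp_db = 15,
                         amp_sd_log10 = 0.15,
                         base_uV = 10,
                         soz_fraction = 0.25,
                         resected_fraction = 0.3,
                         soz_rate_factor = 2,
                         simulate_outcomes = FALSE,
                         szfree_fraction = 0.5,
                         residual_fr_factor_szfree = 0,
                         residual_fr_factor_nonfree = 1,
                         min_event_gap_s = 0.5,
                         edge_margin_s = 1.5,
                         slow_wave_amp = 4,
                         rate_artifact = 0,
                         seed = 1L) {
  prime_latency_mode <- match.arg(prime_latency_mode)
  cfg <- as.list(environment())
  rates <- c(rate_fRonO, rate_RonO, rate_spike, rate_artifact)
  if (any(rates < 0)) stop("event rates must be non-negative")
  if (p_prime < 0 || p_prime > 1) stop("p_prime must lie in [0, 1]")
  if (fs_ieeg < 1200) stop("fs_ieeg must be at least 1200 Hz (600 Hz Nyquist)")
  if (abs(sum(spike_mix) - 1) > 1e-6) stop("spike_mix must sum to 1")
  if (n_contacts < 1L) stop("need at least 1 contact")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d patient(s) x %d contacts x %g min @ ",
                     "%g Hz; p_prime=%g, snr=%g dB, seed=%d\n"),
              x$n_patients, x$n_contacts, x$recording_minutes, x$fs_ieeg,
              x$p_prime, x$snr_db, x$seed))
  invisible(x)
}
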