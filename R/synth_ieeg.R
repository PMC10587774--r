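# Waveform synthesis: renders ground-truth events into 1/f background iEEG.
# snr_db is the ratio of an event's peak amplitude to the broadband
# background SD (pink noise plus slow wave); epileptiform spikes carry an
# extra spike_amp_db on top, reflecting that inter-ictal spikes are the
# largest-amplitude inter-ictal events.

# biphasic epileptiform spike template, unit peak amplitude; dur in s.
# The leading deflection is sharp (4 ms SD) so the spike has broadband
# power well above the EEG bulk, rooted below ~100 Hz.
spike_template <- function(dur, fs, sharp_sd = 0.004) {
  t <- seq(0, dur, by = 1 / fs)
  ta <- 0.012
  tb <- ta + 0.45 * dur
  v <- -exp(-((t - ta)^2) / (2 * sharp_sd^2)) +
    0.55 * exp(-((t - tb)^2) / (2 * (0.18 * dur)^2))
  v / max(abs(v))
}

# Gaussian-windowed sinusoid burst; onset at time 0, duration dur (s)
hfo_burst <- function(dur, cf, fs) {
  t <- seq(0, dur, by = 1 / fs)
  sb <- dur / 6
  exp(-((t - dur / 2)^2) / (2 * sb^2)) * sin(2 * pi * cf * t + runif(1, 0, 2 * pi))
}

# nominal whitened log10 wavelet power of an event, used as the
# ground-truth power covariate for unit-train generation
truth_log10_power <- function(ev, cfg) {
  3.4 + 2 * log10(ev$amp_rel) +
    ifelse(ev$class %in% SPIKE_CLASSES, cfg$spike_amp_db / 10, 0)
}

#' Generate a synthetic iEEG cohort with ground truth
#'
#' Draws ground-truth events with \code{\link{gen_ground_truth}} and renders
#' them into per-patient recordings: pink (1/f) background noise plus a
#' 0.5-2 Hz slow wave, Gaussian-windowed sinusoid bursts for ripples
#' (80-200 Hz) and fast ripples (200-600 Hz), biphasic sharp transients for
#' epileptiform spikes, and HFO bursts riding on the spike for fRonS/RonS.
#' Event amplitudes are \code{10^(snr_db/20)} times the realized broadband
#' background SD of the channel (computed empirically per seed), times the
#' event's lognormal relative amplitude; spikes get an additional
#' \code{spike_amp_db}.  Identical seeds give bit-identical recordings.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param seed optional integer overriding \code{cfg$seed}.
#' @return list of class \code{synth_ieeg} with \code{recordings} (list of
#'   \code{\link{ieeg_recording}}, one per patient) and \code{truth} (a
#'   \code{synth_truth}).
#' @export
gen_ieeg <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- gen_ground_truth(cfg, seed = seed)
  fs <- cfg$fs_ieeg
  n <- round(cfg$recording_minutes * 60 * fs)
  base_uV <- cfg$base_uV
  recs <- list()
  for (pid in unique(truth$electrodes$patient_id)) {
    el <- truth$electrodes[truth$electrodes$patient_id == pid, ]
    x <- matrix(0, nrow(el), n)
    for (i in seq_len(nrow(el))) {
      ch <- el$channel[i]
      bg <- pink_noise(n)
      f_sw <- runif(1, 0.5, 2)
      sw <- cfg$slow_wave_amp * sin(2 * pi * f_sw * (0:(n - 1)) / fs +
                                      runif(1, 0, 2 * pi))
      sig <- bg + sw
      sd_bg <- sd(sig)
      ev <- truth$events[truth$events$channel == ch, , drop = FALSE]
      snr_amp <- 10^(cfg$snr_db / 20) * sd_bg
      spike_amp <- snr_amp * 10^(cfg$spike_amp_db / 20)
      if (nrow(ev)) for (j in seq_len(nrow(ev))) {
        e <- ev[j, ]
        if (e$class %in% SPIKE_CLASSES) {
          tpl <- spike_template(e$spike_dur_ms / 1000, fs)
          i0 <- round(e$onset_s * fs) + 1L
          idx <- i0:(i0 + length(tpl) - 1L)
          ok <- idx >= 1L & idx <= n
          sig[idx[ok]] <- sig[idx[ok]] + spike_amp * e$amp_rel * tpl[ok]
        }
        if (e$class != "SharpSpike") {
          burst <- hfo_burst(e$duration_ms / 1000, e$freq_hz, fs)
          i0 <- round((e$onset_s + e$hfo_lag_ms / 1000) * fs) + 1L
          idx <- i0:(i0 + length(burst) - 1L)
          ok <- idx >= 1L & idx <= n
          sig[idx[ok]] <- sig[idx[ok]] + snr_amp * e$amp_rel * burst[ok]
        }
      }
      if (cfg$rate_artifact > 0) {
        n_art <- rpois(1, cfg$rate_artifact * cfg$recording_minutes)
        if (n_art > 0) {
          at <- runif(n_art, 1, cfg$recording_minutes * 60 - 1)
          for (a in at) {
            i0 <- round(a * fs) + 1L
            idx <- i0:(i0 + round(0.005 * fs))
            sig[idx] <- sig[idx] + 2000 / base_uV   # 2 mV square pulse
          }
        }
      }
      x[i, ] <- sig * base_uV
    }
    rownames(x) <- el$channel
    recs[[pid]] <- ieeg_recording(x, fs, el$channel, pid)
  }
  structure(list(recordings = recs, truth = truth), class = "synth_ieeg")
}

#' @export
print.synth_ieeg <- function(x, ...) {
  cat(sprintf("<synth_ieeg> %d recording(s), %d ground-truth events\n",
              length(x$recordings), nrow(x$truth$events)))
  invisible(x)
}
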