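# Ground-truth event generation: the statistical core of the synthetic
# cohort.  Waveform synthesis (gen_ieeg) renders these events into the iEEG;
# the events-only path is much cheaper and is what the coincidence
# Monte-Carlo studies use.

gen_electrodes <- function(cfg, patient_id) {
  n <- cfg$n_contacts
  # depth-electrode shafts: 8 contacts at 5 mm pitch along random
  # trajectories through a ~90 mm implant volume
  n_shaft <- ceiling(n / 8)
  xyz <- matrix(0, 0, 3)
  for (s in seq_len(n_shaft)) {
    o <- runif(3, 15, 75)
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    xyz <- rbind(xyz, t(o + outer(dirv, (0:7) * 5)))
  }
  xyz <- xyz[seq_len(n), , drop = FALSE]
  colnames(xyz) <- c("x_mm", "y_mm", "z_mm")
  # SOZ: spatially contiguous cluster at the heart of the implant (the
  # implant is planned to surround the suspected seizure-onset zone)
  n_soz <- max(1L, round(cfg$soz_fraction * n))
  cen0 <- colMeans(xyz)
  d <- sqrt(rowSums((xyz - matrix(cen0, n, 3, byrow = TRUE))^2))
  soz <- integer(n); soz[order(d)[seq_len(n_soz)]] <- 1L
  # resection: contacts nearest the SOZ centroid (overlaps the SOZ)
  n_res <- max(1L, round(cfg$resected_fraction * n))
  cen <- colMeans(xyz[soz == 1L, , drop = FALSE])
  dres <- sqrt(rowSums((xyz - matrix(cen, n, 3, byrow = TRUE))^2))
  resected <- integer(n); resected[order(dres)[seq_len(n_res)]] <- 1L
  data.frame(patient_id = patient_id,
             channel = sprintf("%s_C%02d", patient_id, seq_len(n)),
             xyz, soz = soz, resected = resected,
             stringsAsFactors = FALSE)
}

draw_event_params <- function(class, cfg) {
  if (class %in% c("RonO", "RonS")) {
    cf <- runif(1, 80, 200 - 1e-9)
    dur <- runif(1, max(20, 4000 / cf), 100)
  } else if (class %in% c("fRonO", "fRonS")) {
    cf <- runif(1, 200, 600)
    dur <- runif(1, 20, 100)
  } else {
    cf <- NA_real_
    dur <- runif(1, 50, 100)
  }
  list(cf = cf, dur_ms = dur)
}

# one event row (times in seconds, durations in ms)
event_row <- function(patient_id, channel, class, onset, cfg, primed = 0L) {
  p <- draw_event_params(class, cfg)
  amp_rel <- 10^rnorm(1, 0, cfg$amp_sd_log10)
  if (primed) amp_rel <- amp_rel * sqrt(cfg$power_gain_prespike)
  hfo_lag <- if (class %in% c("fRonS", "RonS")) runif(1, 5, 15) else 0
  spike_dur <- if (class %in% SPIKE_CLASSES) runif(1, 50, 100) else NA_real_
  if (class %in% c("fRonS", "RonS")) {
    p$dur_ms <- min(p$dur_ms, spike_dur - hfo_lag)
    offset <- onset + spike_dur / 1000
  } else {
    offset <- onset + p$dur_ms / 1000
  }
  data.frame(patient_id = patient_id, channel = channel, class = class,
             onset_s = onset, offset_s = offset, freq_hz = p$cf,
             duration_ms = p$dur_ms, amp_rel = amp_rel, primed = primed,
             hfo_lag_ms = hfo_lag, spike_dur_ms = spike_dur,
             stringsAsFactors = FALSE)
}

gen_channel_events <- function(cfg, patient_id, channel, is_soz, fr_factor) {
  t_end <- cfg$recording_minutes * 60
  lo <- cfg$edge_margin_s
  hi <- t_end - cfg$edge_margin_s
  minutes <- cfg$recording_minutes
  rf <- if (is_soz) cfg$soz_rate_factor else 1

  draw_onsets <- function(rate) {
    n <- rpois(1, rate * minutes)
    sort(runif(n, lo, hi))
  }

  n_sp <- rpois(1, cfg$rate_spike * minutes * rf)
  sp_on <- sort(runif(n_sp, lo, hi))
  sp_cls <- if (n_sp) sample(names(cfg$spike_mix), n_sp, replace = TRUE,
                             prob = cfg$spike_mix) else character(0)
  # residual-FR scaling thins fRonS together with fRonO
  if (fr_factor < 1 && n_sp) {
    drop <- sp_cls == "fRonS" & runif(n_sp) > fr_factor
    sp_on <- sp_on[!drop]; sp_cls <- sp_cls[!drop]
  }
  # minimum spacing is enforced within each independent stream only:
  # thinning across streams would couple fRonO and spike processes and
  # bias the coincidence statistics away from independence
  thin_gap <- function(on) {
    if (length(on) < 2L || cfg$min_event_gap_s <= 0) return(on)
    keep <- logical(length(on)); last <- -Inf
    for (i in seq_along(on)) {
      if (on[i] - last >= cfg$min_event_gap_s) { keep[i] <- TRUE; last <- on[i] }
    }
    on[keep]
  }
  sp_keep <- thin_gap(sp_on)
  sp_cls <- sp_cls[match(sp_keep, sp_on)]
  sp_on <- sp_keep
  stream <- function(onset, class)
    data.frame(onset = onset, class = rep_len(class, length(onset)),
               stringsAsFactors = FALSE)
  bg <- rbind(
    stream(sp_on, sp_cls),
    stream(thin_gap(draw_onsets(cfg$rate_fRonO * rf * fr_factor)), "fRonO"),
    stream(thin_gap(draw_onsets(cfg$rate_RonO * rf)), "RonO"))
  if (is.null(bg) || nrow(bg) == 0L)
    bg <- data.frame(onset = numeric(0), class = character(0),
                     stringsAsFactors = FALSE)
  bg <- bg[order(bg$onset), , drop = FALSE]

  rows <- lapply(seq_len(nrow(bg)), function(i)
    event_row(patient_id, channel, bg$class[i], bg$onset[i], cfg))

  # priming: dedicated fRonO shortly before a spike; enrichment e scales
  # SOZ priming up and non-SOZ priming down (e = 1 is uniform placement);
  # priming fRonO are fast ripples, so the channel's residual fast-ripple
  # factor scales the priming probability too
  p_pr <- if (is_soz) cfg$p_prime * cfg$prime_soz_enrichment
          else cfg$p_prime / cfg$prime_soz_enrichment
  p_pr <- min(1, p_pr) * fr_factor
  sp_idx <- which(bg$class %in% SPIKE_CLASSES)
  for (i in sp_idx) {
    if (runif(1) < p_pr) {
      lat <- if (cfg$prime_latency_mode == "spikelocked")
        runif(1, 0.0005, 0.010) else runif(1, 0.0005, 0.300)
      on <- bg$onset[i] - lat
      if (on > lo)
        rows[[length(rows) + 1L]] <- event_row(patient_id, channel, "fRonO",
                                               on, cfg, primed = 1L)
    }
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) return(NULL)
  ev <- ev[order(ev$onset_s), , drop = FALSE]

  # below-chance coincidence outside the SOZ: remove background fRonO that
  # happen to land within 300 ms before a spike
  if (!is_soz && cfg$p_suppress_nonsoz > 0 && nrow(ev)) {
    sp <- ev$onset_s[ev$class %in% SPIKE_CLASSES]
    if (length(sp)) {
      lat <- min_positive_latency(ev$onset_s, sp)
      hit <- ev$class == "fRonO" & ev$primed == 0L &
        !is.na(lat) & lat < 300
      drop <- hit & runif(nrow(ev)) < cfg$p_suppress_nonsoz
      ev <- ev[!drop, , drop = FALSE]
    }
  }
  # strictly increasing onsets
  if (nrow(ev) > 1L) {
    dup <- c(FALSE, diff(ev$onset_s) <= 0)
    ev <- ev[!dup, , drop = FALSE]
  }
  ev
}

#' Generate ground-truth events, electrodes and epochs for a synthetic cohort
#'
#' The events-only core of the generator: spikes (fRonS/RonS/sharp) and
#' background HFOs are homogeneous Poisson processes per contact; with
#' probability \code{p_prime} a spike receives a dedicated preceding fRonO
#' whose latency is drawn on (0, 300] ms and whose power is scaled by
#' \code{power_gain_prespike}.  Seizure-onset-zone contacts carry
#' \code{soz_rate_factor} times the background rates and (optionally) an
#' enriched priming probability.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param seed optional integer overriding \code{cfg$seed}.
#' @return list of class \code{synth_truth} with \code{events} (one row per
#'   injected event incl. waveform parameters), \code{electrodes},
#'   \code{epochs} (full recording per channel) and \code{outcomes} (per
#'   patient, Engel-1 flag when \code{simulate_outcomes} is on).
#' @export
gen_ground_truth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  t_end <- cfg$recording_minutes * 60
  all_ev <- list(); all_el <- list(); outc <- list()
  n_free <- round(cfg$szfree_fraction * cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    el <- gen_electrodes(cfg, pid)
    szfree <- cfg$simulate_outcomes && p <= n_free
    outc[[p]] <- data.frame(patient_id = pid,
                            engel1 = as.integer(szfree),
                            stringsAsFactors = FALSE)
    for (i in seq_len(nrow(el))) {
      frf <- 1
      if (cfg$simulate_outcomes && el$resected[i] == 0L)
        frf <- if (szfree) cfg$residual_fr_factor_szfree
               else cfg$residual_fr_factor_nonfree
      ev <- gen_channel_events(cfg, pid, el$channel[i],
                               el$soz[i] == 1L, frf)
      if (!is.null(ev)) all_ev[[length(all_ev) + 1L]] <- ev
    }
    all_el[[p]] <- el
  }
  events <- if (length(all_ev)) do.call(rbind, all_ev) else
    event_row("x", "x", "fRonO", 0, cfg)[0, ]
  rownames(events) <- NULL
  electrodes <- do.call(rbind, all_el)
  epochs <- data.frame(patient_id = electrodes$patient_id,
                       channel = electrodes$channel,
                       start_s = 0, end_s = t_end,
                       stringsAsFactors = FALSE)
  structure(list(events = events, electrodes = electrodes, epochs = epochs,
                 outcomes = do.call(rbind, outc), config = cfg),
            class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> %d events on %d contacts (%d patient(s))\n",
              nrow(x$events), nrow(x$electrodes),
              length(unique(x$electrodes$patient_id))))
  print(table(x$events$class))
  invisible(x)
}

#' Ground-truth events in the classified-events schema
#'
#' Converts a \code{\link{gen_ground_truth}} result into the same data frame
#' layout that \code{\link{classify_all}} produces (with coincidence flags
#' filled by \code{\link{flag_coincidence}}), so the coincidence, firing and
#' localization stages can be run directly on ground truth.
#'
#' @param truth a \code{synth_truth}.
#' @return events data frame.
#' @export
truth_events_table <- function(truth) {
  ev <- truth$events
  out <- data.frame(patient_id = ev$patient_id, channel = ev$channel,
                    class = ev$class, onset_s = ev$onset_s,
                    offset_s = ev$offset_s, peak_freq_hz = ev$freq_hz,
                    log10_power = truth_log10_power(ev, truth$config),
                    duration_ms = ev$duration_ms,
                    stringsAsFactors = FALSE)
  flag_coincidence(out)
}
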