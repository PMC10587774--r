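# CSV readers/writers for electrode metadata, unit spike trains, artifact-free
# epochs, classified events and the plain-text run configuration.

events_csv_cols <- c("patient_id", "channel", "class", "onset_s", "offset_s",
                     "peak_freq_hz", "log10_power", "duration_ms", "prespike",
                     "latency_to_spike_ms", "followed_fRonO", "followed_RonO")

#' Write classified HFO/spike events to CSV
#'
#' @param events data frame of classified events (one row per event) with at
#'   least \code{patient_id}, \code{channel}, \code{class}, \code{onset_s},
#'   \code{offset_s}; remaining schema columns are filled with \code{NA}/0 if
#'   absent.  \code{class} must be one of \code{fRonO}, \code{RonO},
#'   \code{fRonS}, \code{RonS}, \code{SharpSpike}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  if (nrow(events) > 0 && !all(events$class %in% EVENT_CLASSES))
    stop("unknown event class label: ",
         paste(setdiff(unique(events$class), EVENT_CLASSES), collapse = ", "))
  for (cn in events_csv_cols)
    if (is.null(events[[cn]]))
      events[[cn]] <- if (cn %in% c("prespike", "followed_fRonO",
                                    "followed_RonO")) 0L else NA_real_
  out <- events[, events_csv_cols, drop = FALSE]
  num <- c("onset_s", "offset_s", "peak_freq_hz", "log10_power",
           "duration_ms", "latency_to_spike_ms")
  for (cn in num) out[[cn]] <- round(as.numeric(out[[cn]]), 6)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read classified events written by \code{write_events}
#'
#' @param path CSV path.
#' @return data frame with the events schema.
#' @export
read_events <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(events_csv_cols, names(ev))
  if (length(miss)) stop("events file missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(ev) && !all(ev$class %in% EVENT_CLASSES))
    stop("unknown event class label in events file")
  ev
}

validate_electrodes <- function(el) {
  need <- c("patient_id", "channel", "x_mm", "y_mm", "z_mm", "soz", "resected")
  miss <- setdiff(need, names(el))
  if (length(miss)) stop("electrodes table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(el[, c("x_mm", "y_mm", "z_mm")]))))
    stop("electrode coordinates must be finite")
  if (!all(el$soz %in% c(0, 1)) || !all(el$resected %in% c(0, 1)))
    stop("soz/resected flags must be 0 or 1")
  el$soz <- as.integer(el$soz)
  el$resected <- as.integer(el$resected)
  el
}

#' Read the cohort CSV tables from a directory
#'
#' Reads \code{electrodes.csv}, \code{units.csv} and \code{epochs.csv} as
#' written by \code{\link{gen_cohort}}, validates them, and assembles the unit
#' spike trains.  Unsorted action-potential times are sorted with a warning.
#'
#' @param dir directory containing the tables.
#' @return list with \code{electrodes} (data frame), \code{units} (list of
#'   \code{unit_spike_train}) and \code{epochs} (data frame with
#'   \code{patient_id}, \code{channel}, \code{start_s}, \code{end_s}).
#' @export
read_tables <- function(dir) {
  el <- validate_electrodes(read.csv(file.path(dir, "electrodes.csv"),
                                     stringsAsFactors = FALSE))
  ep <- read.csv(file.path(dir, "epochs.csv"), stringsAsFactors = FALSE)
  need <- c("patient_id", "channel", "start_s", "end_s")
  if (length(setdiff(need, names(ep))))
    stop("epochs table missing columns")
  ut <- read.csv(file.path(dir, "units.csv"), stringsAsFactors = FALSE)
  units <- list()
  if (nrow(ut)) {
    need <- c("patient_id", "unit_id", "contact", "unit_type", "spike_time_ms")
    miss <- setdiff(need, names(ut))
    if (length(miss)) stop("units table missing columns: ",
                           paste(miss, collapse = ", "))
    for (uid in unique(ut$unit_id)) {
      rows <- ut[ut$unit_id == uid, ]
      tms <- rows$spike_time_ms
      if (is.unsorted(tms)) {
        warning("unsorted AP times for unit ", uid, "; sorting")
        tms <- sort(tms)
      }
      units[[length(units) + 1L]] <- unit_spike_train(
        unit_id = uid, patient_id = rows$patient_id[1],
        contact = rows$contact[1], unit_type = rows$unit_type[1],
        ap_times_ms = tms)
    }
  }
  list(electrodes = el, units = units, epochs = ep)
}

#' Unit spike train container
#'
#' @param unit_id unique unit identifier (unique across patients).
#' @param patient_id patient identifier.
#' @param contact macroelectrode contact label whose microwire bundle the
#'   unit was isolated from.
#' @param unit_type \code{"single"} or \code{"multi"}.
#' @param ap_times_ms sorted non-negative action-potential times in ms.
#' @return object of class \code{unit_spike_train}.
#' @export
unit_spike_train <- function(unit_id, patient_id, contact, unit_type,
                             ap_times_ms) {
  stopifnot(unit_type %in% c("single", "multi"),
            !is.unsorted(ap_times_ms), all(ap_times_ms >= 0))
  structure(list(unit_id = unit_id, patient_id = patient_id,
                 contact = contact, unit_type = unit_type,
                 ap_times_ms = as.numeric(ap_times_ms)),
            class = "unit_spike_train")
}

#' @export
print.unit_spike_train <- function(x, ...) {
  cat(sprintf("<unit_spike_train> %s (%s) on %s/%s: %d APs\n", x$unit_id,
              x$unit_type, x$patient_id, x$contact, length(x$ap_times_ms)))
  invisible(x)
}

#' Default analysis parameters
#'
#' The tunables of the analysis stages, serialized alongside the generator
#' configuration by \code{\link{gen_cohort}}: the Gaussian rate kernel SD
#' (ms), baseline extent (ms), trial window (ms), pre-spike coincidence
#' window (ms), surrogate count, unit-inclusion level and the fast-ripple
#' peak-frequency cut (Hz) of the rate-distance graph.
#'
#' @return named list of analysis defaults.
#' @export
analysis_config <- function() {
  list(kernel_ms = 100, baseline_ms = 750, window_ms = 2000,
       prespike_ms = 300, n_surrogates = 500, alpha_unit = 0.001,
       fr_freq_cut_hz = 350)
}

#' Write/read a plain-text key=value run configuration
#'
#' @param cfg named list of scalar values.
#' @param path file path.
#' @return for the reader, a named list (numbers parsed where possible).
#' @export
write_run_config <- function(cfg, path) {
  keep <- vapply(cfg, function(v) is.atomic(v) && length(v) == 1L, TRUE)
  lines <- sprintf("%s=%s", names(cfg)[keep],
                   vapply(cfg[keep], function(v) format(v, digits = 15), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}
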