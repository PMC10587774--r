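# Minimal EDF (European Data Format) reader/writer for multichannel iEEG.
# EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal, and data
# records of little-endian 16-bit integers scaled between a physical and a
# digital range.  All channels must share one sampling rate; one data record
# spans one second.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' iEEG recording container
#'
#' Bundles a channels-by-samples matrix in microvolts with its sampling rate,
#' channel labels, patient identifier and per-channel artifact-free epochs
#' (half-open intervals in seconds).
#'
#' @param samples numeric matrix, channels in rows.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per row.
#' @param patient_id string.
#' @param epochs named list of two-column matrices (start, end) in seconds,
#'   one per channel; defaults to the full duration for every channel.
#' @return an object of class \code{ieeg_recording}.
#' @export
ieeg_recording <- function(samples, fs, channel_labels = rownames(samples),
                           patient_id = "P01", epochs = NULL) {
  samples <- as.matrix(samples)
  stopifnot(fs > 0, nrow(samples) >= 1L)
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(nrow(samples)))
  dur <- ncol(samples) / fs
  if (is.null(epochs))
    epochs <- setNames(rep(list(cbind(start = 0, end = dur)),
                           nrow(samples)), channel_labels)
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 patient_id = patient_id, epochs = epochs,
                 duration_s = dur),
            class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> patient %s: %d channels x %.1f s @ %g Hz\n",
              x$patient_id, nrow(x$samples), x$duration_s, x$fs))
  invisible(x)
}

#' Write an iEEG recording to an EDF file
#'
#' Signals are quantized to 16 bits over a symmetric physical range in
#' microvolts; one data record holds one second of data, so the recording is
#' truncated to a whole number of seconds.
#'
#' @param rec an \code{\link{ieeg_recording}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ieeg_recording"))
  fs <- rec$fs
  stopifnot(abs(fs - round(fs)) < 1e-9)
  fs <- as.integer(round(fs))
  nrec <- floor(ncol(rec$samples) / fs)
  stopifnot(nrec >= 1L)
  x <- rec$samples[, seq_len(nrec * fs), drop = FALSE]
  ns <- nrow(x)

  pmax_ <- apply(abs(x), 1, max)
  pmax_ <- ifelse(pmax_ > 0, pmax_ * 1.01, 1)
  dmin <- -32768L; dmax <- 32767L
  # digital value d maps to physical  -pmax + (d - dmin) * (2*pmax)/(dmax-dmin)
  dig <- matrix(0L, ns, ncol(x))
  for (i in seq_len(ns)) {
    d <- round((x[i, ] + pmax_[i]) / (2 * pmax_[i]) * (dmax - dmin)) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$patient_id, 80),
    edf_pad("hfoprime synthetic iEEG", 80),
    edf_pad("01.01.26", 8),
    edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    paste0(vapply(rec$channel_labels, edf_pad, "", width = 16), collapse = ""),
    paste0(vapply(rep("", ns), edf_pad, "", width = 80), collapse = ""),
    paste0(vapply(rep("uV", ns), edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(sprintf("%.6g", -pmax_), edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(sprintf("%.6g", pmax_), edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep(dmin, ns), edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep(dmax, ns), edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep("", ns), edf_pad, "", width = 80), collapse = ""),
    paste0(vapply(rep(fs, ns), edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(rep("", ns), edf_pad, "", width = 32), collapse = ""))
  for (f in fields) writeChar(f, con, eos = NULL)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) writeBin(dig[i, idx], con, size = 2L,
                                    endian = "little")
  }
  invisible(path)
}

edf_read_field <- function(con, n) trimws(readChar(con, n, useBytes = TRUE))

#' Read an EDF file into an iEEG recording
#'
#' All signals must share one sampling rate.  Samples are returned in the
#' physical unit stored in the file (microvolts for files written by
#' \code{\link{write_edf}}).
#'
#' @param path EDF file path.
#' @param epochs optional per-channel artifact-free epoch list; defaults to
#'   the full recording.
#' @return an \code{\link{ieeg_recording}}.
#' @export
read_edf <- function(path, epochs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ver <- edf_read_field(con, 8)
  if (!identical(ver, "0")) stop("malformed EDF header (version field)")
  patient_id <- edf_read_field(con, 80)
  edf_read_field(con, 80); edf_read_field(con, 8); edf_read_field(con, 8)
  hbytes <- as.integer(edf_read_field(con, 8))
  edf_read_field(con, 44)
  nrec <- as.integer(edf_read_field(con, 8))
  recdur <- as.numeric(edf_read_field(con, 8))
  ns <- as.integer(edf_read_field(con, 4))
  if (is.na(ns) || ns < 1L) stop("EDF file contains no signals")
  if (is.na(nrec) || nrec < 1L || is.na(recdur) || recdur <= 0)
    stop("malformed EDF header (record fields)")
  if (!identical(hbytes, 256L * (ns + 1L)))
    stop("malformed EDF header (header size)")

  rd <- function(w) vapply(seq_len(ns), function(i) edf_read_field(con, w), "")
  labels <- rd(16); rd(80); rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  nsamp <- as.integer(rd(8))
  rd(32)
  if (length(unique(nsamp)) != 1L)
    stop("mixed sampling rates across EDF signals are not supported")
  fs <- nsamp[1] / recdur
  x <- matrix(0, ns, nrec * nsamp[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, integer(), n = nsamp[1], size = 2L, signed = TRUE,
                   endian = "little")
      x[i, ((r - 1) * nsamp[1] + 1):(r * nsamp[1])] <-
        pmin_[i] + (d - dmin[i]) * scale[i]
    }
  }
  rownames(x) <- labels
  ieeg_recording(x, fs, labels, patient_id, epochs)
}
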