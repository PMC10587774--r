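# Morlet wavelet time-frequency maps and isopower contour extraction.
# The classifier's topology rules (closed vs open contours, contour groups)
# live in classify.R; this file produces the maps and the labelled contours.

#' Default analysis frequency grid
#'
#' 64 log-spaced frequencies from 60 to 800 Hz, spanning both HFO bands
#' with margin below 80 Hz (so that broadband spike signatures are visible)
#' and enough headroom above 600 Hz that the spectral spread of a brief
#' fast-ripple burst near the band edge still closes inside the map.
#'
#' @param n number of grid steps.
#' @param lo,hi grid limits in Hz.
#' @return numeric vector of frequencies.
#' @export
tfr_freq_grid <- function(n = 64, lo = 60, hi = 800) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Morlet wavelet power map of a signal segment
#'
#' Complex Morlet convolution implemented in the frequency domain (one-sided
#' Gaussian kernels of width f/n_cycles), returning power over a log-spaced
#' frequency grid.  With \code{whiten = TRUE} each frequency row is divided
#' by its own median power across the segment, flattening the 1/f background
#' so that event power is expressed relative to the channel's background at
#' that frequency.
#'
#' @param segment numeric vector (one channel).
#' @param fs sampling rate in Hz (at least 1200).
#' @param freqs frequency grid (default \code{\link{tfr_freq_grid}}).
#' @param n_cycles Morlet width in cycles (default 7).
#' @param whiten divide each row by its median power (default TRUE).
#' @param dt_out time resolution of the returned map in seconds; the map is
#'   decimated to roughly this step (default 2 ms) to keep contour
#'   extraction cheap.
#' @return object of class \code{tf_map}: \code{power} (frequencies x
#'   times), \code{freqs}, \code{times} (seconds from segment start),
#'   \code{fs}, \code{coi_s} (cone-of-influence half-width per frequency)
#'   and \code{whiten_ref} (the per-row median raw power).
#' @export
wavelet_tfr <- function(segment, fs, freqs = tfr_freq_grid(),
                        n_cycles = 7, whiten = TRUE, dt_out = 0.002) {
  n <- length(segment)
  if (fs < 1200) stop("sampling rate below 1200 Hz")
  if (n < fs * 0.2) stop("segment too short for time-frequency analysis")
  if (max(freqs) >= fs / 2) stop("frequency grid reaches Nyquist")
  x <- segment - mean(segment)
  X <- fft(x)
  fax <- (seq_len(n) - 1) * fs / n
  pos <- fax <= fs / 2
  dec <- max(1L, floor(dt_out * fs))
  keep <- seq(1L, n, by = dec)
  pw <- matrix(0, length(freqs), length(keep))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sf <- f / n_cycles
    H <- numeric(n)
    H[pos] <- exp(-((fax[pos] - f)^2) / (2 * sf^2))
    w <- fft(X * H, inverse = TRUE) / n
    pw[k, ] <- Mod(w[keep])^2
  }
  ref <- apply(pw, 1, median)
  if (whiten) {
    ref_safe <- ifelse(ref > 0, ref, 1)
    pw <- pw / ref_safe
  }
  structure(list(power = pw, freqs = freqs,
                 times = (keep - 1) / fs, fs = fs,
                 coi_s = 2 * n_cycles / (2 * pi * freqs),
                 whiten_ref = ref, whitened = whiten),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d freqs (%.0f-%.0f Hz) x %d times (%.3f s)%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              max(x$times), if (x$whitened) ", whitened" else ""))
  invisible(x)
}

# restrict a tf_map to a time range (whitening reference is unchanged:
# rows were whitened over the full window)
tf_subset <- function(tf, t0, t1) {
  keep <- tf$times >= t0 & tf$times <= t1
  if (!any(keep)) return(tf)
  tf$power <- tf$power[, keep, drop = FALSE]
  tf$times <- tf$times[keep]
  tf
}

#' Contour threshold of a time-frequency map
#'
#' The isopower floor below which contours are discarded:
#' \code{0.2 * (max - min) + min} of the map's power.  For a constant map
#' the threshold equals that constant (and no contours exist above it).
#'
#' @param tf a \code{tf_map} (or bare numeric matrix).
#' @param frac threshold fraction (default 0.2).
#' @return scalar power level.
#' @export
contour_threshold <- function(tf, frac = 0.2) {
  p <- if (inherits(tf, "tf_map")) tf$power else tf
  frac * (max(p) - min(p)) + min(p)
}

# Power-weighted mean log-frequency and peak power of the grid cells
# enclosed by a closed contour polygon.
enclosed_stats <- function(tf, cx, cy) {
  it <- which(tf$times >= min(cx) & tf$times <= max(cx))
  jf <- which(tf$freqs >= min(cy) & tf$freqs <= max(cy))
  if (!length(it) || !length(jf)) {
    # contour smaller than one grid cell: use nearest grid point
    it <- which.min(abs(tf$times - mean(cx)))
    jf <- which.min(abs(tf$freqs - mean(cy)))
    return(list(peak_t = tf$times[it], peak_f = tf$freqs[jf],
                peak_power = tf$power[jf, it],
                mean_freq = tf$freqs[jf]))
  }
  grid <- expand.grid(t = tf$times[it], f = tf$freqs[jf])
  ins <- pracma::inpolygon(grid$t, grid$f, cx, cy, boundary = TRUE)
  if (!any(ins)) {
    it0 <- it[which.min(abs(tf$times[it] - mean(cx)))]
    jf0 <- jf[which.min(abs(tf$freqs[jf] - mean(cy)))]
    return(list(peak_t = tf$times[it0], peak_f = tf$freqs[jf0],
                peak_power = tf$power[jf0, it0],
                mean_freq = tf$freqs[jf0]))
  }
  sub <- tf$power[jf, it, drop = FALSE]
  pv <- t(sub)[ins]            # expand.grid runs over t fastest
  tt <- grid$t[ins]; ff <- grid$f[ins]
  imax <- which.max(pv)
  list(peak_t = tt[imax], peak_f = ff[imax], peak_power = pv[imax],
       mean_freq = exp(sum(pv * log(ff)) / sum(pv)))
}

#' Extract and label isopower contours
#'
#' Computes iso-power contours at a ladder of evenly spaced levels from the
#' threshold to the map maximum, discards contours below the threshold and
#' labels each contour closed (first and last vertex identical) or open.
#' Closed contours are grouped by the local power maximum they enclose: a
#' nested family of closed contours around one peak forms one closed-loop
#' contour (CLC) group.
#'
#' @param tf a \code{tf_map}.
#' @param level threshold power level (default
#'   \code{\link{contour_threshold}}).
#' @param n_levels number of ladder levels from threshold to max.
#' @return object of class \code{contour_set}: a data frame \code{contours}
#'   (level, closed flag, time/frequency extent, enclosed peak, group id)
#'   with the vertex polylines in attribute \code{vertices}, plus the
#'   threshold and map maximum.
#' @export
extract_contours <- function(tf, level = contour_threshold(tf),
                             n_levels = 10) {
  stopifnot(inherits(tf, "tf_map"))
  pmax_ <- max(tf$power)
  empty <- data.frame(level = numeric(0), closed = logical(0),
                      min_t = numeric(0), max_t = numeric(0),
                      min_f = numeric(0), max_f = numeric(0),
                      peak_t = numeric(0), peak_f = numeric(0),
                      peak_power = numeric(0), mean_freq = numeric(0),
                      group = integer(0))
  if (!(pmax_ > level) || !is.finite(level)) {
    return(structure(list(contours = empty, vertices = list(),
                          threshold = level, max_power = pmax_),
                     class = "contour_set"))
  }
  levels <- seq(level, pmax_, length.out = n_levels)
  cl <- contourLines(x = tf$times, y = tf$freqs, z = t(tf$power),
                     levels = levels[levels < pmax_])
  if (!length(cl)) {
    return(structure(list(contours = empty, vertices = list(),
                          threshold = level, max_power = pmax_),
                     class = "contour_set"))
  }
  rows <- vector("list", length(cl))
  verts <- vector("list", length(cl))
  for (i in seq_along(cl)) {
    cc <- cl[[i]]
    nv <- length(cc$x)
    closed <- cc$x[1] == cc$x[nv] && cc$y[1] == cc$y[nv]
    st <- if (closed) enclosed_stats(tf, cc$x, cc$y) else
      list(peak_t = NA_real_, peak_f = NA_real_, peak_power = NA_real_,
           mean_freq = NA_real_)
    rows[[i]] <- data.frame(level = cc$level, closed = closed,
                            min_t = min(cc$x), max_t = max(cc$x),
                            min_f = min(cc$y), max_f = max(cc$y),
                            peak_t = st$peak_t, peak_f = st$peak_f,
                            peak_power = st$peak_power,
                            mean_freq = st$mean_freq, group = NA_integer_)
    verts[[i]] <- cbind(t = cc$x, f = cc$y)
  }
  df <- do.call(rbind, rows)
  # group closed contours by the peak cell they enclose
  ic <- which(df$closed)
  if (length(ic)) {
    key <- paste(signif(df$peak_t[ic], 10), signif(df$peak_f[ic], 10))
    df$group[ic] <- as.integer(factor(key, levels = unique(key)))
  }
  structure(list(contours = df, vertices = verts, threshold = level,
                 max_power = pmax_),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  df <- x$contours
  cat(sprintf("<contour_set> %d contours (%d closed in %d groups, %d open)\n",
              nrow(df), sum(df$closed),
              length(unique(df$group[df$closed])), sum(!df$closed)))
  invisible(x)
}
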