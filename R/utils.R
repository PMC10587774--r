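# Internal numeric helpers shared across modules.

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector (the signal plus i
#' times its Hilbert transform), used for band-envelope computation.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Robust z-score against median/MAD computed over a reference subset.
robust_z <- function(x, ref = x) {
  m <- median(ref)
  s <- mad(ref, center = m)
  if (s <= 0) s <- sd(ref)
  if (!is.finite(s) || s <= 0) return(rep(0, length(x)))
  (x - m) / s
}

# Contiguous runs of TRUE in a logical vector: matrix with start/end indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Clip intervals (matrix cols lo, hi) to a set of allowed [start, end) epochs;
# returns intervals fully inside some epoch.
inside_epochs <- function(lo, hi, epochs) {
  if (length(lo) == 0L) return(logical(0))
  ok <- logical(length(lo))
  for (k in seq_len(nrow(epochs))) {
    ok <- ok | (lo >= epochs[k, 1] & hi <= epochs[k, 2])
  }
  ok
}

# Draw n points uniformly from a union of half-open intervals [start, end).
runif_in_epochs <- function(n, epochs) {
  len <- epochs[, 2] - epochs[, 1]
  tot <- sum(len)
  stopifnot(tot > 0)
  u <- runif(n, 0, tot)
  cum <- cumsum(len)
  idx <- findInterval(u, c(0, cum[-length(cum)] + 1e-12)) # interval index
  idx <- pmin(pmax(idx, 1L), nrow(epochs))
  off <- u - c(0, cum)[idx]
  epochs[idx, 1] + off
}

# Total length of an epoch set.
epoch_length <- function(epochs) sum(epochs[, 2] - epochs[, 1])

# Subtract a set of bad intervals from a set of epochs (all matrices with
# columns start, end); returns the remaining intervals, sorted.
subtract_intervals <- function(epochs, bad) {
  if (is.null(bad) || nrow(bad) == 0L) return(epochs)
  out <- list()
  for (k in seq_len(nrow(epochs))) {
    segs <- matrix(epochs[k, ], ncol = 2)
    for (b in seq_len(nrow(bad))) {
      nxt <- list()
      for (s in seq_len(nrow(segs))) {
        lo <- segs[s, 1]; hi <- segs[s, 2]
        blo <- bad[b, 1]; bhi <- bad[b, 2]
        if (bhi <= lo || blo >= hi) {
          nxt[[length(nxt) + 1L]] <- c(lo, hi)
        } else {
          if (blo > lo) nxt[[length(nxt) + 1L]] <- c(lo, blo)
          if (bhi < hi) nxt[[length(nxt) + 1L]] <- c(bhi, hi)
        }
      }
      segs <- if (length(nxt)) do.call(rbind, nxt) else matrix(numeric(0), ncol = 2)
      if (nrow(segs) == 0L) break
    }
    if (nrow(segs)) out[[length(out) + 1L]] <- segs
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2,
                                  dimnames = list(NULL, c("start", "end"))))
  res <- do.call(rbind, out)
  res <- res[order(res[, 1]), , drop = FALSE]
  colnames(res) <- c("start", "end")
  res
}

# 1/f ("pink") Gaussian noise with unit standard deviation.
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))            # avoid divide-by-zero at DC
  f <- pmin(f, n - f + 1)              # fold to two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE) / n)
  x / sd(x)
}

# The five event class labels used throughout.
EVENT_CLASSES <- c("fRonO", "RonO", "fRonS", "RonS", "SharpSpike")
SPIKE_CLASSES <- c("fRonS", "RonS", "SharpSpike")
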