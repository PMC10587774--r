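# Shared fixtures and independent oracles used across test files.

# small, fast synthetic cohort configuration (events-only scale)
tiny_cfg <- function(...) {
  args <- list(n_patients = 1L, n_contacts = 4L, recording_minutes = 4,
               seed = 1L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

# construct a tf_map directly from a power field (freqs x times)
make_tf_map <- function(power, freqs, times) {
  structure(list(power = power, freqs = freqs, times = times,
                 fs = 1 / diff(times[1:2]),
                 coi_s = rep(0, length(freqs)),
                 whiten_ref = rep(1, length(freqs)), whitened = TRUE),
            class = "tf_map")
}

# random smooth blob map: k well-separated 2D Gaussians in (time, log f),
# some optionally truncated by the map edge; returns the map and the
# number of blob centres lying inside the map
random_blob_map <- function(seed, n_f = 48, n_t = 200) {
  set.seed(seed)
  freqs <- tfr_freq_grid(n = n_f, lo = 60, hi = 800)
  times <- seq(0, 0.8, length.out = n_t)
  lf <- log(freqs)
  pw <- matrix(0.02, n_f, n_t)
  k <- sample(1:4, 1)
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < k && tries < 200) {
    tries <- tries + 1
    ct <- runif(1, -0.1, 0.9)                 # may fall off the time edge
    cf <- runif(1, min(lf) + 0.2, max(lf) - 0.2)
    if (nrow(centers) == 0 ||
        all(abs(centers[, 1] - ct) > 0.25 | abs(centers[, 2] - cf) > 0.8))
      centers <- rbind(centers, c(ct, cf))
  }
  st <- 0.025; sf <- 0.12
  amp <- runif(nrow(centers), 1, 5)
  for (i in seq_len(nrow(centers))) {
    pw <- pw + amp[i] * outer(exp(-(lf - centers[i, 2])^2 / (2 * sf^2)),
                              exp(-(times - centers[i, 1])^2 / (2 * st^2)))
  }
  list(tf = make_tf_map(pw, freqs, times), centers = centers)
}

# flood-fill (4-connected) components of a logical mask; returns the label
# matrix — the independent connected-components oracle
flood_fill_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# brute-force Holm step-down: reject while sorted p_(i) <= alpha/(m-i+1)
holm_bruteforce <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  keep <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) keep[ord[i]] <- TRUE
    else break
  }
  keep
}

# brute-force O(n*m) minimum positive latency in ms
latency_bruteforce <- function(hfo, spikes) {
  vapply(hfo, function(h) {
    d <- spikes - h
    d <- d[d > 0]
    if (length(d)) min(d) * 1000 else NA_real_
  }, 0)
}

# brute-force eccentricity/radius of a weight matrix with NA = no edge
radius_bruteforce <- function(w) {
  n <- nrow(w)
  ecc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- w[i, setdiff(seq_len(n), i)]
    v <- v[is.finite(v)]
    if (length(v)) ecc[i] <- max(v)
  }
  if (all(is.na(ecc))) return(NA_real_)
  min(ecc, na.rm = TRUE)
}

# independent peri-event firing oracle: Poisson spikes at `base` Hz with
# in-event rate `rin` on [0, d], smoothed by exact Gaussian bumps and
# sampled on the package's 40 Hz grid; returns mean hfodiff over nrep draws
hfodiff_oracle <- function(durs, base, rin, nrep, sigma = 0.1) {
  ts <- seq(-1, 0.975, by = 0.025)
  mean(replicate(nrep, {
    d <- durs[sample.int(length(durs), 1)]
    sp <- runif(rpois(1, base * 2.8), -1.4, 1.4)
    sp <- c(sp, runif(rpois(1, (rin - base) * d), 0, d))
    rate <- vapply(ts, function(t) sum(dnorm(t - sp, 0, sigma)), 0)
    max(rate[ts >= 0 & ts <= d]) - mean(rate[ts >= -0.75 & ts < 0])
  }))
}
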