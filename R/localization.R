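# Resection-cohort localization: SOZ/resection event ratios and the
# fast-ripple rate-distance graph radius difference.

#' Within-patient event ratio in the SOZ or resection
#'
#' The number of events of the requested kind on flagged contacts divided by
#' the total number of such events, per patient.
#'
#' @param events classified and flagged events data frame.
#' @param electrodes electrode table with \code{channel}, \code{soz},
#'   \code{resected}.
#' @param class event class (e.g. \code{"fRonO"}), or a logical vector /
#'   predicate selecting event rows (e.g. pre-spike fRonO only).
#' @param region \code{"soz"} or \code{"resected"}.
#' @param patient optional patient id; default uses all rows (call per
#'   patient for within-patient ratios).
#' @return ratio in [0, 1], or \code{NA} if the patient has no such events.
#' @export
event_ratios <- function(events, electrodes, class = "fRonO",
                         region = c("soz", "resected"), patient = NULL) {
  region <- match.arg(region)
  if (!is.null(patient)) {
    events <- events[events$patient_id == patient, , drop = FALSE]
    electrodes <- electrodes[electrodes$patient_id == patient, , drop = FALSE]
  }
  sel <- if (is.function(class)) class(events)
         else if (is.logical(class)) class
         else events$class %in% class
  ev <- events[sel, , drop = FALSE]
  if (!nrow(ev)) return(NA_real_)
  flagged <- electrodes$channel[electrodes[[region]] == 1L]
  sum(ev$channel %in% flagged) / nrow(ev)
}

#' Fast-ripple rate-distance adjacency matrix
#'
#' Node weights are per-contact event rates (events/min over the
#' artifact-free recording) of fRonS events plus fRonO events with peak
#' frequency above \code{freq_cut_hz}; the edge weight between two
#' generator sites (contacts with nonzero rate) is the mean of their rates
#' times their Euclidean distance in mm.  Contacts that generate no
#' qualifying events carry no edges (every pair weight would be compared
#' against the \code{> 0} rule) and are excluded from the graph, so the
#' radius describes the spatial spread of fast-ripple-generating tissue.
#'
#' @param events flagged events for one patient.
#' @param electrodes electrode rows for the same patient (coordinates in
#'   mm).
#' @param subset \code{"all"} or \code{"resected"} contacts.
#' @param minutes artifact-free recording minutes for the rate denominator.
#' @param freq_cut_hz fRonO peak-frequency cut (default 350 Hz).
#' @return object of class \code{rate_distance_graph}: the symmetric weight
#'   matrix (zero diagonal, \code{NA} where no edge) and the per-contact
#'   rates (all contacts in the subset, including rate-zero ones).
#' @export
rate_distance_matrix <- function(events, electrodes,
                                 subset = c("all", "resected"),
                                 minutes, freq_cut_hz = 350) {
  subset <- match.arg(subset)
  el <- electrodes
  if (subset == "resected") el <- el[el$resected == 1L, , drop = FALSE]
  if (nrow(el) < 2L) stop("need at least 2 contacts in subset")
  sel <- events$class == "fRonS" |
    (events$class == "fRonO" & !is.na(events$peak_freq_hz) &
       events$peak_freq_hz > freq_cut_hz)
  ev <- events[sel, , drop = FALSE]
  rate <- vapply(el$channel, function(ch)
    sum(ev$channel == ch) / minutes, 0)
  gen <- rate > 0
  if (sum(gen) < 2L) stop("fewer than 2 generator sites in subset")
  xyz <- as.matrix(el[gen, c("x_mm", "y_mm", "z_mm"), drop = FALSE])
  d <- as.matrix(stats::dist(xyz))
  w <- (outer(rate[gen], rate[gen], "+") / 2) * d
  w[w <= 0 & row(w) != col(w)] <- NA   # coincident contacts: no edge
  diag(w) <- 0
  dimnames(w) <- list(el$channel[gen], el$channel[gen])
  structure(list(weights = w, rates = rate, subset = subset),
            class = "rate_distance_graph")
}

#' Geometric radius of a rate-distance graph
#'
#' Treats the weight matrix as a distance matrix: a node's eccentricity is
#' the largest finite off-diagonal entry in its row (absent edges are
#' skipped); the radius is the minimum eccentricity.  Nodes disconnected
#' from every other node are excluded with a warning.
#'
#' @param g a \code{\link{rate_distance_matrix}} result or bare symmetric
#'   matrix (\code{NA} = no edge).
#' @return scalar radius.
#' @export
graph_radius <- function(g) {
  w <- if (inherits(g, "rate_distance_graph")) g$weights else as.matrix(g)
  n <- nrow(w)
  if (n < 2L) stop("need at least 2 nodes")
  ecc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- w[i, -i]
    v <- v[is.finite(v)]
    if (length(v)) ecc[i] <- max(v)
  }
  if (all(is.na(ecc))) stop("graph has no finite edges")
  if (any(is.na(ecc))) warning("isolated node(s) excluded from the radius")
  min(ecc, na.rm = TRUE)
}

#' Radius difference between the full and the resected contact graph
#'
#' \code{sqrt(radius_all - radius_resected)}; smaller values mean less
#' residual fast-ripple-generating tissue after the resection.  When the
#' resected-graph radius exceeds the full-graph radius the root is
#' undefined and \code{NA} is returned with attribute
#' \code{negative_argument = TRUE}.
#'
#' @param r_all radius over all contacts.
#' @param r_resected radius over resected contacts.
#' @return scalar (possibly \code{NA} with a flag attribute).
#' @export
radius_difference <- function(r_all, r_resected) {
  if (r_all < r_resected) {
    out <- NA_real_
    attr(out, "negative_argument") <- TRUE
    return(out)
  }
  sqrt(r_all - r_resected)
}

#' Per-patient localization metrics
#'
#' Computes, for each patient: SOZ and resection ratios for solitary fRonO,
#' pre-spike fRonO and spikes, and the fast-ripple rate-distance radii and
#' radius difference.
#'
#' @param events flagged events data frame (all patients).
#' @param electrodes electrode table (all patients).
#' @param minutes recording minutes per patient.
#' @param freq_cut_hz fRonO frequency cut for the rate-distance graph.
#' @return data frame, one row per patient.
#' @export
localization_metrics <- function(events, electrodes, minutes,
                                 freq_cut_hz = 350) {
  out <- list()
  for (pid in unique(electrodes$patient_id)) {
    ev <- events[events$patient_id == pid, , drop = FALSE]
    el <- electrodes[electrodes$patient_id == pid, , drop = FALSE]
    pre_fro <- function(e) e$class == "fRonO" & e$prespike == 1
    sol_fro <- function(e) e$class == "fRonO" & e$prespike == 0
    spikes <- function(e) e$class %in% SPIKE_CLASSES
    r_all <- tryCatch(graph_radius(rate_distance_matrix(
      ev, el, "all", minutes, freq_cut_hz)), error = function(e) NA_real_)
    r_res <- tryCatch(graph_radius(rate_distance_matrix(
      ev, el, "resected", minutes, freq_cut_hz)),
      error = function(e) NA_real_)
    rd <- if (is.na(r_all) || is.na(r_res)) NA_real_
          else suppressWarnings(radius_difference(r_all, r_res))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid,
      soz_ratio_fRonO = event_ratios(ev, el, sol_fro, "soz"),
      soz_ratio_prespike_fRonO = event_ratios(ev, el, pre_fro, "soz"),
      soz_ratio_spikes = event_ratios(ev, el, spikes, "soz"),
      resection_ratio_fRonO = event_ratios(ev, el, sol_fro, "resected"),
      resection_ratio_prespike_fRonO = event_ratios(ev, el, pre_fro,
                                                    "resected"),
      radius_all = r_all, radius_resected = r_res,
      radius_difference = as.numeric(rd),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Outcome-stratified cohort comparison
#'
#' Summarises per-patient localization metrics by post-operative outcome
#' (Engel 1, seizure-free, versus worse) with Wilcoxon rank-sum tests, and
#' compares pre-spike against solitary fRonO resection ratios within
#' patients with a Wilcoxon signed-rank test.
#'
#' @param metrics data frame from \code{\link{localization_metrics}}.
#' @param outcomes data frame with \code{patient_id} and \code{engel1}
#'   (1 = seizure-free).
#' @return list with the merged table, group medians, rank-sum p-values per
#'   metric and the signed-rank comparison.
#' @export
cohort_report <- function(metrics, outcomes) {
  df <- merge(metrics, outcomes, by = "patient_id")
  g1 <- df[df$engel1 == 1L, ]
  g0 <- df[df$engel1 == 0L, ]
  if (nrow(g1) < 2L || nrow(g0) < 2L)
    stop("need at least 2 patients per outcome group")
  cols <- c("soz_ratio_fRonO", "soz_ratio_prespike_fRonO",
            "resection_ratio_fRonO", "resection_ratio_prespike_fRonO",
            "radius_difference")
  ranksum <- lapply(setNames(cols, cols), function(cn) {
    a <- g1[[cn]]; b <- g0[[cn]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(list(p = NA_real_, median_szfree = median(a),
                  median_nonfree = median(b)))
    wt <- suppressWarnings(wilcox.test(a, b))
    list(p = wt$p.value, median_szfree = median(a),
         median_nonfree = median(b))
  })
  ok <- complete.cases(df[, c("resection_ratio_prespike_fRonO",
                              "resection_ratio_fRonO")])
  signrank <- if (sum(ok) >= 2L) suppressWarnings(wilcox.test(
    df$resection_ratio_prespike_fRonO[ok], df$resection_ratio_fRonO[ok],
    paired = TRUE))$p.value else NA_real_
  list(table = df, ranksum = ranksum,
       signrank_prespike_vs_solitary_resection = signrank)
}
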