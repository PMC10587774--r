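# Gaussian identity-link mixed-effects models of event-locked firing, with
# crossed random intercepts for unit, contact and patient, fitted by
# maximum likelihood via lme4.

#' Specify a firing-rate mixed model
#'
#' @param response \code{"hfodiff_fr"} or \code{"bl_fr"}.
#' @param fixed fixed-effect columns (subset of \code{log10_power},
#'   \code{prespike}, \code{followed_fRonO}, \code{followed_RonO},
#'   \code{unit_type}; at most three).
#' @param interactions character vector of interaction terms such as
#'   \code{"log10_power:prespike"} (at most four).
#' @param random grouping columns for random intercepts (default unit,
#'   contact and patient identifiers, crossed; identifiers are unique
#'   across patients so crossed and nested coincide).
#' @return list of class \code{glmm_spec}.
#' @export
glmm_spec <- function(response = c("hfodiff_fr", "bl_fr"),
                      fixed = "log10_power", interactions = character(0),
                      random = c("unit_id", "contact", "patient_id")) {
  response <- match.arg(response)
  allowed <- c("log10_power", "prespike", "followed_fRonO",
               "followed_RonO", "unit_type")
  if (!all(fixed %in% allowed))
    stop("unknown fixed effect: ", paste(setdiff(fixed, allowed),
                                         collapse = ", "))
  if (length(fixed) > 3L) stop("at most three fixed effects")
  if (length(interactions) > 4L) stop("at most four interaction terms")
  structure(list(response = response, fixed = fixed,
                 interactions = interactions, random = random),
            class = "glmm_spec")
}

#' Assemble the model frame for a firing-rate mixed model
#'
#' Selects the response, fixed-effect and grouping columns, drops rows with
#' missing values and rows from units excluded by the inclusion test, and
#' drops (with a warning) fixed effects that have a single level in the
#' data.
#'
#' @param trials an \code{\link{build_trials}} data frame.
#' @param spec a \code{\link{glmm_spec}}.
#' @param include optional result of \code{\link{unit_inclusion_test}};
#'   rows of excluded units are removed.
#' @return list with \code{frame} (data frame) and the pruned \code{spec}.
#' @export
build_design <- function(trials, spec, include = NULL) {
  stopifnot(inherits(spec, "glmm_spec"))
  need <- unique(c(spec$response, spec$fixed, spec$random))
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- trials[, need, drop = FALSE]
  if (!is.null(include)) {
    ok <- include$unit_id[include$included]
    df <- df[df$unit_id %in% ok, , drop = FALSE]
  }
  df <- df[complete.cases(df), , drop = FALSE]
  fixed <- spec$fixed
  for (fx in fixed) {
    if (length(unique(df[[fx]])) < 2L) {
      warning("fixed effect '", fx, "' has a single level; dropped")
      fixed <- setdiff(fixed, fx)
    }
  }
  inter <- spec$interactions[vapply(spec$interactions, function(tm)
    all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% fixed), TRUE)]
  spec$fixed <- fixed
  spec$interactions <- inter
  list(frame = df, spec = spec)
}

glmm_formula <- function(spec) {
  fx <- c(spec$fixed, spec$interactions)
  rhs <- if (length(fx)) paste(fx, collapse = " + ") else "1"
  re <- paste(sprintf("(1 | %s)", spec$random), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs, "+", re))
}

#' Fit a Gaussian identity-link mixed model of firing rate
#'
#' Fits the model by maximum likelihood (\code{lme4::lmer}, \code{REML =
#' FALSE}) with a fixed intercept and crossed random intercepts.  Wald
#' p-values (coefficient over SE against the normal reference) are
#' reported for the fixed effects.
#'
#' @param design result of \code{\link{build_design}} (or a bare data
#'   frame, in which case \code{spec} must be given).
#' @param spec a \code{\link{glmm_spec}} when \code{design} is a data frame.
#' @param zero_variance evaluate the profiled mixed-model deviance with all
#'   random-effect variances forced to zero and return the corresponding
#'   fixed effects (which coincide with ordinary least squares); used for
#'   degenerate-boundary checks.
#' @return object of class \code{glmm_fit}: coefficient table, random-effect
#'   variance components, residual SD, convergence flag, the fitted
#'   \code{merMod} and the formula.
#' @export
fit_glmm <- function(design, spec = NULL, zero_variance = FALSE) {
  if (is.data.frame(design)) design <- list(frame = design, spec = spec)
  stopifnot(inherits(design$spec, "glmm_spec"))
  fml <- glmm_formula(design$spec)
  if (zero_variance) {
    devfun <- lme4::lmer(fml, data = design$frame, REML = FALSE,
                         devFunOnly = TRUE)
    nth <- length(environment(devfun)$pp$theta)
    devfun(rep(0, nth))
    pp <- environment(devfun)$pp
    beta <- pp$beta(1)
    names(beta) <- colnames(pp$X)
    coefs <- data.frame(term = names(beta), estimate = unname(beta),
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs, varcomp = NULL,
                          sigma = NA_real_, converged = TRUE,
                          formula = fml, model = NULL,
                          n = nrow(design$frame), zero_variance = TRUE),
                     class = "glmm_fit"))
  }
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = design$frame, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L &&
    !any(grepl("failed to converge", msgs))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zv <- fe / se
  coefs <- data.frame(term = names(fe), estimate = unname(fe),
                      se = unname(se), z = unname(zv),
                      p = 2 * pnorm(-abs(unname(zv))),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs, varcomp = vc,
                 sigma = stats::sigma(fit), converged = conv,
                 formula = fml, model = fit, n = nrow(design$frame)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Gaussian mixed model (identity link, ML):\n  ",
      paste(trimws(deparse(x$formula)), collapse = " "), "\n", sep = "")
  cat(sprintf("  n = %d, converged: %s\n", x$n, x$converged))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
summary.glmm_fit <- function(object, ...) {
  print(object)
  cat("Random-effect standard deviations:\n")
  print(object$varcomp[, c("grp", "sdcor")], digits = 4)
  invisible(object)
}

#' @export
coef.glmm_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Simulate firing-rate trials from the mixed-model generative process
#'
#' Draws trials with known fixed effects (power slope, pre-spike shift and
#' their interaction), crossed Gaussian random intercepts and residual
#' noise, for parameter-recovery studies.
#'
#' @param n_trials number of trials.
#' @param n_units,n_contacts,n_patients numbers of grouping levels (units
#'   are nested in contacts, contacts in patients, but identifiers are
#'   globally unique).
#' @param beta named vector: \code{intercept}, \code{log10_power},
#'   \code{prespike}, \code{interaction}.
#' @param re_sd named vector of random-intercept SDs (unit, contact,
#'   patient).
#' @param sigma residual SD.
#' @param p_prespike probability a trial is flagged pre-spike.
#' @param seed integer seed.
#' @return data frame with \code{hfodiff_fr}, \code{log10_power},
#'   \code{prespike}, grouping columns and the true linear predictor.
#' @export
simulate_glmm_trials <- function(n_trials = 5000, n_units = 50,
                                 n_contacts = 10, n_patients = 5,
                                 beta = c(intercept = 1, log10_power = 2,
                                          prespike = 0.5, interaction = 0.8),
                                 re_sd = c(unit = 0.5, contact = 0.3,
                                           patient = 0.3),
                                 sigma = 2, p_prespike = 0.3, seed = 1L) {
  set.seed(seed)
  unit <- sample.int(n_units, n_trials, replace = TRUE)
  contact_of_unit <- ((seq_len(n_units) - 1L) %% n_contacts) + 1L
  patient_of_contact <- ((seq_len(n_contacts) - 1L) %% n_patients) + 1L
  contact <- contact_of_unit[unit]
  patient <- patient_of_contact[contact]
  u_re <- rnorm(n_units, 0, re_sd["unit"])
  c_re <- rnorm(n_contacts, 0, re_sd["contact"])
  p_re <- rnorm(n_patients, 0, re_sd["patient"])
  lp10 <- rnorm(n_trials, 1.5, 0.4)
  pre <- rbinom(n_trials, 1, p_prespike)
  mu <- beta["intercept"] + beta["log10_power"] * lp10 +
    beta["prespike"] * pre + beta["interaction"] * lp10 * pre +
    u_re[unit] + c_re[contact] + p_re[patient]
  data.frame(hfodiff_fr = mu + rnorm(n_trials, 0, sigma),
             log10_power = lp10, prespike = pre,
             unit_id = sprintf("U%03d", unit),
             contact = sprintf("C%03d", contact),
             patient_id = sprintf("P%02d", patient),
             true_mu = mu, stringsAsFactors = FALSE)
}

#' Parameter-recovery report for the firing-rate mixed model
#'
#' For each configuration in a grid, simulates trials, fits the model and
#' summarises bias, RMSE and 95 percent Wald confidence-interval coverage
#' of each fixed effect over seeds.
#'
#' @param grid data frame of configurations with columns \code{n_trials}
#'   and optionally \code{slope} (true power slope) and
#'   \code{interaction}.
#' @param n_seeds seeds per configuration.
#' @param seed0 base seed.
#' @return data frame: one row per (configuration, term) with mean bias,
#'   RMSE and CI coverage.
#' @export
recovery_report <- function(grid = data.frame(n_trials = c(1000, 5000)),
                            n_seeds = 10, seed0 = 1L) {
  spec <- glmm_spec("hfodiff_fr", fixed = c("log10_power", "prespike"),
                    interactions = "log10_power:prespike")
  out <- list()
  for (g in seq_len(nrow(grid))) {
    slope <- if ("slope" %in% names(grid)) grid$slope[g] else 2
    inter <- if ("interaction" %in% names(grid)) grid$interaction[g] else 0.8
    beta <- c(intercept = 1, log10_power = slope, prespike = 0.5,
              interaction = inter)
    truth <- c("(Intercept)" = 1, log10_power = slope, prespike = 0.5,
               "log10_power:prespike" = inter)
    est <- cov <- list()
    for (s in seq_len(n_seeds)) {
      df <- simulate_glmm_trials(grid$n_trials[g], beta = beta,
                                 seed = seed0 + 1000L * g + s)
      fit <- fit_glmm(build_design(df, spec))
      co <- fit$coefficients
      est[[s]] <- setNames(co$estimate, co$term)
      cov[[s]] <- setNames(abs(co$estimate - truth[co$term]) <=
                             1.96 * co$se, co$term)
    }
    em <- do.call(rbind, est); cm <- do.call(rbind, cov)
    for (tm in colnames(em)) {
      out[[length(out) + 1L]] <- data.frame(
        config = g, n_trials = grid$n_trials[g], term = tm,
        true = unname(truth[tm]),
        bias = mean(em[, tm]) - truth[tm],
        rmse = sqrt(mean((em[, tm] - truth[tm])^2)),
        coverage = mean(cm[, tm]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
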