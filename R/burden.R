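# Mixed-effects models of clone mutation burdens. Clones from the same
# biopsy share UV exposure, and biopsies from the same patient are
# correlated, so models carry nested random intercepts for patient and
# biopsy-within-patient. Likelihood-ratio tests always compare ML fits;
# REML is used for final estimates.

#' Fit a linear mixed model of clone burdens
#'
#' Response ~ fixed terms + (1 | patient) + (1 | biopsy within patient).
#'
#' @param records Data frame with one row per clone: the response column,
#'   covariates, \code{patient_id} and \code{biopsy_id}.
#' @param response Name of the response column.
#' @param fixed_terms Character vector of fixed-effect terms (default
#'   \code{"age"}).
#' @param reml Use REML (final estimates); set FALSE (ML) for fits that
#'   will be compared by a likelihood-ratio test.
#' @return Object of class \code{lmm_fit}: \code{coefficients} (estimate,
#'   SE, Wald 95\% CI, z-based p), \code{ranef_sd} (patient,
#'   biopsy-in-patient, residual SDs), \code{loglik}, \code{mode},
#'   \code{singular} flag, and the underlying \code{lme4} fit in
#'   \code{$model}.
#' @export
fit_burden_lmm <- function(records, response, fixed_terms = "age",
                           reml = TRUE) {
  stopifnot(response %in% names(records))
  if (length(unique(records$patient_id)) < 2)
    stop("need at least two patients")
  fml <- stats::reformulate(c(fixed_terms,
                              "(1 | patient_id)",
                              "(1 | patient_id:biopsy_id)"),
                            response = response)
  fit <- lme4::lmer(fml, data = records, REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      ci_lo = unname(est - 1.96 * se),
                      ci_hi = unname(est + 1.96 * se),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 ranef_sd = stats::setNames(vc$sdcor, vc$grp),
                 loglik = as.numeric(stats::logLik(fit)),
                 df = attr(stats::logLik(fit), "df"),
                 mode = if (reml) "REML" else "ML",
                 singular = lme4::isSingular(fit),
                 formula = fml, model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit (%s)%s: %s\n", x$mode,
              if (x$singular) " [variance at boundary]" else "",
              deparse(x$formula)))
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat("random-effect SDs:\n")
  print(round(x$ranef_sd, 2))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param fit_full,fit_reduced \code{lmm_fit} objects (or any objects with
#'   \code{loglik} and \code{df}); both must be ML fits and the reduced
#'   model must be nested in the full one.
#' @return List: \code{statistic} (2 delta log-likelihood), \code{df},
#'   \code{p_value}.
#' @export
lrt_nested <- function(fit_full, fit_reduced) {
  if (inherits(fit_full, "lmm_fit") &&
      (fit_full$mode != "ML" || fit_reduced$mode != "ML"))
    stop("likelihood-ratio tests require ML fits")
  df <- fit_full$df - fit_reduced$df
  if (df < 0) stop("models are not nested (full model has fewer parameters)")
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' PUVA dose-response model of psoralen burden
#'
#' Regresses per-clone psoralen-attributed burden on the ordinal PUVA
#' band (treatment-dummy coding against the no-PUVA band) with nested
#' random effects, and reports per-band contrasts and the LRT against the
#' intercept-only model.
#'
#' @param records Data frame with \code{burden_psoralen},
#'   \code{puva_cycles_band}, \code{patient_id}, \code{biopsy_id}.
#' @param response Response column (default \code{"burden_psoralen"}).
#' @return List of class \code{puva_fit}: \code{fit} (REML
#'   \code{lmm_fit}), \code{contrasts} (band vs no-PUVA, in band order),
#'   \code{lrt} (ML LRT against intercept-only).
#' @export
puva_dose_model <- function(records, response = "burden_psoralen") {
  d <- records
  # dummy (treatment) coding against the "0" band; drop empty bands
  bands <- levels(factor(as.character(d$puva_cycles_band),
                         levels = c("0", "1-50", "51-200", ">200", "unknown")))
  present <- bands[bands %in% as.character(d$puva_cycles_band)]
  d$band <- factor(as.character(d$puva_cycles_band), levels = present)
  fit <- fit_burden_lmm(d, response, fixed_terms = "band", reml = TRUE)
  full_ml <- fit_burden_lmm(d, response, fixed_terms = "band", reml = FALSE)
  null_ml <- fit_burden_lmm(d, response, fixed_terms = "1", reml = FALSE)
  ct <- fit$coefficients[grepl("^band", fit$coefficients$term), , drop = FALSE]
  ct$band <- sub("^band", "", ct$term)
  ct <- ct[order(match(ct$band, present)), ]
  structure(list(fit = fit, contrasts = ct,
                 lrt = lrt_nested(full_ml, null_ml)),
            class = "puva_fit")
}

#' @export
print.puva_fit <- function(x, ...) {
  cat("PUVA band contrasts vs no-PUVA:\n")
  print(x$contrasts[, c("band", "estimate", "ci_lo", "ci_hi")],
        digits = 4, row.names = FALSE)
  cat(sprintf("LRT vs intercept-only: chi2 = %.2f, df = %d, p = %.3g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  invisible(x)
}

#' Median-VAF clonality versus age
#'
#' Regresses per-patient median microbiopsy VAF on age and tests, by LRT,
#' whether carrying the psoralen signature shifts clonality after
#' accounting for age.
#'
#' @param data Data frame with one row per patient: \code{median_vaf},
#'   \code{age}, and logical \code{psoralen_positive}.
#' @return List: \code{slope} (VAF per year), \code{fit} (lm),
#'   \code{psoralen_lrt} (statistic, df, p).
#' @export
clonality_vs_age <- function(data) {
  if (nrow(data) < 3) stop("need at least 3 patients")
  base <- stats::lm(median_vaf ~ age, data = data)
  out <- list(slope = unname(stats::coef(base)["age"]), fit = base,
              psoralen_lrt = NULL)
  if (!is.null(data$psoralen_positive) &&
      length(unique(data$psoralen_positive)) > 1) {
    full <- stats::lm(median_vaf ~ age + psoralen_positive, data = data)
    stat <- as.numeric(2 * (stats::logLik(full) - stats::logLik(base)))
    out$psoralen_lrt <- list(statistic = stat, df = 1,
                             p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
  }
  out
}

#' Basal stem cells founding a microbiopsy
#'
#' Assuming a basal stem-cell diameter of 9 um and vertical stratification,
#' the number of founding basal stem cells is the microbiopsy's projected
#' surface area divided by the footprint of one cell.
#'
#' @param area Surface area in um^2 (> 0).
#' @param cell_diameter Basal cell diameter in um (default 9).
#' @return Integer count(s), rounded to the nearest whole cell.
#' @export
estimate_basal_stem_cells <- function(area, cell_diameter = 9) {
  if (any(area <= 0)) stop("area must be positive")
  round(area / (pi * (cell_diameter / 2)^2))
}

#' Detection sensitivity of a clone's mutations
#'
#' Probability that a mutation at a given VAF is genotypable
#' (depth >= 4 and alt >= 3 in the calling sample) when depth is
#' Poisson-distributed. Observed clone burdens can be divided by this to
#' correct for VAF- and coverage-dependent detection.
#'
#' @param vaf Variant allele fraction(s).
#' @param mean_depth Mean sequencing depth.
#' @param min_alt,min_depth Genotyping thresholds.
#' @return Detection probability, vectorized over \code{vaf}.
#' @export
detection_probability <- function(vaf, mean_depth = 56, min_alt = 3,
                                  min_depth = 4) {
  dmax <- max(20, stats::qpois(1 - 1e-10, mean_depth))
  depths <- min_depth:dmax
  pd <- stats::dpois(depths, mean_depth)
  vapply(vaf, function(v) {
    sum(pd * stats::pbinom(min_alt - 1, depths, v, lower.tail = FALSE))
  }, numeric(1))
}

#' Sensitivity-corrected clone burden
#'
#' @param burden Observed mutation count(s).
#' @param vaf Characteristic VAF of the clone (e.g. its centroid in the
#'   best-covered microbiopsy).
#' @param mean_depth Mean depth.
#' @return Corrected burden \code{burden / detection_probability(...)}.
#' @export
correct_burden <- function(burden, vaf, mean_depth = 56) {
  burden / detection_probability(vaf, mean_depth)
}
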