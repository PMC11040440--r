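#' Effect estimates on the risk-difference scale
#'
#' Container for a mortality risk difference (MRD) expressed per 100
#' children, the field's standard additive effect scale. Wald confidence
#' intervals are `estimate +/- 1.96 * se`.
#'
#' @param estimate risk difference, per 100 children.
#' @param se standard error, per 100 children.
#' @param method one of `"crude"`, `"glm_adjusted"`, `"tmle"`, `"synergy"`.
#' @param adjustment_set character vector of adjustment covariates.
#' @param cohort_tag optional tag: `"hypothesis"`, `"validation"` or
#'   `"combined"`.
#' @param n number of children (unweighted) behind the estimate.
#' @param ci_low,ci_high optional explicit interval bounds; default Wald.
#' @return an object of class `effect_estimate`.
#' @export
effect_estimate <- function(estimate, se, method = "crude",
                            adjustment_set = character(), cohort_tag = NULL,
                            n = NA_integer_, ci_low = NULL, ci_high = NULL) {
  stopifnot(is.numeric(estimate), length(estimate) == 1L)
  if (!is.na(se) && se < 0) stop_("standard error must be non-negative")
  ci_low <- ci_low %||% (estimate - 1.96 * se)
  ci_high <- ci_high %||% (estimate + 1.96 * se)
  if (!is.na(ci_low) && !is.na(ci_high) &&
      !(ci_low <= estimate && estimate <= ci_high)) {
    stop_("confidence interval [%g, %g] does not bracket estimate %g",
          ci_low, ci_high, estimate)
  }
  structure(
    list(estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
         method = match.arg(method, c("crude", "glm_adjusted", "tmle",
                                      "synergy")),
         adjustment_set = adjustment_set, cohort_tag = cohort_tag, n = n),
    class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Risk difference (%s): %.*f per 100 (95%% CI %.*f to %.*f)\n",
              x$method, digits, x$estimate, digits, x$ci_low, digits,
              x$ci_high))
  if (length(x$adjustment_set)) {
    cat("  adjusted for:", paste(x$adjustment_set, collapse = ", "), "\n")
  }
  if (!is.null(x$cohort_tag)) cat("  cohort:", x$cohort_tag, "\n")
  invisible(x)
}

#' @export
coef.effect_estimate <- function(object, ...) {
  c(estimate = object$estimate)
}

#' Risk difference between two risks
#'
#' Subtracts two per-100 risks and combines their standard errors in
#' quadrature (`se = sqrt(se_in^2 + se_out^2)`), with a Wald interval.
#' Inputs may be bare numerics with `se_in`/`se_out`, or the risk objects
#' returned by [crude_risk()] / [km_risk()].
#'
#' @param risk_in,risk_out risks per 100 children (numeric, or objects
#'   with `$estimate` and `$se`).
#' @param se_in,se_out per-100 standard errors when risks are numeric.
#' @param method method tag for the resulting [effect_estimate()].
#' @param cohort_tag optional cohort tag.
#' @return an [effect_estimate()].
#' @examples
#' risk_difference(9.5, 5.0, se_in = 0.9, se_out = 0.2)
#' @export
risk_difference <- function(risk_in, risk_out, se_in = 0, se_out = 0,
                            method = "crude", cohort_tag = NULL) {
  if (is.list(risk_in)) { se_in <- risk_in$se; risk_in <- risk_in$estimate }
  if (is.list(risk_out)) { se_out <- risk_out$se; risk_out <- risk_out$estimate }
  if (risk_in < 0 || risk_in > 100 || risk_out < 0 || risk_out > 100) {
    stop_("risks must lie in [0, 100] per 100 children")
  }
  effect_estimate(estimate = risk_in - risk_out,
                  se = sqrt(se_in^2 + se_out^2),
                  method = method, cohort_tag = cohort_tag)
}

#' Population attributable fraction
#'
#' Fraction of all deaths that would be prevented if the exposure's causal
#' excess risk were removed:
#' `PAF = 100 * prevalence * aMRD / overall_risk` (in percent). The
#' conventional reporting precision is one decimal; the full-precision
#' value is returned so that the identity `PAF` linear in prevalence and
#' in the risk difference holds exactly.
#'
#' @param prevalence_exposed proportion of children exposed, in `[0, 1]`.
#' @param amrd adjusted mortality risk difference, per 100 children.
#' @param overall_risk overall mortality risk, per 100 children; must be
#'   positive.
#' @return PAF in percent (numeric scalar).
#' @examples
#' paf(418 / 27998, 3.4, (19311 * 5.2 + 8687 * 2.9) / 27998)
#' @export
paf <- function(prevalence_exposed, amrd, overall_risk) {
  if (overall_risk <= 0) stop_("overall risk must be positive")
  if (prevalence_exposed < 0 || prevalence_exposed > 1) {
    stop_("prevalence must be a proportion in [0, 1]")
  }
  100 * prevalence_exposed * amrd / overall_risk
}
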