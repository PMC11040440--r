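# Risk estimators on the weighted cohort: Kaplan-Meier cumulative risk,
# weighted crude risks inside/outside a subgroup, and the additive
# synergy statistic.

#' Kaplan-Meier cumulative mortality risk
#'
#' Cumulative risk `1 - S(horizon)` per 100 children, accounting for
#' right-censoring during follow-up, with a Greenwood-variance log-log
#' confidence interval.
#'
#' @param cohort table with `age_exit` (years) and `event` (1 = death)
#'   columns; censored children contribute until their emigration age.
#' @param horizon age horizon in years (at most 3).
#' @param weights optional per-child weights.
#' @return list with `estimate`, `ci_low`, `ci_high`, `se` (per 100).
#' @export
km_risk <- function(cohort, horizon = EXIT_AGE, weights = NULL) {
  stopifnot(horizon > ENTRY_AGE, horizon <= EXIT_AGE)
  w <- weights %||% rep(1, nrow(cohort))
  sf <- survival::survfit(survival::Surv(age_exit, event) ~ 1,
                          data = cohort, weights = w,
                          conf.type = "log-log")
  sm <- summary(sf, times = horizon, extend = FALSE)
  if (length(sm$surv) == 0 || sm$n.risk == 0) {
    stop_("no children remain at risk at horizon %.2f years", horizon)
  }
  s <- sm$surv
  list(estimate = 100 * (1 - s),
       ci_low = 100 * (1 - sm$upper),
       ci_high = 100 * (1 - sm$lower),
       se = 100 * sm$std.err)
}

#' Weighted crude mortality risks inside versus outside a subgroup
#'
#' IPCW-weighted mean of the death indicator per 100 children on each
#' side of a subgroup, with Wald intervals from the weighted
#' (frequency-type) variance.
#'
#' @param wc a `weighted_cohort`.
#' @param subgroup logical membership vector, a covariate name, or a
#'   [subgroup_to_rule()] rule.
#' @return list of class `crude_risks` with elements `inside` and
#'   `outside`, each holding `estimate`, `se`, `ci_low`, `ci_high`
#'   (per 100) and `n`.
#' @export
crude_risk <- function(wc, subgroup) {
  stopifnot(inherits(wc, "weighted_cohort"))
  m <- as_membership(subgroup, wc)
  if (!any(m) || all(m)) {
    stop_("very few children: subgroup must be nonempty on both sides")
  }
  one <- function(idx) {
    ms <- weighted_mean_se(wc$died[idx], wc$.weight[idx])
    list(estimate = 100 * ms$mean, se = 100 * ms$se,
         ci_low = 100 * ms$mean - 196 * ms$se,
         ci_high = 100 * ms$mean + 196 * ms$se, n = sum(idx))
  }
  structure(list(inside = one(m), outside = one(!m)),
            class = "crude_risks")
}

#' @export
print.crude_risks <- function(x, digits = 1, ...) {
  f <- function(r, lab) cat(sprintf(
    "  %s: %.*f (95%% CI %.*f to %.*f) per 100, n = %d\n", lab, digits,
    r$estimate, digits, r$ci_low, digits, r$ci_high, r$n))
  cat("Crude mortality risks:\n")
  f(x$inside, "within subgroup")
  f(x$outside, "rest")
  invisible(x)
}

#' Additive synergy statistic for a conjunction subgroup
#'
#' Estimates the risk in the subgroup beyond the sum of its components'
#' linear effects: a weighted linear-probability model of death on the
#' subgroup indicator, each component main effect and linear calendar
#' time (no other confounders). The subgroup coefficient, per 100
#' children, with a robust (sandwich) standard error, is returned.
#'
#' @param wc a `weighted_cohort`.
#' @param subgroup membership (logical vector, covariate name or rule)
#'   defined as the conjunction of `components`.
#' @param components character vector of the component covariate names.
#' @param calendar calendar-time covariate name (default `birth_year`).
#' @param cohort_tag optional tag for the estimate.
#' @return an [effect_estimate()] with method `"synergy"`.
#' @export
synergy_statistic <- function(wc, subgroup, components,
                              calendar = "birth_year", cohort_tag = NULL) {
  stopifnot(inherits(wc, "weighted_cohort"), length(components) >= 2)
  m <- as_membership(subgroup, wc)
  dat <- data.frame(.y = wc$died, .S = as.numeric(m))
  for (cc in components) {
    v <- wc[[cc]]
    if (is.null(v)) stop_("unknown component covariate '%s'", cc)
    dat[[cc]] <- if (is.numeric(v)) v else as.numeric(factor(v))
    if (isTRUE(all.equal(dat[[cc]], dat$.S))) {
      stop_("subgroup is collinear with component '%s'", cc)
    }
  }
  dat$.cal <- wc[[calendar]]
  est <- lpm_coef(dat, ".y", ".S", setdiff(names(dat), c(".y", ".S")),
                  wc$.weight)
  effect_estimate(estimate = est$coef, se = est$se, method = "synergy",
                  adjustment_set = c(components, calendar),
                  cohort_tag = cohort_tag, n = nrow(wc))
}

# weighted linear-probability model; returns the exposure coefficient and
# its HC0 sandwich SE, both on the per-100 scale
lpm_coef <- function(dat, y, a, covs, w) {
  rhs <- paste(c(a, covs), collapse = " + ")
  if (!length(c(a, covs))) rhs <- "1"
  fml <- stats::as.formula(paste(y, "~", rhs))
  env <- environment(fml)
  assign(".lpm_w", w, envir = env)
  fit <- lm(fml, data = dat, weights = .lpm_w)
  beta <- coef(fit)
  if (anyNA(beta)) {
    stop_("collinear design: coefficient(s) %s not estimable",
          paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  vc <- sandwich::vcovHC(fit, type = "HC0")
  k <- match(a, names(beta))
  list(coef = 100 * beta[[k]], se = 100 * sqrt(vc[k, k]), fit = fit)
}

# resolve a subgroup specification into a logical membership vector
as_membership <- function(subgroup, tab) {
  if (inherits(subgroup, "subgroup_rule")) return(rule_members(subgroup, tab))
  if (is.character(subgroup) && length(subgroup) == 1L) {
    v <- tab[[subgroup]]
    if (is.null(v)) stop_("unknown covariate '%s'", subgroup)
    return(v == 1 | v == TRUE)
  }
  if (is.logical(subgroup) || is_binary01(subgroup)) {
    stopifnot(length(subgroup) == nrow(tab))
    return(as.logical(subgroup))
  }
  stop_("cannot interpret subgroup specification")
}
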