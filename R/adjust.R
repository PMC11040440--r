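# Backdoor-adjusted single-factor risk differences. Covariates live in
# three causally ordered domains (environmental -> household ->
# individual/birth); the adjustment set for an exposure blocks the
# common causes in the higher-order domains, plus linear calendar time.

#' Covariate schema: domains and calendar time
#'
#' @param environmental,household,birth character vectors of covariate
#'   names per domain.
#' @param calendar calendar-time covariate (always adjusted for, except
#'   for unconfounded exposures).
#' @param unconfounded exposures that need no adjustment (randomized by
#'   nature, e.g. sex and birth season).
#' @return object of class `covariate_schema`.
#' @export
covariate_schema <- function(environmental, household, birth,
                             calendar = "birth_year",
                             unconfounded = c("boy", "rainy_season")) {
  all_cov <- c(environmental, household, birth)
  if (anyDuplicated(all_cov)) {
    stop_("each covariate must belong to exactly one domain")
  }
  structure(list(environmental = environmental, household = household,
                 birth = birth, calendar = calendar,
                 unconfounded = unconfounded),
            class = "covariate_schema")
}

#' Schema implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @param ... passed to [covariate_schema()].
#' @return a `covariate_schema`.
#' @export
schema_from_config <- function(config, ...) {
  nm <- function(d) vapply(Filter(function(cv) cv$domain == d,
                                  config$covariates), `[[`, "", "name")
  covariate_schema(environmental = nm("environmental"),
                   household = nm("household"), birth = nm("birth"), ...)
}

#' Backdoor adjustment set for a single exposure
#'
#' Environmental exposures are adjusted for calendar time only;
#' household exposures additionally for all environmental covariates;
#' individual/birth exposures additionally for the household covariates.
#' Exposures listed as unconfounded (sex, birth season) get the empty
#' set.
#'
#' @param exposure covariate name.
#' @param schema a [covariate_schema()].
#' @return character vector of adjustment covariate names.
#' @export
adjustment_set <- function(exposure, schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  if (exposure %in% schema$unconfounded) return(character())
  if (exposure %in% schema$environmental) return(schema$calendar)
  if (exposure %in% schema$household) {
    return(c(schema$calendar, schema$environmental))
  }
  if (exposure %in% schema$birth) {
    return(c(schema$calendar, schema$environmental,
             setdiff(schema$household, exposure)))
  }
  stop_("unknown covariate '%s'", exposure)
}

#' Adjusted risk difference from a weighted linear-probability model
#'
#' Weighted least-squares regression of the death indicator on the
#' exposure and the adjustment covariates; the exposure coefficient is
#' the adjusted risk difference per 100 children, with an HC0 sandwich
#' standard error and Wald interval. With an empty adjustment set and
#' unit weights this reproduces the crude risk difference exactly.
#'
#' @param wc a `weighted_cohort`.
#' @param exposure binary exposure: covariate name, logical vector or
#'   rule.
#' @param adjust character vector of adjustment covariate names (e.g.
#'   from [adjustment_set()]).
#' @param cohort_tag optional tag.
#' @return an [effect_estimate()] with method `"glm_adjusted"`.
#' @export
glm_risk_difference <- function(wc, exposure, adjust = character(),
                                cohort_tag = NULL) {
  stopifnot(inherits(wc, "weighted_cohort"))
  a <- as.numeric(as_membership(exposure, wc))
  dat <- data.frame(.y = wc$died, .A = a)
  for (v in adjust) {
    if (is.null(wc[[v]])) stop_("unknown adjustment covariate '%s'", v)
    dat[[v]] <- if (is.character(wc[[v]])) factor(wc[[v]]) else wc[[v]]
  }
  est <- lpm_coef(dat, ".y", ".A", adjust, wc$.weight)
  effect_estimate(estimate = est$coef, se = est$se,
                  method = "glm_adjusted", adjustment_set = adjust,
                  cohort_tag = cohort_tag, n = nrow(wc))
}

#' Similarity test between two independent cohort estimates
#'
#' Two-sample z-test of the hypothesis that the hypothesis-generating
#' and temporal-validation estimates share one underlying effect:
#' `z = (e1 - e2) / sqrt(se1^2 + se2^2)`, two-sided p-value.
#'
#' @param e1,e2 [effect_estimate()]s from *independent* cohorts.
#' @return two-sided p-value.
#' @export
similarity_test <- function(e1, e2) {
  stopifnot(inherits(e1, "effect_estimate"), inherits(e2, "effect_estimate"))
  if (!is.null(e1$cohort_tag) && !is.null(e2$cohort_tag) &&
      identical(e1$cohort_tag, e2$cohort_tag)) {
    stop_("estimates come from the same cohort; the test requires independent cohorts")
  }
  if (!(e1$se > 0) || !(e2$se > 0)) stop_("both standard errors must be positive")
  z <- (e1$estimate - e2$estimate) / sqrt(e1$se^2 + e2$se^2)
  2 * stats::pnorm(-abs(z))
}

#' Pooled (combined) estimate over both cohorts
#'
#' Concatenates the two weighted cohorts and runs one pooled TMLE with
#' calendar time forced into the adjustment set.
#'
#' @param wc1,wc2 disjoint `weighted_cohort`s (no shared `child_id`).
#' @param exposure subgroup membership applicable to both cohorts
#'   (covariate name or rule; or a list of two logical vectors).
#' @param adjust adjustment covariates; calendar time is added if absent.
#' @param calendar calendar covariate name.
#' @return an [effect_estimate()] with `cohort_tag = "combined"`.
#' @export
combined_estimate <- function(wc1, wc2, exposure, adjust = character(),
                              calendar = "birth_year") {
  stopifnot(inherits(wc1, "weighted_cohort"), inherits(wc2, "weighted_cohort"))
  if (length(intersect(wc1$child_id, wc2$child_id))) {
    stop_("cohorts overlap: shared child_id values")
  }
  if (is.list(exposure) && !inherits(exposure, "subgroup_rule")) {
    a <- c(as.logical(exposure[[1]]), as.logical(exposure[[2]]))
  } else {
    a <- c(as_membership(exposure, wc1), as_membership(exposure, wc2))
  }
  pooled <- rbind(as.data.frame(wc1), as.data.frame(wc2))
  pooled <- as_weighted_cohort(pooled, weights = pooled$.weight)
  adjust <- union(adjust, calendar)
  out <- tmle_risk_difference(pooled, a, adjust, cohort_tag = "combined")
  out
}
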