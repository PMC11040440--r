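#' Simulation configuration for synthetic HDSS cohorts
#'
#' Defines the data-generating process of a synthetic urban HDSS child
#' cohort: a linear calendar trend in baseline mortality risk, covariates
#' in three causally ordered domains (environmental -> household ->
#' individual/birth), one circular spatial hotspot, one two-factor
#' synergistic subgroup, and a logistic emigration (censoring) model.
#' The risk model is additive on the per-100 scale, so planted risk
#' differences are exactly the estimands of the downstream estimators.
#'
#' Defaults emulate the published structure of the Bissau cohort study
#' design: 21,005 children over birth years 2003--2016, overall
#' 6-week-to-3-year mortality declining from about 5 to about 3 per 100,
#' roughly a quarter of children emigrating before age 3 (informatively),
#' a high-risk residential hotspot, a no-prenatal-consultations style
#' single risk factor, and a twin-by-rainy-season style synergy.
#'
#' @param n_children number of children to simulate.
#' @param birth_year_range inclusive integer pair of birth years.
#' @param seed integer seed; the same seed yields a byte-identical cohort.
#' @param baseline_risk list with `intercept` (per-100 risk of the
#'   all-reference covariate pattern in the first birth year) and `slope`
#'   (per-100 change per birth year).
#' @param covariates list of covariate definitions, each a list with
#'   `name`, `domain` (`"environmental"`, `"household"` or `"birth"`),
#'   and either `prob` + `effect` (binary; `effect` in per-100 risk when
#'   present) or `levels` + `prob` + `effect` vectors (categorical;
#'   first level is the reference with effect 0). Binary covariates may
#'   carry `dep`, a named numeric of logit shifts on earlier binary
#'   covariates (household may depend on environmental, birth on both).
#' @param hotspot list: `center` (x, y meters), `radius` (m), `excess`
#'   (per-100 added risk inside), `density` (residential density
#'   multiplier inside the circle).
#' @param synergy list: `pair` (two binary covariate names) and `excess`
#'   (per-100 added risk when both are present).
#' @param censoring list: `intercept` and named `coef` on binary
#'   covariates, a logistic model of P(emigrated before age 3).
#'   `intercept = -Inf` disables censoring.
#' @param area bounding box, named numeric `c(xmin, xmax, ymin, ymax)` in
#'   projected meters.
#' @return an object of class `sim_config`.
#' @seealso [generate_cohort()], [true_subgroup_labels()]
#' @export
sim_config <- function(n_children = 21005,
                       birth_year_range = c(2003L, 2016L),
                       seed = 1L,
                       baseline_risk = list(intercept = 2.4, slope = -0.18),
                       covariates = default_covariates(),
                       hotspot = list(center = c(1400, 600), radius = 200,
                                      excess = 4, density = 2),
                       synergy = list(pair = c("twin", "rainy_season"),
                                      excess = 6.8),
                       censoring = list(intercept = -1.6,
                                        coef = c(maternal_schooling_lt7 = 0.4,
                                                 crowding = 0.3)),
                       area = c(xmin = 0, xmax = 2000, ymin = 0, ymax = 2000)) {
  if (n_children < 1) stop_("n_children must be >= 1")
  birth_year_range <- as.integer(birth_year_range)
  stopifnot(length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2])
  cov_names <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(cov_names)) stop_("duplicate covariate names")
  domains <- vapply(covariates, `[[`, "", "domain")
  if (!all(domains %in% c("environmental", "household", "birth"))) {
    stop_("covariate domains must be environmental, household or birth")
  }
  if (!is.null(synergy) && !all(synergy$pair %in% cov_names)) {
    stop_("synergy pair members must be configured covariates")
  }
  cfg <- structure(
    list(n_children = as.integer(n_children),
         birth_year_range = birth_year_range, seed = as.integer(seed),
         baseline_risk = baseline_risk, covariates = covariates,
         hotspot = hotspot, synergy = synergy, censoring = censoring,
         area = area),
    class = "sim_config")
  check_risk_bounds(cfg)
  cfg
}

#' Default covariate battery for the synthetic cohort
#'
#' Three-domain covariate set echoing the published baseline table:
#' environmental exposures of the residence, household social covariates,
#' and individual/birth covariates, each with a marginal prevalence and a
#' per-100 additive risk increment.
#'
#' @return list of covariate definitions for [sim_config()].
#' @export
default_covariates <- function() {
  list(
    # risk-increasing coding throughout (additive model stays in [0, 100])
    list(name = "far_from_road", domain = "environmental",
         prob = 0.94, effect = 0.8),
    list(name = "vegetation_top10", domain = "environmental",
         prob = 0.07, effect = 0),
    list(name = "high_density", domain = "environmental",
         prob = 0.09, effect = 0.5),
    list(name = "maternal_schooling_lt7", domain = "household",
         prob = 0.61, effect = 1.0, dep = c(high_density = 0.2)),
    list(name = "crowding", domain = "household",
         prob = 0.83, effect = 0.8, dep = c(high_density = 0.3)),
    list(name = "polygamous", domain = "household",
         prob = 0.18, effect = 0.8),
    list(name = "ethnicity", domain = "household",
         levels = c("balanta", "fula_mandinga", "manjaco_mancanha",
                    "pepel", "other"),
         prob = c(0.08, 0.28, 0.19, 0.16, 0.29),
         effect = c(0, 0.1, 0.3, 0.3, 0.4)),
    list(name = "twin", domain = "birth", prob = 0.03, effect = 4.3),
    list(name = "boy", domain = "birth", prob = 0.51, effect = 0),
    list(name = "rainy_season", domain = "birth", prob = 0.49, effect = 0),
    list(name = "no_prenatal_consultations", domain = "birth",
         prob = 0.04, effect = 4.0,
         dep = c(maternal_schooling_lt7 = 0.3))
  )
}

# The additive risk model must stay inside [0, 100] per 100 for every
# covariate pattern; silently clamping would corrupt the planted ground
# truth, so a violating configuration is rejected up front.
check_risk_bounds <- function(cfg) {
  yr <- cfg$birth_year_range
  trend <- cfg$baseline_risk$intercept +
    cfg$baseline_risk$slope * (c(0, diff(yr)))
  effs <- unlist(lapply(cfg$covariates, function(cv) cv$effect))
  lo <- min(trend) + sum(pmin(effs, 0))
  hi <- max(trend) + sum(pmax(effs, 0)) +
    max(0, cfg$hotspot$excess %||% 0) + max(0, cfg$synergy$excess %||% 0)
  if (lo < 0 || hi > 100) {
    stop_(paste0("configuration allows per-100 risks outside [0, 100] ",
                 "(extreme pattern range %.2f to %.2f): reduce effect ",
                 "sizes or the baseline trend"), lo, hi)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic HDSS cohort configuration: %d children, births %d-%d, seed %d\n",
              x$n_children, x$birth_year_range[1], x$birth_year_range[2],
              x$seed))
  cat(sprintf("  baseline risk %.2f per 100 at %d, slope %+.3f/year\n",
              x$baseline_risk$intercept, x$birth_year_range[1],
              x$baseline_risk$slope))
  syn <- if (is.null(x$synergy)) "none" else
    sprintf("%s +%.1f per 100", paste(x$synergy$pair, collapse = " & "),
            x$synergy$excess)
  cat(sprintf("  %d covariates; hotspot +%.1f per 100 (r=%.0f m); synergy %s\n",
              length(x$covariates), x$hotspot$excess, x$hotspot$radius, syn))
  invisible(x)
}
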