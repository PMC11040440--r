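# Shared builders for the test suite. All fixtures are generated in code.

# simplified four-covariate configuration: independent binaries, no
# covariate dependence links, optional planted effects
flat_config <- function(n = 20000, seed = 1, intercept = 5, slope = 0,
                        eff = c(twin = 0, rainy_season = 0,
                                polygamous = 0, maternal_schooling_lt7 = 0),
                        synergy_excess = NULL, hotspot_excess = 0,
                        hotspot_density = 1,
                        cens_intercept = -Inf, cens_coef = c(),
                        years = c(2003L, 2016L)) {
  covs <- list(
    list(name = "twin", domain = "birth", prob = 0.03,
         effect = unname(eff["twin"])),
    list(name = "rainy_season", domain = "birth", prob = 0.49,
         effect = unname(eff["rainy_season"])),
    list(name = "polygamous", domain = "household", prob = 0.18,
         effect = unname(eff["polygamous"])),
    list(name = "maternal_schooling_lt7", domain = "household",
         prob = 0.61, effect = unname(eff["maternal_schooling_lt7"]))
  )
  syn <- if (is.null(synergy_excess)) NULL else
    list(pair = c("twin", "rainy_season"), excess = synergy_excess)
  sim_config(
    n_children = n, birth_year_range = years, seed = seed,
    baseline_risk = list(intercept = intercept, slope = slope),
    covariates = covs,
    hotspot = list(center = c(1000, 1000), radius = 200,
                   excess = hotspot_excess, density = hotspot_density),
    synergy = syn,
    censoring = list(intercept = cens_intercept, coef = cens_coef),
    area = c(xmin = 0, xmax = 2000, ymin = 0, ymax = 2000))
}

# hand-built cohort table -> weighted cohort with chosen weights
make_wc <- function(df, weights = NULL) {
  if (is.null(df$censored)) df$censored <- 0L
  if (is.null(df$child_id)) df$child_id <- sprintf("t%05d", seq_len(nrow(df)))
  as_weighted_cohort(df, weights = weights)
}

# adjusted Rand index between two labelings
arand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- ch2(tab)
  sum_a <- ch2(rowSums(tab))
  sum_b <- ch2(colSums(tab))
  n <- length(a)
  expect <- sum_a * sum_b / ch2(rep(1, n) * 0 + n)
  expect <- sum_a * sum_b / (n * (n - 1) / 2)
  (sum_ij - expect) / ((sum_a + sum_b) / 2 - expect)
}

# reconstruct an SE from a printed 95% CI
se_from_ci <- function(lo, hi) (hi - lo) / 3.92

printed_estimate <- function(est, lo, hi, tag) {
  effect_estimate(estimate = est, se = se_from_ci(lo, hi),
                  method = "tmle", cohort_tag = tag,
                  ci_low = lo, ci_high = hi)
}
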