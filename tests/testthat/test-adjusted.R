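# Backdoor adjustment sets, GLM risk differences, the from-scratch TMLE,
# similarity tests and pooled estimates.

schema <- covariate_schema(
  environmental = c("far_from_road", "vegetation_top10", "high_density"),
  household = c("maternal_schooling_lt7", "crowding", "polygamous",
                "ethnicity"),
  birth = c("twin", "boy", "rainy_season", "no_prenatal_consultations"))

test_that("adjustment sets follow the domain hierarchy", {
  expect_equal(adjustment_set("maternal_schooling_lt7", schema),
               c("birth_year", "far_from_road", "vegetation_top10",
                 "high_density"))
  expect_equal(adjustment_set("vegetation_top10", schema), "birth_year")
  expect_equal(adjustment_set("boy", schema), character())
  expect_equal(adjustment_set("rainy_season", schema), character())
  expect_setequal(adjustment_set("twin", schema),
                  c("birth_year", schema$environmental, schema$household))
  expect_error(adjustment_set("not_a_covariate", schema), "unknown")
})

test_that("unadjusted GLM risk difference equals the crude difference exactly", {
  cfg <- flat_config(n = 5000, seed = 1, intercept = 5,
                     eff = c(twin = 6, rainy_season = 0, polygamous = 0,
                             maternal_schooling_lt7 = 0))
  wc <- as_weighted_cohort(generate_cohort(cfg))
  g <- glm_risk_difference(wc, "twin")
  cr <- crude_risk(wc, "twin")
  d <- risk_difference(cr$inside, cr$outside)
  expect_equal(g$estimate, d$estimate, tolerance = 1e-10)
  expect_equal(g$se, d$se, tolerance = 1e-10)
})

# one shared confounded design: Z raises both exposure and death risk
confounded_sim <- function(n, seed, rd = 4) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, plogis(-1.5 + 2.5 * z))
  y <- rbinom(n, 1, (2 + 4 * z + rd * a) / 100)
  make_wc(data.frame(died = y, expo = a, z = z, censored = 0L))
}

test_that("adjustment removes planted confounding that the crude estimate keeps", {
  wc <- confounded_sim(50000, seed = 2)
  adj <- glm_risk_difference(wc, "expo", adjust = "z")
  crude <- glm_risk_difference(wc, "expo")
  expect_lt(abs(adj$estimate - 4), 3 * adj$se)
  expect_gt(abs(crude$estimate - 4), 3 * crude$se)
})

test_that("an independent exposure has a null adjusted effect", {
  set.seed(3)
  n <- 20000
  wc <- make_wc(data.frame(died = rbinom(n, 1, 0.05),
                           expo = rbinom(n, 1, 0.3),
                           z = rbinom(n, 1, 0.5), censored = 0L))
  e <- glm_risk_difference(wc, "expo", adjust = "z")
  expect_lt(abs(e$estimate), 3 * e$se)
})

test_that("TMLE with an empty adjustment set reduces to the crude difference", {
  wc <- confounded_sim(5000, seed = 4)
  t0 <- tmle_risk_difference(wc, "expo")
  cr <- crude_risk(wc, "expo")
  expect_equal(t0$estimate, cr$inside$estimate - cr$outside$estimate,
               tolerance = 1e-8)
})

test_that("TMLE equals the unadjusted difference under randomized exposure", {
  set.seed(5)
  n <- 50000
  z <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, 0.5)                      # randomized
  y <- rbinom(n, 1, (3 + 3 * z + 4 * a) / 100)
  wc <- make_wc(data.frame(died = y, expo = a, z = z, censored = 0L))
  tm <- tmle_risk_difference(wc, "expo", adjust = "z")
  cr <- crude_risk(wc, "expo")
  expect_lt(abs(tm$estimate - (cr$inside$estimate - cr$outside$estimate)),
            0.1)
})

test_that("TMLE recovers a planted confounded risk difference and solves its score", {
  wc <- confounded_sim(50000, seed = 6)
  tm <- tmle_risk_difference(wc, "expo", adjust = "z")
  fit <- attr(tm, "fit")
  expect_lt(abs(tm$estimate - 4), 3 * tm$se)
  expect_lt(abs(fit$mean_ic), 1e-8)
  expect_true(all(fit$Q1 >= 0 & fit$Q1 <= 1))
  expect_true(all(fit$g >= 0.01 & fit$g <= 0.99))
})

test_that("TMLE refuses a one-sided subgroup", {
  wc <- confounded_sim(500, seed = 7)
  expect_error(tmle_risk_difference(wc, rep(TRUE, nrow(wc))), "one-sided")
})

test_that("similarity test reproduces printed two-cohort comparisons", {
  # area D: 4.0 (0.1, 8.0) vs 2.0 (-2.8, 6.7) -> p ~ .51
  p_d <- similarity_test(printed_estimate(4.0, 0.1, 8.0, "hypothesis"),
                         printed_estimate(2.0, -2.8, 6.7, "validation"))
  expect_lt(abs(p_d - 0.51), 0.03)
  # area B: 1.9 (-1.2, 5.0) vs -2.2 (-4.0, -0.4) -> p ~ .02
  p_b <- similarity_test(printed_estimate(1.9, -1.2, 5.0, "hypothesis"),
                         printed_estimate(-2.2, -4.0, -0.4, "validation"))
  expect_lt(abs(p_b - 0.02), 0.03)
})

test_that("similarity test is symmetric, shift-invariant, and guards cohorts", {
  e1 <- printed_estimate(3.1, 0.1, 6.1, "hypothesis")
  e2 <- printed_estimate(1.2, -1.0, 3.4, "validation")
  expect_equal(similarity_test(e1, e2), similarity_test(e2, e1))
  e1s <- printed_estimate(3.1 + 5, 0.1 + 5, 6.1 + 5, "hypothesis")
  e2s <- printed_estimate(1.2 + 5, -1.0 + 5, 3.4 + 5, "validation")
  expect_equal(similarity_test(e1, e2), similarity_test(e1s, e2s))
  expect_equal(similarity_test(e1, e1s <- printed_estimate(3.1, 0.1, 6.1,
                                                           "validation")),
               1)
  expect_error(similarity_test(e1, printed_estimate(1, 0, 2, "hypothesis")),
               "independent")
})

test_that("single-factor Wald screening has nominal false-positive rate", {
  hits <- 0
  for (s in 1:200) {
    set.seed(1000 + s)
    n <- 2000
    wc <- make_wc(data.frame(died = rbinom(n, 1, 0.05),
                             expo = rbinom(n, 1, 0.3), censored = 0L))
    e <- glm_risk_difference(wc, "expo")
    if (e$ci_low > 0 || e$ci_high < 0) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.02)
  expect_lt(hits / 200, 0.09)
})

test_that("pooling two copies of a cohort keeps the estimate and shrinks the SE", {
  wc <- confounded_sim(20000, seed = 8)
  wc$birth_year <- 2005L
  wc2 <- wc
  wc2$child_id <- paste0("v", wc2$child_id)
  wc2$birth_year <- 2013L
  single <- tmle_risk_difference(wc, "expo", adjust = "z",
                                 cohort_tag = "hypothesis")
  comb <- combined_estimate(wc, wc2, "expo", adjust = "z")
  expect_equal(comb$estimate, single$estimate, tolerance = 0.2)
  expect_equal(comb$se / single$se, 1 / sqrt(2), tolerance = 0.05)
  expect_identical(comb$cohort_tag, "combined")
  expect_error(combined_estimate(wc, wc, "expo"), "overlap")
})

test_that("a sign-reversing effect pools to the prevalence-weighted average", {
  set.seed(9)
  n <- 30000
  mk <- function(rd, year, pref) {
    a <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, (6 + rd * a) / 100)
    df <- data.frame(died = y, expo = a, censored = 0L,
                     birth_year = year,
                     child_id = paste0(pref, seq_len(n)))
    make_wc(df)
  }
  wc1 <- mk(4, 2005L, "h")
  wc2 <- mk(-4, 2013L, "v")
  comb <- combined_estimate(wc1, wc2, "expo")
  expect_lt(abs(comb$estimate - 0), 3 * comb$se)
})
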