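# The non-negative risk-decomposition network: encoding, training
# constraints, exact decomposition, clustering and rule extraction.

cool_wc <- function(n, seed, synergy = NULL, eff = c(twin = 0,
                                                     rainy_season = 0,
                                                     polygamous = 0,
                                                     maternal_schooling_lt7 = 0),
                    intercept = 5) {
  cfg <- flat_config(n = n, seed = seed, intercept = intercept, eff = eff,
                     synergy_excess = synergy)
  as_weighted_cohort(generate_cohort(cfg))
}

test_that("encoding is one-hot with reference levels dropped, and invertible", {
  wc <- as_weighted_cohort(generate_cohort(sim_config(n_children = 800,
                                                      seed = 1)))
  des <- encode_features(wc)
  expect_true(all(des$X %in% c(0, 1)))
  expect_equal(sum(grepl("^ethnicity=", colnames(des$X))), 4)  # 5 levels - ref
  expect_true("twin" %in% colnames(des$X))
  expect_true(any(grepl("^birth_year_band=", colnames(des$X))))
  dec <- decode_features(des)
  expect_equal(dec$twin, wc$twin)
  expect_equal(dec$ethnicity, wc$ethnicity)
})

test_that("constant features are dropped with a warning", {
  wc <- cool_wc(600, seed = 2)
  wc$always0 <- 0
  expect_warning(
    des <- encode_features(wc, features = c("twin", "always0"),
                           calendar_bands = FALSE),
    "constant")
  expect_equal(colnames(des$X), "twin")
})

test_that("a null outcome trains to baseline risk with no contributions", {
  wc <- cool_wc(20000, seed = 3)
  des <- encode_features(wc, calendar_bands = FALSE)
  fit <- train_cool(des, hidden = 5, epochs = 2000, restarts = 3, seed = 1)
  se <- sqrt(0.05 * 0.95 / nrow(wc))
  expect_lt(abs(fit$Rb - mean(wc$died)), 3 * se + 0.005)
  prof <- risk_contributions(fit, des)
  expect_lt(mean(rowSums(prof$C)), 0.005)
})

test_that("training is deterministic given data, hyperparameters and seed", {
  wc <- cool_wc(3000, seed = 4, synergy = 10)
  des <- encode_features(wc, calendar_bands = FALSE)
  f1 <- train_cool(des, hidden = 4, epochs = 500, restarts = 2, seed = 9)
  f2 <- train_cool(des, hidden = 4, epochs = 500, restarts = 2, seed = 9)
  expect_identical(f1$W1, f2$W1)
  expect_identical(f1$w2, f2$w2)
  expect_identical(f1$Rb, f2$Rb)
})

test_that("weights stay non-negative and the decomposition is complete", {
  wc <- cool_wc(20000, seed = 5, synergy = 10,
                eff = c(twin = 2, rainy_season = 0, polygamous = 3,
                        maternal_schooling_lt7 = 0))
  des <- encode_features(wc, calendar_bands = FALSE)
  fit <- train_cool(des, hidden = 6, epochs = 4000, restarts = 3, seed = 2)
  expect_true(all(fit$W1 >= 0))
  expect_true(all(fit$w2 >= 0))
  expect_true(all(fit$b <= 0))
  prof <- risk_contributions(fit, des)
  expect_true(all(prof$C >= 0))
  # exact completeness: baseline + contributions + clamp = prediction
  expect_lt(max(abs(prof$baseline + rowSums(prof$C) + prof$clamp - prof$p)),
            1e-10)
  # contributions only on active features
  expect_true(all(prof$C[des$X == 0] == 0))
})

test_that("a single causal feature receives its planted contribution", {
  devs <- vapply(1:10, function(s) {
    wc <- cool_wc(10000, seed = 100 + s,
                  eff = c(twin = 10, rainy_season = 0, polygamous = 0,
                          maternal_schooling_lt7 = 0))
    des <- encode_features(wc, calendar_bands = FALSE)
    fit <- train_cool(des, hidden = 5, epochs = 3000, restarts = 3, seed = s)
    prof <- risk_contributions(fit, des)
    mean(prof$C[wc$twin == 1, "twin"])
  }, 0)
  expect_lt(abs(mean(devs) - 0.10), 0.02)
})

test_that("degenerate contribution cases behave per the decomposition contract", {
  wc <- cool_wc(5000, seed = 6, synergy = 10)
  des <- encode_features(wc, calendar_bands = FALSE)
  fit <- train_cool(des, hidden = 4, epochs = 2000, restarts = 2, seed = 3)
  prof <- risk_contributions(fit, des)
  zero_rows <- rowSums(des$X) == 0
  if (any(zero_rows)) {
    expect_true(all(prof$C[zero_rows, ] == 0))
    expect_equal(unname(prof$p[zero_rows]),
                 rep(min(max(fit$Rb, 0), 1), sum(zero_rows)))
  }
  one_active <- which(rowSums(des$X) == 1)
  if (length(one_active)) {
    i <- one_active[1]
    f <- which(des$X[i, ] == 1)
    expect_equal(sum(prof$C[i, -f]), 0)
  }
})

test_that("clustering recovers planted disjoint risk groups", {
  hits <- vapply(1:10, function(s) {
    set.seed(200 + s)
    n <- 8000
    g <- sample(0:2, n, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    df <- data.frame(f1 = as.integer(g == 1), f2 = as.integer(g == 2),
                     censored = 0L)
    df$died <- rbinom(n, 1, 0.03 + 0.10 * df$f1 + 0.18 * df$f2)
    wc <- make_wc(df)
    des <- encode_features(wc, features = c("f1", "f2"), calendar_bands = FALSE)
    fit <- train_cool(des, hidden = 4, epochs = 3000, restarts = 3, seed = s)
    grp <- extract_subgroups(risk_contributions(fit, des), max_groups = 3)
    arand(grp$assignment, g)
  }, 0)
  expect_gte(sum(hits > 0.9), 9)
})

test_that("all-zero contributions collapse to a single group", {
  prof <- structure(list(C = matrix(0, 50, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                         baseline = 0.05, clamp = rep(0, 50),
                         p = rep(0.05, 50), y = rbinom(50, 1, 0.05),
                         w = rep(1, 50), child_id = as.character(1:50)),
                    class = "cool_profile")
  grp <- extract_subgroups(prof, max_groups = 4)
  expect_equal(length(unique(grp$assignment)), 1)
  expect_error(subgroup_to_rule(grp, 1,
                                structure(list(X = prof$C * 0,
                                               meta = list(),
                                               features = c("a", "b")),
                                          class = "cool_design")),
               "no defining features|no positive")
})

test_that("small groups are flagged as very-few-children", {
  set.seed(7)
  n <- 5000
  df <- data.frame(rare = as.integer(seq_len(n) <= 10), censored = 0L)
  df$died <- rbinom(n, 1, 0.04 + 0.5 * df$rare)
  wc <- make_wc(df)
  des <- encode_features(wc, features = "rare", calendar_bands = FALSE)
  fit <- train_cool(des, hidden = 3, epochs = 2000, restarts = 2, seed = 1)
  grp <- extract_subgroups(risk_contributions(fit, des), max_groups = 3,
                           min_prevalence = 0.005)
  rare_grp <- grp$assignment[df$rare == 1][1]
  row <- grp$summary[grp$summary$group == rare_grp, ]
  expect_true(row$flagged)
})

test_that("rule extraction honours threshold semantics and tie-breaking", {
  wc <- cool_wc(30000, seed = 8, synergy = 10)
  des <- encode_features(wc, calendar_bands = FALSE)
  fit <- train_cool(des, hidden = 6, epochs = 6000, restarts = 5, seed = 4)
  prof <- risk_contributions(fit, des)
  grp <- extract_subgroups(prof, max_groups = 6)
  both <- wc$twin == 1 & wc$rainy_season == 1
  g <- as.integer(names(which.max(table(grp$assignment[both]))))
  rule <- subgroup_to_rule(grp, g, des, threshold = 0.5)
  expect_setequal(rule$features, c("twin", "rainy_season"))
  # threshold 0: every active feature in the group
  rule0 <- subgroup_to_rule(grp, g, des, threshold = 0)
  active <- colnames(des$X)[colMeans(des$X[grp$assignment == g, ,
                                           drop = FALSE]) > 0]
  expect_true(all(rule$features %in% rule0$features))
  expect_true(all(rule0$features %in% active))
  # threshold 1: single feature, alphabetical tie-break
  rule1 <- subgroup_to_rule(grp, g, des, threshold = 1)
  expect_length(rule1$features, 1)
  # rule membership evaluates on the raw cohort
  expect_equal(rule_members(rule, wc), both)
})
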