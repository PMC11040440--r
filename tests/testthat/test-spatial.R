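# Sliding-window risk surface: oracle equivalence against a brute-force
# per-window loop, masking semantics, membership geometry and the ASCII
# grid round trip.

test_that("cumulative-sum scan equals the brute-force window loop", {
  wc <- toy_wc()
  bbox <- c(xmin = 0, xmax = 740, ymin = 0, ymax = 740)
  surf <- scan_surface(wc, bbox = bbox, min_count = 5, reference_year = 2006)
  ref <- brute_surface(wc, bbox, 250, 10, 5, 2006)
  expect_equal(dim(surf$risk), c(50, 50))
  expect_equal(surf$count, ref$count)
  expect_equal(surf$risk, ref$risk, tolerance = 1e-9)
})

test_that("windows below the child minimum are masked, at exactly the stated count", {
  wc <- toy_wc(n = 900, seed = 3)
  surf <- scan_surface(wc, bbox = c(xmin = 0, xmax = 740, ymin = 0,
                                    ymax = 740), min_count = 100)
  expect_true(any(surf$count < 100) && any(surf$count >= 100))
  expect_true(all(is.na(surf$risk[surf$count < 100])))
  expect_true(all(!is.na(surf$risk[surf$count >= 100])))
  # monotone masking: raising min_count never unmasks
  surf2 <- scan_surface(wc, bbox = c(xmin = 0, xmax = 740, ymin = 0,
                                     ymax = 740), min_count = 110)
  expect_true(all(is.na(surf2$risk[is.na(surf$risk)])))
})

test_that("a flat homogeneous field reproduces the global risk", {
  set.seed(8)
  n <- 40000
  df <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                   birth_year = sample(2003:2010, n, replace = TRUE),
                   censored = 0L, died = rbinom(n, 1, 0.05))
  wc <- make_wc(df)
  surf <- scan_surface(wc, bbox = c(xmin = 0, xmax = 1000, ymin = 0,
                                    ymax = 1000), min_count = 100)
  vals <- surf$risk[!is.na(surf$risk)]
  # every unmasked window mean within 3 SE of 5 per 100
  n_win <- surf$count[!is.na(surf$risk)]
  se <- 100 * sqrt(0.05 * 0.95 / n_win)
  expect_gt(mean(abs(vals - 5) < 3 * se), 0.99)
  expect_lt(abs(mean(vals) - 5), 0.3)
})

test_that("window membership matches the half-open geometry", {
  wc <- toy_wc(n = 500, seed = 4)
  bbox <- c(xmin = 0, xmax = 740, ymin = 0, ymax = 740)
  surf <- scan_surface(wc, bbox = bbox, min_count = 1)
  # interior point far from edges: full 25 x 25 overlap
  expect_equal(nrow(window_membership(400, 400, surf)), 625)
  # bbox corner: a single window
  expect_equal(nrow(window_membership(0, 0, surf)), 1)
  # outside: empty
  expect_equal(nrow(window_membership(-5, 100, surf)), 0)
  # oracle: brute-force containment over all nodes
  for (pt in list(c(123.4, 77), c(739, 739), c(250, 0))) {
    mine <- window_membership(pt[1], pt[2], surf)
    hits <- which(outer(
      seq_len(nrow(surf$risk)),
      seq_len(ncol(surf$risk)),
      function(i, j) {
        x0 <- surf$x0 + (i - 1) * surf$step
        y0 <- surf$y0 + (j - 1) * surf$step
        pt[1] >= x0 & pt[1] < x0 + surf$window &
          pt[2] >= y0 & pt[2] < y0 + surf$window
      }), arr.ind = TRUE)
    expect_equal(mine[order(mine[, 1], mine[, 2]), , drop = FALSE],
                 unname(as.matrix(hits[order(hits[, 1], hits[, 2]), ,
                                       drop = FALSE])),
                 ignore_attr = TRUE)
  }
})

test_that("degenerate scan inputs error", {
  wc <- toy_wc(n = 100)
  expect_error(scan_surface(wc, bbox = c(xmin = 0, xmax = 200, ymin = 0,
                                         ymax = 200)),
               "smaller than one window")
  expect_error(scan_surface(wc[0, ], min_count = 1), "empty")
})

test_that("area effect needs both sides and is null without a hotspot", {
  cfg <- flat_config(n = 30000, seed = 6, intercept = 5)
  wc <- as_weighted_cohort(generate_cohort(cfg))
  circ <- list(center = c(1000, 1000), radius = 250)
  e <- area_effect(wc, circ, method = "glm")
  expect_lt(abs(e$estimate), 3 * e$se)
  expect_error(area_effect(wc, list(center = c(1000, 1000), radius = 5000)),
               "both sides")
})

test_that("a planted hotspot excess is estimated by area_effect", {
  cfg <- flat_config(n = 50000, seed = 7, intercept = 5,
                     hotspot_excess = 4, hotspot_density = 2)
  wc <- as_weighted_cohort(generate_cohort(cfg))
  e <- area_effect(wc, list(center = c(1000, 1000), radius = 200),
                   method = "tmle")
  expect_lt(abs(e$estimate - 4), 3 * e$se)
})

test_that("ESRI ASCII export round-trips values, mask and geometry", {
  wc <- toy_wc(n = 2500, seed = 9)
  surf <- scan_surface(wc, bbox = c(xmin = 0, xmax = 740, ymin = 0,
                                    ymax = 740), min_count = 80)
  path <- file.path(tempdir(), "surf.asc")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_equal(back$risk, surf$risk, tolerance = 1e-12)
  expect_identical(is.na(back$risk), is.na(surf$risk))
  expect_equal(back$ncols, nrow(surf$risk))
  expect_equal(back$nrows, ncol(surf$risk))
  expect_equal(length(readLines(path)) - 6, ncol(surf$risk))

  # all-masked surface: file is entirely NODATA
  surf$risk[] <- NA_real_
  write_surface(surf, path)
  expect_true(all(is.na(read_surface(path)$risk)))

  expect_error(write_surface(surf, path, format = "tif"), "unknown format")
  unlink(path)
})
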