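# Spatial test fixtures and the brute-force oracle for the sliding
# window scan.

# brute-force reference: per-window weighted residual means, written
# exactly as the definition reads (no cumulative sums)
brute_surface <- function(wc, bbox, window, step, min_count, ref_year) {
  fit <- lm(wc$died ~ I(wc$birth_year - ref_year), weights = wc$.weight)
  mu0 <- unname(coef(fit)[1])
  res <- wc$died - fitted(fit)
  nx <- (bbox["xmax"] - bbox["xmin"]) / step - window / step + 1
  ny <- (bbox["ymax"] - bbox["ymin"]) / step - window / step + 1
  risk <- count <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) {
    x0 <- bbox["xmin"] + (i - 1) * step
    inx <- wc$x >= x0 & wc$x < x0 + window
    for (j in seq_len(ny)) {
      y0 <- bbox["ymin"] + (j - 1) * step
      m <- inx & wc$y >= y0 & wc$y < y0 + window
      count[i, j] <- sum(m)
      risk[i, j] <- if (sum(m) >= min_count) {
        100 * (mu0 + sum(wc$.weight[m] * res[m]) / sum(wc$.weight[m]))
      } else NA_real_
    }
  }
  list(risk = risk, count = count)
}

toy_wc <- function(n = 3000, seed = 1, side = 740) {
  set.seed(seed)
  df <- data.frame(
    x = runif(n, 0, side), y = runif(n, 0, side),
    birth_year = sample(2003:2010, n, replace = TRUE),
    censored = 0L)
  df$died <- rbinom(n, 1, 0.04 + 0.002 * (df$birth_year - 2003))
  make_wc(df, weights = runif(n, 1, 2))
}
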