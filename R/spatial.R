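# Sliding-window spatial risk mapping: a 250 m x 250 m window moved in
# 10 m steps over the study area, reporting the birth-year-trend adjusted
# mortality risk per window and masking windows with too few children.

#' Sliding-window spatial mortality-risk surface
#'
#' Fits one global weighted linear-probability trend of death on
#' centered birth year, then maps the trend-adjusted risk: each grid
#' node's value is the global adjusted risk at the reference year plus
#' the weighted mean residual of the children inside its half-open
#' `window x window` square `[x, x + window) x [y, y + window)`. Nodes
#' containing fewer than `min_count` children (unweighted) are masked.
#'
#' Implemented with 2-D cumulative sums over a `step`-sized cell grid,
#' which is exactly equivalent to the brute-force per-window loop.
#'
#' @param wc a `weighted_cohort` with `x`, `y` coordinates in projected
#'   meters.
#' @param bbox named numeric `c(xmin, xmax, ymin, ymax)`; default the
#'   coordinate range of the data.
#' @param window window side length in meters (default 250).
#' @param step grid resolution in meters (default 10); must divide
#'   `window`.
#' @param min_count minimum unweighted children per window (default 100).
#' @param reference_year anchor year of the trend adjustment; default the
#'   midpoint of the cohort's birth-year range.
#' @return object of class `risk_surface`: matrices `risk` (per 100,
#'   `NA` = masked), `count` and `wcount` indexed `[i, j]` over window
#'   origins `x0 + (i-1) step`, `y0 + (j-1) step`, plus the geometry.
#' @export
scan_surface <- function(wc, bbox = NULL, window = 250, step = 10,
                         min_count = 100, reference_year = NULL) {
  stopifnot(inherits(wc, "weighted_cohort"), min_count >= 1)
  if (nrow(wc) == 0) stop_("empty cohort")
  if (window %% step != 0) stop_("step must divide window")
  bbox <- bbox %||% c(xmin = min(wc$x), xmax = max(wc$x),
                      ymin = min(wc$y), ymax = max(wc$y))
  if (bbox["xmax"] - bbox["xmin"] < window ||
      bbox["ymax"] - bbox["ymin"] < window) {
    stop_("bounding box smaller than one window")
  }
  reference_year <- reference_year %||%
    floor(mean(range(wc$birth_year)))

  # global linear trend, weighted; residuals carry the spatial signal
  yr <- wc$birth_year - reference_year
  fit <- lm(wc$died ~ yr, weights = wc$.weight)
  mu0 <- unname(coef(fit)[1])          # adjusted global risk at reference year
  res <- wc$died - fitted(fit)

  k <- window %/% step
  ncx <- ceiling((bbox["xmax"] - bbox["xmin"]) / step)
  ncy <- ceiling((bbox["ymax"] - bbox["ymin"]) / step)
  if (ncx < k || ncy < k) stop_("bounding box smaller than one window")
  ci <- floor((wc$x - bbox["xmin"]) / step) + 1
  cj <- floor((wc$y - bbox["ymin"]) / step) + 1
  ok <- ci >= 1 & ci <= ncx & cj >= 1 & cj <= ncy
  cell <- (cj[ok] - 1) * ncx + ci[ok]
  acc <- function(v) {
    m <- matrix(0, ncx, ncy)
    s <- tapply(v, cell, sum)
    m[as.integer(names(s))] <- s
    m
  }
  cnt <- acc(rep(1, sum(ok)))
  wcnt <- acc(wc$.weight[ok])
  wres <- acc((wc$.weight * res)[ok])

  count <- window_sums(cnt, k)
  wcount <- window_sums(wcnt, k)
  wressum <- window_sums(wres, k)
  risk <- 100 * (mu0 + wressum / wcount)
  risk[count < min_count] <- NA_real_

  structure(list(risk = risk, count = count, wcount = wcount,
                 x0 = unname(bbox["xmin"]), y0 = unname(bbox["ymin"]),
                 step = step, window = window, min_count = min_count,
                 reference_year = reference_year, bbox = bbox,
                 global_risk = 100 * mu0),
            class = "risk_surface")
}

# sum of every k x k block of cells via 2-D cumulative sums
window_sums <- function(m, k) {
  S <- apply(apply(m, 2, cumsum), 1, cumsum)  # S[j, i] = cumsum both dims
  S <- t(S)
  pad <- matrix(0, nrow(S) + 1, ncol(S) + 1)
  pad[-1, -1] <- S
  nx <- nrow(m) - k + 1
  ny <- ncol(m) - k + 1
  pad[(1 + k):(nx + k), (1 + k):(ny + k)] -
    pad[1:nx, (1 + k):(ny + k)] -
    pad[(1 + k):(nx + k), 1:ny] +
    pad[1:nx, 1:ny]
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf("Risk surface: %d x %d nodes (window %g m, step %g m), %.1f%% masked (< %d children)\n",
              nrow(x$risk), ncol(x$risk), x$window, x$step,
              100 * mean(is.na(x$risk)), x$min_count))
  cat(sprintf("  trend-adjusted at reference year %d; global risk %.2f per 100\n",
              x$reference_year, x$global_risk))
  invisible(x)
}

#' @export
plot.risk_surface <- function(x, ...) {
  xs <- x$x0 + (seq_len(nrow(x$risk)) - 1) * x$step + x$window / 2
  ys <- x$y0 + (seq_len(ncol(x$risk)) - 1) * x$step + x$window / 2
  graphics::image(xs, ys, x$risk, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(25, "Reds", rev = TRUE), ...)
  invisible(x)
}

#' Window membership of a point
#'
#' All grid nodes whose half-open window contains the point; a point in
#' the grid interior belongs to up to `(window/step)^2` overlapping
#' windows.
#'
#' @param x,y point coordinates in meters.
#' @param surface a [scan_surface()] result.
#' @return two-column integer matrix of node indices `(i, j)`; zero rows
#'   if the point lies outside the bounding box.
#' @export
window_membership <- function(x, y, surface) {
  b <- surface$bbox
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (x < b["xmin"] || x > b["xmax"] || y < b["ymin"] || y > b["ymax"]) {
    return(empty)
  }
  rng <- function(u, u0, n) {
    hi <- floor((u - u0) / surface$step) + 1
    lo <- floor((u - u0 - surface$window) / surface$step) + 2
    seq(max(1, lo), min(n, hi))
  }
  is <- rng(x, surface$x0, nrow(surface$risk))
  js <- rng(y, surface$y0, ncol(surface$risk))
  if (!length(is) || !length(js)) return(empty)
  out <- as.matrix(expand.grid(i = is, j = js))
  # enforce half-open inclusion exactly
  keep <- x >= surface$x0 + (out[, 1] - 1) * surface$step &
    x < surface$x0 + (out[, 1] - 1) * surface$step + surface$window &
    y >= surface$y0 + (out[, 2] - 1) * surface$step &
    y < surface$y0 + (out[, 2] - 1) * surface$step + surface$window
  out[keep, , drop = FALSE]
}

#' Calendar-adjusted risk difference for a circular area
#'
#' Compares children living inside a circle to those outside it, with
#' adjustment for linear calendar time, via [glm_risk_difference()] or
#' [tmle_risk_difference()].
#'
#' @param wc a `weighted_cohort`.
#' @param circle list with `center` (x, y) and `radius` meters.
#' @param method `"glm"` or `"tmle"`.
#' @param calendar calendar covariate name.
#' @param cohort_tag optional tag.
#' @return an [effect_estimate()].
#' @export
area_effect <- function(wc, circle, method = c("glm", "tmle"),
                        calendar = "birth_year", cohort_tag = NULL) {
  method <- match.arg(method)
  m <- in_circle(wc$x, wc$y, circle)
  if (!any(m) || all(m)) stop_("circle must leave children on both sides")
  if (method == "glm") {
    glm_risk_difference(wc, m, adjust = calendar, cohort_tag = cohort_tag)
  } else {
    tmle_risk_difference(wc, m, adjust = calendar, cohort_tag = cohort_tag)
  }
}

#' Export / import a risk surface as an ESRI ASCII grid
#'
#' Writes the masked risk raster in the plain-text `.asc` format
#' (NODATA_value for masked nodes), at full double precision so a
#' write-read round trip is lossless. `cellsize` is the node spacing
#' (`step`); the grid registers window *origins*.
#'
#' @param surface a [scan_surface()] result.
#' @param path output path.
#' @param format only `"asc"` is supported.
#' @return `write_surface` returns `path` invisibly; `read_surface` a
#'   list with the `risk` matrix and grid geometry.
#' @export
write_surface <- function(surface, path, format = "asc") {
  if (!identical(format, "asc")) stop_("unknown format '%s'", format)
  r <- surface$risk
  nx <- nrow(r); ny <- ncol(r)
  hdr <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
           sprintf("xllcorner %.10g", surface$x0),
           sprintf("yllcorner %.10g", surface$y0),
           sprintf("cellsize %.10g", surface$step),
           "NODATA_value -9999")
  vals <- r
  vals[is.na(vals)] <- -9999
  # rows from north (max j) to south
  lines <- vapply(rev(seq_len(ny)), function(j)
    paste(formatC(vals[, j], format = "g", digits = 17), collapse = " "),
    "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1:6], " +")
  val <- function(i) as.numeric(hdr[[i]][2])
  nx <- as.integer(val(1)); ny <- as.integer(val(2))
  nodata <- val(6)
  body <- lapply(ln[-(1:6)], function(s) as.numeric(strsplit(trimws(s), " +")[[1]]))
  m <- do.call(rbind, body)           # ny rows (north to south) x nx cols
  risk <- t(m[rev(seq_len(ny)), , drop = FALSE])
  risk[risk == nodata] <- NA_real_
  list(risk = risk, x0 = val(3), y0 = val(4), step = val(5),
       ncols = nx, nrows = ny)
}

#' Local maxima of a risk surface
#'
#' Greedy peak extraction over unmasked nodes: repeatedly take the
#' highest-risk node and suppress all nodes within `separation` meters of
#' it. A non-inferential convenience for proposing candidate high-risk
#' circles.
#'
#' @param surface a [scan_surface()] result.
#' @param threshold minimum per-100 risk for a peak.
#' @param max_peaks maximum number of peaks.
#' @param separation minimum center-to-center distance between peaks (m).
#' @return data.frame with window-center coordinates `x`, `y` and `risk`.
#' @export
surface_peaks <- function(surface, threshold, max_peaks = 4,
                          separation = 500) {
  r <- surface$risk
  idx <- which(!is.na(r) & r >= threshold, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(x = numeric(), y = numeric(), risk = numeric()))
  }
  cx <- surface$x0 + (idx[, 1] - 1) * surface$step + surface$window / 2
  cy <- surface$y0 + (idx[, 2] - 1) * surface$step + surface$window / 2
  v <- r[idx]
  ord <- order(-v)
  cx <- cx[ord]; cy <- cy[ord]; v <- v[ord]
  keep <- integer()
  for (i in seq_along(v)) {
    if (length(keep) >= max_peaks) break
    if (all((cx[i] - cx[keep])^2 + (cy[i] - cy[keep])^2 >= separation^2)) {
      keep <- c(keep, i)
    }
  }
  data.frame(x = cx[keep], y = cy[keep], risk = v[keep])
}
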