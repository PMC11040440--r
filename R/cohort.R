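# Synthetic cohort generation: the ground-truth data-generating process
# that every downstream estimator is tested against.

ENTRY_AGE <- 6 / 52   # follow-up entry, years (6 weeks)
EXIT_AGE <- 3         # end of follow-up, years

#' Generate a synthetic HDSS child cohort
#'
#' Draws one cohort from the data-generating process in a [sim_config()]:
#' residential coordinates (uniform over the study area, denser inside
#' the hotspot), covariates in causal domain order with configured
#' logistic dependence links, death by age 3 from the additive per-100
#' risk model (linear calendar trend + covariate increments + hotspot
#' excess + synergy excess), and emigration before age 3 from the
#' logistic censoring model. Follow-up runs from 6 weeks to 3 years of
#' age; the death indicator is undefined (`NA`) for emigrated children.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `hdss_cohort`, one row per child, with
#'   columns `child_id`, `birth_year`, `x`, `y`, the configured
#'   covariates, `censored`, `died`, `age_exit` (age in years at death,
#'   emigration, or 3), and `event` (1 = observed death). Attributes
#'   `config` and `fingerprint` tie the cohort to its configuration.
#' @examples
#' coh <- generate_cohort(sim_config(n_children = 500))
#' mean(coh$died[coh$censored == 0])
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_children
  yr <- config$birth_year_range

  birth_year <- sample(seq(yr[1], yr[2]), n, replace = TRUE)

  xy <- draw_coordinates(n, config)
  covs <- draw_covariates(n, config$covariates)

  risk <- config$baseline_risk$intercept +
    config$baseline_risk$slope * (birth_year - yr[1])
  for (cv in config$covariates) {
    v <- covs[[cv$name]]
    if (is.null(cv$levels)) {
      risk <- risk + cv$effect * v
    } else {
      risk <- risk + cv$effect[match(v, cv$levels)]
    }
  }
  in_hotspot <- in_circle(xy$x, xy$y, config$hotspot)
  risk <- risk + (config$hotspot$excess %||% 0) * in_hotspot
  if (!is.null(config$synergy)) {
    both <- covs[[config$synergy$pair[1]]] == 1 &
      covs[[config$synergy$pair[2]]] == 1
    risk <- risk + config$synergy$excess * both
  }
  bad <- which(risk < 0 | risk > 100)
  if (length(bad)) {
    i <- bad[1]
    patt <- paste(vapply(config$covariates, function(cv)
      sprintf("%s=%s", cv$name, covs[[cv$name]][i]), ""), collapse = ", ")
    stop_("covariate pattern {%s} in year %d yields per-100 risk %.2f outside [0, 100]",
          patt, birth_year[i], risk[i])
  }
  died <- rbinom(n, 1, risk / 100)

  cens_lin <- rep(config$censoring$intercept, n)
  for (nm in names(config$censoring$coef)) {
    if (is.null(covs[[nm]])) stop_("censoring model names unknown covariate '%s'", nm)
    cens_lin <- cens_lin + config$censoring$coef[[nm]] * covs[[nm]]
  }
  p_cens <- ifelse(is.infinite(cens_lin) & cens_lin < 0, 0, plogis(cens_lin))
  censored <- rbinom(n, 1, p_cens)

  # observation ages: emigration or death times uniform over follow-up
  age_exit <- rep(EXIT_AGE, n)
  u <- runif(n, ENTRY_AGE, EXIT_AGE)
  age_exit[censored == 1] <- u[censored == 1]
  obs_death <- censored == 0 & died == 1
  age_exit[obs_death] <- u[obs_death]
  died[censored == 1] <- NA_integer_

  out <- data.frame(child_id = sprintf("c%06d", seq_len(n)),
                    birth_year = birth_year, x = xy$x, y = xy$y,
                    covs, censored = censored, died = died,
                    age_exit = age_exit,
                    event = as.integer(obs_death),
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "fingerprint") <- fingerprint(unclass(config))
  class(out) <- c("hdss_cohort", "data.frame")
  out
}

draw_coordinates <- function(n, config) {
  a <- config$area
  hs <- config$hotspot
  area_tot <- (a["xmax"] - a["xmin"]) * (a["ymax"] - a["ymin"])
  frac_hs <- pi * hs$radius^2 / area_tot
  d <- hs$density %||% 1
  p_in <- d * frac_hs / (d * frac_hs + (1 - frac_hs))
  inside <- runif(n) < p_in
  x <- runif(n, a["xmin"], a["xmax"])
  y <- runif(n, a["ymin"], a["ymax"])
  # resample inside-children uniformly within the hotspot circle
  k <- sum(inside)
  if (k) {
    r <- hs$radius * sqrt(runif(k))
    th <- runif(k, 0, 2 * pi)
    x[inside] <- hs$center[1] + r * cos(th)
    y[inside] <- hs$center[2] + r * sin(th)
  }
  # outside-children that landed in the circle: rejection resample
  while (any(bad <- !inside & in_circle(x, y, hs))) {
    x[bad] <- runif(sum(bad), a["xmin"], a["xmax"])
    y[bad] <- runif(sum(bad), a["ymin"], a["ymax"])
  }
  list(x = unname(x), y = unname(y))
}

draw_covariates <- function(n, covariates) {
  out <- list()
  for (cv in covariates) {
    if (!is.null(cv$levels)) {
      out[[cv$name]] <- sample(cv$levels, n, replace = TRUE, prob = cv$prob)
    } else {
      lin <- rep(qlogis(cv$prob), n)
      for (nm in names(cv$dep %||% c())) {
        if (is.null(out[[nm]])) {
          stop_("covariate '%s' depends on '%s', which is not generated earlier",
                cv$name, nm)
        }
        lin <- lin + cv$dep[[nm]] * out[[nm]]
      }
      out[[cv$name]] <- rbinom(n, 1, plogis(lin))
    }
  }
  out
}

in_circle <- function(x, y, circle) {
  (x - circle$center[1])^2 + (y - circle$center[2])^2 <= circle$radius^2
}

#' Ground-truth subgroup membership for a generated cohort
#'
#' Returns, per child, the planted hotspot and synergy-pair membership
#' indicators used by recovery tests. The cohort must carry the
#' fingerprint of exactly this configuration.
#'
#' @param config the [sim_config()] that generated `cohort`.
#' @param cohort a cohort from [generate_cohort()].
#' @return `data.frame` with `child_id`, `hotspot` and `synergy` logicals.
#' @export
true_subgroup_labels <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(attr(cohort, "fingerprint"), fingerprint(unclass(config)))) {
    stop_("cohort fingerprint does not match this configuration")
  }
  syn <- if (is.null(config$synergy)) rep(FALSE, nrow(cohort)) else
    cohort[[config$synergy$pair[1]]] == 1 & cohort[[config$synergy$pair[2]]] == 1
  data.frame(child_id = cohort$child_id,
             hotspot = in_circle(cohort$x, cohort$y, config$hotspot),
             synergy = syn, stringsAsFactors = FALSE)
}

#' Write / read a cohort as CSV with a JSON sidecar
#'
#' The sidecar records the configuration fingerprint and seed so that
#' downstream stages can verify provenance.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   cohort with its fingerprint attribute restored.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  cfg <- attr(cohort, "config")
  jsonlite::write_json(
    list(fingerprint = attr(cohort, "fingerprint"),
         seed = cfg$seed %||% NA, n_children = nrow(cohort)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(out, "fingerprint") <- meta$fingerprint
  }
  class(out) <- c("hdss_cohort", "data.frame")
  out
}

#' @export
print.hdss_cohort <- function(x, ...) {
  cat(sprintf("HDSS cohort: %d children, births %d-%d; %d emigrated (censored), %d observed deaths\n",
              nrow(x), min(x$birth_year), max(x$birth_year),
              sum(x$censored), sum(x$event)))
  invisible(x)
}

# baseline covariate columns (everything that is known by 6 weeks of age)
baseline_covariates <- function(cohort) {
  setdiff(names(cohort),
          c("child_id", "x", "y", "censored", "died", "age_exit", "event",
            ".weight"))
}
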