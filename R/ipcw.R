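# Inverse probability of censoring weighting (IPCW). Emigration before
# age 3 is treated as a single binary censoring event; uncensored
# children are reweighted by 1 / P(remaining under observation) so that
# the weighted sample recovers the pre-emigration target population.

#' Fit the censoring (emigration) model
#'
#' Logistic regression of the emigration indicator on baseline
#' covariates. With no censored children the trivial model P(censored)=0
#' is returned.
#'
#' @param cohort a cohort table containing a 0/1 `censored` column.
#' @param covariates covariate names; default all baseline covariates
#'   (including `birth_year`).
#' @return object of class `censoring_model`.
#' @export
fit_censoring_model <- function(cohort, covariates = NULL) {
  covariates <- covariates %||% baseline_covariates(cohort)
  stopifnot(all(covariates %in% names(cohort)))
  if (sum(cohort$censored) == 0) {
    return(structure(list(trivial = TRUE, covariates = covariates),
                     class = "censoring_model"))
  }
  if (all(cohort$censored == 1)) stop_("cohort has no uncensored children")
  dat <- cohort[, c("censored", covariates), drop = FALSE]
  fit <- suppressWarnings(
    glm(censored ~ ., data = dat, family = binomial()))
  beta <- coef(fit)[-1]
  sep <- !is.na(beta) & abs(beta) > 15
  if (any(sep)) {
    stop_("perfect separation in censoring model for covariate(s): %s",
          paste(names(beta)[sep], collapse = ", "))
  }
  structure(list(trivial = FALSE, fit = fit, covariates = covariates),
            class = "censoring_model")
}

#' @export
print.censoring_model <- function(x, ...) {
  if (x$trivial) {
    cat("Censoring model: no censored children, P(censored) = 0\n")
  } else {
    cat("Censoring model (logistic), covariates:",
        paste(x$covariates, collapse = ", "), "\n")
    cat(sprintf("  mean fitted P(censored) = %.3f\n",
                mean(fitted(x$fit))))
  }
  invisible(x)
}

#' @export
predict.censoring_model <- function(object, newdata, ...) {
  if (object$trivial) return(rep(0, nrow(newdata)))
  as.vector(predict(object$fit, newdata = newdata, type = "response"))
}

#' Construct IPCW weights and the weighted cohort
#'
#' Drops censored children and weights each remaining child by
#' `1 / P(uncensored | covariates)`, truncated at `truncate_at`.
#' Weights are unstabilized, so every weight is at least 1 and the
#' weighted sample size exceeds the raw one.
#'
#' @param model a [fit_censoring_model()] fit.
#' @param cohort the cohort the model was fitted on (same schema).
#' @param truncate_at upper truncation for the weights (default 10).
#' @return a `weighted_cohort`: the uncensored rows with a `.weight`
#'   column and diagnostics (`max_weight`, `mean_weight`, `n_truncated`,
#'   `weighted_n`) in attribute `diagnostics`.
#' @export
compute_ipcw <- function(model, cohort, truncate_at = 10) {
  stopifnot(inherits(model, "censoring_model"), truncate_at > 0)
  p_unc <- 1 - predict(model, cohort)
  keep <- cohort$censored == 0
  if (any(p_unc[keep] <= 0)) {
    stop_("fitted P(uncensored) = 0 for %d uncensored children",
          sum(p_unc[keep] <= 0))
  }
  w_raw <- 1 / p_unc[keep]
  w <- pmin(w_raw, truncate_at)
  out <- cohort[keep, , drop = FALSE]
  out$.weight <- w
  attr(out, "diagnostics") <- list(
    max_weight = max(w), mean_weight = mean(w),
    n_truncated = sum(w_raw > truncate_at), truncate_at = truncate_at,
    weighted_n = sum(w))
  attr(out, "fingerprint") <- attr(cohort, "fingerprint")
  class(out) <- c("weighted_cohort", "data.frame")
  out
}

#' @export
print.weighted_cohort <- function(x, ...) {
  d <- attr(x, "diagnostics") %||%
    list(weighted_n = sum(x$.weight), mean_weight = mean(x$.weight),
         max_weight = max(x$.weight), n_truncated = NA_integer_)
  cat(sprintf("IPCW-weighted cohort: %d children, weighted n = %.0f (mean w %.2f, max %.2f, %d truncated)\n",
              nrow(x), d$weighted_n, d$mean_weight, d$max_weight,
              d$n_truncated))
  invisible(x)
}

#' Write the per-child weights and a diagnostics report
#'
#' @param wc a [compute_ipcw()] result.
#' @param path CSV path for `(child_id, weight)`; diagnostics JSON is
#'   written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_weights <- function(wc, path) {
  utils::write.csv(data.frame(child_id = wc$child_id, weight = wc$.weight),
                   path, row.names = FALSE)
  jsonlite::write_json(attr(wc, "diagnostics"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Treat a cohort as weighted
#'
#' Drops censored children and attaches the supplied weights (default all
#' 1). Convenience for analyses without informative emigration.
#'
#' @param cohort a cohort table with a `censored` column.
#' @param weights optional per-child weights for the uncensored rows.
#' @return a `weighted_cohort`.
#' @export
as_weighted_cohort <- function(cohort, weights = NULL) {
  out <- cohort[cohort$censored == 0, , drop = FALSE]
  out$.weight <- weights %||% rep(1, nrow(out))
  attr(out, "diagnostics") <- list(max_weight = max(out$.weight),
                                   mean_weight = mean(out$.weight),
                                   n_truncated = 0L,
                                   weighted_n = sum(out$.weight))
  attr(out, "fingerprint") <- attr(cohort, "fingerprint")
  class(out) <- c("weighted_cohort", "data.frame")
  out
}
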