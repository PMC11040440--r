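# Non-negative shallow-network risk decomposition ("causes of outcome
# learning"). A one-hidden-layer network with non-negative weights, a
# baseline-risk intercept and relu hidden units models each child's risk
# as baseline plus a sum of non-negative excess-risk terms; the excess
# risk is then attributed to the active features, and children are
# clustered on their per-feature risk-contribution profiles to propose
# candidate multifactorial subgroups.

#' Encode cohort features as a binary design matrix
#'
#' One-hot encodes the selected baseline covariates (reference level
#' dropped for categoricals) and encodes calendar time as birth-year
#' bands so the network can absorb period effects without attributing
#' them to covariates. The reference band is the most recent one (lowest
#' risk under a declining trend), keeping band contributions
#' non-negative in direction.
#'
#' @param wc a `weighted_cohort` (uncensored children with weights).
#' @param features covariate names; default all baseline covariates
#'   except the calendar variable (which is never encoded as an ordinary
#'   feature).
#' @param calendar calendar covariate name.
#' @param band_width width of the birth-year bands, in years.
#' @param calendar_bands whether to add the period-band features.
#' @return object of class `cool_design`: binary matrix `X`, outcome
#'   `y`, weights `w`, and a `meta` map from design columns back to
#'   source columns/levels.
#' @export
encode_features <- function(wc, features = NULL, calendar = "birth_year",
                            band_width = 3, calendar_bands = TRUE) {
  stopifnot(inherits(wc, "weighted_cohort"))
  features <- setdiff(features %||% baseline_covariates(wc), calendar)
  cols <- list(); meta <- list()
  for (f in features) {
    v <- wc[[f]]
    if (is.null(v)) stop_("unknown feature '%s'", f)
    if (is_binary01(v)) {
      if (length(unique(v)) < 2) {
        warning(sprintf("dropping constant feature '%s'", f), call. = FALSE)
        next
      }
      cols[[f]] <- as.numeric(v)
      meta[[f]] <- list(source = f, level = NULL)
    } else {
      lv <- sort(unique(as.character(v)))
      if (length(lv) < 2) {
        warning(sprintf("dropping constant feature '%s'", f), call. = FALSE)
        next
      }
      for (l in lv[-1]) {          # first level = reference
        nm <- paste0(f, "=", l)
        cols[[nm]] <- as.numeric(v == l)
        meta[[nm]] <- list(source = f, level = l, reference = lv[1])
      }
    }
  }
  if (calendar_bands && !is.null(wc[[calendar]])) {
    yr <- wc[[calendar]]
    brk <- seq(min(yr), max(yr) + band_width, by = band_width)
    band <- cut(yr, breaks = brk, right = FALSE, include.lowest = TRUE)
    lv <- levels(band)
    for (l in lv[-length(lv)]) {   # most recent band = reference
      nm <- paste0(calendar, "_band=", l)
      cols[[nm]] <- as.numeric(band == l)
      meta[[nm]] <- list(source = calendar, level = l,
                         reference = lv[length(lv)], calendar = TRUE)
    }
  }
  X <- do.call(cbind, cols)
  structure(list(X = X, y = wc$died, w = wc$.weight,
                 features = colnames(X), meta = meta,
                 child_id = wc$child_id),
            class = "cool_design")
}

#' Decode design rows back to covariate values
#'
#' Inverse of [encode_features()] for the non-calendar features; used to
#' audit that the encoding is lossless.
#'
#' @param design a `cool_design`.
#' @return data.frame of the reconstructed covariate values.
#' @export
decode_features <- function(design) {
  out <- list()
  for (nm in names(design$meta)) {
    m <- design$meta[[nm]]
    if (isTRUE(m$calendar)) next
    if (is.null(m$level)) {
      out[[m$source]] <- design$X[, nm]
    } else {
      if (is.null(out[[m$source]])) {
        out[[m$source]] <- rep(m$reference, nrow(design$X))
      }
      out[[m$source]][design$X[, nm] == 1] <- m$level
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Train the non-negative risk-decomposition network
#'
#' Minimizes the weighted squared error of
#' `p_i = R_b + sum_h w2_h relu(W1[, h] . x_i + b_h)` by full-batch
#' projected gradient descent: after each step negative entries of `W1`
#' and `w2` are set to 0, hidden biases are capped at 0 and the baseline
#' risk `R_b` is clamped to `[0, 1]`. Training operates on the collapsed
#' unique binary patterns (exactly equivalent gradients, much faster).
#' The best of `restarts` seeded initializations by final loss is
#' returned; results are bit-reproducible given (data, hyperparameters,
#' seed).
#'
#' A small L2 penalty (`decay`) on `W1` and `w2` breaks the flat ridge
#' between the baseline intercept and always-active hidden units: without
#' it, part of the baseline risk can drift into feature contributions on
#' outcome-independent data. The default is small enough not to bias
#' planted effects visibly.
#'
#' @param design a [encode_features()] design.
#' @param hidden number of hidden ("synergy") units, default 10.
#' @param lr learning rate.
#' @param epochs gradient steps per restart.
#' @param restarts number of random initializations.
#' @param decay L2 penalty coefficient on `W1` and `w2`.
#' @param seed integer seed governing all initializations.
#' @return object of class `cool_fit`: `W1` (features x hidden, >= 0),
#'   `b` (<= 0), `w2` (>= 0), `Rb`, the training `loss` (weighted MSE),
#'   a `trace` of losses, and the hyperparameters.
#' @export
train_cool <- function(design, hidden = 10, lr = 1, epochs = 10000,
                       restarts = 10, decay = 1e-6, seed = 1) {
  stopifnot(inherits(design, "cool_design"))
  n <- nrow(design$X)
  if (n < 10 * hidden) stop_("need at least 10 children per hidden unit")
  if (length(unique(design$y)) < 2) {
    stop_("outcome must include both classes")
  }
  cp <- collapse_patterns(design)
  const <- sum(cp$wg * cp$ybar2) / cp$W   # sum w y^2 / W, loss offset
  best <- NULL
  for (r in seq_len(restarts)) {
    f <- cool_gd(cp, hidden, lr, epochs, derive_seed(seed, r), const, decay)
    if (is.null(best) || f$loss < best$loss) best <- f
  }
  structure(c(best,
              list(features = design$features,
                   hyper = list(hidden = hidden, lr = lr, epochs = epochs,
                                restarts = restarts, seed = seed))),
            class = "cool_fit")
}

collapse_patterns <- function(design) {
  key <- apply(design$X, 1, paste, collapse = "")
  first <- !duplicated(key)
  U <- design$X[first, , drop = FALSE]
  grp <- match(key, key[first])
  wg <- as.vector(tapply(design$w, grp, sum))
  sg <- as.vector(tapply(design$w * design$y, grp, sum))
  y2 <- as.vector(tapply(design$w * design$y^2, grp, sum))
  list(U = U, wg = wg, sg = sg, ybar2 = y2 / wg, W = sum(wg), grp = grp)
}

cool_gd <- function(cp, H, lr, epochs, seed, const, decay = 0) {
  U <- cp$U; wg <- cp$wg; sg <- cp$sg; W <- cp$W
  FF <- ncol(U)
  set.seed(seed)
  W1 <- matrix(runif(FF * H, 0, 0.05), FF, H,
               dimnames = list(colnames(U), NULL))
  b <- rep(-0.01, H)
  w2 <- runif(H, 0, 0.05)
  Rb <- sum(sg) / W
  trace <- numeric()
  w2m <- function() matrix(w2, nrow(U), H, byrow = TRUE)
  for (e in seq_len(epochs)) {
    Z <- U %*% W1 + matrix(b, nrow(U), H, byrow = TRUE)
    act <- Z > 0
    Rl <- ifelse(act, Z, 0)
    p <- Rb + as.vector(Rl %*% w2)
    eg <- wg * p - sg                     # d(loss)/dp per pattern, /2
    if (!all(is.finite(eg))) {
      stop_("training diverged (non-finite loss); reduce the learning rate")
    }
    M <- (eg * act) * w2m()
    W1 <- pmax(W1 - lr * (2 * (t(U) %*% M) / W + 2 * decay * W1), 0)
    w2 <- pmax(w2 - lr * (2 * as.vector(t(Rl) %*% eg) / W + 2 * decay * w2), 0)
    b <- pmin(b - lr * 2 * colSums(M) / W, 0)
    # the intercept's quadratic curvature is 2 (every child), so its
    # stable step is lr/2; the relu-gated layers are far below that bound
    Rb <- min(max(Rb - lr * sum(eg) / W, 0), 1)
    if (e %% 500 == 0 || e == epochs) {
      trace <- c(trace, sum(wg * p^2 - 2 * p * sg) / W + const)
    }
  }
  Z <- U %*% W1 + matrix(b, nrow(U), H, byrow = TRUE)
  p <- Rb + as.vector(pmax(Z, 0) %*% w2)
  loss <- sum(wg * p^2 - 2 * p * sg) / W + const
  if (!is.finite(loss)) {
    stop_("training diverged (non-finite loss); reduce the learning rate")
  }
  list(W1 = W1, b = b, w2 = w2, Rb = Rb, loss = loss, trace = trace,
       seed = seed)
}

#' @export
print.cool_fit <- function(x, ...) {
  cat(sprintf("Non-negative risk network: %d features, %d hidden units\n",
              nrow(x$W1), length(x$w2)))
  cat(sprintf("  baseline risk %.4f; training weighted MSE %.6f (best of %d restarts)\n",
              x$Rb, x$loss, x$hyper$restarts))
  invisible(x)
}

#' @export
predict.cool_fit <- function(object, design, ...) {
  stopifnot(inherits(design, "cool_design"))
  Z <- design$X %*% object$W1 +
    matrix(object$b, nrow(design$X), length(object$w2), byrow = TRUE)
  p <- object$Rb + as.vector(pmax(Z, 0) %*% object$w2)
  pmin(pmax(p, 0), 1)
}

#' Per-child per-feature risk contributions
#'
#' Decomposes each child's predicted excess risk over the baseline into
#' feature contributions: each hidden unit's output is attributed to the
#' child's active features proportionally to their share of the positive
#' pre-activation,
#' `c_if = sum_h w2_h relu_h (W1[f, h] x_if) / (sum_f' W1[f', h] x_if')`.
#' The decomposition is complete: `R_b + sum_f c_if + clamp = p_i`
#' exactly, where `clamp` is the (usually zero) adjustment from clamping
#' predictions into `[0, 1]`.
#'
#' @param fit a [train_cool()] fit.
#' @param design the design it was trained on (or a compatible one).
#' @return object of class `cool_profile`: contribution matrix `C`
#'   (children x features), `baseline`, `clamp`, predictions `p`, plus
#'   `y`, `w`, `child_id` carried through for clustering.
#' @export
risk_contributions <- function(fit, design) {
  stopifnot(inherits(fit, "cool_fit"), inherits(design, "cool_design"))
  if (!identical(fit$features, design$features)) {
    stop_("design features do not match the trained model")
  }
  X <- design$X
  H <- length(fit$w2)
  Z <- X %*% fit$W1 + matrix(fit$b, nrow(X), H, byrow = TRUE)
  Rl <- pmax(Z, 0)
  pre <- X %*% fit$W1                    # positive pre-activation (b excluded)
  C <- matrix(0, nrow(X), ncol(X), dimnames = list(NULL, colnames(X)))
  for (h in seq_len(H)) {
    idx <- which(Rl[, h] > 0)
    if (!length(idx)) next
    if (any(pre[idx, h] <= 0)) {
      stop("internal error: active relu with non-positive feature pre-activation")
    }
    share <- (X[idx, , drop = FALSE] *
                matrix(fit$W1[, h], length(idx), ncol(X), byrow = TRUE)) /
      pre[idx, h]
    C[idx, ] <- C[idx, ] + fit$w2[h] * Rl[idx, h] * share
  }
  p_raw <- fit$Rb + rowSums(C)
  p <- pmin(pmax(p_raw, 0), 1)
  structure(list(C = C, baseline = fit$Rb, clamp = p - p_raw, p = p,
                 y = design$y, w = design$w, child_id = design$child_id),
            class = "cool_profile")
}

#' Cluster contribution profiles into candidate subgroups
#'
#' Hierarchical clustering (Ward linkage, Euclidean distance) of the
#' per-child contribution vectors, operating on the unique profiles with
#' multiplicity weights, cut into at most `max_groups` groups. Groups
#' below `min_prevalence` are kept but flagged as "very few children"
#' and excluded from validation candidates.
#'
#' @param profile a [risk_contributions()] profile.
#' @param max_groups maximum number of groups.
#' @param min_prevalence minimum group prevalence (proportion of
#'   children), default 0.005.
#' @return object of class `cool_subgroups`: per-child `assignment`,
#'   per-group `summary` (size, prevalence, weighted mean observed risk,
#'   mean total contribution, `flagged`), the group-mean contribution
#'   matrix `mean_contributions`, feature activity `mean_activity`, and
#'   the `dendrogram` (an `hclust`, `NULL` for a single profile).
#' @export
extract_subgroups <- function(profile, max_groups = 8,
                              min_prevalence = 0.005) {
  stopifnot(inherits(profile, "cool_profile"))
  if (max_groups < 1) stop_("max_groups must be >= 1")
  C <- profile$C
  key <- apply(round(C, 10), 1, paste, collapse = ",")
  first <- !duplicated(key)
  Uc <- C[first, , drop = FALSE]
  grp <- match(key, key[first])
  counts <- tabulate(grp, nbins = nrow(Uc))
  if (nrow(Uc) == 1L) {
    assign <- rep(1L, nrow(C))
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::dist(Uc), method = "ward.D2",
                        members = counts)
    k <- min(max_groups, nrow(Uc))
    assign <- stats::cutree(hc, k = k)[grp]
  }
  gids <- sort(unique(assign))
  n <- nrow(C)
  summ <- do.call(rbind, lapply(gids, function(g) {
    idx <- assign == g
    data.frame(group = g, n = sum(idx), prevalence = mean(idx),
               mean_risk = 100 * sum(profile$w[idx] * profile$y[idx]) /
                 sum(profile$w[idx]),
               mean_contribution = mean(rowSums(C[idx, , drop = FALSE])),
               flagged = mean(idx) < min_prevalence)
  }))
  mc <- do.call(rbind, lapply(gids, function(g)
    colMeans(C[assign == g, , drop = FALSE])))
  dimnames(mc) <- list(gids, colnames(C))
  structure(list(assignment = assign, summary = summ,
                 mean_contributions = mc, dendrogram = hc,
                 min_prevalence = min_prevalence),
            class = "cool_subgroups")
}

#' @export
print.cool_subgroups <- function(x, ...) {
  cat("Contribution-profile subgroups (Ward/Euclidean):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Turn a contribution subgroup into a conjunction rule
#'
#' Names a group by the features that define it: the features whose
#' group-mean contribution is at least `threshold` times the group's top
#' feature contribution (restricted to features actually active in the
#' group). With `threshold = 0` every active feature is included; with
#' `threshold >= 1` ties at the top are broken alphabetically and a
#' single-feature rule is returned.
#'
#' @param groups a [extract_subgroups()] result.
#' @param group group id.
#' @param design the `cool_design` the profiles came from.
#' @param threshold fraction of the top contribution (default 0.5).
#' @return object of class `subgroup_rule`: design-column `features`, a
#'   human-readable `label`, and the feature `meta` needed to evaluate
#'   membership on a cohort table via [rule_members()].
#' @export
subgroup_to_rule <- function(groups, group, design, threshold = 0.5) {
  stopifnot(inherits(groups, "cool_subgroups"),
            inherits(design, "cool_design"))
  idx <- groups$assignment == group
  if (!any(idx)) stop_("group %s is empty", group)
  mc <- groups$mean_contributions[as.character(group), ]
  active <- colMeans(design$X[idx, , drop = FALSE]) > 0
  if (!any(active)) stop_("no defining features: group has no active features")
  top <- max(mc[active])
  if (top <= 0) stop_("no defining features: group has no positive contributions")
  if (threshold >= 1) {
    cand <- names(mc)[active & mc >= top - 1e-12]
    feats <- sort(cand)[1]
  } else {
    feats <- names(mc)[active & mc >= threshold * top & mc > 0]
    if (!length(feats)) stop_("no defining features at this threshold")
  }
  new_rule(feats, design$meta[feats])
}

new_rule <- function(features, meta) {
  structure(list(features = features,
                 label = paste(features, collapse = " & "),
                 meta = meta),
            class = "subgroup_rule")
}

#' @export
print.subgroup_rule <- function(x, ...) {
  cat("Subgroup rule:", x$label, "\n")
  invisible(x)
}

#' Evaluate rule membership on a cohort or design
#'
#' @param rule a `subgroup_rule`.
#' @param tab a cohort table, `weighted_cohort` or `cool_design`.
#' @return logical membership vector.
#' @export
rule_members <- function(rule, tab) {
  stopifnot(inherits(rule, "subgroup_rule"))
  if (inherits(tab, "cool_design")) {
    miss <- setdiff(rule$features, colnames(tab$X))
    if (length(miss)) stop_("unknown covariate '%s'", miss[1])
    return(rowSums(tab$X[, rule$features, drop = FALSE]) ==
             length(rule$features))
  }
  m <- rep(TRUE, nrow(tab))
  for (f in rule$features) {
    info <- rule$meta[[f]]
    src <- if (!is.null(info)) info$source else f
    v <- tab[[src]]
    if (is.null(v)) stop_("unknown covariate '%s'", src)
    if (!is.null(info) && isTRUE(info$calendar)) {
      # calendar band feature: parse "[a,b)" interval
      bounds <- as.numeric(strsplit(gsub("\\[|\\)|\\]", "", info$level),
                                    ",")[[1]])
      m <- m & v >= bounds[1] & v < bounds[2]
    } else if (!is.null(info) && !is.null(info$level)) {
      m <- m & v == info$level
    } else {
      m <- m & (v == 1 | v == TRUE)
    }
  }
  m
}
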