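# The inductive-deductive workflow: split the cohort temporally,
# discover candidate subgroups on the hypothesis-generating side only,
# freeze them (hashed), then re-estimate everything on the validation
# side and assemble the summary table with PAFs.

#' Study configuration for the discovery/validation pipeline
#'
#' @param split_year last birth year of the hypothesis-generating cohort
#'   (default 2011: births 2003-2011 vs 2012-2016).
#' @param window,step,min_count spatial-scan parameters (meters,
#'   meters, children).
#' @param spatial_excess per-100 excess over the global adjusted risk a
#'   window must reach to seed a candidate circle.
#' @param circle_radius radius (m) of candidate circles drawn around
#'   spatial peaks.
#' @param max_areas maximum number of candidate areas.
#' @param cool_hidden,cool_epochs,cool_restarts,cool_max_groups
#'   hyperparameters of the risk-decomposition stage.
#' @param min_prevalence minimum subgroup prevalence for a candidate.
#' @param min_cell "very few children" suppression threshold: minimum
#'   children per cell (subgroup side x cohort) for estimates to be
#'   reported.
#' @param truncate_at IPCW weight truncation.
#' @param seed master seed.
#' @return a list of class `study_config`.
#' @export
study_config <- function(split_year = 2011, window = 250, step = 10,
                         min_count = 100, spatial_excess = 3,
                         circle_radius = 250, max_areas = 4,
                         cool_hidden = 10, cool_epochs = 10000,
                         cool_restarts = 10, cool_max_groups = 8,
                         min_prevalence = 0.005, min_cell = 20,
                         truncate_at = 10, seed = 1) {
  structure(as.list(environment()), class = "study_config")
}

#' Temporal split into hypothesis-generating and validation cohorts
#'
#' Deterministic partition by birth year: children born in or before
#' `split_year` form the hypothesis-generating cohort, the rest the
#' temporal validation cohort.
#'
#' @param cohort a cohort table (or `weighted_cohort`).
#' @param split_year last birth year of the hypothesis cohort.
#' @return list with elements `hypothesis` and `validation`.
#' @export
temporal_split <- function(cohort, split_year = 2011) {
  h <- cohort$birth_year <= split_year
  if (!any(h) || all(h)) {
    stop_("split year %d leaves one side empty (birth years %d-%d)",
          split_year, min(cohort$birth_year), max(cohort$birth_year))
  }
  list(hypothesis = cohort[h, , drop = FALSE],
       validation = cohort[!h, , drop = FALSE])
}

#' Discover candidate subgroups on the hypothesis-generating cohort
#'
#' Runs the three discovery analyses and returns the union of their
#' candidates, each with provenance:
#' \itemize{
#'   \item \emph{spatial}: circles of `circle_radius` around
#'     sliding-window peaks exceeding the global adjusted risk by
#'     `spatial_excess` per 100;
#'   \item \emph{single_factor}: binary covariates whose backdoor-
#'     adjusted risk-difference CI excludes 0 (no multiplicity
#'     correction; exploratory by design);
#'   \item \emph{cool}: conjunction rules from contribution-profile
#'     clusters with prevalence above `min_prevalence`.
#' }
#' The candidate list is fingerprinted so that validation can verify the
#' rules were frozen before it ran.
#'
#' @param wc the hypothesis-generating `weighted_cohort`.
#' @param schema a [covariate_schema()].
#' @param config a [study_config()].
#' @return object of class `discovery`: `candidates` (list) and
#'   `fingerprint`.
#' @export
run_discovery <- function(wc, schema, config = study_config()) {
  stopifnot(inherits(wc, "weighted_cohort"),
            inherits(schema, "covariate_schema"))
  cands <- list()

  # spatial
  surf <- tryCatch(
    scan_surface(wc, window = config$window, step = config$step,
                 min_count = config$min_count),
    error = function(e) NULL)
  if (!is.null(surf)) {
    pk <- surface_peaks(surf, threshold = surf$global_risk +
                          config$spatial_excess,
                        max_peaks = config$max_areas,
                        separation = 2 * config$circle_radius)
    for (i in seq_len(nrow(pk))) {
      cands[[length(cands) + 1]] <- list(
        type = "spatial", label = sprintf("area %s", LETTERS[i]),
        circle = list(center = c(pk$x[i], pk$y[i]),
                      radius = config$circle_radius),
        peak_risk = pk$risk[i])
    }
  }

  # single factors
  for (f in c(schema$environmental, schema$household, schema$birth)) {
    v <- wc[[f]]
    if (is.null(v) || !is_binary01(v) || length(unique(v)) < 2) next
    est <- tryCatch(
      glm_risk_difference(wc, f, adjustment_set(f, schema),
                          cohort_tag = "hypothesis"),
      error = function(e) NULL)
    if (is.null(est)) next
    if (est$ci_low > 0 || est$ci_high < 0) {
      cands[[length(cands) + 1]] <- list(
        type = "single_factor", label = f, exposure = f,
        estimate = est$estimate)
    }
  }

  # multifactorial (risk decomposition + clustering)
  design <- encode_features(wc)
  fit <- train_cool(design, hidden = config$cool_hidden,
                    epochs = config$cool_epochs,
                    restarts = config$cool_restarts, seed = config$seed)
  prof <- risk_contributions(fit, design)
  groups <- extract_subgroups(prof, max_groups = config$cool_max_groups,
                              min_prevalence = config$min_prevalence)
  for (g in groups$summary$group) {
    row <- groups$summary[groups$summary$group == g, ]
    if (row$flagged) next
    if (row$mean_contribution < 0.005) next  # background / noise group
    rule <- tryCatch(subgroup_to_rule(groups, g, design),
                     error = function(e) NULL)
    if (is.null(rule)) next
    # skip pure calendar-band rules (period effects, not subgroups)
    if (all(vapply(rule$meta, function(m) isTRUE(m$calendar), TRUE))) next
    cands[[length(cands) + 1]] <- list(
      type = "cool", label = rule$label, rule = rule,
      prevalence = row$prevalence)
  }

  # drop duplicate rules (same defining features from different routes)
  labs <- vapply(cands, `[[`, "", "label")
  cands <- cands[!duplicated(labs)]

  structure(list(candidates = cands, fingerprint = fingerprint(cands)),
            class = "discovery")
}

#' @export
print.discovery <- function(x, ...) {
  cat(sprintf("Discovery artifact: %d candidate subgroups (fingerprint %s)\n",
              length(x$candidates), x$fingerprint))
  for (cd in x$candidates) cat(sprintf("  [%s] %s\n", cd$type, cd$label))
  invisible(x)
}

#' Serialize / restore a discovery artifact as JSON
#'
#' @param disc a [run_discovery()] artifact.
#' @param path JSON path.
#' @return `write_discovery` returns `path`; `read_discovery` the
#'   restored `discovery` object (fingerprint re-verified).
#' @export
write_discovery <- function(disc, path) {
  jsonlite::write_json(serialize_candidates(disc$candidates),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_discovery
#' @export
read_discovery <- function(path) {
  raw <- jsonlite::read_json(path)
  cands <- lapply(raw, deserialize_candidate)
  structure(list(candidates = cands, fingerprint = fingerprint(cands)),
            class = "discovery")
}

serialize_candidates <- function(cands) {
  lapply(cands, function(cd) {
    if (!is.null(cd$rule)) {
      cd$rule <- list(features = cd$rule$features, label = cd$rule$label,
                      meta = cd$rule$meta)
    }
    cd
  })
}

deserialize_candidate <- function(cd) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  out <- list(type = cd$type, label = cd$label)
  if (!is.null(cd$circle)) {
    out$circle <- list(center = num(unlist(cd$circle$center)),
                       radius = as.numeric(cd$circle$radius))
    out$peak_risk <- num(cd$peak_risk)
  }
  if (!is.null(cd$exposure)) {
    out$exposure <- cd$exposure
    out$estimate <- num(cd$estimate)
  }
  if (!is.null(cd$rule)) {
    meta <- lapply(cd$rule$meta, function(m) {
      m$calendar <- if (isTRUE(m$calendar)) TRUE else NULL
      lapply(m, function(v) if (is.null(v)) NULL else unlist(v))
    })
    out$rule <- new_rule(unlist(cd$rule$features), meta)
    out$prevalence <- num(cd$prevalence)
  }
  out
}

candidate_membership <- function(cd, wc) {
  switch(cd$type,
         spatial = in_circle(wc$x, wc$y, cd$circle),
         single_factor = as_membership(cd$exposure, wc),
         cool = rule_members(cd$rule, wc),
         stop_("unknown candidate type '%s'", cd$type))
}

candidate_adjustment <- function(cd, schema) {
  switch(cd$type,
         spatial = schema$calendar,
         single_factor = adjustment_set(cd$exposure, schema),
         cool = c(schema$calendar, schema$environmental,
                  schema$household))
}

#' Validate frozen candidates on the temporal validation cohort
#'
#' For each candidate discovered on the hypothesis-generating cohort,
#' computes in both cohorts the prevalence, crude risks inside/outside,
#' the synergy statistic (conjunction rules only) and the TMLE adjusted
#' risk difference with the candidate-type-graded adjustment set
#' (spatial: calendar; single factor: backdoor set; multifactorial:
#' calendar + environmental + household), then the similarity p-value,
#' the pooled combined TMLE estimate, and the PAF based on the combined
#' estimate and the pooled overall risk. Cells with fewer than
#' `min_cell` children on either side of either cohort are reported as
#' "very few children" with estimates suppressed.
#'
#' The discovery artifact's fingerprint is re-verified so that rules
#' tampered with after discovery are rejected.
#'
#' @param disc a [run_discovery()] artifact (or one restored by
#'   [read_discovery()]).
#' @param wc_h,wc_v hypothesis and validation `weighted_cohort`s.
#' @param schema a [covariate_schema()].
#' @param config a [study_config()].
#' @return data.frame of class `summary_table`, one row per candidate.
#' @export
validate_candidates <- function(disc, wc_h, wc_v, schema,
                                config = study_config()) {
  stopifnot(inherits(disc, "discovery"))
  if (!identical(disc$fingerprint, fingerprint(disc$candidates))) {
    stop_("discovery artifact fingerprint mismatch: candidates were modified after discovery")
  }
  overall_h <- weighted_mean_se(wc_h$died, wc_h$.weight)
  overall_v <- weighted_mean_se(wc_v$died, wc_v$.weight)
  wn_h <- sum(wc_h$.weight); wn_v <- sum(wc_v$.weight)
  overall_risk <- 100 * (wn_h * overall_h$mean + wn_v * overall_v$mean) /
    (wn_h + wn_v)

  rows <- lapply(disc$candidates, function(cd) {
    m_h <- candidate_membership(cd, wc_h)
    m_v <- candidate_membership(cd, wc_v)
    adj <- candidate_adjustment(cd, schema)
    row <- data.frame(
      subgroup = cd$label, type = cd$type,
      n_h = sum(m_h), pct_h = 100 * mean(m_h),
      n_v = sum(m_v), pct_v = 100 * mean(m_v),
      risk_in_h = NA_real_, risk_out_h = NA_real_,
      risk_in_v = NA_real_, risk_out_v = NA_real_,
      synergy_h = NA_real_, synergy_v = NA_real_,
      amrd_h = NA_real_, amrd_h_lo = NA_real_, amrd_h_hi = NA_real_,
      amrd_v = NA_real_, amrd_v_lo = NA_real_, amrd_v_hi = NA_real_,
      similarity_p = NA_real_,
      combined = NA_real_, combined_lo = NA_real_, combined_hi = NA_real_,
      paf = NA_real_, note = "", stringsAsFactors = FALSE)
    few <- function(m, wc) min(sum(m), sum(!m)) < config$min_cell
    if (few(m_h, wc_h) || few(m_v, wc_v)) {
      row$note <- "very few children"
      return(row)
    }
    cr_h <- crude_risk(wc_h, m_h); cr_v <- crude_risk(wc_v, m_v)
    row$risk_in_h <- cr_h$inside$estimate
    row$risk_out_h <- cr_h$outside$estimate
    row$risk_in_v <- cr_v$inside$estimate
    row$risk_out_v <- cr_v$outside$estimate
    if (cd$type == "cool" && length(cd$rule$features) >= 2) {
      comp <- vapply(cd$rule$features, function(f) {
        info <- cd$rule$meta[[f]]
        if (!is.null(info) && !is.null(info$source)) info$source else f
      }, "")
      syn <- function(wc, m, tag) tryCatch(
        synergy_statistic(wc, m, components = unname(comp),
                          calendar = schema$calendar,
                          cohort_tag = tag)$estimate,
        error = function(e) NA_real_)
      row$synergy_h <- syn(wc_h, m_h, "hypothesis")
      row$synergy_v <- syn(wc_v, m_v, "validation")
    }
    # rare subgroups routinely pin g at its truncation bound; the
    # per-fit diagnostics keep the truncation fraction, so the summary
    # assembly itself stays quiet
    e_h <- suppressWarnings(
      tmle_risk_difference(wc_h, m_h, adj, cohort_tag = "hypothesis"))
    e_v <- suppressWarnings(
      tmle_risk_difference(wc_v, m_v, adj, cohort_tag = "validation"))
    row$amrd_h <- e_h$estimate; row$amrd_h_lo <- e_h$ci_low
    row$amrd_h_hi <- e_h$ci_high
    row$amrd_v <- e_v$estimate; row$amrd_v_lo <- e_v$ci_low
    row$amrd_v_hi <- e_v$ci_high
    row$similarity_p <- similarity_test(e_h, e_v)
    cmb <- suppressWarnings(
      combined_estimate(wc_h, wc_v, list(m_h, m_v), adjust = adj,
                        calendar = schema$calendar))
    row$combined <- cmb$estimate
    row$combined_lo <- cmb$ci_low; row$combined_hi <- cmb$ci_high
    prev <- (sum(wc_h$.weight[m_h]) + sum(wc_v$.weight[m_v])) /
      (wn_h + wn_v)
    row$paf <- paf(prev, cmb$estimate, overall_risk)
    row
  })
  out <- do.call(rbind, rows) %||%
    data.frame(subgroup = character(), stringsAsFactors = FALSE)
  attr(out, "overall_risk") <- overall_risk
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Run the whole discovery / temporal-validation pipeline
#'
#' End-to-end orchestration: simulate (or read) the cohort, fit the
#' censoring model and IPCW weights on the full cohort, split
#' temporally, run the three discovery analyses on the
#' hypothesis-generating side, freeze the candidates, and validate them
#' on the temporal side. Deterministic given the seed.
#'
#' @param config a [study_config()], a list, or a path to a YAML file
#'   with (optionally) `sim:` and `study:` sections mirroring
#'   [sim_config()] and [study_config()] arguments, plus optional
#'   `cohort_csv` and `out_dir`.
#' @param cohort optional pre-built cohort table (overrides simulation).
#' @param out_dir optional output directory; if given, the cohort CSV,
#'   weights CSV, discovery JSON, summary CSV and a JSON run report are
#'   written there.
#' @return (invisibly) list with the cohort, weighted cohorts,
#'   discovery artifact and `summary` table.
#' @export
run_pipeline <- function(config = NULL, cohort = NULL, out_dir = NULL) {
  sim_args <- list(); study_args <- list(); cohort_csv <- NULL
  if (is.character(config)) {
    cfgl <- yaml::read_yaml(config)
    sim_args <- cfgl$sim %||% list()
    study_args <- cfgl$study %||% list()
    cohort_csv <- cfgl$cohort_csv
    out_dir <- out_dir %||% cfgl$out_dir
    if (!is.null(cfgl$seed)) {
      sim_args$seed <- sim_args$seed %||% cfgl$seed
      study_args$seed <- study_args$seed %||% cfgl$seed
    }
  } else if (inherits(config, "study_config")) {
    study_args <- unclass(config)
  } else if (is.list(config)) {
    sim_args <- config$sim %||% list()
    study_args <- config$study %||% list()
  }
  scfg <- do.call(study_config, study_args)

  if (is.null(cohort)) {
    if (!is.null(cohort_csv)) {
      cohort <- read_cohort(cohort_csv)
      simcfg <- NULL
    } else {
      simcfg <- do.call(sim_config, sim_args)
      cohort <- generate_cohort(simcfg)
    }
  } else {
    simcfg <- attr(cohort, "config")
  }
  schema <- if (!is.null(simcfg)) schema_from_config(simcfg) else
    schema_from_cohort(cohort)

  cm <- fit_censoring_model(cohort)
  wc <- compute_ipcw(cm, cohort, truncate_at = scfg$truncate_at)
  halves <- temporal_split(wc, scfg$split_year)
  wc_h <- halves$hypothesis; wc_v <- halves$validation

  disc <- run_discovery(wc_h, schema, scfg)
  summ <- validate_candidates(disc, wc_h, wc_v, schema, scfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_weights(wc, file.path(out_dir, "weights.csv"))
    write_discovery(disc, file.path(out_dir, "discovery.json"))
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = scfg$seed, split_year = scfg$split_year,
           n_children = nrow(cohort),
           weighted_n = attr(wc, "diagnostics")$weighted_n,
           weight_diagnostics = attr(wc, "diagnostics"),
           n_candidates = length(disc$candidates),
           discovery_fingerprint = disc$fingerprint,
           overall_risk = attr(summ, "overall_risk")),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(cohort = cohort, weighted = wc, hypothesis = wc_h,
                 validation = wc_v, discovery = disc, summary = summ,
                 schema = schema))
}

# fallback schema inference when no simulation config is attached:
# everything binary or categorical except coordinates/outcomes is
# treated as household-domain unless named like the defaults
schema_from_cohort <- function(cohort) {
  covs <- setdiff(baseline_covariates(cohort), "birth_year")
  env <- intersect(covs, c("far_from_road", "vegetation_top10",
                           "high_density"))
  birth <- intersect(covs, c("twin", "boy", "rainy_season",
                             "no_prenatal_consultations"))
  covariate_schema(environmental = env,
                   household = setdiff(covs, c(env, birth)),
                   birth = birth)
}
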