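# End-to-end pipeline: uni-lineage screens -> separatrix constraints ->
# constrained multi-lineage screen -> trajectory clustering -> AML screens.
# Every artifact is stamped with the configuration hash and stage seeds so a
# rerun with the same configuration reproduces identical tables.

# re-simulate the chemo protocol for accepted cohort rows (the cohort table
# stores parameters and equilibria, not full trajectories)
.cohort_trajectories <- function(cohort, params, scope = c("N", "L", "M")) {
  sampled <- intersect(.param_roster()$name, names(cohort))
  eq_cols <- paste0("eq_", leuko_states())
  rows <- which(cohort$accepted)
  trajs <- lapply(rows, function(i) {
    pars <- params
    pars[sampled] <- as.numeric(cohort[i, sampled])
    pars <- mirror_cancer_params(pars, "monocyte")
    eq <- setNames(as.numeric(cohort[i, eq_cols]), leuko_states())
    run_chemo_protocol(pars, eq, scope = scope)
  })
  names(trajs) <- as.character(cohort$run_id[rows])
  trajs
}

#' Fit separatrix constraints from uni-lineage cohorts
#'
#' Stem-cell pairs are fitted on the pooled accepted rows of all three
#' uni-lineage cohorts; lineage-specific pairs on their own cohort. With
#' `all_pairs = TRUE` every parameter pair that is observable within a
#' single cohort is fitted (so each sampled parameter is also boxed to its
#' accepted range), which is how the pipeline concentrates the multi-lineage
#' resampling in the viable region.
#'
#' @param cohorts Named list of uni-lineage cohort tibbles (`N`, `L`, `M`).
#' @param pairs List of parameter pairs (default
#'   [default_separatrix_pairs()]).
#' @param all_pairs Fit every within-cohort pair instead of `pairs`.
#' @return Named list of `separatrix_constraint` objects (pairs with fewer
#'   than 2 distinct accepted points are skipped).
#' @export
fit_cohort_separatrices <- function(cohorts,
                                    pairs = default_separatrix_pairs(),
                                    all_pairs = FALSE) {
  pooled <- dplyr::bind_rows(lapply(cohorts, function(co) {
    co[co$accepted, intersect(names(co), .param_roster()$name), drop = FALSE]
  }))
  lin_groups <- c(N = "neutrophil", L = "lymphocyte", M = "monocyte")
  cut_pairs <- pairs
  if (all_pairs) {
    stem <- .group_params("stem")
    pairs <- utils::combn(stem, 2, simplify = FALSE)
    for (l in names(cohorts)) {
      nms <- intersect(names(cohorts[[l]]), .group_params(
        .scope_groups(l)))
      extra <- utils::combn(nms, 2, simplify = FALSE)
      keep <- vapply(extra, function(pr) !all(pr %in% stem), logical(1))
      pairs <- c(pairs, extra[keep])
    }
  }
  out <- list()
  for (pair in pairs) {
    # corner cuts need dense bin statistics; at cohort scale only the
    # canonical pairs carry them, the rest contribute range boxes
    box_only <- all_pairs &&
      !any(vapply(cut_pairs, function(pr) setequal(pr, pair), logical(1)))
    src <- if (all(pair %in% .group_params("stem"))) {
      pooled
    } else {
      hit <- names(which(vapply(names(lin_groups), function(l) {
        any(pair %in% .group_params(c(lin_groups[[l]],
                                      if (l == "M") "macrophage")))
      }, logical(1))))[1]
      co <- cohorts[[hit]]
      co[co$accepted, , drop = FALSE]
    }
    con <- try(fit_separatrix(src, pair), silent = TRUE)
    if (!inherits(con, "try-error")) {
      if (box_only) {
        con$grid <- NULL
        con$cuts <- list()
      }
      out[[paste(pair, collapse = "_vs_")]] <- con
    }
  }
  out
}

#' Run the full virtual-cohort pipeline
#'
#' Executes, in order: nominal calibration, the three uni-lineage screens,
#' separatrix fitting, the constrained multi-lineage screen, trajectory
#' normalization and k-means stratification, the PRCC sensitivity report,
#' and the two cancer-parameter screens (free, and with the mitosis rate
#' fixed). Artifacts are returned as a named list and, when `out_dir` is
#' given, written as CSV/JSON files stamped with the configuration hash.
#'
#' @param config A [default_config()] list.
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return Invisible list: `fixture`, `uni` (list of cohorts), `constraints`,
#'   `multi`, `clusters`, `representatives`, `sensitivity`, `aml_free`,
#'   `aml_fixed_mitosis`, `survival`, `hash`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  hash <- config_hash(config)
  seed <- config$seed
  eqc <- config$equilibrium

  say("[1/6] calibrating nominal fixture")
  fixture <- make_nominal_fixture(thresholds = config$criteria)
  params <- fixture$params

  say("[2/6] uni-lineage screens (n = ", config$sampling$n_uni, " each)")
  uni <- lapply(setNames(c("N", "L", "M"), c("N", "L", "M")), function(l) {
    screen_unilineage(l, n = config$sampling$n_uni,
                      seed = seed + match(l, c("N", "L", "M")),
                      params = params, thresholds = config$criteria,
                      eq_control = eqc)
  })

  say("[3/6] separatrix constraints")
  constraints <- fit_cohort_separatrices(uni, all_pairs = TRUE)

  say("[4/6] constrained multi-lineage screen (n = ",
      config$sampling$n_multi, ")")
  multi <- screen_multilineage(n = config$sampling$n_multi, seed = seed + 10,
                               constraints = constraints, params = params,
                               thresholds = config$criteria, eq_control = eqc)

  say("[5/6] clustering accepted dynamics")
  n_acc <- sum(multi$accepted)
  if (n_acc < 4) stop("too few accepted multi-lineage patients to cluster")
  trajs <- .cohort_trajectories(multi, params)
  dynamics <- normalize_trajectories(trajs)
  k <- min(config$clustering$k, floor(n_acc / 2))
  clusters <- cluster_trajectories(dynamics, k = k, seed = seed + 20,
                                   n_init = config$clustering$n_init)
  reps <- dplyr::inner_join(
    dplyr::mutate(clusters$representatives,
                  run_id = as.integer(.data$run_id)),
    multi, by = "run_id"
  )
  sensitivity <- sensitivity_report(multi)

  say("[6/6] cancer-parameter screens (", config$cancer$n_per,
      " draws x ", k, " representatives)")
  aml_free <- cancer_parameter_screen(
    reps, params = params, n_per = config$cancer$n_per, seed = seed + 30,
    cancer_source = config$cancer$source, fix_mitosis = FALSE,
    horizon = config$cancer$horizon,
    diagnosis_window = config$cancer$diagnosis_window,
    thresholds = config$cancer$thresholds, method = config$cancer$method,
    endpoint = config$cancer$endpoint,
    mr_upper_absolute = config$cancer$mr_upper_absolute)
  aml_fixed <- cancer_parameter_screen(
    reps, params = params, n_per = config$cancer$n_per, seed = seed + 40,
    cancer_source = config$cancer$source, fix_mitosis = TRUE,
    horizon = config$cancer$horizon,
    diagnosis_window = config$cancer$diagnosis_window,
    thresholds = config$cancer$thresholds, method = config$cancer$method,
    endpoint = config$cancer$endpoint,
    mr_upper_absolute = config$cancer$mr_upper_absolute)
  surv <- survival_curves(
    aml_free$outcomes[aml_free$outcomes$diagnosed, c("cluster", "death_day")])

  out <- list(fixture = fixture, uni = uni, constraints = constraints,
              multi = multi, clusters = clusters, representatives = reps,
              sensitivity = sensitivity, aml_free = aml_free,
              aml_fixed_mitosis = aml_fixed, survival = surv, hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) {
      df$config_hash <- hash
      df
    }
    for (l in names(uni)) {
      utils::write.csv(stamp(uni[[l]]),
                       file.path(out_dir, paste0("cohort_uni_", l, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(stamp(multi), file.path(out_dir, "cohort_multi.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(constraints, function(con) {
        list(pair = con$pair, box = con$box, cutoff = con$cutoff,
             grid = con$grid,
             cuts = lapply(con$cuts, function(cut) cut[c(
               "corner", "slope", "intercept", "sx", "sy", "x0", "y0")]))
      }),
      file.path(out_dir, "constraints.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(stamp(tidy(clusters)),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(stamp(sensitivity),
                     file.path(out_dir, "prcc.csv"), row.names = FALSE)
    utils::write.csv(stamp(aml_free$outcomes),
                     file.path(out_dir, "outcomes.csv"), row.names = FALSE)
    utils::write.csv(stamp(dplyr::bind_rows(
      dplyr::mutate(aml_free$correlations, screen = "free"),
      dplyr::mutate(aml_fixed$correlations, screen = "fixed_mitosis"))),
      file.path(out_dir, "correlations.csv"), row.names = FALSE)
  }
  invisible(out)
}
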