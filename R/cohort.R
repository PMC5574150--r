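# Virtual-cohort generation: log-space Latin hypercube sampling of the
# uncertain parameters, equilibrium screening, the 7-day chemotherapy
# protocol, and the acceptability criteria - per uni-lineage sub-model and
# for the integrated multi-lineage model.

.group_params <- function(groups) {
  roster <- .param_roster()
  roster$name[roster$group %in% groups & !roster$fixed]
}

.scope_groups <- function(lineage) {
  switch(lineage,
    N = c("stem", "neutrophil"),
    L = c("stem", "lymphocyte"),
    M = c("stem", "monocyte", "macrophage"),
    multi = c("stem", "neutrophil", "lymphocyte", "monocyte", "macrophage"),
    stop("unknown lineage scope: ", lineage)
  )
}

.scope_lineages <- function(lineage) {
  if (identical(lineage, "multi")) c("N", "L", "M") else lineage
}

#' Default sampling bounds for a screening run
#'
#' Rates and Michaelis constants are sampled in log space between 1/5 and 5
#' times their nominal value; self-renewal probabilities are sampled linearly
#' on `[0.5, 1]` (the range that maintains stem-cell mass without collapse);
#' lineage-split fractions linearly on 1/5 to 5 times nominal, capped at 0.9.
#' Chemotherapy pharmacology, marrow capacity, and the cancer block are
#' protocol constants and are not sampled here.
#'
#' @param lineage `"N"`, `"L"`, `"M"`, or `"multi"` - which uni-lineage
#'   sub-model (lineage-specific plus stem-cell parameters) or the full model
#'   is being screened.
#' @param params Nominal parameter vector the bounds are centred on.
#' @param fold Fold-range around nominal for log-scale parameters (default 5).
#' @return A tibble with columns `name`, `lower`, `upper`, `scale`.
#' @export
default_sampling_bounds <- function(lineage = "multi",
                                    params = calibrate_nominal(),
                                    fold = 5) {
  roster <- .param_roster()
  nms <- .group_params(.scope_groups(lineage))
  rows <- roster[match(nms, roster$name), ]
  lower <- upper <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    nm <- rows$name[i]
    nom <- params[[nm]]
    if (grepl("^a", nm)) {            # self-renewal probabilities
      lower[i] <- 0.5; upper[i] <- 1
    } else if (nm == "fN") {          # split fractions: keep the partition
      lower[i] <- nom / fold; upper[i] <- min(fold * nom, 0.75)
    } else if (nm == "fL") {
      lower[i] <- nom / fold; upper[i] <- min(fold * nom, 0.5)
    } else {
      lower[i] <- nom / fold; upper[i] <- fold * nom
    }
  }
  out <- tibble::tibble(name = rows$name, lower = lower, upper = upper,
                        scale = rows$scale)
  if (any(out$lower >= out$upper)) stop("degenerate sampling bounds")
  out
}

#' Latin hypercube sample of a bounded parameter space
#'
#' Stratified (one point per equal-probability stratum per marginal) sampling
#' of `n` parameter vectors. Log-scale parameters are stratified on the log
#' of their bounds, linear-scale parameters on the raw bounds. Reproducible
#' under a fixed seed.
#'
#' @param bounds Bounds tibble (see [default_sampling_bounds()]).
#' @param n Number of samples (>= 1).
#' @param seed Integer RNG seed.
#' @return A tibble with `n` rows and one column per parameter.
#' @export
lhs_sample <- function(bounds, n, seed = 1) {
  stopifnot(n >= 1, all(bounds$lower < bounds$upper))
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(bounds))
  cols <- lapply(seq_len(nrow(bounds)), function(j) {
    lo <- bounds$lower[j]; hi <- bounds$upper[j]
    if (identical(bounds$scale[j], "log")) {
      exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    } else {
      lo + u[, j] * (hi - lo)
    }
  })
  names(cols) <- bounds$name
  tibble::as_tibble(cols)
}

# starting state for equilibrium search under a lineage scope
.x0_for_scope <- function(scope) {
  x0 <- calibration_targets()
  keep <- c("S",
            if ("N" %in% scope) c("N2", "Nbm", "Npb", "Nmp"),
            if ("L" %in% scope) c("L2", "L3", "L3pb"),
            if ("M" %in% scope) c("M2", "Mbm", "Mpb", "Mmp", "MAC"))
  x0[setdiff(leuko_states(), keep)] <- 0
  x0
}

# screen one parameter draw: equilibrium, chemo protocol, criteria
.screen_one <- function(draw, nominal, scope_lineages, thresholds,
                        eq_control = list()) {
  pars <- nominal
  pars[names(draw)] <- as.numeric(draw)
  if (pars[["fN"]] + pars[["fL"]] > 0.98) {
    return(list(tag = "invalid", report = NULL, eq = NULL))
  }
  pars <- mirror_cancer_params(pars, "monocyte")
  eq <- do.call(find_equilibrium, c(
    list(params = pars, x0 = .x0_for_scope(scope_lineages),
         scope = scope_lineages), eq_control))
  if (!identical(eq$tag, "nontrivial")) {
    return(list(tag = eq$tag, report = NULL, eq = eq$state, params = pars))
  }
  traj <- run_chemo_protocol(pars, eq$state, scope = scope_lineages)
  rep <- evaluate_acceptability(traj, thresholds)
  list(tag = eq$tag, report = rep, eq = eq$state, params = pars)
}

.empty_report <- function() {
  tibble::tibble(
    c1 = NA, c2 = NA, c3 = NA, c4 = NA, c5 = NA, c6 = NA, c7 = NA,
    accepted = FALSE, pb_total_final = NA_real_, stem_final = NA_real_,
    final_Npb = NA_real_, final_L3pb = NA_real_, final_Mpb = NA_real_,
    stem_nadir = NA_real_, nadir_frac_max = NA_real_,
    overshoot_ratio_max = NA_real_, overshoot_state = NA_character_,
    overshoot_S = NA_real_, overshoot_Npb = NA_real_,
    overshoot_L3pb = NA_real_, overshoot_Mpb = NA_real_,
    peak1 = NA_real_, peak2 = NA_real_, n_peaks_max = NA_integer_
  )
}

.assemble_cohort <- function(draws, results, lineage, seed) {
  reports <- dplyr::bind_rows(lapply(results, function(r) {
    if (is.null(r$report)) .empty_report() else r$report
  }))
  eqs <- matrix(NA_real_, nrow = length(results), ncol = 17)
  for (i in seq_along(results)) {
    if (!is.null(results[[i]]$eq)) eqs[i, ] <- unname(results[[i]]$eq)
  }
  colnames(eqs) <- paste0("eq_", leuko_states())
  dplyr::bind_cols(
    tibble::tibble(
      run_id = seq_len(nrow(draws)),
      lineage = lineage,
      seed = seed,
      equilibrium_tag = vapply(results, function(r) r$tag, character(1))
    ),
    draws, reports, tibble::as_tibble(as.data.frame(eqs))
  )
}

#' Screen a uni-lineage virtual cohort
#'
#' Draws `n` Latin hypercube samples of the stem-cell plus lineage-specific
#' parameters, locates each sample's equilibrium, simulates the 7-day
#' chemotherapy protocol on every nontrivial equilibrium, and applies the
#' seven acceptability criteria. Other lineages are out of scope: their
#' states stay at zero and differentiation into them is dropped, so criteria
#' referencing absent states pass vacuously.
#'
#' @param lineage `"N"`, `"L"`, or `"M"`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param params Nominal parameter vector (defaults recomputed from
#'   calibration).
#' @param bounds Sampling bounds; defaults to [default_sampling_bounds()].
#' @param thresholds Criteria thresholds.
#' @param eq_control Optional overrides for [find_equilibrium()]
#'   (e.g. `list(max_horizon = 3000)`).
#' @return A cohort tibble: one row per sample with the sampled parameter
#'   values, `equilibrium_tag` (`nontrivial`, `trivial`, `none`, `invalid`),
#'   criteria flags `c1`..`c7`, `accepted`, diagnostics, and the equilibrium
#'   state (`eq_*` columns).
#' @export
screen_unilineage <- function(lineage, n, seed = 1,
                              params = calibrate_nominal(),
                              bounds = default_sampling_bounds(lineage, params),
                              thresholds = criteria_thresholds(),
                              eq_control = list()) {
  lineage <- match.arg(lineage, c("N", "L", "M"))
  if (n == 0) {
    return(.assemble_cohort(lhs_sample(bounds, 1, seed)[0, ], list(), lineage, seed))
  }
  draws <- lhs_sample(bounds, n, seed)
  results <- lapply(seq_len(n), function(i) {
    .screen_one(draws[i, ], params, .scope_lineages(lineage), thresholds,
                eq_control)
  })
  .assemble_cohort(draws, results, lineage, seed)
}

#' Screen the multi-lineage virtual cohort
#'
#' As [screen_unilineage()], but on the integrated model with all three
#' lineages active and all criteria applied to every lineage. When separatrix
#' `constraints` are supplied, Latin hypercube proposals are filtered by
#' rejection until `n` survivors are collected, concentrating the screen in
#' the parameter region the uni-lineage cohorts found viable.
#'
#' @inheritParams screen_unilineage
#' @param constraints Optional list of separatrix constraints
#'   (see [fit_separatrix()]).
#' @param max_batches Proposal batches to attempt before declaring the
#'   constraint set infeasible (acceptance below ~0.1 percent).
#' @return A cohort tibble (see [screen_unilineage()]); attribute
#'   `proposal_acceptance` records the constraint filter's acceptance rate.
#' @export
screen_multilineage <- function(n, seed = 1, constraints = NULL,
                                params = calibrate_nominal(),
                                bounds = default_sampling_bounds("multi", params),
                                thresholds = criteria_thresholds(),
                                eq_control = list(), max_batches = 50) {
  filter <- constrain_sampler(constraints)
  kept <- NULL
  proposed <- 0L
  batch_seed <- seed
  batch_size <- max(as.integer(2 * n), 500L)
  for (b in seq_len(max_batches)) {
    props <- lhs_sample(bounds, batch_size, batch_seed)
    ok <- filter(props)
    proposed <- proposed + nrow(props)
    kept <- dplyr::bind_rows(kept, props[ok, ])
    if (nrow(kept) >= n) break
    if (proposed >= 1e5 && nrow(kept) / proposed < 0.001) {
      stop("separatrix constraints reject > 99.9% of proposals; infeasible",
           call. = FALSE)
    }
    batch_seed <- batch_seed + 1000L
  }
  if (nrow(kept) < n) {
    stop("could not collect enough constrained proposals", call. = FALSE)
  }
  draws <- kept[seq_len(n), ]
  results <- lapply(seq_len(n), function(i) {
    .screen_one(draws[i, ], params, c("N", "L", "M"), thresholds, eq_control)
  })
  out <- .assemble_cohort(draws, results, "multi", seed)
  attr(out, "proposal_acceptance") <- nrow(kept) / proposed
  out
}

#' Compare overshoot between multi- and uni-lineage accepted cohorts
#'
#' Pools per-state post-chemotherapy overshoot ratios (stem plus each
#' in-scope circulating lineage) over the accepted rows of each arm and
#' tests, one-sided, whether the multi-lineage arm has smaller overshoot
#' than the uni-lineage arm (Wilcoxon rank-sum). The comparison is
#' state-matched: a uni-lineage cohort contributes only the states it
#' models, so the arms are not biased by the multi-lineage model simply
#' having more states to overshoot.
#'
#' @param uni Named list of uni-lineage cohort tibbles.
#' @param multi Multi-lineage cohort tibble.
#' @return List: `p_value`, `n_multi`, `n_uni`, `median_multi`,
#'   `median_uni`.
#' @export
compare_overshoot <- function(uni, multi) {
  pull_over <- function(co) {
    cols <- intersect(c("overshoot_S", "overshoot_Npb", "overshoot_L3pb",
                        "overshoot_Mpb"), names(co))
    v <- unlist(co[co$accepted, cols])
    v[is.finite(v)]
  }
  u <- unlist(lapply(uni, pull_over))
  m <- pull_over(multi)
  stopifnot(length(u) > 0, length(m) > 0)
  wt <- stats::wilcox.test(m, u, alternative = "less", exact = FALSE)
  list(p_value = wt$p.value, n_multi = length(m), n_uni = length(u),
       median_multi = stats::median(m), median_uni = stats::median(u))
}
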