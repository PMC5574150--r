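# Untreated AML progression in virtual patients: clonal initiation from one
# cancer stem cell, clinical endpoint scoring (diagnosis at >20% blasts,
# death at the lethal marrow density), empirical survival curves, and the
# cancer-parameter screens.

#' AML endpoint thresholds
#'
#' @return Named list: `blast_fraction` (diagnosis at >20\% blasts in marrow
#'   or blood), `stem_min` (cancer stem concentration must exceed 1 cell/uL
#'   for diagnosis), `death_conc` (death when the cancer concentration in
#'   marrow or blood exceeds 3e5 cells/uL, the theoretical maximal marrow
#'   density), `seed_concentration` (one cancer stem cell in ~5 L of blood,
#'   2e-4 cells/uL).
#' @export
aml_thresholds <- function() {
  list(blast_fraction = 0.2, stem_min = 1, death_conc = 3e5,
       seed_concentration = 2e-4)
}

#' Initiate AML in a healthy virtual patient
#'
#' Seeds the cancer progenitor state of a healthy equilibrium with one
#' cancer stem cell (as a concentration) and integrates forward. The clone
#' carries the supplied cancer parameters (defaulting to the patient's own
#' source-lineage rates) with all homeostatic feedback removed and no
#' recruitment back. Integration halts early, via a root function, once the
#' leukemic burden is far beyond the lethal density - every clinical
#' endpoint has been crossed by then.
#'
#' @param params Named healthy parameter vector.
#' @param equilibrium Healthy equilibrium state (cancer states must be 0).
#' @param cancer_params Optional named vector overriding any of `dMc`,
#'   `aMc2`, `mrMc2`, `mbMc`.
#' @param seed_concentration Initial cancer progenitor concentration
#'   (cells/uL).
#' @param horizon Days to simulate (daily grid).
#' @param cancer_source Lineage the clone mirrors (`"monocyte"` or
#'   `"neutrophil"`); sets the maturation-rate alias and the default cancer
#'   rates.
#' @return A `leuko_trajectory` (possibly ending before `horizon` if the
#'   burden root fires).
#' @export
initiate_aml <- function(params, equilibrium, cancer_params = NULL,
                         seed_concentration = aml_thresholds()$seed_concentration,
                         horizon = 730,
                         cancer_source = c("monocyte", "neutrophil")) {
  cancer_source <- match.arg(cancer_source)
  equilibrium <- setNames(as.numeric(equilibrium), leuko_states())
  if (any(equilibrium[c("Mc2", "Mcbm", "Mcpb")] > 0)) {
    stop("equilibrium already contains cancer cells", call. = FALSE)
  }
  pars <- mirror_cancer_params(validate_params(params), cancer_source)
  if (!is.null(cancer_params)) {
    stopifnot(all(names(cancer_params) %in% c("dMc", "aMc2", "mrMc2", "mbMc")))
    pars[names(cancer_params)] <- as.numeric(cancer_params)
  }
  x0 <- equilibrium
  x0[["Mc2"]] <- seed_concentration
  t_grid <- seq(0, horizon, by = 1)
  pp <- .pack_parms(pars, no_chemo(), c("N", "L", "M"), cancer_source)
  sol <- deSolve::lsodar(
    y = x0, times = t_grid, func = "leuko_derivs", parms = pp,
    dllname = "leukosim", initfunc = "leuko_initmod",
    rootfunc = "leuko_root", nroot = 1L,
    rtol = 1e-6, atol = 1e-9, maxsteps = 20000
  )
  mat <- unclass(sol)[, 1 + seq_len(17), drop = FALSE]
  times_out <- unclass(sol)[, 1]
  mat[mat < 0] <- 0
  colnames(mat) <- leuko_states()
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- tibble::add_column(out, time = times_out, .before = 1)
  attr(out, "params") <- pars
  attr(out, "schedule") <- no_chemo()
  attr(out, "scope") <- c("N", "L", "M")
  attr(out, "cancer_source") <- cancer_source
  attr(out, "diagnostics") <- list(
    ok = TRUE,
    message = if (length(times_out) < length(t_grid)) "halted at burden root" else "ok",
    min_state = min(mat)
  )
  class(out) <- c("leuko_trajectory", class(out))
  out
}

# first time v rises above thr, linearly interpolated between samples
.first_crossing <- function(tt, v, thr) {
  above <- which(v > thr)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(tt[1])
  tt[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (tt[i] - tt[i - 1])
}

#' Score clinical endpoints of an AML trajectory
#'
#' Diagnosis is the first day both conditions hold: blasts exceed 20\% of
#' the marrow or the circulating blood, and the cancer stem concentration
#' exceeds 1 cell/uL. Death is the first day the cancer concentration in the
#' marrow or the blood exceeds 3e5 cells/uL. Crossings are located on the
#' daily grid with linear interpolation; since the untreated clone grows
#' monotonically, each condition stays true once crossed and the diagnosis
#' day is the later of the two condition crossings.
#'
#' @param traj An [initiate_aml()] trajectory.
#' @param thresholds See [aml_thresholds()].
#' @return One-row tibble: `diagnosed`, `diagnosis_day`, `died`,
#'   `death_day`, `survival_days`, `censored`, `peak_blast_pb`.
#' @export
score_outcome <- function(traj, thresholds = aml_thresholds()) {
  m <- as.data.frame(traj)
  tt <- m$time
  bm_cancer <- m$Mc2 + m$Mcbm
  bm_total <- rowSums(m[, .bm_states()])
  pb_cancer <- m$Mcpb
  pb_total <- rowSums(m[, .circulating_pb_states()])
  blast <- pmax(bm_cancer / pmax(bm_total, .Machine$double.eps),
                pb_cancer / pmax(pb_total, .Machine$double.eps))
  t_blast <- .first_crossing(tt, blast, thresholds$blast_fraction)
  t_stem <- .first_crossing(tt, m$Mc2, thresholds$stem_min)
  t_diag <- if (is.na(t_blast) || is.na(t_stem)) NA_real_ else max(t_blast, t_stem)
  t_death <- .first_crossing(tt, pmax(bm_cancer, pb_cancer),
                             thresholds$death_conc)
  # for clones with sub-day doubling the interpolated crossings can land out
  # of order within one grid day; the endpoints then coincide clinically
  if (!is.na(t_diag) && !is.na(t_death)) t_death <- max(t_death, t_diag)
  diagnosed <- !is.na(t_diag)
  died <- !is.na(t_death)
  tibble::tibble(
    diagnosed = diagnosed,
    diagnosis_day = t_diag,
    died = died,
    death_day = t_death,
    survival_days = if (diagnosed && died) t_death - t_diag else NA_real_,
    censored = !(diagnosed && died),
    peak_blast_pb = max(pb_cancer / pmax(pb_total, .Machine$double.eps))
  )
}

#' Empirical survival curves and time-to-death summaries per cluster
#'
#' With every death observed inside the horizon the survival function is the
#' plain empirical one: `S(t)` = fraction of the cluster with death day
#' beyond `t`. Box summaries use the 1.5 IQR outlier rule.
#'
#' @param outcomes Tibble with columns `cluster` and `death_day` (one row
#'   per simulated patient; censored rows are dropped with a message).
#' @return List of tibbles: `curves` (`cluster`, `time`, `survival`) and
#'   `summaries` (`cluster`, `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n_outliers`).
#' @export
survival_curves <- function(outcomes) {
  stopifnot(all(c("cluster", "death_day") %in% names(outcomes)))
  cen <- is.na(outcomes$death_day)
  if (any(cen)) {
    message(sum(cen), " censored patients dropped from survival curves")
    outcomes <- outcomes[!cen, , drop = FALSE]
  }
  curves <- purrr::map_dfr(sort(unique(outcomes$cluster)), function(cl) {
    d <- outcomes$death_day[outcomes$cluster == cl]
    tt <- sort(unique(d))
    tibble::tibble(cluster = cl, time = c(0, tt),
                   survival = c(1, vapply(tt, function(t0) mean(d > t0),
                                          numeric(1))))
  })
  summaries <- outcomes |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$death_day),
      q1 = stats::quantile(.data$death_day, 0.25),
      q3 = stats::quantile(.data$death_day, 0.75),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      whisker_lo = pmax(.data$q1 - 1.5 * (.data$q3 - .data$q1), 0),
      whisker_hi = .data$q3 + 1.5 * (.data$q3 - .data$q1)
    )
  n_out <- vapply(seq_len(nrow(summaries)), function(i) {
    cl <- summaries$cluster[i]
    d <- outcomes$death_day[outcomes$cluster == cl]
    sum(d < summaries$whisker_lo[i] | d > summaries$whisker_hi[i])
  }, numeric(1))
  summaries$n_outliers <- n_out
  list(curves = curves, summaries = summaries)
}

#' Cancer-parameter sampling bounds
#'
#' The screened ranges of the four cancer parameters, anchored on the
#' reference (source-lineage) rates of a given patient: death rate
#' `[1e-4, 1] x d_ref`, self-renewal probability `[0.01 x a_ref, 1]`,
#' mitosis rate `[0.5, 30] x mr_ref` (death and mobilization slower than the
#' healthy lineage, mitosis faster), mobilization `[1e-4, 1] x mb_ref`. The
#' mitosis upper bound is relative to the reference rate by default; set
#' `mr_upper_absolute = TRUE` to cap at an absolute 30/day instead.
#'
#' @param params Patient parameter vector (reference rates are read off it).
#' @param cancer_source `"monocyte"` or `"neutrophil"`.
#' @param mr_upper_absolute Interpret the mitosis upper bound as 30/day.
#' @return Bounds tibble as for [lhs_sample()].
#' @export
cancer_bounds <- function(params, cancer_source = "monocyte",
                          mr_upper_absolute = FALSE) {
  ref <- if (identical(cancer_source, "neutrophil")) {
    c(d = params[["dN"]], a = params[["aN2"]],
      mr = params[["mrN2"]], mb = params[["mbN"]])
  } else {
    c(d = params[["dM"]], a = params[["aM2"]],
      mr = params[["mrM2"]], mb = params[["mbM"]])
  }
  tibble::tibble(
    name = c("dMc", "aMc2", "mrMc2", "mbMc"),
    lower = c(1e-4 * ref[["d"]], 0.01 * ref[["a"]], 0.5 * ref[["mr"]],
              1e-4 * ref[["mb"]]),
    upper = c(ref[["d"]], 1,
              if (mr_upper_absolute) 30 else 30 * ref[["mr"]],
              ref[["mb"]]),
    scale = c("log", "linear", "log", "log")
  )
}

#' Cancer-parameter screen over representative patients
#'
#' For each representative patient, draws a Latin hypercube over the four
#' cancer parameters within [cancer_bounds()], simulates untreated AML from
#' the patient's healthy equilibrium, keeps the diagnosed cases (blasts >
#' 20\% and cancer stem concentration > 1 cell/uL within the diagnosis
#' window), and correlates each cancer parameter with the clinical endpoint
#' per cluster and pooled. The default endpoint is the number of days until
#' death at the lethal marrow/blood density, and the default statistic is
#' the Spearman rank correlation - consistent with the rank-based
#' sensitivity analysis used elsewhere in the workflow and robust to the
#' hyperbolic dependence of lifetime on the clone's net growth rate.
#' Post-diagnosis survival and Pearson correlation (log10 scale for rates,
#' raw scale for the self-renewal probability) are available through the
#' arguments.
#'
#' @param representatives Tibble with one row per representative: a
#'   `cluster` column, the sampled healthy parameter columns, and the
#'   equilibrium `eq_*` columns (as produced by the screening functions).
#' @param params Nominal parameter vector completing the unsampled entries.
#' @param n_per Cancer draws per representative (625 at full scale).
#' @param seed Integer seed.
#' @param cancer_source Source lineage of the clone.
#' @param fix_mitosis Hold `mrMc2` at its reference value and sample only
#'   the other three parameters (the constrained screen).
#' @param horizon Simulation horizon per patient (days).
#' @param diagnosis_window Only cases diagnosed within this many days count
#'   as diagnosed (365: the clone is left to accumulate for one year).
#' @param thresholds See [aml_thresholds()].
#' @param method Correlation method (`"spearman"` or `"pearson"`).
#' @param endpoint Correlated endpoint: `"death_day"` (days from cancer
#'   initiation to death) or `"survival_days"` (days from diagnosis to
#'   death).
#' @param mr_upper_absolute See [cancer_bounds()].
#' @return A `leuko_aml_screen`: list with `outcomes` (one row per draw) and
#'   `correlations` (`parameter`, `cluster` - including `"pooled"` -,
#'   `estimate`, `p_value`, `n`, `significant` at p < 0.05).
#' @export
cancer_parameter_screen <- function(representatives,
                                    params = calibrate_nominal(),
                                    n_per = 625, seed = 1,
                                    cancer_source = c("monocyte", "neutrophil"),
                                    fix_mitosis = FALSE,
                                    horizon = 730, diagnosis_window = 365,
                                    thresholds = aml_thresholds(),
                                    method = c("spearman", "pearson"),
                                    endpoint = c("death_day", "survival_days"),
                                    mr_upper_absolute = FALSE) {
  endpoint <- match.arg(endpoint)
  cancer_source <- match.arg(cancer_source)
  method <- match.arg(method)
  sampled_cols <- intersect(.param_roster()$name, names(representatives))
  eq_cols <- paste0("eq_", leuko_states())
  stopifnot(all(eq_cols %in% names(representatives)),
            "cluster" %in% names(representatives))

  outcomes <- purrr::map_dfr(seq_len(nrow(representatives)), function(i) {
    row <- representatives[i, ]
    pars <- params
    pars[sampled_cols] <- as.numeric(row[1, sampled_cols])
    pars <- mirror_cancer_params(pars, cancer_source)
    eq <- setNames(as.numeric(row[1, eq_cols]), leuko_states())
    eq[c("Mc2", "Mcbm", "Mcpb")] <- 0
    bounds <- cancer_bounds(pars, cancer_source, mr_upper_absolute)
    if (fix_mitosis) bounds <- bounds[bounds$name != "mrMc2", ]
    draws <- lhs_sample(bounds, n_per, seed = seed + i)
    if (fix_mitosis) draws$mrMc2 <- pars[["mrMc2"]]
    purrr::map_dfr(seq_len(n_per), function(j) {
      cp <- unlist(draws[j, c("dMc", "aMc2", "mrMc2", "mbMc")])
      traj <- initiate_aml(pars, eq, cancer_params = cp,
                           seed_concentration = thresholds$seed_concentration,
                           horizon = horizon, cancer_source = cancer_source)
      sc <- score_outcome(traj, thresholds)
      dplyr::bind_cols(
        tibble::tibble(cluster = row$cluster, draw = j),
        tibble::as_tibble(as.list(cp)), sc
      )
    })
  })
  outcomes$diagnosed <- outcomes$diagnosed &
    !is.na(outcomes$diagnosis_day) &
    outcomes$diagnosis_day <= diagnosis_window

  corr_params <- c("dMc", "aMc2", "mrMc2", "mbMc")
  if (fix_mitosis) corr_params <- setdiff(corr_params, "mrMc2")
  diagnosed <- outcomes[outcomes$diagnosed & !is.na(outcomes[[endpoint]]), ]
  corr_one <- function(df, label) {
    purrr::map_dfr(corr_params, function(pn) {
      v <- if (pn == "aMc2" || method == "spearman") df[[pn]] else log10(df[[pn]])
      n <- nrow(df)
      if (n < 4 || stats::sd(v) == 0) {
        return(tibble::tibble(parameter = pn, cluster = label,
                              estimate = NA_real_, p_value = NA_real_,
                              n = n, significant = FALSE))
      }
      ct <- suppressWarnings(
        stats::cor.test(v, df[[endpoint]], method = method))
      tibble::tibble(parameter = pn, cluster = label,
                     estimate = unname(ct$estimate), p_value = ct$p.value,
                     n = n, significant = ct$p.value < 0.05)
    })
  }
  correlations <- dplyr::bind_rows(
    purrr::map_dfr(sort(unique(diagnosed$cluster)), function(cl) {
      corr_one(diagnosed[diagnosed$cluster == cl, ], as.character(cl))
    }),
    corr_one(diagnosed, "pooled")
  )
  structure(list(outcomes = outcomes, correlations = correlations,
                 cancer_source = cancer_source, fix_mitosis = fix_mitosis,
                 method = method, endpoint = endpoint, n_per = n_per,
                 seed = seed),
            class = "leuko_aml_screen")
}

#' @export
print.leuko_aml_screen <- function(x, ...) {
  pooled <- x$correlations[x$correlations$cluster == "pooled", ]
  cat(sprintf("<leuko_aml_screen> %s-derived AML, %d draws/patient%s\n",
              x$cancer_source, x$n_per,
              if (x$fix_mitosis) " (mitosis rate fixed)" else ""))
  cat(sprintf("  diagnosed: %d / %d\n", sum(x$outcomes$diagnosed),
              nrow(x$outcomes)))
  print(as.data.frame(pooled), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.leuko_aml_screen <- function(x, ...) {
  x$correlations
}

#' @export
glance.leuko_aml_screen <- function(x, ...) {
  pooled <- x$correlations[x$correlations$cluster == "pooled", ]
  tibble::tibble(
    n_patients = length(unique(x$outcomes$cluster)),
    n_draws = nrow(x$outcomes),
    n_diagnosed = sum(x$outcomes$diagnosed),
    top_parameter = pooled$parameter[which.max(abs(pooled$estimate))],
    top_estimate = pooled$estimate[which.max(abs(pooled$estimate))]
  )
}
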