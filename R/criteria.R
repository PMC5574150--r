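# The seven dynamic acceptability criteria applied to a chemotherapy
# recovery trajectory, plus the diagnostics used to audit them.

#' Default thresholds for the acceptability criteria
#'
#' All clinically meaningful cutoffs in one overrideable list:
#' \describe{
#'   \item{pb_recovery_min}{criterion 1 - final total circulating leukocyte
#'     concentration must exceed this (80 cells/uL).}
#'   \item{stem_range}{criterion 2 - final stem-cell concentration band
#'     (`c(1, 100)` cells/uL); recovery from the nadir must also exceed
#'     `stem_recovery_gain` (fractional).}
#'   \item{pb_ranges}{criterion 3 - final circulating concentration range per
#'     lineage (cells/uL): adult normal ranges for neutrophils, lymphocytes,
#'     monocytes.}
#'   \item{marginal_log10_max}{criterion 4 - maximal absolute log10 ratio of
#'     marginal pool to circulating pool (one order of magnitude).}
#'   \item{depletion_max}{criterion 5 - fraction of the pre-chemo baseline
#'     allowed to remain at the end of chemotherapy (20\%).}
#'   \item{overshoot_max}{criterion 6 - recovery overshoot must be below this
#'     multiple (12) of the value five days after the overshoot peak (or the
#'     final value if the simulation ends sooner).}
#'   \item{osc_threshold}{criterion 7 - oscillation damping threshold (0.18).}
#'   \item{osc_form}{`"damping"` (default): a solution is sufficiently damped
#'     when the second post-chemo peak amplitude has decreased by at least
#'     `osc_threshold` relative to the first, i.e. `A2 <= (1 - 0.18) * A1`;
#'     `"deviation"`: symmetric form `|A2 - A1| / A1 < 0.18`.}
#'   \item{peak_guard}{peaks closer than this fraction (1\%) above the final
#'     value are ignored as numerical ripple.}
#' }
#' @return Named list of thresholds.
#' @export
criteria_thresholds <- function() {
  list(
    pb_recovery_min = 80,
    stem_range = c(1, 100),
    stem_recovery_gain = 0.05,
    pb_ranges = list(N = c(1500, 8000), L = c(1000, 4800), M = c(200, 800)),
    marginal_log10_max = 1,
    depletion_max = 0.2,
    overshoot_max = 12,
    osc_threshold = 0.18,
    osc_form = "damping",
    peak_guard = 0.01
  )
}

# local maxima of v (daily grid), keeping only peaks above final*(1+guard)
.find_peaks <- function(v, guard, final) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  idx[v[idx] > final * (1 + guard) & v[idx] > 0]
}

# overshoot ratio: post-chemo maximum over its value five days later
# (or the final value, whichever comes first)
.overshoot_ratio <- function(tt, v) {
  imax <- which.max(v)
  t_ref <- tt[imax] + 5
  ref <- if (t_ref >= tt[length(tt)]) {
    v[length(v)]
  } else {
    stats::approx(tt, v, xout = t_ref)$y
  }
  max(v) / max(ref, .Machine$double.eps)
}

#' Evaluate the seven acceptability criteria on a recovery trajectory
#'
#' Applies the seven dynamic acceptability criteria to a chemotherapy
#' protocol trajectory (see [run_chemo_protocol()]):
#' peripheral blood recovery above 80 cells/uL (c1); stem-cell recovery into
#' the 1-100 cells/uL band with a post-nadir increase (c2); final circulating
#' counts per lineage inside clinical normal ranges (c3); marginal pools
#' within one order of magnitude of the circulating pool for neutrophils and
#' monocytes (c4); depletion below 20\% of baseline at the end of
#' chemotherapy (c5); recovery overshoot below 12 times the value five days
#' after the peak (c6); and sufficiently damped post-chemotherapy
#' oscillations (c7). Criteria c5-c7 are applied to the stem cells and to
#' each in-scope circulating lineage; a failure in any one state fails the
#' criterion. Criteria referencing absent states pass vacuously (e.g. c4 for
#' a lymphocyte-only model, which has no marginal pool).
#'
#' @param traj A `leuko_trajectory` covering the protocol window (chemo start
#'   through recovery; at least daily sampling through day 150).
#' @param thresholds See [criteria_thresholds()].
#' @return A one-row tibble: logicals `c1`..`c7`, `accepted` (their
#'   conjunction), and diagnostics (`pb_total_final`, `stem_final`,
#'   `stem_nadir`, `nadir_frac_max`, `overshoot_ratio_max`, `peak1`, `peak2`,
#'   `n_peaks_max`).
#' @export
evaluate_acceptability <- function(traj, thresholds = criteria_thresholds()) {
  stopifnot(inherits(traj, "leuko_trajectory"))
  th <- thresholds
  schedule <- attr(traj, "schedule")
  scope <- attr(traj, "scope")
  tt <- traj$time
  if (max(tt) - schedule$end < 100 || max(diff(tt[tt <= schedule$end + 150])) > 1 + 1e-8) {
    stop("trajectory too short or too coarse for criteria evaluation", call. = FALSE)
  }
  diag_ok <- attr(traj, "diagnostics")$ok

  m <- as.data.frame(traj)
  final <- unlist(m[nrow(m), leuko_states()])
  baseline <- unlist(m[1, leuko_states()])
  i_end <- which.min(abs(tt - schedule$end))
  at_end <- unlist(m[i_end, leuko_states()])
  post <- m[tt >= schedule$end, , drop = FALSE]

  pb_map <- c(N = "Npb", L = "L3pb", M = "Mpb")
  mp_map <- c(N = "Nmp", M = "Mmp")
  pb_states <- unname(pb_map[intersect(c("N", "L", "M"), scope)])
  eval_states <- c("S", pb_states)

  # c1: total circulating leukocytes recover
  pb_total_final <- sum(final[.circulating_pb_states()])
  c1 <- pb_total_final > th$pb_recovery_min

  # c2: stem cells recover into band, with a post-nadir increase
  stem_post <- post$S
  stem_nadir <- min(stem_post)
  c2 <- final[["S"]] >= th$stem_range[1] && final[["S"]] <= th$stem_range[2] &&
    final[["S"]] > stem_nadir * (1 + th$stem_recovery_gain)

  # c3: final circulating counts within clinical ranges, per in-scope lineage
  c3 <- all(vapply(intersect(c("N", "L", "M"), scope), function(l) {
    rng <- th$pb_ranges[[l]]
    v <- final[[pb_map[[l]]]]
    v >= rng[1] && v <= rng[2]
  }, logical(1)))

  # c4: marginal pool within one order of magnitude of circulating pool
  # (neutrophils and monocytes; no lymphocyte marginal pool exists)
  c4 <- all(vapply(intersect(c("N", "M"), scope), function(l) {
    mp <- final[[mp_map[[l]]]]
    pb <- final[[pb_map[[l]]]]
    if (mp <= 0 || pb <= 0) return(FALSE)
    abs(log10(mp) - log10(pb)) <= th$marginal_log10_max
  }, logical(1)))

  # c5: depletion at the end of chemotherapy
  nadir_frac <- at_end[eval_states] / pmax(baseline[eval_states], .Machine$double.eps)
  c5 <- all(nadir_frac < th$depletion_max)

  # c6: recovery overshoot bounded
  over <- vapply(eval_states, function(s) .overshoot_ratio(post$time, post[[s]]),
                 numeric(1))
  c6 <- all(over < th$overshoot_max)

  # c7: damped oscillations, measured on post-chemo peak amplitudes about the
  # final value; fewer than two significant peaks passes vacuously
  peak_info <- lapply(eval_states, function(s) {
    v <- post[[s]]
    idx <- .find_peaks(v, th$peak_guard, final[[s]])
    amps <- v[idx] - final[[s]]
    amps[amps > 0]
  })
  c7 <- all(vapply(peak_info, function(amps) {
    if (length(amps) < 2) return(TRUE)
    a1 <- amps[1]; a2 <- amps[2]
    if (identical(th$osc_form, "deviation")) {
      abs(a2 - a1) / a1 < th$osc_threshold
    } else {
      a2 <= (1 - th$osc_threshold) * a1
    }
  }, logical(1)))

  over_named <- setNames(rep(NA_real_, 4), c("S", "Npb", "L3pb", "Mpb"))
  over_named[eval_states] <- over
  worst <- which.max(over)
  first_amps <- peak_info[[which.max(vapply(peak_info, length, integer(1)))]]
  out <- tibble::tibble(
    c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6, c7 = c7,
    accepted = diag_ok && c1 && c2 && c3 && c4 && c5 && c6 && c7,
    pb_total_final = pb_total_final,
    stem_final = final[["S"]],
    final_Npb = final[["Npb"]],
    final_L3pb = final[["L3pb"]],
    final_Mpb = final[["Mpb"]],
    stem_nadir = stem_nadir,
    nadir_frac_max = max(nadir_frac),
    overshoot_ratio_max = max(over),
    overshoot_state = eval_states[worst],
    overshoot_S = over_named[["S"]],
    overshoot_Npb = over_named[["Npb"]],
    overshoot_L3pb = over_named[["L3pb"]],
    overshoot_Mpb = over_named[["Mpb"]],
    peak1 = if (length(first_amps) >= 1) first_amps[1] else NA_real_,
    peak2 = if (length(first_amps) >= 2) first_amps[2] else NA_real_,
    n_peaks_max = max(vapply(peak_info, length, integer(1)))
  )
  out
}

#' Simulate the standard chemotherapy protocol from an equilibrium
#'
#' Runs the model from a (nontrivial) equilibrium through the default 7-day
#' induction course starting at day -7, with daily output through day 150 and
#' monthly output to day 300 - dense enough for all seven criteria.
#'
#' @param params Named parameter vector.
#' @param equilibrium Equilibrium state vector (cells/uL).
#' @param schedule A [chemo_schedule()].
#' @param scope Active lineages.
#' @param t_end Final simulated day (default 300).
#' @return A `leuko_trajectory`.
#' @export
run_chemo_protocol <- function(params, equilibrium,
                               schedule = chemo_schedule(),
                               scope = c("N", "L", "M"), t_end = 300) {
  t_grid <- protocol_grid(start = schedule$start, t_end = t_end)
  simulate_model(params, equilibrium, t_grid, schedule = schedule,
                 scope = scope)
}

#' Protocol time grid
#'
#' Daily samples from `start` (default day -7) through day 150, then one
#' sample every 30 days to `t_end`. With the defaults this is the 162-point
#' grid used for trajectory normalization and clustering.
#'
#' @param start First day (default -7).
#' @param t_end Last day (default 300).
#' @return Numeric vector of days.
#' @export
protocol_grid <- function(start = -7, t_end = 300) {
  c(seq(start, 150, by = 1), seq(180, t_end, by = 30))
}
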