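# Core ODE machinery: chemotherapy schedule, reference derivatives, stiff
# integration through deSolve (compiled RHS), equilibrium location.

#' Chemotherapy schedule
#'
#' Induction chemotherapy is modelled as a one-compartment pharmacokinetic
#' problem: a constant-rate drug infusion between `start` and `end` (default
#' day -7 to day 0, i.e. a 7-day course ending when the recovery clock
#' starts) with first-order elimination. The pharmacodynamic effect is a
#' linear log-kill on the masked states, with killed cells routed into the
#' apoptotic-debris state.
#'
#' @param start,end Infusion window (days); `end` must exceed `start`.
#' @param infusion Infusion rate (drug units/day). Zero disables chemo.
#' @param kill_states Character vector of states subject to the drug;
#'   defaults to every state except macrophages and debris.
#' @return An object of class `chemo_schedule`.
#' @export
chemo_schedule <- function(start = -7, end = 0, infusion = 1,
                           kill_states = .default_kill_states()) {
  stopifnot(end > start, infusion >= 0)
  bad <- setdiff(kill_states, leuko_states())
  if (length(bad) > 0) stop("unknown kill states: ", paste(bad, collapse = ", "))
  structure(
    list(start = start, end = end, infusion = infusion,
         kill_states = kill_states),
    class = "chemo_schedule"
  )
}

#' No-chemotherapy schedule
#' @return A `chemo_schedule` with zero infusion.
#' @export
no_chemo <- function() chemo_schedule(infusion = 0)

#' Drug concentration under a chemotherapy schedule
#'
#' Closed-form solution of the one-compartment pharmacokinetic model:
#' zero before the infusion starts, saturating rise
#' `(I/kel) * (1 - exp(-kel * (t - start)))` during the infusion, and
#' exponential washout after it ends. Continuous in `t`.
#'
#' @param t Time (days); vectorised.
#' @param schedule A [chemo_schedule()].
#' @param kel Elimination rate (1/day), > 0.
#' @return Drug level (arbitrary units), same length as `t`.
#' @export
chemo_concentration <- function(t, schedule, kel) {
  stopifnot(inherits(schedule, "chemo_schedule"), kel > 0)
  plateau <- schedule$infusion / kel
  at_end <- plateau * (1 - exp(-kel * (schedule$end - schedule$start)))
  out <- numeric(length(t))
  during <- t > schedule$start & t <= schedule$end
  after <- t > schedule$end
  out[during] <- plateau * (1 - exp(-kel * (t[during] - schedule$start)))
  out[after] <- at_end * exp(-kel * (t[after] - schedule$end))
  out
}

# Pack parameters + schedule + lineage scope into the flat numeric vector
# consumed by both RHS implementations. Layout documented in src/leuko_rhs.c.
.pack_parms <- function(params, schedule = no_chemo(),
                        scope = c("N", "L", "M"),
                        cancer_source = "monocyte") {
  p <- validate_params(params)
  mask <- as.numeric(leuko_states() %in% schedule$kill_states)
  c(unname(p),
    .cancer_smc(p, cancer_source),
    schedule$start, schedule$end, schedule$infusion,
    as.numeric("N" %in% scope), as.numeric("L" %in% scope),
    as.numeric("M" %in% scope),
    mask)
}

#' Reference derivatives of the 17-state model
#'
#' Pure-R implementation of the model right-hand side, used as the readable
#' reference and for term-level testing; production integration uses the
#' compiled equivalent. Each state's derivative is the sum of its production
#' terms (asymmetric self-renewal, maturation influx), movement terms
#' (mobilization, recruitment, margination, demargination, each inhibited by
#' the destination compartment's concentration), and loss terms (natural
#' death, chemotherapy kill). Stem self-renewal is inhibited by the stem
#' concentration and by total live marrow occupancy relative to capacity;
#' progenitor self-renewal by the same-lineage circulating mature cells.
#' Macrophages are driven by monocyte activation and debris (positive
#' feedback) and in turn assist tissue recruitment and debris clearance.
#' The leukemic clone follows the monocyte-form equations with every
#' homeostatic feedback removed and no recruitment back; its growth is
#' unregulated exponential, ending only at the lethal marrow density (a
#' clinical endpoint scored downstream, not a brake in the equations).
#'
#' @param t Time (days).
#' @param x Named or unnamed state vector of length 17 (canonical order).
#' @param params Named parameter vector (see [leuko_parameters()]).
#' @param schedule A [chemo_schedule()].
#' @param scope Active lineages; differentiation influx into lineages
#'   outside the scope is dropped.
#' @param cancer_source Lineage the leukemic clone mirrors for its
#'   maturation rate.
#' @return Named numeric vector of derivatives (cells/uL/day).
#' @export
leuko_derivatives <- function(t, x, params, schedule = no_chemo(),
                              scope = c("N", "L", "M"),
                              cancer_source = "monocyte") {
  if (any(!is.finite(x))) stop("non-finite state values", call. = FALSE)
  if (any(x < -1e-6)) stop("state vector has negative entries", call. = FALSE)
  pp <- .pack_parms(params, schedule, scope, cancer_source)
  x <- pmax(as.numeric(x), 0)
  names(x) <- leuko_states()
  p <- validate_params(params)
  g <- function(nm) p[[nm]]

  chemo <- chemo_concentration(t, schedule, g("kel"))
  mask <- as.numeric(leuko_states() %in% schedule$kill_states)
  kill <- g("kkill") * chemo * mask * x
  BM <- sum(x[.bm_states()])

  aSe <- g("aS") * negative_feedback(g("kS"), x[["S"]]) *
    negative_feedback(g("kBM"), BM / g("Kbm"))
  sr_S <- self_renewal_fluxes(g("aS"), g("mrS"), x[["S"]],
                              inhibition = aSe / g("aS"))
  d <- numeric(17)
  names(d) <- leuko_states()
  d["S"] <- sr_S$net - g("dS") * x[["S"]] - kill[["S"]]

  fM <- 1 - g("fN") - g("fL")
  recMAC <- positive_feedback(g("kMAC"), x[["MAC"]])
  scopeN <- as.numeric("N" %in% scope)
  scopeL <- as.numeric("L" %in% scope)
  scopeM <- as.numeric("M" %in% scope)

  # neutrophils
  aNe <- g("aN2") * negative_feedback(g("kN"), x[["Npb"]])
  sr_N <- self_renewal_fluxes(g("aN2"), g("mrN2"), x[["N2"]],
                              inhibition = aNe / g("aN2"))
  matN <- sr_N$out + g("sN2") * x[["N2"]]
  FmobN <- g("mbN") * negative_feedback(g("kmovN"), x[["Npb"]]) * x[["Nbm"]]
  FrecN <- g("rN") * recMAC * negative_feedback(g("kmovN"), x[["Nbm"]]) * x[["Npb"]]
  FmgN <- g("mgN") * negative_feedback(g("kmovN"), x[["Nmp"]]) * x[["Npb"]]
  FdmN <- g("dmN") * negative_feedback(g("kmovN"), x[["Npb"]]) * x[["Nmp"]]
  d["N2"] <- scopeN * g("fN") * sr_S$out + sr_N$net -
    g("sN2") * x[["N2"]] - g("d2") * x[["N2"]] - kill[["N2"]]
  d["Nbm"] <- matN - FmobN + FrecN - g("dN") * x[["Nbm"]] - kill[["Nbm"]]
  d["Npb"] <- FmobN + FdmN - FmgN - FrecN - g("dN") * x[["Npb"]] - kill[["Npb"]]
  d["Nmp"] <- FmgN - FdmN - g("dN") * x[["Nmp"]] - kill[["Nmp"]]

  # lymphocytes
  aLe <- g("aL2") * negative_feedback(g("kL"), x[["L3pb"]])
  sr_L <- self_renewal_fluxes(g("aL2"), g("mrL2"), x[["L2"]],
                              inhibition = aLe / g("aL2"))
  matL <- sr_L$out + g("sL2") * x[["L2"]]
  FmobL <- g("mbL") * negative_feedback(g("kmovL"), x[["L3pb"]]) * x[["L3"]]
  FrecL <- g("rL") * recMAC * negative_feedback(g("kmovL"), x[["L3"]]) * x[["L3pb"]]
  d["L2"] <- scopeL * g("fL") * sr_S$out + sr_L$net -
    g("sL2") * x[["L2"]] - g("d2") * x[["L2"]] - kill[["L2"]]
  d["L3"] <- matL - FmobL + FrecL - g("dL3") * x[["L3"]] - kill[["L3"]]
  d["L3pb"] <- FmobL - FrecL - g("dL3pb") * x[["L3pb"]] - kill[["L3pb"]]

  # monocytes
  aMe <- g("aM2") * negative_feedback(g("kM"), x[["Mpb"]])
  sr_M <- self_renewal_fluxes(g("aM2"), g("mrM2"), x[["M2"]],
                              inhibition = aMe / g("aM2"))
  matM <- sr_M$out + g("sM2") * x[["M2"]]
  FmobM <- g("mbM") * negative_feedback(g("kmovM"), x[["Mpb"]]) * x[["Mbm"]]
  FrecM <- g("rM") * recMAC * negative_feedback(g("kmovM"), x[["Mbm"]]) * x[["Mpb"]]
  FmgM <- g("mgM") * negative_feedback(g("kmovM"), x[["Mmp"]]) * x[["Mpb"]]
  FdmM <- g("dmM") * negative_feedback(g("kmovM"), x[["Mpb"]]) * x[["Mmp"]]
  Fact <- g("actMAC") * x[["Mpb"]]
  d["M2"] <- scopeM * fM * sr_S$out + sr_M$net -
    g("sM2") * x[["M2"]] - g("d2") * x[["M2"]] - kill[["M2"]]
  d["Mbm"] <- matM - FmobM + FrecM - g("dM") * x[["Mbm"]] - kill[["Mbm"]]
  d["Mpb"] <- FmobM + FdmM - FmgM - FrecM - Fact - g("dMpb") * x[["Mpb"]] - kill[["Mpb"]]
  d["Mmp"] <- FmgM - FdmM - g("dMpb") * x[["Mmp"]] - kill[["Mmp"]]

  # macrophages and debris
  d["MAC"] <- Fact + g("prMAC") * positive_feedback(g("kA"), x[["A"]]) * x[["MAC"]] -
    g("dMAC") * x[["MAC"]]
  d["A"] <- sum(kill) - g("clA") * positive_feedback(g("kMAC"), x[["MAC"]]) * x[["A"]]

  # leukemic clone (feedback-free: no homeostatic regulation, no capacity
  # gate - the lethal marrow density is a clinical endpoint, not a brake)
  sMc <- .cancer_smc(p, cancer_source)
  d["Mc2"] <- (2 * g("aMc2") - 1) * g("mrMc2") * x[["Mc2"]] -
    sMc * x[["Mc2"]] - g("dMc") * x[["Mc2"]] - kill[["Mc2"]]
  d["Mcbm"] <- 2 * (1 - g("aMc2")) * g("mrMc2") * x[["Mc2"]] +
    sMc * x[["Mc2"]] - g("mbMc") * x[["Mcbm"]] - g("dMc") * x[["Mcbm"]] - kill[["Mcbm"]]
  d["Mcpb"] <- g("mbMc") * x[["Mcbm"]] - g("dMc") * x[["Mcpb"]] - kill[["Mcpb"]]

  d
}

#' Simulate the model on a time grid
#'
#' Stiff-capable integration (deSolve `lsoda`, compiled right-hand side,
#' relative tolerance 1e-6, absolute tolerance 1e-9 cells/uL). Sub-tolerance
#' negative excursions are floored to zero in the returned trajectory;
#' larger excursions or solver failures flag the trajectory instead of being
#' hidden.
#'
#' @param params Named parameter vector.
#' @param x0 Initial state: named or unnamed numeric vector of length 17,
#'   non-negative.
#' @param t_grid Strictly increasing time grid (days).
#' @param schedule A [chemo_schedule()].
#' @param scope Active lineages (see [leuko_derivatives()]).
#' @param cancer_source Lineage mirrored by the leukemic clone.
#' @param rtol,atol Solver tolerances.
#' @return A `leuko_trajectory`: a tibble with a `time` column and the 17
#'   state columns, plus attributes `params`, `schedule`, `scope`, and
#'   `diagnostics` (list with `ok`, `message`, `min_state`).
#' @export
simulate_model <- function(params, x0, t_grid, schedule = no_chemo(),
                           scope = c("N", "L", "M"),
                           cancer_source = "monocyte",
                           rtol = 1e-6, atol = 1e-9) {
  stopifnot(length(x0) == 17, all(diff(t_grid) > 0))
  if (any(!is.finite(x0)) || any(x0 < 0)) {
    stop("initial state must be finite and non-negative", call. = FALSE)
  }
  x0 <- stats::setNames(as.numeric(x0), leuko_states())
  pp <- .pack_parms(params, schedule, scope, cancer_source)

  sol <- try(deSolve::lsoda(
    y = x0, times = t_grid, func = "leuko_derivs", parms = pp,
    dllname = "leukosim", initfunc = "leuko_initmod",
    rtol = rtol, atol = atol, maxsteps = 20000
  ), silent = TRUE)

  ok <- TRUE
  msg <- "ok"
  if (inherits(sol, "try-error")) {
    ok <- FALSE
    msg <- paste("solver error:", attr(sol, "condition")$message)
    mat <- matrix(NA_real_, nrow = length(t_grid), ncol = 17)
    times_out <- t_grid
  } else {
    mat <- unclass(sol)[, -1, drop = FALSE]
    times_out <- unclass(sol)[, 1]
    if (nrow(mat) < length(t_grid) || any(!is.finite(mat))) {
      ok <- FALSE
      msg <- "integration did not span the requested grid"
      pad <- length(t_grid) - nrow(mat)
      if (pad > 0) {
        mat <- rbind(mat, matrix(NA_real_, nrow = pad, ncol = 17))
        times_out <- t_grid
      }
    }
  }
  min_state <- suppressWarnings(min(mat, na.rm = TRUE))
  if (ok && min_state < -1e-6) {
    ok <- FALSE
    msg <- sprintf("negative excursion beyond solver floor (%.3g)", min_state)
  }
  mat[is.finite(mat) & mat < 0] <- 0
  colnames(mat) <- leuko_states()

  out <- tibble::as_tibble(as.data.frame(mat))
  out <- tibble::add_column(out, time = times_out, .before = 1)
  attr(out, "params") <- validate_params(params)
  attr(out, "schedule") <- schedule
  attr(out, "scope") <- scope
  attr(out, "cancer_source") <- cancer_source
  attr(out, "diagnostics") <- list(ok = ok, message = msg, min_state = min_state)
  class(out) <- c("leuko_trajectory", class(out))
  out
}

#' @export
print.leuko_trajectory <- function(x, ...) {
  diag <- attr(x, "diagnostics")
  cat(sprintf("<leuko_trajectory> %d time points, day %.4g to %.4g [%s]\n",
              nrow(x), min(x$time), max(x$time),
              if (isTRUE(diag$ok)) "ok" else diag$message))
  NextMethod()
}

#' Locate an equilibrium by long-horizon integration
#'
#' Integrates the model without chemotherapy in windows until the residual
#' `max |dx/dt|` falls below `tol * max(x)` (the infinity-norm residual
#' criterion), then classifies the endpoint: `"trivial"` if every state is
#' below `eps`, `"nontrivial"` if converged with some state above `eps`,
#' `"none"` if the horizon is exhausted or the solver fails (as happens for
#' stiff parameter draws).
#'
#' @param params Named parameter vector.
#' @param x0 Initial state (length 17, non-negative).
#' @param scope Active lineages.
#' @param max_horizon Total integration horizon (days).
#' @param window Window length between residual checks (days).
#' @param tol Relative residual tolerance.
#' @param eps Concentration below which a state counts as extinct (cells/uL).
#' @return A list with `state` (named vector), `tag` (`"nontrivial"`,
#'   `"trivial"`, `"none"`), `residual`, and `days` integrated.
#' @export
find_equilibrium <- function(params, x0, scope = c("N", "L", "M"),
                             max_horizon = 4000, window = 400,
                             tol = 1e-6, eps = 1e-6) {
  stopifnot(length(x0) == 17)
  x <- stats::setNames(pmax(as.numeric(x0), 0), leuko_states())
  elapsed <- 0
  resid <- Inf
  while (elapsed < max_horizon) {
    traj <- simulate_model(params, x,
                           t_grid = c(0, window / 2, window - 1, window),
                           schedule = no_chemo(), scope = scope)
    diag <- attr(traj, "diagnostics")
    if (!isTRUE(diag$ok)) {
      return(list(state = x, tag = "none", residual = NA_real_,
                  days = elapsed, message = diag$message))
    }
    prev <- as.numeric(traj[nrow(traj) - 1, leuko_states()])
    x <- stats::setNames(as.numeric(traj[nrow(traj), leuko_states()]),
                         leuko_states())
    elapsed <- elapsed + window
    scale <- max(x, eps)
    if (all(x < eps)) {
      return(list(state = x, tag = "trivial", residual = max(abs(x - prev)),
                  days = elapsed))
    }
    # cheap convergence probe: state change over the window's final day
    if (max(abs(x - prev)) <= tol * scale) {
      rhs <- leuko_derivatives(0, x, params, schedule = no_chemo(),
                               scope = scope)
      resid <- max(abs(rhs))
      if (resid <= tol * scale) {
        return(list(state = x, tag = "nontrivial", residual = resid,
                    days = elapsed))
      }
    }
  }
  list(state = x, tag = "none", residual = resid, days = elapsed)
}
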