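# Nominal parameter calibration.
#
# Fitted parameter values for this class of model are not portable between
# reconstructions, so the package derives its own nominal set by construction:
# fix the seven literature death rates, pick clinically normal homeostatic
# concentrations, and back-solve the remaining rates and Michaelis constants
# from steady-state flux balance at those concentrations. The resulting set is
# then polished by long-horizon integration (find_equilibrium) and verified
# against the seven acceptability criteria by make_nominal_fixture().

#' Clinically normal homeostatic target concentrations
#'
#' Default cell concentrations (cells/uL) used as the operating point of the
#' calibration: circulating neutrophils 3000, lymphocytes 2000, monocytes 400
#' (all well inside adult normal ranges), marginal pools equal to the
#' circulating pools, marrow reserves a small multiple of the circulating
#' pools, stem cells 10 (inside the accepted 1-100 band), and an empty
#' debris/cancer compartment.
#'
#' @return Named numeric vector over the 17 states.
#' @export
calibration_targets <- function() {
  c(S = 10,
    N2 = 3000, Nbm = 6000, Npb = 3000, Nmp = 3000,
    L2 = 1700, L3 = 4000, L3pb = 2000,
    M2 = 340, Mbm = 800, Mpb = 400, Mmp = 400,
    MAC = 80, A = 0,
    Mc2 = 0, Mcbm = 0, Mcpb = 0)
}

#' Literature-fixed death rates
#'
#' The seven death rates fixed from literature ranges rather than sampled
#' (1/day): progenitors (`d2`), mature neutrophils (`dN`, shared across
#' marrow, blood and marginal pool), lymphocytes in the tissue/thymus (`dL3`,
#' high because of thymic selection) and in the blood (`dL3pb`, long-lived),
#' monocytes in the marrow (`dM`) and blood/marginal pool (`dMpb`), and
#' activated macrophages (`dMAC`).
#'
#' @return Named numeric vector of length 7.
#' @export
literature_death_rates <- function() {
  c(d2 = 0.05, dN = 0.25, dL3 = 0.4, dL3pb = 0.02,
    dM = 0.1, dMpb = 0.3, dMAC = 0.05)
}

#' Back-solve a nominal parameter set from steady-state balance
#'
#' Given target homeostatic concentrations and the fixed death rates, choose
#' structural rates (mitosis, maturation, margination) at physiologic orders
#' of magnitude and solve the remaining mobilization rates, self-renewal
#' probabilities, and Michaelis constants so that every compartment's fluxes
#' balance at the targets. Michaelis constants are placed so feedback factors
#' sit on the responsive part of their curves at the operating point (the
#' slope there is what damps post-chemotherapy oscillations).
#'
#' @param targets Named state vector of homeostatic concentrations.
#' @param deaths Named vector of the seven fixed death rates.
#' @return Named parameter vector of length 51 (canonical order).
#' @export
calibrate_nominal <- function(targets = calibration_targets(),
                              deaths = literature_death_rates()) {
  tg <- targets
  d <- deaths
  p <- c()

  # --- protocol constants -------------------------------------------------
  Kbm <- 3e5           # marrow capacity, cells/uL
  kkill <- 1.2         # chemo kill coefficient, 1/(drug unit * day)
  kel <- 1.0           # drug elimination, 1/day

  # --- stem cells ---------------------------------------------------------
  mrS <- 0.3; dS <- 0.01; aS <- 0.7
  aSe <- (1 + dS / mrS) / 2                   # balances (2a-1)mr = dS
  BMstar <- sum(tg[.bm_states()])
  fb_S <- 0.85                                 # chosen split of the inhibition
  kS <- tg[["S"]] * fb_S / (1 - fb_S)
  fb_BM <- (aSe / aS) / fb_S
  occ <- BMstar / Kbm
  kBM <- occ * fb_BM / (1 - fb_BM)
  outS <- 2 * (1 - aSe) * mrS * tg[["S"]]      # total differentiation flux

  # --- macrophages (needed for recruitment factors) -----------------------
  actMAC <- 0.01; kMAC <- 100; prMAC <- 0.2; kA <- 500; clA <- 1
  # MAC* = actMAC * Mpb* / dMAC at A = 0; targets are chosen consistent
  recMAC <- tg[["MAC"]] / (kMAC + tg[["MAC"]])

  # --- per-lineage back-solve ----------------------------------------------
  solve_myeloid <- function(pre, bm, pb, mp, d_bm, d_pb, d_mp, influx,
                            mr, s2, a2, kmov, dm_rate, r_rate,
                            extra_pb_loss = 0) {
    # progenitor: influx + ((2a_eff-1)mr - s2 - d2) * pre = 0
    a_eff <- (s2 + d[["d2"]] - influx / pre) / (2 * mr) + 0.5
    stopifnot(a_eff > 0.5, a_eff < a2)
    k2 <- pb * (a_eff / a2) / (1 - a_eff / a2)
    mat <- 2 * (1 - a_eff) * mr * pre + s2 * pre
    Frec <- r_rate * recMAC * negative_feedback(kmov, bm) * pb
    Fdm <- dm_rate * negative_feedback(kmov, pb) * mp
    Fmg <- Fdm + d_mp * mp
    mg_rate <- Fmg / (negative_feedback(kmov, mp) * pb)
    Fmob <- mat + Frec - d_bm * bm
    stopifnot(Fmob > 0)
    mb_rate <- Fmob / (negative_feedback(kmov, pb) * bm)
    # check circulating balance closes (residual absorbed by equilibration)
    list(a2 = a2, mr = mr, s2 = s2, k2 = k2, mb = mb_rate, r = r_rate,
         mg = mg_rate, dm = dm_rate, kmov = kmov, a_eff = a_eff)
  }

  # lineage split fractions
  fN <- 0.5; fL <- 0.3

  N <- solve_myeloid(pre = tg[["N2"]], bm = tg[["Nbm"]], pb = tg[["Npb"]],
                     mp = tg[["Nmp"]], d_bm = d[["dN"]], d_pb = d[["dN"]],
                     d_mp = d[["dN"]], influx = fN * outS,
                     mr = 1.0, s2 = 0.2, a2 = 0.8, kmov = 15000,
                     dm_rate = 0.5, r_rate = 0.1)

  M <- solve_myeloid(pre = tg[["M2"]], bm = tg[["Mbm"]], pb = tg[["Mpb"]],
                     mp = tg[["Mmp"]], d_bm = d[["dM"]], d_pb = d[["dMpb"]],
                     d_mp = d[["dMpb"]], influx = (1 - fN - fL) * outS,
                     mr = 1.0, s2 = 0.2, a2 = 0.8, kmov = 2000,
                     dm_rate = 0.5, r_rate = 0.1,
                     extra_pb_loss = actMAC * tg[["Mpb"]])

  # lymphocytes: no marginal pool
  mrL <- 1.0; sL <- 0.2; aL <- 0.8; kmovL <- 10000; rL <- 0.1
  a_effL <- (sL + d[["d2"]] - fL * outS / tg[["L2"]]) / (2 * mrL) + 0.5
  kL <- tg[["L3pb"]] * (a_effL / aL) / (1 - a_effL / aL)
  matL <- 2 * (1 - a_effL) * mrL * tg[["L2"]] + sL * tg[["L2"]]
  FrecL <- rL * recMAC * negative_feedback(kmovL, tg[["L3"]]) * tg[["L3pb"]]
  FmobL <- FrecL + d[["dL3pb"]] * tg[["L3pb"]]
  mbL <- FmobL / (negative_feedback(kmovL, tg[["L3pb"]]) * tg[["L3"]])

  p <- c(
    aS = aS, mrS = mrS, fN = fN, fL = fL, kS = unname(kS), kBM = unname(kBM),
    dS = dS,
    aN2 = N$a2, mrN2 = N$mr, sN2 = N$s2, kN = unname(N$k2), mbN = unname(N$mb),
    rN = N$r, mgN = unname(N$mg), dmN = N$dm, kmovN = N$kmov,
    aL2 = aL, mrL2 = mrL, sL2 = sL, kL = unname(kL), mbL = unname(mbL),
    rL = rL, kmovL = kmovL,
    aM2 = M$a2, mrM2 = M$mr, sM2 = M$s2, kM = unname(M$k2), mbM = unname(M$mb),
    rM = M$r, mgM = unname(M$mg), dmM = M$dm, kmovM = M$kmov,
    actMAC = actMAC, prMAC = prMAC, kA = kA, kMAC = kMAC, clA = clA,
    kkill = kkill, kel = kel, Kbm = Kbm,
    dMc = 0, aMc2 = 0, mrMc2 = 0, mbMc = 0
  )
  p <- c(p, d)
  p <- mirror_cancer_params(p, "monocyte")
  validate_params(p)
}
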