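# Synthetic fixtures: every input the pipeline and its tests need is
# generated in code - the calibrated nominal patient, pseudo transplant
# recovery panels standing in for clinical recovery data (which are not
# redistributable), labelled point clouds for the separatrix oracle, and
# planted-cluster dynamics for the clustering oracle.

#' Build and verify the calibrated nominal fixture
#'
#' Runs the steady-state calibration, locates the equilibrium by
#' long-horizon integration, simulates the standard chemotherapy protocol,
#' and checks all seven acceptability criteria. Calibration failure (no
#' nontrivial equilibrium, or any criterion failing) is an explicit error
#' with the offending diagnostics attached.
#'
#' @param targets Homeostatic target concentrations
#'   (see [calibration_targets()]).
#' @param thresholds Criteria thresholds.
#' @return List with `params` (51 named values), `equilibrium` (17 named
#'   values), and `report` (the one-row acceptability tibble).
#' @export
make_nominal_fixture <- function(targets = calibration_targets(),
                                 thresholds = criteria_thresholds()) {
  params <- calibrate_nominal(targets)
  eq <- find_equilibrium(params, targets)
  if (!identical(eq$tag, "nontrivial")) {
    stop("nominal calibration failed: equilibrium tag = ", eq$tag,
         " (residual ", format(eq$residual), ")", call. = FALSE)
  }
  traj <- run_chemo_protocol(params, eq$state)
  report <- evaluate_acceptability(traj, thresholds)
  if (!isTRUE(report$accepted)) {
    failing <- paste0("c", which(!unlist(report[paste0("c", 1:7)])))
    stop("nominal fixture fails criteria: ",
         paste(failing, collapse = ", "), call. = FALSE)
  }
  list(params = params, equilibrium = eq$state, report = report)
}

#' Pseudo transplant-recovery patient panel
#'
#' Emulates a panel of per-patient daily absolute neutrophil, lymphocyte and
#' monocyte counts over ~60 days after marrow-ablating treatment: each
#' synthetic patient is the nominal model simulated through the
#' chemotherapy protocol with patient-specific recovery speed, an overshoot
#' peak in a configurable minority of patients, and multiplicative lognormal
#' measurement noise. Overshoot magnitudes respect the empirical 12x bound
#' (peak over the value five days later).
#'
#' @param n_patients Number of synthetic patients.
#' @param overshoot_fraction Fraction of patients whose neutrophil recovery
#'   overshoots (default 0.15: roughly 40 of 47 patients show none).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 disables noise).
#' @param seed Integer seed.
#' @param days Days of follow-up post-treatment.
#' @return A `pseudo_hsct_panel` tibble: `patient`, `day`, `neutrophils`,
#'   `lymphocytes`, `monocytes` (cells/uL), `overshoot` flag.
#' @export
make_pseudo_hsct_panel <- function(n_patients = 47, overshoot_fraction = 0.15,
                                   noise_cv = 0.2, seed = 1, days = 60) {
  stopifnot(overshoot_fraction >= 0, overshoot_fraction <= 1, noise_cv >= 0)
  fixture <- make_nominal_fixture()
  set.seed(seed)
  overshoot <- stats::runif(n_patients) < overshoot_fraction
  sdlog <- sqrt(log(1 + noise_cv^2))
  base_params <- fixture$params

  purrr::map_dfr(seq_len(n_patients), function(i) {
    pars <- base_params
    # patient-to-patient recovery variation: mildly scaled mitosis rates;
    # overshooting patients carry weaker peripheral-blood feedback
    speed <- exp(stats::rnorm(1, 0, 0.15))
    pars[c("mrN2", "mrL2", "mrM2")] <- pars[c("mrN2", "mrL2", "mrM2")] * speed
    if (overshoot[i]) pars[["kN"]] <- pars[["kN"]] * 3
    eq <- find_equilibrium(pars, fixture$equilibrium)
    state0 <- if (identical(eq$tag, "nontrivial")) eq$state else fixture$equilibrium
    traj <- simulate_model(pars, state0, t_grid = seq(-7, days, by = 1),
                           schedule = chemo_schedule())
    m <- as.data.frame(traj)
    m <- m[m$time >= 0, ]
    noise <- function(n) {
      if (noise_cv == 0) rep(1, n) else stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    clip12 <- function(v) {
      # enforce the empirical overshoot bound by flattening the peak until
      # it is below 12x its value five days later
      for (it in 1:5) {
        ratio <- .overshoot_ratio(m$time, v)
        if (!is.finite(ratio) || ratio <= 12) break
        imax <- which.max(v)
        ref <- v[imax] / ratio
        v <- pmin(v, 11.9 * ref)
      }
      v
    }
    nr <- nrow(m)
    tibble::tibble(
      patient = i, day = m$time,
      neutrophils = clip12(m$Npb * noise(nr)),
      lymphocytes = m$L3pb * noise(nr),
      monocytes = m$Mpb * noise(nr),
      overshoot = overshoot[i]
    )
  })
}

#' Labelled point cloud with a known log-space boundary
#'
#' Test oracle for the separatrix method: points uniform in a log10-space
#' box, labelled acceptable exactly when they fall below the line
#' `log10(y) = slope * log10(x) + intercept`.
#'
#' @param slope,intercept Boundary line in log10 coordinates.
#' @param box List with `x` and `y` log10 ranges.
#' @param n Number of points.
#' @param seed Integer seed.
#' @param flip Label the points *above* the line acceptable instead.
#' @return Tibble `x`, `y` (raw scale), `acceptable`, with the ground truth
#'   stored in attributes `slope`, `intercept`, `flip`.
#' @export
make_separatrix_oracle <- function(slope = -1, intercept = 0,
                                   box = list(x = c(-1, 1), y = c(-1, 1)),
                                   n = 10000, seed = 1, flip = FALSE) {
  set.seed(seed)
  lx <- stats::runif(n, box$x[1], box$x[2])
  ly <- stats::runif(n, box$y[1], box$y[2])
  below <- ly < slope * lx + intercept
  acc <- if (flip) !below else below
  out <- tibble::tibble(x = 10^lx, y = 10^ly, acceptable = acc)
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  attr(out, "flip") <- flip
  out
}

#' Planted-cluster normalized dynamics
#'
#' Test oracle for trajectory clustering: `k_true` smooth template recovery
#' shapes over the 162-point grid, each replicated with bounded noise.
#'
#' @param k_true Number of planted clusters.
#' @param n_per Members per cluster.
#' @param separation Distance between templates (0 collapses them).
#' @param seed Integer seed.
#' @param noise Within-cluster perturbation scale.
#' @return A `normalized_dynamics` matrix with attribute `true_labels`.
#' @export
make_planted_clusters <- function(k_true = 3, n_per = 20, separation = 1,
                                  seed = 1, noise = 0.02) {
  stopifnot(separation >= 0, k_true >= 1)
  set.seed(seed)
  grid <- cluster_grid()
  ng <- length(grid)
  states <- leuko_states()
  templates <- lapply(seq_len(k_true), function(j) {
    # recovery-like curves differing in timing and overshoot by `separation`
    t50 <- 20 + separation * 15 * (j - 1)
    peak <- 1 + separation * 0.3 * (j %% 2)
    vapply(seq_along(states), function(s) {
      base <- 1 / (1 + exp(-(grid - t50) / 6))
      wave <- 1 + (peak - 1) * exp(-(grid - t50 - 15)^2 / 200)
      v <- base * wave
      v / max(v)
    }, numeric(ng))
  })
  rows <- lapply(seq_len(k_true * n_per), function(i) {
    j <- ((i - 1) %/% n_per) + 1
    v <- templates[[j]] + matrix(stats::runif(ng * length(states),
                                              -noise, noise), ng)
    v <- pmax(v, 0)
    v <- apply(v, 2, function(col) col / max(max(col), 1e-12))
    as.numeric(v)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- as.character(seq_len(nrow(mat)))
  colnames(mat) <- as.vector(outer(seq_len(ng), states,
                                   function(i, s) paste0(s, "@", grid[i])))
  structure(mat, grid = grid, run_ids = rownames(mat),
            state_max = NULL,
            true_labels = rep(seq_len(k_true), each = n_per),
            class = c("normalized_dynamics", "matrix", "array"))
}
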