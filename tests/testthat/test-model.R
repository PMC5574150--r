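test_that("chemotherapy pharmacokinetics follow the closed form", {
  sch <- chemo_schedule(start = -7, end = 0, infusion = 1)
  expect_equal(chemo_concentration(-10, sch, kel = 1), 0)
  # saturating rise: 5 days into the infusion at unit rates
  expect_equal(chemo_concentration(-2, sch, kel = 1), 1 - exp(-5))
  # continuous at the end of infusion, then exponential washout
  c_end <- chemo_concentration(0, sch, kel = 1)
  expect_equal(chemo_concentration(3, sch, kel = 1), c_end * exp(-3))
  expect_lt(chemo_concentration(40, sch, kel = 1), 1e-16)
})

test_that("extinction is a fixed point and derivatives stay finite", {
  p <- nominal_params()
  d0 <- leuko_derivatives(0, rep(0, 17), p)
  expect_equal(unname(d0), rep(0, 17))
  d1 <- leuko_derivatives(0, rep(0, 17), p, schedule = chemo_schedule(),
                          scope = "N")
  expect_equal(unname(d1), rep(0, 17))
  expect_error(leuko_derivatives(0, rep(-1, 17), p), "negative")
})

test_that("compiled and reference right-hand sides produce the same dynamics", {
  p <- nominal_params()
  x0 <- nominal_equilibrium() * 0.4  # off equilibrium so dynamics are active
  sch <- chemo_schedule()
  grid <- seq(-7, 23, 1)
  tr_c <- simulate_model(p, x0, t_grid = grid, schedule = sch)

  r_fun <- function(t, y, parms) {
    list(unname(leuko_derivatives(t, y, p, schedule = sch)))
  }
  sol_r <- deSolve::lsoda(y = setNames(as.numeric(x0), leuko_states()),
                          times = grid, func = r_fun, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
  for (s in c("S", "Npb", "L3pb", "Mpb", "A", "MAC")) {
    expect_equal(tr_c[[s]], pmax(unclass(sol_r)[, s], 0),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("mass bookkeeping holds on the progenitor production terms", {
  # symbolically on the RHS: with all movement, death and chemo terms zeroed
  # the progenitor derivative plus its maturation influx equals mr * X
  p <- nominal_params()
  p[c("sN2", "d2", "dN", "mbN", "rN", "mgN", "dmN", "dS")] <- 0
  p[["mrS"]] <- 0
  x <- setNames(rep(0, 17), leuko_states())
  x["N2"] <- 1000; x["Npb"] <- 2000
  d <- leuko_derivatives(0, x, p)
  aNe <- p[["aN2"]] * negative_feedback(p[["kN"]], x[["Npb"]])
  expect_equal(d[["N2"]], (2 * aNe - 1) * p[["mrN2"]] * 1000)
  expect_equal(d[["Nbm"]], 2 * (1 - aNe) * p[["mrN2"]] * 1000)
  expect_equal(d[["N2"]] + d[["Nbm"]], p[["mrN2"]] * 1000)
})

test_that("simulation from zero stays zero and is deterministic", {
  p <- nominal_params()
  tr <- simulate_model(p, rep(0, 17), t_grid = 0:50)
  expect_true(all(as.matrix(tr[, leuko_states()]) == 0))

  x0 <- nominal_equilibrium()
  tr1 <- simulate_model(p, x0, t_grid = seq(0, 100, 5))
  tr2 <- simulate_model(p, x0, t_grid = seq(0, 100, 5))
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
})

test_that("trajectories respect non-negativity within the solver floor", {
  p <- nominal_params()
  set.seed(11)
  bounds <- default_sampling_bounds("N", p)
  draws <- lhs_sample(bounds, 8, seed = 11)
  for (i in seq_len(nrow(draws))) {
    pars <- p
    pars[names(draws)] <- as.numeric(draws[i, ])
    if (pars[["fN"]] + pars[["fL"]] > 0.98) next
    tr <- simulate_model(pars, leukosim:::.x0_for_scope("N"),
                         t_grid = seq(-7, 100, 1),
                         schedule = chemo_schedule(), scope = "N")
    vals <- as.matrix(tr[, leuko_states()])
    expect_true(all(is.na(vals) | vals >= 0))
    expect_gte(attr(tr, "diagnostics")$min_state, -1e-6)
  }
})

test_that("equilibrium finder classifies trivial, nontrivial and divergent", {
  p <- nominal_params()
  expect_identical(find_equilibrium(p, rep(0, 17))$tag, "trivial")

  eq <- find_equilibrium(p, calibration_targets())
  expect_identical(eq$tag, "nontrivial")
  # infinity-norm residual criterion at the classified equilibrium
  rhs <- leuko_derivatives(0, eq$state, p)
  expect_lte(max(abs(rhs)), 1e-6 * max(eq$state))
  # stem cells inside the accepted clinical band
  expect_gte(eq$state[["S"]], 1)
  expect_lte(eq$state[["S"]], 100)

  # pure self-renewal with no effective feedback diverges: no equilibrium
  div <- p
  div[c("aS", "aN2", "aL2", "aM2")] <- 1
  div[c("kS", "kN", "kL", "kM")] <- 1e12
  div[["kBM"]] <- 1e12
  res <- find_equilibrium(div, calibration_targets(), max_horizon = 800,
                          window = 400)
  expect_identical(res$tag, "none")
})

test_that("lineage scoping decouples the sub-models exactly", {
  p <- nominal_params()
  x0 <- leukosim:::.x0_for_scope("N")
  grid <- seq(-7, 150, 1)
  tr_scoped <- simulate_model(p, x0, t_grid = grid,
                              schedule = chemo_schedule(), scope = "N")
  # absent lineages stay identically zero under the scope mask
  expect_equal(max(tr_scoped$L3pb), 0)
  expect_equal(max(tr_scoped$Mpb), 0)
  # cross-feedback neutrality: the scoped trajectory is bitwise independent
  # of the absent lineages' parameters
  p2 <- p
  p2[c("aL2", "mrL2", "kL", "mbL", "aM2", "mrM2", "kM", "mbM",
       "actMAC", "prMAC")] <-
    p2[c("aL2", "mrL2", "kL", "mbL", "aM2", "mrM2", "kM", "mbM",
         "actMAC", "prMAC")] * c(1.2, 3, 0.1, 5, 1.1, 2, 10, 0.2, 4, 0.5)
  tr_scoped2 <- simulate_model(p2, x0, t_grid = grid,
                               schedule = chemo_schedule(), scope = "N")
  expect_identical(tr_scoped$Npb, tr_scoped2$Npb)
  expect_identical(tr_scoped$S, tr_scoped2$S)
  # whereas in full scope those lineages repopulate from stem flux
  tr_full <- simulate_model(p, x0, t_grid = grid,
                            schedule = chemo_schedule(),
                            scope = c("N", "L", "M"))
  expect_gt(max(tr_full$L3pb), 0)
})
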