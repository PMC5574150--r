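# Criteria are evaluated on constructed trajectories whose pass/fail status
# is known by arithmetic, plus the calibrated fixture as an end-to-end case.

# build a synthetic leuko_trajectory from per-state series on a daily grid
synthetic_traj <- function(series, t_end = 300, schedule = chemo_schedule()) {
  grid <- protocol_grid(t_end = t_end)
  m <- matrix(0, nrow = length(grid), ncol = 17,
              dimnames = list(NULL, leuko_states()))
  for (s in names(series)) {
    v <- series[[s]]
    m[, s] <- if (is.function(v)) v(grid) else rep_len(v, length(grid))
  }
  out <- tibble::as_tibble(as.data.frame(m))
  out <- tibble::add_column(out, time = grid, .before = 1)
  attr(out, "schedule") <- schedule
  attr(out, "scope") <- c("N", "L", "M")
  attr(out, "diagnostics") <- list(ok = TRUE, message = "ok", min_state = 0)
  class(out) <- c("leuko_trajectory", class(out))
  out
}

# clinically normal shape: baseline at chemo start, exponential decline to
# the nadir at chemo end, sigmoid recovery back to the level
recovery <- function(level, nadir_frac = 0.01, t50 = 25) {
  function(t) {
    during <- level * nadir_frac^(pmax(t + 7, 0) / 7)
    after <- level * (nadir_frac +
                        (1 - nadir_frac) / (1 + exp(-(t - t50) / 6)))
    ifelse(t <= 0, during, pmax(after, level * nadir_frac))
  }
}

normal_series <- function() {
  list(S = recovery(10), Npb = recovery(3000), Nmp = recovery(3000),
       L3pb = recovery(2000), Mpb = recovery(400), Mmp = recovery(400))
}

test_that("a constant trajectory passes all criteria except depletion", {
  tr <- synthetic_traj(list(S = 10, Npb = 3000, Nmp = 3000, L3pb = 2000,
                            Mpb = 400, Mmp = 400))
  rep <- evaluate_acceptability(tr)
  expect_true(rep$c1); expect_false(rep$c2)  # no nadir, no recovery
  expect_true(rep$c3); expect_true(rep$c4)
  expect_false(rep$c5)                       # no depletion under chemo
  expect_true(rep$c6); expect_true(rep$c7)
  expect_false(rep$accepted)
})

test_that("a normal recovery passes all seven criteria", {
  rep <- evaluate_acceptability(synthetic_traj(normal_series()))
  expect_true(all(unlist(rep[paste0("c", 1:7)])))
  expect_true(rep$accepted)
})

test_that("each criterion fails on its targeted violation", {
  base <- normal_series()

  # c1: peripheral blood fails to recover above 80 cells/uL
  s <- base
  s$Npb <- recovery(30); s$Nmp <- recovery(30); s$L3pb <- recovery(20)
  s$Mpb <- recovery(10); s$Mmp <- recovery(10)
  th <- criteria_thresholds()
  th$pb_ranges <- list(N = c(0, 8000), L = c(0, 4800), M = c(0, 800))
  r <- evaluate_acceptability(synthetic_traj(s), thresholds = th)
  expect_false(r$c1)

  # c2: stem cells settle outside the 1-100 band
  s <- base; s$S <- recovery(300)
  expect_false(evaluate_acceptability(synthetic_traj(s))$c2)

  # c3: neutrophilia at the final time
  s <- base; s$Npb <- recovery(12000)
  expect_false(evaluate_acceptability(synthetic_traj(s))$c3)

  # c4: marginal pool more than one order of magnitude off
  s <- base; s$Nmp <- recovery(3000 * 15)
  expect_false(evaluate_acceptability(synthetic_traj(s))$c4)

  # c5: insufficient depletion (nadir at 30% of baseline)
  s <- base; s$Npb <- recovery(3000, nadir_frac = 0.3)
  expect_false(evaluate_acceptability(synthetic_traj(s))$c5)
})

test_that("overshoot criterion rejects a sharp spike and passes a mild one", {
  base <- normal_series()
  # peak ~16x its value five days later: reject (threshold 12)
  s <- base
  s$Npb <- function(t) {
    recovery(3000)(t) * (1 + 49 * exp(-(t - 40)^2 / 8))
  }
  r <- evaluate_acceptability(synthetic_traj(s))
  expect_gt(r$overshoot_ratio_max, 12)
  expect_false(r$c6)

  # mild overshoot passes
  s <- base
  s$Npb <- function(t) recovery(3000)(t) * (1 + 0.5 * exp(-(t - 40)^2 / 100))
  expect_true(evaluate_acceptability(synthetic_traj(s))$c6)
})

test_that("oscillation criterion distinguishes damped from sustained", {
  base <- normal_series()
  osc <- function(decay) {
    function(t) {
      v <- recovery(3000, t50 = 15)(t)
      mod <- ifelse(t > 40,
                    1 + 0.4 * exp(-decay * (t - 40)) *
                      cos(2 * pi * (t - 40) / 30),
                    1)
      pmax(v * mod, 0)
    }
  }
  # decay 0.05/day: second peak ~22% of the first -> sufficiently damped
  s <- base; s$Npb <- osc(0.05)
  r_damped <- evaluate_acceptability(synthetic_traj(s))
  expect_gte(r_damped$n_peaks_max, 2)
  expect_true(r_damped$c7)

  # near-zero decay: consecutive peaks nearly equal -> sustained, rejected
  s <- base; s$Npb <- osc(0.001)
  r_sus <- evaluate_acceptability(synthetic_traj(s))
  expect_false(r_sus$c7)

  # the symmetric deviation form gives the opposite verdicts on the same
  # two shapes (second peak within 18% of the first passes)
  th <- criteria_thresholds(); th$osc_form <- "deviation"
  s <- base; s$Npb <- osc(0.05)
  expect_false(evaluate_acceptability(synthetic_traj(s), th)$c7)
  s <- base; s$Npb <- osc(0.001)
  expect_true(evaluate_acceptability(synthetic_traj(s), th)$c7)
})

test_that("the calibrated fixture passes end to end", {
  fix <- nominal_fixture()
  expect_true(fix$report$accepted)
  expect_gte(fix$equilibrium[["S"]], 1)
  expect_lte(fix$equilibrium[["S"]], 100)
})

test_that("criteria evaluation rejects trajectories that are too short", {
  tr <- synthetic_traj(normal_series())
  short <- tr[tr$time <= 50, ]
  attr(short, "schedule") <- attr(tr, "schedule")
  attr(short, "scope") <- attr(tr, "scope")
  attr(short, "diagnostics") <- attr(tr, "diagnostics")
  class(short) <- class(tr)
  expect_error(evaluate_acceptability(short), "short")
})
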