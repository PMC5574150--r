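test_that("AML initiation respects seeding and extinction", {
  p <- nominal_params()
  eq <- nominal_equilibrium()

  # zero seed: cancer stays identically zero
  tr0 <- initiate_aml(p, eq, seed_concentration = 0, horizon = 200)
  expect_equal(max(tr0$Mc2), 0)
  expect_equal(max(tr0$Mcpb), 0)

  # subcritical clone (symmetric division with positive death) goes extinct
  tr_ext <- initiate_aml(p, eq, cancer_params = c(aMc2 = 0.5),
                         horizon = 200)
  expect_lt(tr_ext$Mc2[nrow(tr_ext)], 2e-4)
  expect_false(score_outcome(tr_ext)$diagnosed)

  # seeding a contaminated equilibrium errors
  bad_eq <- eq; bad_eq[["Mc2"]] <- 1
  expect_error(initiate_aml(p, bad_eq), "cancer")
})

test_that("feedback-free growth matches the analytic exponential", {
  p <- nominal_params()
  # isolated clone: start from an empty system so no capacity or blast
  # interactions exist; growth rate is (2a-1)mr - s - d
  x0 <- setNames(rep(0, 17), leuko_states())
  cp <- c(dMc = 0.05, aMc2 = 0.8, mrMc2 = 0.9, mbMc = 0.1)
  lam <- (2 * cp[["aMc2"]] - 1) * cp[["mrMc2"]] - p[["sM2"]] - cp[["dMc"]]
  pars <- p
  pars[names(cp)] <- cp
  x0[["Mc2"]] <- 1
  tr <- simulate_model(pars, x0, t_grid = seq(0, 30, 1))
  expect_equal(tr$Mc2, exp(lam * tr$time), tolerance = 0.01)

  # declining clone when losses beat net self-renewal
  cp2 <- c(dMc = 0.5, aMc2 = 0.55, mrMc2 = 0.5, mbMc = 0.1)
  lam2 <- (2 * cp2[["aMc2"]] - 1) * cp2[["mrMc2"]] - p[["sM2"]] - cp2[["dMc"]]
  expect_lt(lam2, 0)
  pars2 <- p; pars2[names(cp2)] <- cp2
  tr2 <- simulate_model(pars2, x0, t_grid = seq(0, 30, 1))
  expect_equal(tr2$Mc2, exp(lam2 * tr2$time), tolerance = 0.01)
})

test_that("outcome scoring applies the diagnosis and death thresholds", {
  # constructed trajectory: blasts cross 20% at day 100, lethal density at
  # day 160, stem condition crossed early -> survival 60 days
  grid <- 0:200
  m <- matrix(0, length(grid), 17, dimnames = list(NULL, leuko_states()))
  m[, "Nbm"] <- 8000
  m[, "Mc2"] <- 10                       # > 1 cell/uL from the start
  m[, "Mcbm"] <- 2000 * pmin(grid / 100, 1) +
    ifelse(grid > 100, (grid - 100) * 5000, 0)
  tr <- tibble::as_tibble(as.data.frame(m))
  tr <- tibble::add_column(tr, time = grid, .before = 1)
  class(tr) <- c("leuko_trajectory", class(tr))
  # bm blast fraction = Mcbm+Mc2 over marrow total: crosses 0.2 at day ~100
  sc <- score_outcome(tr)
  expect_true(sc$diagnosed)
  expect_equal(sc$diagnosis_day, 100, tolerance = 2)
  expect_equal(sc$death_day, 160, tolerance = 1)
  expect_equal(sc$survival_days, sc$death_day - sc$diagnosis_day)

  # cancer never exceeding 1 cell/uL stays undiagnosed and censored
  m2 <- m; m2[, "Mc2"] <- 0.5; m2[, "Mcbm"] <- 0.1
  tr2 <- tibble::as_tibble(as.data.frame(m2))
  tr2 <- tibble::add_column(tr2, time = grid, .before = 1)
  class(tr2) <- c("leuko_trajectory", class(tr2))
  sc2 <- score_outcome(tr2)
  expect_false(sc2$diagnosed)
  expect_true(sc2$censored)
})

test_that("faster cancer mitosis shortens life, never lengthens it", {
  p <- nominal_params()
  eq <- nominal_equilibrium()
  base <- score_outcome(initiate_aml(p, eq))
  faster <- score_outcome(initiate_aml(
    p, eq, cancer_params = c(mrMc2 = 2 * p[["mrM2"]])))
  expect_true(base$died && faster$died)
  expect_lt(faster$death_day, base$death_day)

  # ordering invariants
  expect_gte(base$survival_days, 0)
  expect_lte(base$diagnosis_day, base$death_day)

  # a grid in mitosis rate: death day is non-increasing
  mrs <- p[["mrM2"]] * c(0.8, 1.5, 3, 6)
  deaths <- vapply(mrs, function(mr) {
    score_outcome(initiate_aml(p, eq, cancer_params = c(mrMc2 = mr)))$death_day
  }, numeric(1))
  expect_true(all(diff(deaths) < 1e-8))
})

test_that("survival curves are proper non-increasing step functions", {
  out <- tibble::tibble(cluster = rep(1:2, each = 5),
                        death_day = c(200, 200, 200, 200, 200,
                                      50, 80, 120, 160, 300))
  sc <- survival_curves(out)
  c1 <- sc$curves[sc$curves$cluster == 1, ]
  expect_equal(c1$survival[c1$time == 0], 1)
  expect_equal(c1$survival[c1$time == 200], 0)
  for (cl in 1:2) {
    s <- sc$curves$survival[sc$curves$cluster == cl]
    expect_true(all(diff(s) <= 0))
  }
  expect_equal(sc$summaries$median[sc$summaries$cluster == 2], 120)
})

test_that("cancer bounds follow the screened ranges per source lineage", {
  p <- nominal_params()
  b <- cancer_bounds(p, "monocyte")
  expect_equal(b$lower[b$name == "dMc"], 1e-4 * p[["dM"]])
  expect_equal(b$upper[b$name == "dMc"], p[["dM"]])
  expect_equal(b$upper[b$name == "aMc2"], 1)
  expect_equal(b$upper[b$name == "mrMc2"], 30 * p[["mrM2"]])
  b_abs <- cancer_bounds(p, "monocyte", mr_upper_absolute = TRUE)
  expect_equal(b_abs$upper[b_abs$name == "mrMc2"], 30)
  b_n <- cancer_bounds(p, "neutrophil")
  expect_equal(b_n$upper[b_n$name == "mbMc"], p[["mbN"]])
})

test_that("the cancer screen correlates parameters with survival sensibly", {
  p <- nominal_params()
  eq <- nominal_equilibrium()
  reps <- tibble::tibble(cluster = 1:2)
  for (s in leuko_states()) reps[[paste0("eq_", s)]] <- eq[[s]]
  scr <- cancer_parameter_screen(reps, params = p, n_per = 40, seed = 3)
  pooled <- scr$correlations[scr$correlations$cluster == "pooled", ]
  est_mr <- pooled$estimate[pooled$parameter == "mrMc2"]
  expect_lt(est_mr, 0)
  expect_true(pooled$significant[pooled$parameter == "mrMc2"])

  # shuffled survival: correlations lose significance
  d <- scr$outcomes[scr$outcomes$diagnosed, ]
  set.seed(1)
  shuf <- cor.test(log10(d$mrMc2), sample(d$survival_days))
  expect_gt(shuf$p.value, 0.001)

  # neutrophil-derived variant only swaps the reference lineage
  scr_n <- cancer_parameter_screen(reps, params = p, n_per = 40, seed = 3,
                                   cancer_source = "neutrophil")
  pooled_n <- scr_n$correlations[scr_n$correlations$cluster == "pooled", ]
  expect_lt(pooled_n$estimate[pooled_n$parameter == "mrMc2"], 0)

  # fixed-mitosis screen: self-renewal becomes the dominant parameter
  scr_f <- cancer_parameter_screen(reps, params = p, n_per = 40, seed = 3,
                                   fix_mitosis = TRUE)
  pooled_f <- scr_f$correlations[scr_f$correlations$cluster == "pooled", ]
  expect_false("mrMc2" %in% pooled_f$parameter)
  best <- pooled_f$parameter[which.max(abs(pooled_f$estimate))]
  expect_identical(best, "aMc2")
})
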