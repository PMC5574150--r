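test_that("Latin hypercube sampling stratifies each marginal", {
  # one parameter, log scale over [1, 16], n = 4: one point per octave
  b <- tibble::tibble(name = "x", lower = 1, upper = 16, scale = "log")
  s <- lhs_sample(b, 4, seed = 9)
  strata <- findInterval(log2(s$x), c(0, 1, 2, 3, 4), rightmost.closed = TRUE)
  expect_setequal(strata, 1:4)

  # fraction bounds respected
  b <- tibble::tibble(name = "a", lower = 0.5, upper = 1, scale = "linear")
  s <- lhs_sample(b, 1000, seed = 2)
  expect_gte(min(s$a), 0.5)
  expect_lte(max(s$a), 1)

  # marginal uniformity: Kolmogorov-Smirnov distance < 0.02 at n = 1e4
  b <- tibble::tibble(name = c("r", "a"),
                      lower = c(0.1, 0), upper = c(10, 1),
                      scale = c("log", "linear"))
  s <- lhs_sample(b, 1e4, seed = 3)
  u_log <- (log(s$r) - log(0.1)) / (log(10) - log(0.1))
  ks <- function(u) max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks(u_log), 0.02)
  expect_lt(ks(s$a), 0.02)

  # reproducibility under the seed
  expect_identical(lhs_sample(b, 50, seed = 7), lhs_sample(b, 50, seed = 7))
})

test_that("the chemo protocol run behaves as the criteria presume", {
  p <- nominal_params()
  eq <- nominal_equilibrium()

  # zero kill rate: the trajectory stays at equilibrium
  p0 <- p; p0[["kkill"]] <- 0
  tr0 <- run_chemo_protocol(p0, eq)
  expect_equal(tr0$Npb[length(tr0$Npb)], eq[["Npb"]], tolerance = 1e-3)
  expect_equal(min(tr0$Npb), eq[["Npb"]], tolerance = 1e-3)

  # nominal kill: nadir below baseline during chemo, recovery after
  tr <- run_chemo_protocol(p, eq)
  rep <- evaluate_acceptability(tr)
  expect_lt(rep$nadir_frac_max, 0.2)
  expect_true(rep$accepted)

  # doubling the kill rate never lessens depletion
  p2 <- p; p2[["kkill"]] <- 2 * p[["kkill"]]
  rep2 <- evaluate_acceptability(run_chemo_protocol(p2, eq))
  expect_lte(rep2$nadir_frac_max, rep$nadir_frac_max + 1e-8)
})

test_that("uni-lineage screening produces a coherent cohort table", {
  co <- test_uni_cohorts()$N
  expect_equal(nrow(co), 1000)
  expect_true(all(co$equilibrium_tag %in%
                    c("nontrivial", "trivial", "none", "invalid")))
  # acceptance decomposes as the conjunction of the stored criteria
  nt <- co[co$equilibrium_tag == "nontrivial", ]
  expect_equal(nt$accepted,
               nt$c1 & nt$c2 & nt$c3 & nt$c4 & nt$c5 & nt$c6 & nt$c7)
  # accepted rows all carry nontrivial equilibria
  expect_true(all(co$equilibrium_tag[co$accepted] == "nontrivial"))
  # empty request gives an empty table
  expect_equal(nrow(screen_unilineage("N", n = 0, params = nominal_params())),
               0)
})

test_that("screening is deterministic under the seed", {
  p <- nominal_params()
  a <- screen_unilineage("M", n = 25, seed = 31, params = p)
  b <- screen_unilineage("M", n = 25, seed = 31, params = p)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("lymphocyte screens pass the marginal-pool criterion vacuously", {
  co <- test_uni_cohorts()$L
  nt <- co[co$equilibrium_tag == "nontrivial", ]
  expect_true(all(nt$c4))
})
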