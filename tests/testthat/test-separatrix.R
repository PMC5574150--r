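test_that("a uniform lattice yields a box-only constraint", {
  # perfectly uniform accepted points: every bin ties the cutoff exactly, so
  # no bin beats it and no corner can be obliquely cut - the constraint
  # degenerates to the bounding box
  g <- expand.grid(x = 10^seq(-0.95, 0.95, length.out = 20),
                   y = 10^seq(-0.95, 0.95, length.out = 20))
  con <- fit_separatrix(g, c("x", "y"))
  expect_length(con$cuts, 0)
  inside <- satisfies_constraint(con, data.frame(x = 1, y = 1))
  expect_true(inside)
  expect_false(satisfies_constraint(con, data.frame(x = 100, y = 1)))
})

test_that("fewer than 100 accepted points degrade to the bounding box", {
  set.seed(5)
  pts <- data.frame(x = 10^runif(50, -1, 1), y = 10^runif(50, -1, 1))
  con <- fit_separatrix(pts, c("x", "y"))
  expect_null(con$grid)
  expect_length(con$cuts, 0)
  expect_error(fit_separatrix(pts[1, ][c(1, 1), ], c("x", "y")), "distinct")
})

test_that("a known linear boundary is recovered within one bin width", {
  for (seed in 1:3) {
    for (slope in c(-0.6, -1, -1.6)) {
      orc <- make_separatrix_oracle(slope = slope, intercept = 0,
                                    n = 10000, seed = seed)
      con <- fit_separatrix(orc[orc$acceptable, ], c("x", "y"))
      expect_gte(length(con$cuts), 1)
      # the cut nearest the excluded upper-right corner should match the
      # boundary: compare global slope and intercept in log10 space
      cut <- con$cuts[["ur"]]
      expect_false(is.null(cut))
      gslope <- cut$sy * cut$slope / cut$sx
      gint <- (cut$y0 + cut$sy * cut$intercept) - gslope * cut$x0
      bin_h <- diff(con$box$y) / con$nbin
      expect_lt(abs(gslope - slope), 0.25)
      expect_lt(abs(gint - 0), bin_h)

      # classification agreement >= 95% away from a one-bin boundary band
      grid <- expand.grid(lx = seq(con$box$x[1] + 1e-6, con$box$x[2] - 1e-6,
                                   length.out = 60),
                          ly = seq(con$box$y[1] + 1e-6, con$box$y[2] - 1e-6,
                                   length.out = 60))
      truth <- grid$ly < slope * grid$lx
      pred <- satisfies_constraint(con, data.frame(x = 10^grid$lx,
                                                   y = 10^grid$ly))
      away <- abs(grid$ly - slope * grid$lx) > bin_h
      expect_gte(mean(pred[away] == truth[away]), 0.95)
    }
  }
})

test_that("satisfies_constraint honours box, cuts and missing columns", {
  orc <- make_separatrix_oracle(n = 5000, seed = 11)
  acc <- orc[orc$acceptable, ]
  con <- fit_separatrix(acc, c("x", "y"))

  # a training point in an acceptable bin is retained
  mid <- acc[which.min(abs(log10(acc$x)) + abs(log10(acc$y) + 0.5)), ]
  expect_true(satisfies_constraint(con, mid))
  # outside the bounding box
  expect_false(satisfies_constraint(con, data.frame(x = 1e4, y = 1)))
  # deep inside the removed corner
  expect_false(satisfies_constraint(
    con, data.frame(x = 10^(con$box$x[2] - 0.01),
                    y = 10^(con$box$y[2] - 0.01))))
  expect_error(satisfies_constraint(con, data.frame(x = 1)), "lack")
})

test_that("conservativeness: most accepted training points are retained", {
  orc <- make_separatrix_oracle(n = 8000, seed = 21)
  acc <- orc[orc$acceptable, ]
  con <- fit_separatrix(acc, c("x", "y"))
  kept <- satisfies_constraint(con, acc)
  # corner cuts may only remove low-density corners: at most 4 * cutoff-share
  # of the accepted points, with slack for staircase geometry
  expect_gte(mean(kept), 0.9)
})

test_that("refitting on filtered points reproduces the bounding box", {
  orc <- make_separatrix_oracle(n = 8000, seed = 31)
  acc <- orc[orc$acceptable, ]
  con <- fit_separatrix(acc, c("x", "y"))
  kept <- acc[satisfies_constraint(con, acc), ]
  con2 <- fit_separatrix(kept, c("x", "y"))
  bin <- c(diff(con$box$x), diff(con$box$y)) / con$nbin
  expect_lt(max(abs(con2$box$x - con$box$x)), bin[1])
  expect_lt(max(abs(con2$box$y - con$box$y)), bin[2])
})

test_that("flipped labels cut the complementary corner", {
  orc <- make_separatrix_oracle(slope = -1, n = 10000, seed = 41, flip = TRUE)
  con <- fit_separatrix(orc[orc$acceptable, ], c("x", "y"))
  expect_false(is.null(con$cuts[["ll"]]))
})

test_that("the rejection filter composes constraints and tracks its rate", {
  # empty constraint list accepts everything
  f0 <- constrain_sampler(NULL)
  pts <- tibble::tibble(x = 10^runif(1000, -1, 1), y = 10^runif(1000, -1, 1))
  expect_true(all(f0(pts)))
  expect_equal(acceptance_rate(f0), 1)

  # one box constraint covering 25% of the proposal box area
  quarter <- expand.grid(x = 10^seq(-0.999, 0, length.out = 40),
                         y = 10^seq(-0.999, 0, length.out = 40))
  con <- fit_separatrix(quarter, c("x", "y"))
  f1 <- constrain_sampler(con)
  set.seed(8)
  props <- tibble::tibble(x = 10^runif(1e4, -1, 1), y = 10^runif(1e4, -1, 1))
  keep <- f1(props)
  expect_equal(mean(keep), 0.25, tolerance = 0.08)

  # no point retained by the oracle filter violates the true boundary by
  # more than one bin width
  orc <- make_separatrix_oracle(n = 10000, seed = 51)
  con_o <- fit_separatrix(orc[orc$acceptable, ], c("x", "y"))
  f2 <- constrain_sampler(list(con_o))
  kept <- props[f2(props), ]
  bin_h <- diff(con_o$box$y) / con_o$nbin
  viol <- log10(kept$y) > -log10(kept$x) + bin_h
  expect_equal(sum(viol), 0)
})
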