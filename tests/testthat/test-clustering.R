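test_that("normalization maps trajectories into [0,1] with unit maxima", {
  p <- nominal_params()
  tr <- run_chemo_protocol(p, nominal_equilibrium())
  nd <- normalize_trajectories(list(a = tr))
  expect_equal(dim(nd), c(1, 17 * 162))
  expect_gte(min(nd), 0)
  expect_lte(max(nd), 1)
  grid <- attr(nd, "grid")
  expect_length(grid, 162)
  # every active state attains its own maximum (1); absent cancer states
  # stay identically zero with no division error
  per_state <- matrix(unclass(nd)[1, ], nrow = 162)
  colnames(per_state) <- leuko_states()
  for (s in c("S", "Npb", "L3pb", "Mpb")) {
    expect_equal(max(per_state[, s]), 1)
  }
  expect_equal(max(per_state[, "Mcpb"]), 0)

  # scale invariance: a 10x scaled trajectory normalizes identically
  tr10 <- tr
  for (s in leuko_states()) tr10[[s]] <- tr10[[s]] * 10
  nd10 <- normalize_trajectories(list(a = tr10))
  expect_equal(unclass(nd)[1, ], unclass(nd10)[1, ], tolerance = 1e-12)

  # idempotence: normalizing an already normalized series changes nothing
  tr_n <- tr
  for (s in leuko_states()) {
    mx <- max(tr_n[[s]]); if (mx > 0) tr_n[[s]] <- tr_n[[s]] / mx
  }
  nd_n <- normalize_trajectories(list(a = tr_n))
  expect_equal(unclass(nd_n)[1, ], unclass(nd)[1, ], tolerance = 1e-9)

  # constant positive series become all-ones rows
  flat <- tr
  for (s in leuko_states()) flat[[s]] <- 5
  nd_f <- normalize_trajectories(list(a = flat))
  expect_true(all(unclass(nd_f) == 1))

  short <- tr[tr$time <= 100, ]
  expect_error(normalize_trajectories(list(a = short)), "cover")
})

test_that("planted clusters are recovered perfectly at high separation", {
  nd <- make_planted_clusters(k_true = 3, n_per = 15, separation = 1.5,
                              seed = 2)
  fit <- cluster_trajectories(nd, k = 3, seed = 4)
  truth <- attr(nd, "true_labels")
  # perfect recovery up to label permutation
  tab <- table(truth, fit$assignment$cluster)
  expect_equal(sum(apply(tab, 1, max)), length(truth))
  # representatives are actual members of their clusters
  for (i in seq_len(3)) {
    rep_id <- fit$representatives$run_id[fit$representatives$cluster == i]
    expect_true(rep_id %in%
                  fit$assignment$run_id[fit$assignment$cluster == i])
  }
  # label recovery is invariant to the seed
  fit2 <- cluster_trajectories(nd, k = 3, seed = 99)
  tab2 <- table(fit$assignment$cluster, fit2$assignment$cluster)
  expect_equal(sum(apply(tab2, 1, max)), length(truth))
})

test_that("k-means edge cases and determinism", {
  nd <- make_planted_clusters(k_true = 2, n_per = 8, separation = 1, seed = 3)
  # k = set size: every point its own cluster, zero WCSS
  fit <- cluster_trajectories(nd, k = nrow(nd), seed = 1)
  expect_equal(fit$wcss, 0, tolerance = 1e-12)
  expect_true(all(fit$sizes == 1))
  # same seed twice: identical assignments
  f1 <- cluster_trajectories(nd, k = 4, seed = 12)
  f2 <- cluster_trajectories(nd, k = 4, seed = 12)
  expect_identical(f1$assignment, f2$assignment)
  # WCSS non-increasing in k for best-of-restarts
  w <- vapply(2:6, function(k) {
    cluster_trajectories(nd, k, seed = 5, n_init = 8)$wcss
  }, numeric(1))
  expect_true(all(diff(w) <= 1e-8))
})

test_that("select_k finds planted structure and accepts a pinned k", {
  nd <- make_planted_clusters(k_true = 3, n_per = 12, separation = 1.5,
                              seed = 6)
  res <- select_k(nd, k_range = 2:6, seed = 2)
  expect_equal(res$k, 3)
  expect_false(res$pinned)

  # a single blob: silhouettes stay low
  blob <- make_planted_clusters(k_true = 1, n_per = 30, separation = 0,
                                seed = 7, noise = 0.05)
  res_b <- select_k(blob, k_range = 2:5, seed = 2)
  expect_lt(max(res_b$diagnostics$silhouette), 0.5)

  res_p <- select_k(nd, k_range = 2:6, seed = 2, pin_k = 5)
  expect_equal(res_p$k, 5)
  expect_true(res_p$pinned)
})

test_that("cluster tidiers expose assignments and diagnostics", {
  nd <- make_planted_clusters(k_true = 2, n_per = 10, separation = 1, seed = 8)
  fit <- cluster_trajectories(nd, k = 2, seed = 3)
  td <- tidy(fit)
  expect_true(all(c("run_id", "cluster", "representative_run") %in% names(td)))
  expect_equal(nrow(td), 20)
  g <- glance(fit)
  expect_equal(g$k, 2)
  expect_equal(g$n, 20)
})
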