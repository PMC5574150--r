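# Shared, lazily computed fixtures. Everything is generated in code; the
# heavier cohort screens are memoised so several test files can share them.

.test_cache <- new.env(parent = emptyenv())

nominal_fixture <- function() {
  if (is.null(.test_cache$fixture)) {
    .test_cache$fixture <- make_nominal_fixture()
  }
  .test_cache$fixture
}

nominal_params <- function() nominal_fixture()$params
nominal_equilibrium <- function() nominal_fixture()$equilibrium

# small uni-lineage cohorts shared between cohort, separatrix and
# acceptance tests
test_uni_cohorts <- function(n = 1000) {
  key <- paste0("uni_", n)
  if (is.null(.test_cache[[key]])) {
    p <- nominal_params()
    .test_cache[[key]] <- lapply(
      stats::setNames(c("N", "L", "M"), c("N", "L", "M")),
      function(l) screen_unilineage(l, n = n, seed = 100 + match(l, c("N", "L", "M")),
                                    params = p)
    )
  }
  .test_cache[[key]]
}

# constrained multi-lineage cohort shared between acceptance tests
test_multi_cohort <- function(n = 2500) {
  key <- paste0("multi_", n)
  if (is.null(.test_cache[[key]])) {
    cons <- fit_cohort_separatrices(test_uni_cohorts(), all_pairs = TRUE)
    .test_cache[[key]] <- screen_multilineage(
      n = n, seed = 777, constraints = cons, params = nominal_params())
  }
  .test_cache[[key]]
}

# representative patients derived from the shared multi cohort (clustered),
# falling back to accepted rows directly if too few for clustering
test_representatives <- function(max_k = 13) {
  if (is.null(.test_cache$reps)) {
    multi <- test_multi_cohort()
    p <- nominal_params()
    acc <- multi[multi$accepted, , drop = FALSE]
    stopifnot(nrow(acc) >= 2)
    k <- min(max_k, floor(nrow(acc) / 2))
    if (k >= 2) {
      trajs <- leukosim:::.cohort_trajectories(multi, p)
      dyn <- normalize_trajectories(trajs)
      cl <- cluster_trajectories(dyn, k = k, seed = 5)
      reps <- dplyr::inner_join(
        dplyr::mutate(cl$representatives, run_id = as.integer(run_id)),
        multi, by = "run_id")
    } else {
      reps <- dplyr::mutate(acc, cluster = seq_len(nrow(acc)))
    }
    .test_cache$reps <- reps
  }
  .test_cache$reps
}
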