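# Representative-patient stratification: normalize each accepted simulation's
# dynamics by its own per-state maxima, then k-means the flattened
# state x time matrices and take the member nearest each centroid as that
# cluster's simulatable representative.

#' The normalization/clustering time grid
#'
#' 162 points: daily from day -7 through day 150, then one point every 30
#' days (180, 210, 240, 270).
#'
#' @return Numeric vector of 162 days.
#' @export
cluster_grid <- function() {
  protocol_grid(start = -7, t_end = 270)
}

#' Normalize cohort trajectories into dynamic space
#'
#' Resamples each trajectory onto the 162-point grid (linear interpolation)
#' and divides each state's series by that simulation's own maximum of the
#' state, yielding entries in `[0, 1]`. States that are identically zero
#' (e.g. cancer states in healthy simulations) stay zero.
#'
#' @param trajs A list of `leuko_trajectory` objects (or data frames with a
#'   `time` column and the 17 state columns), each covering the grid.
#' @param grid Time grid (defaults to [cluster_grid()]).
#' @param run_ids Optional identifiers (defaults to list names or indices).
#' @return A `normalized_dynamics` object: numeric matrix with one row per
#'   simulation and `17 * length(grid)` columns, with attributes `grid`,
#'   `run_ids`, and `state_max` (the per-run normalization constants).
#' @export
normalize_trajectories <- function(trajs, grid = cluster_grid(),
                                   run_ids = NULL) {
  stopifnot(is.list(trajs), length(trajs) >= 1)
  run_ids <- run_ids %||% (names(trajs) %||% as.character(seq_along(trajs)))
  states <- leuko_states()
  rows <- lapply(trajs, function(tr) {
    tr <- as.data.frame(tr)
    if (min(tr$time) > min(grid) + 1e-9 || max(tr$time) < max(grid) - 1e-9) {
      stop("trajectory does not cover the normalization grid", call. = FALSE)
    }
    vals <- vapply(states, function(s) {
      stats::approx(tr$time, tr[[s]], xout = grid)$y
    }, numeric(length(grid)))
    mx <- apply(vals, 2, max)
    scaled <- sweep(vals, 2, ifelse(mx > 0, mx, 1), "/")
    list(flat = as.numeric(scaled), mx = mx)
  })
  mat <- do.call(rbind, lapply(rows, `[[`, "flat"))
  rownames(mat) <- run_ids
  colnames(mat) <- as.vector(outer(seq_along(grid), states,
                                   function(i, s) paste0(s, "@", grid[i])))
  structure(mat,
            grid = grid,
            run_ids = run_ids,
            state_max = do.call(rbind, lapply(rows, `[[`, "mx")),
            class = c("normalized_dynamics", "matrix", "array"))
}

# k-means++ seeding: first centre uniform, then squared-distance weighted
.kmeanspp_centers <- function(mat, k) {
  n <- nrow(mat)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(mat, 2, mat[centers[1], ], "-")^2)
  for (j in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) == 0) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = probs)
    }
    d2 <- pmin(d2, rowSums(sweep(mat, 2, mat[centers[j + 1], ], "-")^2))
  }
  mat[centers, , drop = FALSE]
}

#' Cluster normalized dynamics into representative patients
#'
#' Lloyd's k-means on the flattened state-by-time vectors with Euclidean
#' distance, k-means++ style seeding, and the best of `n_init` restarts by
#' within-cluster sum of squares. Deterministic under a fixed seed. Each
#' cluster's representative is the actual member nearest its centroid (so it
#' remains simulatable, with a real generating parameter set).
#'
#' @param dynamics A [normalize_trajectories()] result.
#' @param k Number of clusters (>= 1, <= number of simulations).
#' @param seed Integer seed.
#' @param n_init Number of restarts.
#' @return A `leuko_clusters` object: list with `assignment` (tibble
#'   `run_id`, `cluster`), `centroids`, `representatives` (tibble `cluster`,
#'   `run_id`, `dist`), `wcss`, `k`, `sizes`.
#' @export
cluster_trajectories <- function(dynamics, k, seed = 1, n_init = 10) {
  mat <- unclass(dynamics)
  attr(mat, "grid") <- attr(mat, "run_ids") <- attr(mat, "state_max") <- NULL
  n <- nrow(mat)
  stopifnot(k >= 1, n >= k)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- .kmeanspp_centers(mat, k)
    fit <- try(suppressWarnings(
      stats::kmeans(mat, centers = centers, iter.max = 200,
                    algorithm = "Lloyd")
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (any(fit$size == 0)) next  # empty cluster: drop this restart
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
  run_ids <- attr(dynamics, "run_ids")
  assignment <- tibble::tibble(run_id = run_ids, cluster = best$cluster)
  reps <- purrr::map_dfr(seq_len(k), function(cl) {
    members <- which(best$cluster == cl)
    d <- sqrt(rowSums(sweep(mat[members, , drop = FALSE], 2,
                            best$centers[cl, ], "-")^2))
    tibble::tibble(cluster = cl, run_id = run_ids[members[which.min(d)]],
                   dist = min(d))
  })
  structure(
    list(assignment = assignment, centroids = best$centers,
         representatives = reps, wcss = best$tot.withinss, k = k,
         sizes = best$size),
    class = "leuko_clusters"
  )
}

#' @export
print.leuko_clusters <- function(x, ...) {
  cat(sprintf("<leuko_clusters> k = %d, n = %d, WCSS = %.4g\n  sizes: %s\n",
              x$k, nrow(x$assignment), x$wcss,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.leuko_clusters <- function(x, ...) {
  dplyr::left_join(x$assignment,
                   dplyr::rename(x$representatives,
                                 representative_run = "run_id"),
                   by = "cluster")
}

#' @export
glance.leuko_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$assignment), wcss = x$wcss,
                 min_size = min(x$sizes), max_size = max(x$sizes))
}

# mean silhouette width for a label vector on a precomputed distance matrix
.mean_silhouette <- function(D, labels) {
  n <- nrow(D)
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    a <- if (length(own) > 1) mean(D[i, setdiff(own, i)]) else 0
    b <- min(vapply(setdiff(ks, labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    if (length(own) == 1) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Scan k and choose the silhouette-maximizing number of clusters
#'
#' Clusters the dynamics for each `k` in `k_range`, reporting within-cluster
#' sum of squares and mean silhouette width, and picks the k with maximal
#' silhouette. Set `pin_k` to force a specific cluster count (e.g. 13) while
#' still reporting the diagnostics.
#'
#' @param dynamics A [normalize_trajectories()] result.
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed.
#' @param n_init Restarts per k.
#' @param pin_k Optional fixed choice overriding the scan.
#' @return List with `k` (chosen), `diagnostics` (tibble `k`, `wcss`,
#'   `silhouette`), and `pinned` flag.
#' @export
select_k <- function(dynamics, k_range = 2:15, seed = 1, n_init = 5,
                     pin_k = NULL) {
  mat <- unclass(dynamics)
  attr(mat, "grid") <- attr(mat, "run_ids") <- attr(mat, "state_max") <- NULL
  k_range <- k_range[k_range >= 2 & k_range <= floor(nrow(mat) / 2)]
  stopifnot(length(k_range) >= 1)
  D <- as.matrix(stats::dist(mat))
  diag_tab <- purrr::map_dfr(k_range, function(k) {
    fit <- cluster_trajectories(dynamics, k, seed = seed, n_init = n_init)
    labels <- fit$assignment$cluster
    tibble::tibble(k = k, wcss = fit$wcss,
                   silhouette = .mean_silhouette(D, labels))
  })
  chosen <- if (!is.null(pin_k)) pin_k else diag_tab$k[which.max(diag_tab$silhouette)]
  list(k = chosen, diagnostics = diag_tab, pinned = !is.null(pin_k))
}
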