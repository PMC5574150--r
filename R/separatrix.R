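# Separatrix constraints: pairwise log-space inequalities learned from
# accepted parameter sets. For each parameter pair the accepted points are
# boxed by their ranges, the box is divided into a 10 x 10 bin grid, bins
# with fewer accepted points than a uniform-density cutoff are flagged, and
# corner-anchored staircases of flagged bins are replaced by one oblique
# half-plane cut per corner.

# monotone staircase heights anchored at the lower-left corner of a logical
# grid of *unacceptable* bins (TRUE = unacceptable); returns per-column
# heights, non-increasing, zero once broken
.staircase_heights <- function(unacc) {
  nb <- nrow(unacc)
  raw <- vapply(seq_len(nb), function(i) {
    runs <- which(!unacc[i, ])
    if (length(runs) == 0) nb else runs[1] - 1L
  }, integer(1))
  h <- integer(nb)
  cap <- nb
  for (i in seq_len(nb)) {
    cap <- min(cap, raw[i])
    h[i] <- cap
    if (cap == 0L) break
  }
  h
}

# flip the grid so the requested corner maps onto lower-left
.flip_grid <- function(unacc, corner) {
  switch(corner,
    ll = unacc,
    lr = unacc[rev(seq_len(nrow(unacc))), , drop = FALSE],
    ul = unacc[, rev(seq_len(ncol(unacc))), drop = FALSE],
    ur = unacc[rev(seq_len(nrow(unacc))), rev(seq_len(ncol(unacc))), drop = FALSE]
  )
}

# least-squares line through the staircase's inner boundary vertices, in
# corner-local bin units; returns c(slope, intercept) or NULL
.staircase_line <- function(h) {
  w <- sum(h > 0)
  if (w == 0) return(NULL)
  if (sum(h) >= 95) return(NULL)   # covers essentially the whole box
  px <- c(0, seq_len(w), w)
  py <- c(h[1], h[seq_len(w)], 0)
  fit <- stats::lm.fit(cbind(1, px), py)
  m <- fit$coefficients[2]; b <- fit$coefficients[1]
  if (!is.finite(m) || m >= 0) {
    # fall back to the diagonal spanning the staircase extents
    m <- -h[1] / w; b <- h[1]
  }
  c(slope = unname(m), intercept = unname(b))
}

#' Fit a separatrix constraint for one parameter pair
#'
#' Learns, in log10 space, the bounding box of the accepted points, the
#' 10 x 10 bin-acceptance grid (a bin is acceptable when it holds strictly
#' more accepted points than the uniform cutoff `n/100`), and one oblique
#' half-plane cut for each corner whose unacceptable bins form a
#' corner-anchored staircase. With fewer than 100 accepted points the
#' constraint degenerates to the bounding box alone.
#'
#' @param accepted Data frame of accepted parameter sets (must contain both
#'   `pair` columns, all values > 0).
#' @param pair Character vector of two parameter names, `c(x, y)`.
#' @param nbin Bins per axis (10, the method's definition).
#' @return A `separatrix_constraint`: list with `pair`, `box` (log10 ranges),
#'   `grid` (logical acceptance matrix, rows = x bins), `cutoff`, and `cuts`
#'   (per-corner list of half-plane inequalities in log10 coordinates).
#' @export
fit_separatrix <- function(accepted, pair, nbin = 10) {
  stopifnot(length(pair) == 2, all(pair %in% names(accepted)))
  x <- log10(accepted[[pair[1]]])
  y <- log10(accepted[[pair[2]]])
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(paste(x, y))) < 2) {
    stop("need at least 2 distinct accepted points", call. = FALSE)
  }
  box <- list(x = range(x), y = range(y))
  n <- length(x)
  out <- structure(
    list(pair = pair, box = box, nbin = nbin, n_accepted = n,
         cutoff = n / (nbin * nbin), grid = NULL, cuts = list()),
    class = "separatrix_constraint"
  )
  if (n < 100) return(out)

  wx <- diff(box$x) / nbin; wy <- diff(box$y) / nbin
  ix <- pmin(pmax(ceiling((x - box$x[1]) / wx), 1L), nbin)
  iy <- pmin(pmax(ceiling((y - box$y[1]) / wy), 1L), nbin)
  counts <- matrix(0L, nbin, nbin)
  for (k in seq_len(n)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  acc_grid <- counts > out$cutoff
  out$grid <- acc_grid

  corners <- c("ll", "lr", "ul", "ur")
  cuts <- list()
  for (corner in corners) {
    flipped <- .flip_grid(!acc_grid, corner)
    h <- .staircase_heights(flipped)
    line <- .staircase_line(h)
    if (is.null(line)) next
    # map corner-local bin units back to log10 coordinates
    sx <- if (corner %in% c("lr", "ur")) -wx else wx
    sy <- if (corner %in% c("ul", "ur")) -wy else wy
    x0 <- if (corner %in% c("lr", "ur")) box$x[2] else box$x[1]
    y0 <- if (corner %in% c("ul", "ur")) box$y[2] else box$y[1]
    # local: v = m*u + b with u=(X-x0)/sx, v=(Y-y0)/sy; excluded side contains
    # the corner (u=v=0). Express as s(X,Y) = (Y-y0)/sy - m*(X-x0)/sx - b.
    cuts[[corner]] <- list(corner = corner, slope = line[["slope"]],
                           intercept = line[["intercept"]],
                           sx = sx, sy = sy, x0 = x0, y0 = y0)
  }
  out$cuts <- cuts
  out
}

# signed evaluation of a cut at log10 coordinates; retained side is where
# the sign differs from the corner's (the corner itself has s = -intercept)
.cut_retained <- function(cut, X, Y) {
  s <- (Y - cut$y0) / cut$sy - cut$slope * (X - cut$x0) / cut$sx - cut$intercept
  s_corner <- -cut$intercept
  s * sign(s_corner) <= 0
}

#' Does a parameter point satisfy a separatrix constraint?
#'
#' A point satisfies the constraint when, in log10 coordinates, it lies
#' inside the bounding box of the accepted training set and on the retained
#' side of every corner cut.
#'
#' @param constraint A [fit_separatrix()] result.
#' @param points Data frame (or one-row equivalent) containing the pair's
#'   columns.
#' @return Logical vector, one entry per row of `points`.
#' @export
satisfies_constraint <- function(constraint, points) {
  stopifnot(inherits(constraint, "separatrix_constraint"))
  missing <- setdiff(constraint$pair, names(points))
  if (length(missing) > 0) {
    stop("points lack parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- log10(points[[constraint$pair[1]]])
  Y <- log10(points[[constraint$pair[2]]])
  ok <- X >= constraint$box$x[1] & X <= constraint$box$x[2] &
    Y >= constraint$box$y[1] & Y <= constraint$box$y[2]
  for (cut in constraint$cuts) {
    ok <- ok & .cut_retained(cut, X, Y)
  }
  ok & !is.na(ok)
}

#' Build a rejection filter from separatrix constraints
#'
#' Returns a function mapping a tibble of proposals to a logical keep-vector
#' (the conjunction of all constraints). The filter tracks its empirical
#' acceptance rate across calls; read it with `acceptance_rate()`.
#'
#' @param constraints List of `separatrix_constraint` objects (possibly
#'   empty or `NULL`, in which case everything is accepted).
#' @return A filter function with class `separatrix_filter`.
#' @export
constrain_sampler <- function(constraints = NULL) {
  constraints <- constraints %||% list()
  if (inherits(constraints, "separatrix_constraint")) {
    constraints <- list(constraints)
  }
  env <- new.env(parent = emptyenv())
  env$proposed <- 0
  env$kept <- 0
  fn <- function(points) {
    ok <- rep(TRUE, nrow(points))
    for (con in constraints) {
      ok <- ok & satisfies_constraint(con, points)
    }
    env$proposed <- env$proposed + length(ok)
    env$kept <- env$kept + sum(ok)
    ok
  }
  attr(fn, "env") <- env
  class(fn) <- c("separatrix_filter", class(fn))
  fn
}

#' Empirical acceptance rate of a separatrix filter
#' @param filter A [constrain_sampler()] filter.
#' @return Fraction of proposals kept so far (NaN before any call).
#' @export
acceptance_rate <- function(filter) {
  env <- attr(filter, "env")
  env$kept / env$proposed
}

#' Default parameter pairs for separatrix fitting
#'
#' The five pairwise relationships that carry the strongest constraints in
#' acceptable cohorts: each lineage's progenitor self-renewal probability
#' against its mitosis rate, stem self-renewal against stem mitosis rate,
#' and neutrophil self-renewal against the neutrophil peripheral-blood
#' Michaelis constant.
#'
#' @return List of character pairs.
#' @export
default_separatrix_pairs <- function() {
  list(c("aS", "mrS"), c("aN2", "mrN2"), c("aL2", "mrL2"),
       c("aM2", "mrM2"), c("aN2", "kN"))
}

#' @export
print.separatrix_constraint <- function(x, ...) {
  cat(sprintf("<separatrix_constraint> %s vs %s | n = %d, cuts: %s\n",
              x$pair[1], x$pair[2], x$n_accepted,
              if (length(x$cuts)) paste(names(x$cuts), collapse = ", ")
              else "none (box only)"))
  invisible(x)
}
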