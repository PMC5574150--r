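# Partial rank correlation coefficient (PRCC) global sensitivity analysis.
#
# The PRCC of parameter j against an output is the Pearson correlation of the
# residuals left after regressing the *ranks* of x_j and of the output on the
# ranks of all other parameters. Being rank-based it is invariant under any
# strictly monotone transform of any column.

#' Partial rank correlation coefficients
#'
#' Rank-transforms all columns (midranks on ties), then for every parameter
#' regresses its ranks and the output ranks on the ranks of the remaining
#' parameters (with intercept) and correlates the two residual vectors.
#' Two-sided p-values come from the t statistic
#' `prcc * sqrt((n - 2 - (p - 1)) / (1 - prcc^2))` on `n - 2 - (p - 1)`
#' degrees of freedom. Columns that are constant, or linearly dependent on
#' the others in rank space (e.g. a duplicated parameter), are flagged
#' undefined rather than silently computed.
#'
#' @param X Data frame or matrix of sampled parameters (n rows, p columns).
#' @param y Numeric output vector of length n.
#' @return A `leuko_prcc` tibble: `parameter`, `prcc`, `statistic`,
#'   `p_value`, `n`, `note` (`"ok"` or `"undefined"`).
#' @examples
#' set.seed(1)
#' X <- data.frame(a = runif(200), b = runif(200), c = runif(200))
#' y <- X$a + 0.1 * rnorm(200)
#' prcc(X, y)
#' @export
prcc <- function(X, y) {
  X <- as.data.frame(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 2) stop("need n > p + 2 observations", call. = FALSE)
  keep <- complete.cases(X) & is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X)

  R <- vapply(X, function(col) rank(col, ties.method = "average"), numeric(n))
  ry <- rank(y, ties.method = "average")
  const <- apply(R, 2, function(col) stats::var(col) < .Machine$double.eps)

  df <- n - 2 - (p - 1)
  res <- lapply(seq_len(p), function(j) {
    if (const[j]) {
      return(list(prcc = NA_real_, stat = NA_real_, pv = NA_real_,
                  note = "undefined"))
    }
    Z <- cbind(1, R[, -j, drop = FALSE])
    fit_x <- stats::lm.fit(Z, R[, j])
    fit_y <- stats::lm.fit(Z, ry)
    ex <- fit_x$residuals
    ey <- fit_y$residuals
    # rank-degenerate column (duplicate of another): residual variance ~ 0
    if (stats::var(ex) < 1e-10 * stats::var(R[, j])) {
      return(list(prcc = NA_real_, stat = NA_real_, pv = NA_real_,
                  note = "undefined"))
    }
    r <- stats::cor(ex, ey)
    stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    pv <- 2 * stats::pt(-abs(stat), df)
    list(prcc = r, stat = stat, pv = pv, note = "ok")
  })

  out <- tibble::tibble(
    parameter = colnames(R) %||% paste0("x", seq_len(p)),
    prcc = vapply(res, `[[`, numeric(1), "prcc"),
    statistic = vapply(res, `[[`, numeric(1), "stat"),
    p_value = vapply(res, `[[`, numeric(1), "pv"),
    n = n,
    note = vapply(res, `[[`, character(1), "note")
  )
  class(out) <- c("leuko_prcc", class(out))
  out
}

#' Sensitivity report over a screened cohort
#'
#' Runs [prcc()] of the sampled parameters against each configured model
#' output (by default the final homeostatic concentrations of stem cells and
#' the three circulating lineages) over the accepted rows of a cohort table,
#' applies a Benjamini-Hochberg correction across parameters within each
#' output, and ranks parameters by `|prcc|`.
#'
#' @param cohort A cohort tibble from [screen_unilineage()] or
#'   [screen_multilineage()].
#' @param outputs Named character vector mapping output labels to cohort
#'   columns.
#' @param parameters Parameter columns to analyse (defaults to every sampled
#'   roster parameter present in the cohort).
#' @param accepted_only Use only accepted rows (default) or every row with a
#'   nontrivial equilibrium.
#' @return A tibble: `output`, `parameter`, `prcc`, `p_value`, `p_adj`,
#'   `rank`, `n`.
#' @export
sensitivity_report <- function(cohort,
                               outputs = c(stem = "stem_final",
                                           neutrophil_pb = "final_Npb",
                                           lymphocyte_pb = "final_L3pb",
                                           monocyte_pb = "final_Mpb"),
                               parameters = NULL,
                               accepted_only = TRUE) {
  parameters <- parameters %||%
    intersect(.param_roster()$name, names(cohort))
  rows <- if (accepted_only) {
    cohort[which(cohort$accepted), , drop = FALSE]
  } else {
    cohort[cohort$equilibrium_tag == "nontrivial", , drop = FALSE]
  }
  if (accepted_only && nrow(rows) <= length(parameters) + 2) {
    message("too few accepted rows for a partial correlation in ",
            length(parameters), " parameters; using all nontrivial rows")
    rows <- cohort[cohort$equilibrium_tag == "nontrivial", , drop = FALSE]
  }
  outputs <- outputs[outputs %in% names(rows)]
  purrr::map_dfr(names(outputs), function(lbl) {
    y <- rows[[outputs[[lbl]]]]
    tab <- prcc(rows[, parameters, drop = FALSE], y)
    tab <- dplyr::mutate(tab,
      output = lbl,
      p_adj = stats::p.adjust(.data$p_value, method = "BH")
    )
    tab <- dplyr::arrange(tab, dplyr::desc(abs(.data$prcc)))
    tab$rank <- seq_len(nrow(tab))
    dplyr::select(tab, "output", "parameter", "prcc", "p_value", "p_adj",
                  "rank", "n", "note")
  })
}

#' @export
tidy.leuko_prcc <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.leuko_prcc <- function(x, ...) {
  tibble::tibble(
    n = x$n[1],
    n_parameters = nrow(x),
    n_undefined = sum(x$note == "undefined"),
    max_abs_prcc = max(abs(x$prcc), na.rm = TRUE)
  )
}
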