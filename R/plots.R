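# ggplot2 views of the main result types.

#' Plot a simulated trajectory
#'
#' Cell concentrations over time, faceted by state, on a log10 axis by
#' default (concentrations span orders of magnitude through chemotherapy).
#'
#' @param object A `leuko_trajectory`.
#' @param states States to show (default: stem plus the circulating pools).
#' @param log10 Use a log10 concentration axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leuko_trajectory <- function(object,
                                      states = c("S", "Npb", "L3pb", "Mpb"),
                                      log10 = TRUE, ...) {
  long <- tidyr::pivot_longer(as.data.frame(object)[, c("time", states)],
                              -"time", names_to = "state",
                              values_to = "concentration")
  long$state <- factor(long$state, levels = states)
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "day", y = "cells/uL") +
    ggplot2::theme_minimal()
  if (log10) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot a separatrix constraint with its training points
#'
#' @param object A `separatrix_constraint`.
#' @param points Optional data frame of points to overlay (needs the pair's
#'   columns; an `acceptable` column colours them).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.separatrix_constraint <- function(object, points = NULL, ...) {
  box <- object$box
  gg <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = data.frame(xmin = box$x[1], xmax = box$x[2],
                        ymin = box$y[1], ymax = box$y[2]),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      fill = NA, colour = "black", linetype = "dashed")
  if (!is.null(points)) {
    df <- data.frame(x = log10(points[[object$pair[1]]]),
                     y = log10(points[[object$pair[2]]]))
    df$acceptable <- points$acceptable %||% TRUE
    gg <- gg + ggplot2::geom_point(
      data = df, ggplot2::aes(.data$x, .data$y, colour = .data$acceptable),
      alpha = 0.4, size = 0.6)
  }
  for (cut in object$cuts) {
    # express the cut line Y(X) in log10 coordinates
    xs <- seq(box$x[1], box$x[2], length.out = 50)
    ys <- cut$y0 + cut$sy * (cut$slope * (xs - cut$x0) / cut$sx + cut$intercept)
    keep <- ys >= box$y[1] & ys <= box$y[2]
    gg <- gg + ggplot2::geom_line(
      data = data.frame(x = xs[keep], y = ys[keep]),
      ggplot2::aes(.data$x, .data$y), colour = "darkgreen",
      linetype = "dashed")
  }
  gg + ggplot2::labs(x = paste0("log10(", object$pair[1], ")"),
                     y = paste0("log10(", object$pair[2], ")")) +
    ggplot2::theme_minimal()
}

#' Plot cluster centroid dynamics
#'
#' Normalized centroid trajectories of selected states, one colour per
#' cluster - the representative-patient view.
#'
#' @param object A `leuko_clusters` result.
#' @param dynamics The `normalized_dynamics` the clustering was fitted on
#'   (supplies the grid).
#' @param states States to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leuko_clusters <- function(object, dynamics,
                                    states = c("S", "Npb", "L3pb", "Mpb"),
                                    ...) {
  grid <- attr(dynamics, "grid")
  all_states <- leuko_states()
  ng <- length(grid)
  long <- purrr::map_dfr(seq_len(object$k), function(cl) {
    purrr::map_dfr(states, function(s) {
      offset <- (match(s, all_states) - 1) * ng
      tibble::tibble(cluster = factor(cl), state = s, day = grid,
                     value = object$centroids[cl, offset + seq_len(ng)])
    })
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value,
                                     colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = "day", y = "normalized concentration") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster survival curves
#'
#' Step curves of the fraction of each cluster still alive.
#'
#' @param survival A [survival_curves()] result.
#' @return A ggplot object.
#' @export
plot_survival <- function(survival) {
  ggplot2::ggplot(survival$curves,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "day", y = "cumulative survival",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Heatmap of cancer-parameter survival correlations
#'
#' Clusters on the x axis (plus the pooled column), cancer parameters on the
#' y axis; insignificant cells (p >= 0.05) are masked grey.
#'
#' @param object A `leuko_aml_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leuko_aml_screen <- function(object, ...) {
  df <- object$correlations
  df$estimate[!df$significant] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$parameter,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", na.value = "grey80",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "cluster", y = "cancer parameter",
                  fill = "correlation\nwith survival") +
    ggplot2::theme_minimal()
}
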