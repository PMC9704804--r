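#' Plot a fitted mixture over its data
#'
#' Histogram of the log10 sizes with the fitted mixture density (solid) and
#' its weighted components (dashed), the standard visual check of a
#' two-component fit.
#'
#' @param object A `mixture_fit` fitted with `keep_data = TRUE`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mixture_fit <- function(object, bins = 40, ...) {
  if (is.null(object$data))
    abort_fmt("fit was run with `keep_data = FALSE`", "plot_error")
  df <- tibble::tibble(v = object$data)
  grid <- tibble::tibble(x = seq(min(df$v) - 0.3, max(df$v) + 0.3,
                                 length.out = 400))
  grid$total <- dmix(grid$x, object)
  comp_df <- purrr::pmap_dfr(object$components, function(state, mean, sd,
                                                         weight) {
    tibble::tibble(x = grid$x, state = state,
                   density = weight * dnorm(grid$x, mean, sd))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80",
                            colour = "grey50") +
    ggplot2::geom_line(data = comp_df,
                       ggplot2::aes(y = .data$density, group = .data$state),
                       linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$total),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "log10 size", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot dual-connection pairs under a fitted pair-state model
#'
#' Scatter of the (symmetrized) size pairs with density contours of the
#' fitted joint model; the scarcity of points off the diagonal reflects the
#' low probability of the mixed SL/LS states.
#'
#' @param object A fitted `pair_state_model`.
#' @param pairs The pair tibble the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pair_state_model <- function(object, pairs, ...) {
  sym <- symmetrize_pairs(pairs)
  em <- object$emissions
  j <- object$joint
  rng <- range(c(sym$v1, sym$v2))
  gx <- seq(rng[1] - 0.3, rng[2] + 0.3, length.out = 150)
  grid <- tidyr::expand_grid(v1 = gx, v2 = gx)
  combo <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  grid$density <- Reduce(`+`, purrr::map(seq_along(combo), function(c4) {
    h <- combo[[c4]]
    unname(j[c4]) * dnorm(grid$v1, em$mean[h[1]], em$sd[h[1]]) *
      dnorm(grid$v2, em$mean[h[2]], em$sd[h[2]])
  }))
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$v1, y = .data$v2)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_contour(data = grid,
                          ggplot2::aes(z = .data$density),
                          colour = "darkorange") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "log10 size, synapse 1", y = "log10 size, synapse 2") +
    ggplot2::theme_minimal()
}

#' Plot the resampled correlation distribution
#'
#' Kernel density of the Pearson correlations across resampling iterations,
#' with zero marked: under conditional independence the mass should straddle
#' zero.
#'
#' @param object A `resample_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.resample_result <- function(object, ...) {
  ggplot2::ggplot(object$kde, ggplot2::aes(x = .data$r,
                                           y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("Pearson r (%s state)", object$state),
                  y = "density") +
    ggplot2::theme_minimal()
}
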