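#' @importFrom ggplot2 ggplot aes geom_histogram geom_line geom_point
#'   geom_hline geom_vline geom_errorbar labs theme_minimal autoplot
#'   after_stat sec_axis scale_y_continuous position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a fitted corrected-difference mixture
#'
#' Histogram of corrected-difference scores with the two fitted Student's-t
#' component densities overlaid; the autosomal component peaks near `-pi`
#' and the X component near zero.
#'
#' @param object A [fit_t_mixture()] result.
#' @param cd Optional numeric vector of the fitted data (for the
#'   histogram); omitting it draws the densities alone.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.t_mixture_fit <- function(object, cd = NULL, ...) {
  lim <- if (!is.null(cd)) range(cd) else {
    range(object$mu + c(-6, 6) * rep(object$sigma, each = 2))
  }
  grid <- seq(lim[1], lim[2], length.out = 512)
  dens <- dplyr::bind_rows(
    tibble(cd = grid, component = "autosome",
           density = object$w[1] * dt_ls(grid, object$mu[1], object$sigma[1],
                                         object$nu[1])),
    tibble(cd = grid, component = "X",
           density = object$w[2] * dt_ls(grid, object$mu[2], object$sigma[2],
                                         object$nu[2]))
  )
  p <- ggplot(dens, aes(x = .data$cd))
  if (!is.null(cd)) {
    p <- p + geom_histogram(
      data = tibble(cd = cd),
      aes(y = after_stat(.data$density)),
      bins = 60, fill = "grey80", colour = "grey50"
    )
  }
  p +
    geom_line(aes(y = .data$density, colour = .data$component)) +
    labs(x = "corrected difference (per bp)", y = "density",
         colour = NULL) +
    theme_minimal()
}

#' X-probability curve over corrected differences
#'
#' The posterior probability that a scaffold is X-linked as a function of
#' its corrected difference, with the classification threshold marked.
#'
#' @param fit A [fit_t_mixture()] result.
#' @param cd Optional scores to overlay as points.
#' @param threshold Classification cutoff to mark.
#' @return A ggplot.
#' @export
plot_x_probability <- function(fit, cd = NULL, threshold = 0.5) {
  lim <- if (!is.null(cd)) range(cd) else {
    range(fit$mu + c(-6, 6) * rep(fit$sigma, each = 2))
  }
  grid <- seq(lim[1], lim[2], length.out = 512)
  p <- ggplot(tibble(cd = grid, p_x = x_probability(grid, fit)),
              aes(x = .data$cd, y = .data$p_x)) +
    geom_line() +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    labs(x = "corrected difference (per bp)", y = "P(X-linked)") +
    theme_minimal()
  if (!is.null(cd)) {
    p <- p + geom_point(data = tibble(cd = cd, p_x = x_probability(cd, fit)),
                        alpha = 0.4)
  }
  p
}

#' Mean Tajima's D by region class with four-SE bars
#'
#' @param comparisons Tibble from [group_comparison_report()].
#' @return A ggplot.
#' @export
plot_group_comparison <- function(comparisons) {
  long <- dplyr::bind_rows(
    dplyr::transmute(comparisons, comparison = .data$comparison,
                     group = .data$group_a, mean = .data$mean_a,
                     lo = .data$lo_a, hi = .data$hi_a),
    dplyr::transmute(comparisons, comparison = .data$comparison,
                     group = .data$group_b, mean = .data$mean_b,
                     lo = .data$lo_b, hi = .data$hi_b)
  ) |>
    dplyr::distinct() |>
    dplyr::filter(is.finite(.data$mean))
  ggplot(long, aes(x = .data$group, y = .data$mean)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = NULL, y = "mean Tajima's D (bars: 4 SE)") +
    theme_minimal()
}

#' Diversity trajectory of a life-cycle simulation
#'
#' @param sim A [simulate_life_cycle()] result.
#' @return A ggplot of mean pi per recorded year for X and autosomal loci.
#' @export
plot_lifecycle <- function(sim) {
  ggplot(sim$trajectory,
         aes(x = .data$year, y = .data$pi, colour = .data$chromosome)) +
    geom_line() +
    labs(x = "year", y = "mean pi per locus", colour = NULL) +
    theme_minimal()
}
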