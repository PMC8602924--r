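#' Plot the psychometric function
#'
#' Proportion correct against letter size (log axis) for one or more true
#' thresholds, with the guess floor, the lapse-limited ceiling and the
#' threshold criterion marked.
#'
#' @param params A [psychometric_params()].
#' @param thresholds_deg True threshold(s) to draw, degrees.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(params = psychometric_params(),
                              thresholds_deg = c(0.3, 0.6, 1.2)) {
  sizes <- 10^seq(-2, 1, length.out = 200)
  df <- tidyr::expand_grid(
    threshold_deg = thresholds_deg,
    size_deg = sizes
  ) |>
    dplyr::mutate(p = p_correct(.data$size_deg, .data$threshold_deg, params))
  ggplot2::ggplot(df, ggplot2::aes(.data$size_deg, .data$p,
                                   colour = factor(.data$threshold_deg))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(params$guess_rate,
                                       params$threshold_criterion,
                                       1 - params$lapse_rate * (1 - params$guess_rate)),
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "letter size (deg)", y = "p(correct)",
                  colour = "threshold (deg)") +
    ggplot2::theme_minimal()
}

#' Plot posterior in-out asymmetry by cell
#'
#' Violin plot of the posterior IOA draws for each design x location, with
#' the no-asymmetry line at 1.
#'
#' @param object An `ioa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ioa_fit
#' @export
autoplot.ioa_fit <- function(object, ...) {
  pairs <- unique(condition_cells()[, c("design", "location")])
  df <- purrr::pmap_dfr(pairs, function(design, location) {
    tibble::tibble(design = design, location = location,
                   ioa = ioa_draws(object, design, location))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$design, .data$ioa)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~location, nrow = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "in-out ratio (outward / inward threshold)") +
    ggplot2::theme_minimal()
}

#' Plot the simulated-population IOA distribution
#'
#' One violin per design x location of per-simulated-participant IOA, with
#' the criteria lines at 1 and 1.5.
#'
#' @param object An `ioa_population` from [simulate_population()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ioa_population
#' @export
autoplot.ioa_population <- function(object, ...) {
  ggplot2::ggplot(object$participants,
                  ggplot2::aes(.data$design, .data$ioa)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_hline(yintercept = object$criteria, linetype = "dashed") +
    ggplot2::facet_wrap(~location, nrow = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "simulated participant IOA") +
    ggplot2::theme_minimal()
}
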