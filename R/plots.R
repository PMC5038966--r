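#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a morphogen profile
#'
#' @param object A [morphogen_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.morphogen_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$site, y = .data$m)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lattice site x", y = "morphogen signal m(x)") +
    ggplot2::theme_minimal()
}

# shared heatmap of a K x N mean pattern
plot_mean_matrix <- function(mp) {
  df <- tidyr::expand_grid(gene = seq_len(nrow(mp)), site = seq_len(ncol(mp))) |>
    dplyr::mutate(mean = mp[cbind(.data$gene, .data$site)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = factor(.data$gene),
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50", high = "white",
                                  limits = c(-1, 1), name = "<sigma>") +
    ggplot2::labs(x = "lattice site x", y = "gene") +
    ggplot2::theme_minimal()
}

#' Plot the mean expression pattern of a distribution or sample set
#'
#' Greyscale tile map of `<sigma_a(x)>`: white = reliably ON, black =
#' reliably OFF, intermediate grey = noise-dominated sites.
#'
#' @param object A `"pattern_distribution"` or `"sample_set"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pattern_distribution <- function(object, ...) {
  plot_mean_matrix(mean_pattern(object))
}

#' @rdname autoplot.pattern_distribution
#' @export
autoplot.sample_set <- function(object, ...) {
  plot_mean_matrix(mean_pattern(object))
}

#' Plot an optimization trace
#'
#' Accepted objective values and the running best, per restart.
#'
#' @param object A `"pi_optimization"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pi_optimization <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$pi,
                               colour = factor(.data$restart))) +
    ggplot2::geom_step(alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_pi), colour = "black") +
    ggplot2::labs(x = "iteration", y = "positional information (bits)",
                  colour = "restart") +
    ggplot2::theme_minimal()
}

#' Plot an overlap-versus-perturbation curve
#'
#' @param overlaps A tibble from [overlap_profile()].
#' @return A ggplot.
#' @export
plot_overlap <- function(overlaps) {
  ggplot2::ggplot(overlaps, ggplot2::aes(x = .data$epsilon, y = .data$overlap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "dosage offset epsilon", y = "overlap S(epsilon)") +
    ggplot2::theme_minimal()
}
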