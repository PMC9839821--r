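#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

species_long <- function(df) {
  tidyr::pivot_longer(tibble::as_tibble(df),
                      cols = dplyr::matches("^N\\d+$"),
                      names_to = "species", values_to = "count")
}

#' Plot a stochastic trajectory
#'
#' Step plot of the species counts of a recorded jump trajectory, with
#' extinction events marked.
#'
#' @param object An `ml_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ml_trajectory <- function(object, ...) {
  long <- species_long(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$count,
                                          colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
  ext <- attr(object, "extinctions")
  if (!is.null(ext) && any(!is.na(ext))) {
    ev <- tibble::tibble(t = ext[!is.na(ext)],
                         species = names(ext)[!is.na(ext)], count = 0)
    p <- p + ggplot2::geom_point(data = ev, shape = 4, size = 3)
  }
  p
}

#' Plot a mean-field trajectory
#'
#' @param object An `ml_ode` trajectory from [integrate_meanfield()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ml_ode <- function(object, ...) {
  ggplot2::ggplot(species_long(object),
                  ggplot2::aes(x = .data$t, y = .data$count,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "population", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-state field on a lattice plane
#'
#' Tile plot of a field (e.g. mean extinction times) restricted to a plane
#' of constant `N1 + N2 + N3`, shown in the `(N1, N2)` coordinates.
#'
#' @param field Data frame with columns `N1`, `N2`, `N3` and a value column.
#' @param plane_sum Coordinate sum selecting the plane.
#' @param value Name of the value column (default the last column).
#' @return A ggplot object.
#' @export
plot_plane_field <- function(field, plane_sum, value = NULL) {
  sl <- plane_slice(field, plane_sum)
  if (is.null(value)) value <- setdiff(names(sl), c("N1", "N2", "N3"))[1]
  ggplot2::ggplot(sl, ggplot2::aes(x = .data$N1, y = .data$N2,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = value) +
    ggplot2::theme_minimal()
}

#' Plot a fitted Gamma cycle-length distribution
#'
#' Histogram of the cycle-length samples with the maximum-likelihood Gamma
#' density overlaid.
#'
#' @param object An `ml_gamma_fit` from [fit_gamma()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ml_gamma_fit <- function(object, bins = 40, ...) {
  df <- tibble::tibble(x = object$samples)
  grid <- tibble::tibble(
    x = seq(min(df$x), max(df$x), length.out = 400))
  grid$d <- stats::dgamma(grid$x, shape = object$shape, rate = object$rate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$d),
                       colour = "firebrick") +
    ggplot2::labs(x = "cycle length", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot conditional second-extinction densities
#'
#' The two conditional hitting densities given species 3 extinct first: the
#' density of `N1` at the moment species 2 goes extinct and the density of
#' `N2` at the moment species 1 goes extinct. The areas under the curves
#' are the conditional probabilities of each extinction order and sum to 1.
#'
#' @param object An `ml_second_extinction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ml_second_extinction <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(n = object$species2_extinct$N1,
                   prob = object$species2_extinct$prob,
                   curve = "N1 when species 2 extinct"),
    tibble::tibble(n = object$species1_extinct$N2,
                   prob = object$species1_extinct$prob,
                   curve = "N2 when species 1 extinct"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$prob,
                                  colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "remaining population", y = "probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
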