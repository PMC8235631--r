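# ggplot2 views of the scan tables. Each result class gets an autoplot()
# method plus a plot_*() wrapper; aesthetics are deliberately minimal.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot zb_partition_scan
#' @export
autoplot.zb_partition_scan <- function(object, ...) {
  long <- partition_scan_long(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$N_over_xi, y = .data$value,
                                     colour = .data$approximation)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1.5)) +
    ggplot2::labs(
      x = expression(N / xi[max]),
      y = expression(ln * Z / (N * ln * lambda[1])),
      colour = NULL,
      title = sprintf("Partition-function regimes at s* = 1 - 2*sigma (sigma = %g)",
                      attr(object, "sigma"))
    ) +
    ggplot2::theme_minimal()
}

partition_scan_long <- function(object) {
  dplyr::bind_rows(
    tibble::tibble(N_over_xi = object$N_over_xi,
                   value = object$lnZ_ratio_exact, approximation = "exact"),
    tibble::tibble(N_over_xi = object$N_over_xi,
                   value = object$lnZ_ratio_long, approximation = "long chain"),
    tibble::tibble(N_over_xi = object$N_over_xi,
                   value = object$lnZ_ratio_zipper, approximation = "zipper")
  )
}

#' Plot partition-function regime validity
#'
#' Reduced log partition functions (exact, long-chain, zipper, each divided
#' by the infinite-chain `N log lambda1`) against reduced chain length.
#'
#' @param scan A `zb_partition_scan` tibble from [zb_partition_ratio_scan()].
#' @return A ggplot object.
#' @export
plot_partition_limits <- function(scan) autoplot(scan)

#' @method autoplot zb_size_scan
#' @export
autoplot.zb_size_scan <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(sigma = object$sigma, N_over_xi = object$N_over_xi,
                   ratio = object$Tm_ratio, which = "Tm(N) / Tm(inf)"),
    tibble::tibble(sigma = object$sigma, N_over_xi = object$N_over_xi,
                   ratio = object$dT_ratio, which = "dT(N) / dT(inf)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$N_over_xi, y = .data$ratio,
                                     colour = factor(.data$sigma))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$which), scales = "free_y") +
    ggplot2::labs(x = expression(N / xi[max]), y = "ratio to infinite chain",
                  colour = expression(sigma)) +
    ggplot2::theme_minimal()
}

#' Plot size dependence of melting temperature and interval
#'
#' @param scan A `zb_size_scan` tibble from [zb_size_dependence_scan()].
#' @return A ggplot object.
#' @export
plot_size_dependence <- function(scan) autoplot(scan)

#' @method autoplot zb_helicity_family
#' @export
autoplot.zb_helicity_family <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$theta,
                                       colour = factor(.data$N_over_xi))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stability s", y = expression(theta),
                  colour = expression(N / xi[max])) +
    ggplot2::theme_minimal()
}

#' Plot a family of helicity curves
#'
#' @param fam A `zb_helicity_family` tibble from [zb_helicity_family()].
#' @return A ggplot object.
#' @export
plot_helicity_family <- function(fam) autoplot(fam)

#' @method autoplot zb_melting_curve
#' @export
autoplot.zb_melting_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$T, y = .data$theta)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature T (k_B = 1)", y = expression(theta)) +
    ggplot2::theme_minimal()
}

#' Plot a melting curve
#'
#' @param curve A `zb_melting_curve` tibble from [zb_melting_curve()].
#' @return A ggplot object.
#' @export
plot_melting_curve <- function(curve) autoplot(curve)
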