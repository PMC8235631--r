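#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a finite-chain transition summary
#'
#' One row per melting observable: the inflection transition point, its
#' helicity, the interval, and the reduced temperature quantities.
#'
#' @param x A `zb_transition` object from [zb_find_transition()].
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `value`, `units`.
#' @method tidy zb_transition
#' @export
tidy.zb_transition <- function(x, ...) {
  tibble::tibble(
    quantity = c("s_star", "theta_at_transition", "delta_s",
                 "Tm_over_U", "dT_over_U"),
    value = c(x$s_star, x$theta_at_transition, x$delta_s,
              x$Tm_over_U, x$dT_over_U),
    units = c("stability s", "fraction", "stability s",
              "T/U (k_B = 1)", "T/U (k_B = 1)")
  )
}

#' Glance at a finite-chain transition summary
#'
#' @inheritParams tidy.zb_transition
#' @return A one-row tibble with the model inputs and every melting
#'   observable.
#' @method glance zb_transition
#' @export
glance.zb_transition <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma, N = x$N, definition = x$definition,
    s_star = x$s_star, delta_s = x$delta_s,
    theta_at_transition = x$theta_at_transition,
    Tm_over_U = x$Tm_over_U, dT_over_U = x$dT_over_U
  )
}
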