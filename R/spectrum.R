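# Transfer-matrix spectrum of the Zimm-Bragg model.
#
# The Q x Q Potts-like transfer matrix has only two non-trivial eigenvalues;
# in {s, sigma} units they solve lambda^2 - lambda(1 + s) + s(1 - sigma) = 0:
#   lambda_{1,2} = (1 + s +/- sqrt((1 - s)^2 + 4 sigma s)) / 2.
# lambda2 is computed from the Vieta product s(1 - sigma)/lambda1 to avoid
# cancellation near s = 0. Discriminants below 1e-300 are treated as
# degenerate rather than yielding equal roots.

eigen_pair <- function(s, sigma) {
  disc <- (1 - s)^2 + 4 * sigma * s
  if (any(disc < 1e-300)) {
    stop("degenerate transfer-matrix spectrum (discriminant ~ 0); ",
         "use sigma > 0 away from s = 1", call. = FALSE)
  }
  sq <- sqrt(disc)
  lambda1 <- (1 + s + sq) / 2
  lambda2 <- s * (1 - sigma) / lambda1
  list(lambda1 = lambda1, lambda2 = lambda2, sq = sq)
}

# d lambda_{1,2} / ds, vectorized over s.
eigen_pair_deriv <- function(s, sigma) {
  disc <- (1 - s)^2 + 4 * sigma * s
  sq <- sqrt(disc)
  dsq <- (s - 1 + 2 * sigma) / sq
  list(dlambda1 = (1 + dsq) / 2, dlambda2 = (1 - dsq) / 2, sq = sq, dsq = dsq)
}

xi_from_pair <- function(lambda1, lambda2) {
  ifelse(lambda2 <= 0, 0, 1 / (log(lambda1) - log(lambda2)))
}

#' Transfer-matrix eigenvalues and correlation length
#'
#' Computes the two non-trivial eigenvalues of the Zimm-Bragg transfer
#' matrix, their gap, the correlation (persistence) length
#' `xi = 1/log(lambda1/lambda2)`, the Potts-unit eigenvalues
#' `Lambda = Q * lambda`, and the large-`s` asymptotes `s + sigma`
#' (upper branch) and `1 - sigma` (lower branch).
#'
#' @param params A [zb_params()] object.
#' @return A one-row tibble with columns `s`, `sigma`, `lambda1`, `lambda2`,
#'   `gap`, `xi`, `Lambda1`, `Lambda2`, `asymptote_upper`, `asymptote_lower`.
#' @examples
#' zb_spectrum(zb_params(s = 1, sigma = 0.25))   # lambda = 1.5, 0.5
#' zb_spectrum(zb_params(s = 0.998, sigma = 0.001))$xi  # ~ 15.8
#' @export
zb_spectrum <- function(params) {
  p <- as_zb_params(params)
  ev <- eigen_pair(p$s, p$sigma)
  tibble::tibble(
    s = p$s, sigma = p$sigma,
    lambda1 = ev$lambda1, lambda2 = ev$lambda2,
    gap = ev$lambda1 - ev$lambda2,
    xi = xi_from_pair(ev$lambda1, ev$lambda2),
    Lambda1 = p$Q * ev$lambda1, Lambda2 = p$Q * ev$lambda2,
    asymptote_upper = p$s + p$sigma,
    asymptote_lower = 1 - p$sigma
  )
}

#' Correlation length of the helical conformation
#'
#' `xi = 1/log(lambda1/lambda2)`, in repeat units: the characteristic run
#' length of correlated conformation. Finite for all `sigma > 0` (no true
#' phase transition in a 1D short-range model) and maximal at the transition
#' point `s = 1 - 2*sigma`.
#'
#' @inheritParams zb_spectrum
#' @return The correlation length as a single number.
#' @export
zb_correlation_length <- function(params) {
  p <- as_zb_params(params)
  ev <- eigen_pair(p$s, p$sigma)
  xi_from_pair(ev$lambda1, ev$lambda2)
}

#' Infinite-chain transition point and correlation-length maximum
#'
#' At `s* = 1 - 2*sigma` the two eigenvalue asymptotes cross, the eigenvalue
#' gap attains its minimum `2*sqrt(sigma*(1 - sigma))`, and the correlation
#' length attains its maximum `xi_max`. For small `sigma` the maximum is
#' well approximated by `0.5/sqrt(sigma)`.
#'
#' @param sigma Cooperativity parameter in (0, 1). For `sigma >= 0.5` the
#'   crossing point `1 - 2*sigma` leaves the physical range `s > 0`; it is
#'   returned anyway with a warning and `xi_max_exact = NA`.
#' @return A one-row tibble with columns `sigma`, `s_star_inf`,
#'   `xi_max_exact`, `xi_max_approx`, `gap_min`.
#' @examples
#' zb_transition_asymptotics(0.001)  # xi_max ~ 15.8
#' @export
zb_transition_asymptotics <- function(sigma) {
  check_scalar(sigma, "sigma")
  if (sigma <= 0 || sigma >= 1) {
    stop("`sigma` must lie strictly in (0, 1)", call. = FALSE)
  }
  s_star <- 1 - 2 * sigma
  if (s_star <= 0) {
    warning("sigma >= 0.5: crossing point 1 - 2*sigma = ", s_star,
            " leaves the physical range s > 0", call. = FALSE)
    xi_exact <- NA_real_
  } else {
    ev <- eigen_pair(s_star, sigma)
    xi_exact <- xi_from_pair(ev$lambda1, ev$lambda2)
  }
  tibble::tibble(
    sigma = sigma,
    s_star_inf = s_star,
    xi_max_exact = xi_exact,
    xi_max_approx = 0.5 / sqrt(sigma),
    gap_min = 2 * sqrt(sigma * (1 - sigma))
  )
}

# Exact maximal correlation length at the infinite-N transition point;
# the spatial yardstick all size scans are reduced by.
xi_max_exact <- function(sigma) {
  s_star <- 1 - 2 * sigma
  if (s_star <= 0) stop("sigma >= 0.5: no physical transition point", call. = FALSE)
  ev <- eigen_pair(s_star, sigma)
  xi_from_pair(ev$lambda1, ev$lambda2)
}
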