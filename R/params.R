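#' Model parameters for the helix-coil transfer matrix
#'
#' Constructs the parameter set of the Zimm-Bragg model in either of its two
#' equivalent parametrizations and carries both:
#'
#' * `{s, sigma}`: `s` is the helix propagation weight (Boltzmann weight of
#'   extending an existing helical run by one unit) and `sigma` the
#'   cooperativity parameter (penalty for initiating a new run).
#' * `{W, Q}`: `W = exp(U/T)` is the Boltzmann weight of a helical
#'   hydrogen bond and `Q` the phase-space volume (number of conformational
#'   states per repeat unit, one of which is helical).
#'
#' The two are linked by `s = (W - 1)/Q`, `sigma = 1/Q`, so that
#' `s + sigma = W/Q` and `log(s + sigma)` is the reduced free-energy cost
#' of helix formation per repeat unit.
#'
#' @param s Helix propagation weight, `s >= 0` (`s = 0` is the degenerate
#'   all-coil boundary, admitted with a message).
#' @param sigma Cooperativity parameter, strictly in (0, 1).
#' @param W Hydrogen-bond Boltzmann weight, `W >= 1`.
#' @param Q Phase-space volume, `Q > 1`; values below 2 trigger a warning
#'   since the spin derivation assumes at least two states per unit.
#' @param U Hydrogen-bond energy in temperature units (`k_B = 1`); optional,
#'   only needed for temperature mappings.
#'
#' @return An object of class `zb_params`: a list with fields `s`, `sigma`,
#'   `W`, `Q`, `U` and `beta_dG = log(s + sigma)`.
#'
#' @examples
#' zb_params(s = 1, sigma = 0.5)        # equivalent to W = 3, Q = 2
#' zb_params(W = 3, Q = 2)
#' @export
zb_params <- function(s = NULL, sigma = NULL, W = NULL, Q = NULL, U = NULL) {
  has_ss <- !is.null(s) || !is.null(sigma)
  has_wq <- !is.null(W) || !is.null(Q)
  if (has_ss && has_wq) {
    stop("supply exactly one parametrization: {s, sigma} or {W, Q}", call. = FALSE)
  }
  if (has_ss) {
    if (is.null(s) || is.null(sigma)) {
      stop("the {s, sigma} parametrization needs both `s` and `sigma`", call. = FALSE)
    }
    check_scalar(s, "s")
    check_scalar(sigma, "sigma")
    if (sigma <= 0 || sigma >= 1) {
      stop("`sigma` must lie strictly in (0, 1), got ", sigma, call. = FALSE)
    }
    if (s < 0) stop("`s` must be non-negative, got ", s, call. = FALSE)
    Q <- 1 / sigma
    W <- s / sigma + 1
  } else if (has_wq) {
    if (is.null(W) || is.null(Q)) {
      stop("the {W, Q} parametrization needs both `W` and `Q`", call. = FALSE)
    }
    check_scalar(W, "W")
    check_scalar(Q, "Q")
    if (Q <= 1) stop("`Q` must exceed 1, got ", Q, call. = FALSE)
    if (W < 1) stop("`W` must be at least 1, got ", W, call. = FALSE)
    s <- (W - 1) / Q
    sigma <- 1 / Q
  } else {
    stop("supply either {s, sigma} or {W, Q}", call. = FALSE)
  }
  if (Q < 2) {
    warning("Q = 1/sigma = ", signif(Q, 4),
            " < 2: the spin derivation assumes at least 2 states per unit",
            call. = FALSE)
  }
  if (s == 0) {
    rlang::inform("s = 0 (W = 1): degenerate all-coil boundary")
  }
  if (!is.null(U)) {
    check_scalar(U, "U")
    if (U <= 0) stop("`U` must be positive, got ", U, call. = FALSE)
  }
  structure(
    list(s = s, sigma = sigma, W = W, Q = Q, U = U,
         beta_dG = log(s + sigma)),
    class = "zb_params"
  )
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

as_zb_params <- function(x) {
  if (inherits(x, "zb_params")) x else stop("expected a `zb_params` object", call. = FALSE)
}

#' @export
print.zb_params <- function(x, ...) {
  cat("<zb_params>\n")
  cat(sprintf("  s = %.6g, sigma = %.6g   (W = %.6g, Q = %.6g)\n",
              x$s, x$sigma, x$W, x$Q))
  cat(sprintf("  beta*dG = log(s + sigma) = %.6g\n", x$beta_dG))
  if (!is.null(x$U)) cat(sprintf("  U = %.6g (k_B = 1)\n", x$U))
  invisible(x)
}

#' @rdname zb_params
#' @param x A `zb_params` object.
#' @param ... Unused.
#' @method as_tibble zb_params
#' @export
as_tibble.zb_params <- function(x, ...) {
  tibble::tibble(
    s = x$s, sigma = x$sigma, W = x$W, Q = x$Q,
    U = if (is.null(x$U)) NA_real_ else x$U,
    beta_dG = x$beta_dG
  )
}
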