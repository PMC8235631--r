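# Finite-chain partition functions, evaluated in log space.
#
# Exact open-chain form for N repeat units (N - 1 nearest-neighbour bonds):
#   Z = c1 lambda1^N + c2 lambda2^N,
#   c1 = (1 - lambda2)/(lambda1 - lambda2), c2 = (lambda1 - 1)/(lambda1 - lambda2),
# stored as lnZ = N log(lambda1) + log(c1 + c2 exp(-N/xi)) so arbitrarily
# large N never overflows. The same coefficients serve the Potts units
# (C1 = c1, C2 = c2 under Lambda = Q*lambda), whence
# lnZ_Potts = lnZ + N log(Q).

ln_partition_core <- function(s, sigma, N) {
  ev <- eigen_pair(s, sigma)
  c1 <- (1 - ev$lambda2) / ev$sq
  c2 <- (ev$lambda1 - 1) / ev$sq
  ln_l1 <- log(ev$lambda1)
  ln_l2 <- log(ev$lambda2)              # -Inf at the s = 0 boundary
  r <- exp(N * (ln_l2 - ln_l1))         # exp(-N/xi)
  list(lnZ = N * ln_l1 + log(c1 + c2 * r),
       c1 = c1, c2 = c2, ln_lambda1 = ln_l1, r = r)
}

# Single-sequence (zipper) partition function: all-coil plus every placement
# of one uninterrupted helical run of j bonds,
#   Z = 1 + sigma * sum_{j=1..N-1} (N - j) s^j
#     = 1 + sigma*s/(1-s)^2 * (N - 1 - N*s + s^N).
# The closed form is 0/0 at s = 1 and loses ~N|1-s|^-something digits of
# precision to cancellation whenever N|1-s| is small, so the algebraically
# identical positive power sum (no cancellation) is preferred for every
# integer N small enough to sum; the closed form serves non-integer N in
# smooth scans and very long chains. At s = 1 exactly,
# Z = 1 + sigma*N*(N-1)/2.
zipper_Z_reduced <- function(s, sigma, N) {
  if (s < 0) stop("`s` must be non-negative", call. = FALSE)
  if (N < 1) stop("chain length `N` must be at least 1", call. = FALSE)
  if (s == 1) return(1 + sigma * N * (N - 1) / 2)
  sum_safe <- N == round(N) && N <= 2e4 && (s <= 1 || N * log(s) < 700)
  if (sum_safe) {
    if (N < 2) return(1)
    j <- seq_len(N - 1)
    return(1 + sigma * sum((N - j) * s^j))
  }
  if (abs(1 - s) < 1e-3) {
    stop("zipper partition near s = 1 requires integer N <= 2e4 ",
         "(power-sum evaluation; the closed form cancels catastrophically)",
         call. = FALSE)
  }
  1 + sigma * s / (1 - s)^2 * (N - 1 - N * s + s^N)
}

# Unreduced zipper form: the first-order eigenvalues
#   lambda1 = 1 + sigma*s/(1-s), lambda2 = s - sigma*s/(1-s)
# substituted literally into the exact two-term partition function.
zipper_Z_unreduced <- function(s, sigma, N) {
  if (s == 1) {
    stop("zipper eigenvalue expansion is singular at s = 1; ",
         "use the reduced (closed-sum) zipper form", call. = FALSE)
  }
  eps <- sigma * s / (1 - s)
  l1 <- 1 + eps
  l2 <- s - eps
  gap <- l1 - l2
  c1 <- (1 - l2) / gap
  c2 <- (l1 - 1) / gap
  c1 * l1^N + c2 * l2^N
}

#' Log partition function of a finite chain
#'
#' Evaluates `log Z` for a chain of `N` repeat units under a named regime:
#'
#' * `"exact"` — the full two-eigenvalue expression, valid at any `N`;
#' * `"infinite"` — `N log(lambda1)`, the infinite-chain limit;
#' * `"long_chain"` — `N log(lambda1) + log(c1)`, valid once the chain
#'   holds many correlation lengths;
#' * `"zipper"` — the single-sequence approximation (at most one
#'   uninterrupted helical run), valid for `N` up to about `2*xi_max`;
#' * `"zipper_unreduced"` — the first-order zipper eigenvalues substituted
#'   into the exact two-term form (differs from `"zipper"` at second order
#'   in `sigma`).
#'
#' `N` may be non-integer for smooth scans (except the zipper power sum
#' near `s = 1`, which needs integer `N`).
#'
#' @param params A [zb_params()] object.
#' @param N Chain length(s) in repeat units, `N >= 1`; vectorized.
#' @param regime Approximation regime, see above.
#' @param warn_regime Emit a warning when the zipper form is requested
#'   beyond its validity window `N > 2*xi_max`. Default `TRUE`.
#' @return A tibble with one row per `N`: columns `N`, `regime`, `lnZ`,
#'   `c1`, `c2` (boundary coefficients, `NA` where the regime has none).
#' @examples
#' p <- zb_params(s = 1, sigma = 0.5)
#' zb_log_partition(p, N = 1:3)            # lnZ = 0, log 1.5, log 2.5
#' zb_log_partition(p, N = 3, regime = "zipper")
#' @export
zb_log_partition <- function(params, N,
                             regime = c("exact", "infinite", "long_chain",
                                        "zipper", "zipper_unreduced"),
                             warn_regime = TRUE) {
  p <- as_zb_params(params)
  regime <- match.arg(regime)
  if (!is.numeric(N) || length(N) < 1L || any(!is.finite(N)) || any(N < 1)) {
    stop("`N` must be numeric with all values >= 1", call. = FALSE)
  }
  if (regime %in% c("zipper", "zipper_unreduced") && warn_regime) {
    s_star <- 1 - 2 * p$sigma
    if (s_star > 0) {
      xm <- xi_max_exact(p$sigma)
      if (any(N > 2 * xm)) {
        warning("zipper (single-sequence) form used beyond its validity ",
                "window: N > 2*xi_max = ", signif(2 * xm, 4), call. = FALSE)
      }
    }
  }
  res <- switch(
    regime,
    exact = {
      core <- ln_partition_core(p$s, p$sigma, N)
      list(lnZ = core$lnZ, c1 = rep(core$c1, length(N)), c2 = rep(core$c2, length(N)))
    },
    infinite = {
      ev <- eigen_pair(p$s, p$sigma)
      list(lnZ = N * log(ev$lambda1), c1 = rep(NA_real_, length(N)),
           c2 = rep(NA_real_, length(N)))
    },
    long_chain = {
      core <- ln_partition_core(p$s, p$sigma, N)
      stopifnot(core$c1 > 0, core$c1 <= 1)
      list(lnZ = N * core$ln_lambda1 + log(core$c1),
           c1 = rep(core$c1, length(N)), c2 = rep(core$c2, length(N)))
    },
    zipper = {
      lnZ <- vapply(N, function(n) log(zipper_Z_reduced(p$s, p$sigma, n)), 0)
      list(lnZ = lnZ, c1 = rep(NA_real_, length(N)), c2 = rep(NA_real_, length(N)))
    },
    zipper_unreduced = {
      lnZ <- vapply(N, function(n) log(zipper_Z_unreduced(p$s, p$sigma, n)), 0)
      list(lnZ = lnZ, c1 = rep(NA_real_, length(N)), c2 = rep(NA_real_, length(N)))
    }
  )
  tibble::tibble(N = N, regime = regime, lnZ = res$lnZ, c1 = res$c1, c2 = res$c2)
}

#' Log partition function in Potts units
#'
#' The same chain counted with `Q` states per unit rather than the reduced
#' `{s, sigma}` weights: `lnZ_Potts = lnZ_exact + N log(Q)` exactly, with
#' identical boundary coefficients (`C1 = c1`, `C2 = c2` under
#' `Lambda = Q*lambda`). At `N = 1`, `Z_Potts = Q`; at `N = 2`,
#' `Z_Potts = Q^2 + W - 1`.
#'
#' @inheritParams zb_log_partition
#' @return A tibble with columns `N`, `regime` (`"exact"`), `lnZ`, `c1`, `c2`.
#' @examples
#' exp(zb_log_partition_potts(zb_params(W = 3, Q = 2), N = 2)$lnZ)  # 6
#' @export
zb_log_partition_potts <- function(params, N) {
  p <- as_zb_params(params)
  out <- zb_log_partition(p, N, regime = "exact")
  out$lnZ <- out$lnZ + N * log(p$Q)
  out
}

#' First-order zipper eigenvalues
#'
#' Expanding the exact eigenvalues to first order in the small parameter
#' `sigma*s/(1-s)^2` (the probability weight of a coil interruption) gives
#' `lambda1 = 1 + sigma*s/(1-s)` and `lambda2 = s - sigma*s/(1-s)` — the
#' eigenvalue limits behind the single-sequence (zipper) approximation.
#'
#' @inheritParams zb_log_partition
#' @return A one-row tibble with columns `lambda1`, `lambda2`,
#'   `small_parameter`.
#' @examples
#' zb_zipper_eigenvalues(zb_params(s = 0.5, sigma = 0.01))  # 1.01, 0.49
#' @export
zb_zipper_eigenvalues <- function(params) {
  p <- as_zb_params(params)
  if (p$s == 1) {
    stop("zipper eigenvalue expansion is singular at s = 1; ",
         "use zb_log_partition(..., regime = \"zipper\") which evaluates ",
         "the closed power sum", call. = FALSE)
  }
  eps <- p$sigma * p$s / (1 - p$s)
  small <- p$sigma * p$s / (1 - p$s)^2
  tibble::tibble(lambda1 = 1 + eps, lambda2 = p$s - eps,
                 small_parameter = small)
}
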