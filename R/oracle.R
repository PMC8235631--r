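# Brute-force enumeration oracles.
#
# Ground truth for small chains: every one of the Q^N spin configurations
# is visited by mixed-radix counting (in blocks, so memory stays bounded),
# the number of adjacent helical (1,1) pairs is counted, and configurations
# are accumulated into an integer histogram by bond count b = 0..N-1. Then
#   Z      = sum_b count_b * W^b
#   <b>    = sum_b count_b * b * W^b / Z.
# Integer counts make the small-N anchors effectively exact; no randomness
# anywhere.

bond_histogram <- function(N, Q) {
  total <- Q^N
  if (total > 1e7) {
    stop("Q^N = ", format(total), " exceeds the enumeration cap of 1e7; ",
         "use the transfer-matrix partition function instead", call. = FALSE)
  }
  counts <- numeric(N)               # index b + 1, b = 0..N-1
  if (N == 1L) {
    counts[1] <- Q
    return(counts)
  }
  block <- 1e6
  starts <- seq(0, total - 1, by = block)
  for (st in starts) {
    idx <- st:min(st + block - 1, total - 1)
    rem <- idx %/% Q
    prev_helical <- (idx %% Q) == 0   # digit 0 encodes the helical state
    bonds <- integer(length(idx))
    for (i in 2:N) {
      cur_helical <- (rem %% Q) == 0
      bonds <- bonds + (prev_helical & cur_helical)
      prev_helical <- cur_helical
      rem <- rem %/% Q
    }
    counts <- counts + tabulate(bonds + 1L, nbins = N)
  }
  counts
}

check_count <- function(x, name, min = 1) {
  check_scalar(x, name)
  if (x < min || x != round(x)) {
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(x)
}

#' Exhaustive partition function of the spin chain
#'
#' Enumerates all `Q^N` configurations of an open chain of `N` units with
#' `Q` states each (one helical), weighting each adjacent helical pair by
#' `W`: `Z = sum over configurations of W^bonds`, with `N - 1` possible
#' bonds. The independent ground truth for the transfer-matrix formulas.
#'
#' @param N Chain length (integer, `Q^N <= 1e7`).
#' @param Q Number of states per unit, integer `>= 2`.
#' @param W Bond weight, `W >= 1`.
#' @return The exact partition value (a single number).
#' @examples
#' zb_enumerate_partition(N = 2, Q = 3, W = 2)   # W + Q^2 - 1 = 10
#' zb_enumerate_partition(N = 3, Q = 2, W = 3)   # 20
#' @export
zb_enumerate_partition <- function(N, Q, W) {
  check_count(N, "N")
  check_count(Q, "Q", min = 2)
  check_scalar(W, "W")
  if (W < 1) stop("`W` must be at least 1", call. = FALSE)
  counts <- bond_histogram(N, Q)
  sum(counts * W^(seq_along(counts) - 1))
}

#' Exhaustive helicity degree of the spin chain
#'
#' Boltzmann-weighted mean bond count over all `Q^N` configurations,
#' normalized by `N`: the enumeration ground truth for the corrected
#' helicity definition.
#'
#' @inheritParams zb_enumerate_partition
#' @return The helicity degree (a single number in `[0, (N-1)/N]`).
#' @examples
#' zb_enumerate_helicity(N = 2, Q = 2, W = 3)  # 0.25
#' @export
zb_enumerate_helicity <- function(N, Q, W) {
  check_count(N, "N")
  check_count(Q, "Q", min = 2)
  check_scalar(W, "W")
  if (W < 1) stop("`W` must be at least 1", call. = FALSE)
  counts <- bond_histogram(N, Q)
  b <- seq_along(counts) - 1
  wts <- counts * W^b
  sum(wts * b) / (sum(wts) * N)
}

#' Exhaustive single-sequence (zipper) partition function
#'
#' Sums the all-coil configuration (weight 1) plus every placement of a
#' single uninterrupted helical run of `j` bonds (`N - j` placements,
#' weight `sigma * s^j`): `Z = 1 + sigma * sum_{j=1..N-1} (N - j) s^j`.
#' Linear time in `N`.
#'
#' @param N Chain length (integer, `N <= 1e5`).
#' @param s Helix propagation weight.
#' @param sigma Cooperativity parameter.
#' @return The exact zipper partition value.
#' @examples
#' zb_enumerate_zipper(N = 3, s = 1, sigma = 0.5)    # 2.5
#' zb_enumerate_zipper(N = 10, s = 1, sigma = 0.01)  # 1.45
#' @export
zb_enumerate_zipper <- function(N, s, sigma) {
  check_count(N, "N")
  if (N > 1e5) stop("`N` exceeds the linear-sum cap of 1e5", call. = FALSE)
  check_scalar(s, "s")
  check_scalar(sigma, "sigma")
  if (N == 1L) return(1)
  j <- seq_len(N - 1)
  1 + sigma * sum((N - j) * s^j)
}
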