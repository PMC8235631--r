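test_that("exact log partition reproduces hand-enumerated small chains", {
  p <- zb_params(s = 1, sigma = 0.5)
  out <- zb_log_partition(p, N = 1:3)
  # Z = 1 (one unit, no bonds), 1.5 (= 6/Q^2), 2.5 (= 20/Q^3)
  expect_equal(out$lnZ, c(0, log(1.5), log(2.5)), tolerance = 1e-12)
  expect_equal(out$c1 + out$c2, rep(1, 3), tolerance = 1e-12)
  expect_error(zb_log_partition(p, N = 0.5), "N")
})

test_that("Potts-unit partition equals Q^N times the reduced one", {
  expect_equal(exp(zb_log_partition_potts(zb_params(W = 3, Q = 2), 2)$lnZ), 6,
               tolerance = 1e-12)
  expect_equal(exp(zb_log_partition_potts(zb_params(W = 2, Q = 3), 2)$lnZ), 10,
               tolerance = 1e-12)
  for (Q in c(2, 5, 10)) {
    expect_equal(exp(zb_log_partition_potts(zb_params(W = 4, Q = Q), 1)$lnZ),
                 Q, tolerance = 1e-12)
  }
  draws <- draw_params(30, seed = 7L)
  for (i in seq_len(nrow(draws))) {
    p <- zb_params(s = draws$s[i], sigma = draws$sigma[i])
    N <- 1 + (i %% 9)
    expect_equal(zb_log_partition_potts(p, N)$lnZ,
                 zb_log_partition(p, N)$lnZ + N * log(p$Q),
                 tolerance = 1e-12)
  }
})

test_that("infinite and long-chain limits take their closed forms", {
  p <- zb_params(s = 1, sigma = 0.25)
  expect_equal(zb_log_partition(p, 10, "infinite")$lnZ, 10 * log(1.5),
               tolerance = 1e-12)
  expect_equal(zb_log_partition(p, 10, "long_chain")$lnZ,
               10 * log(1.5) + log(0.5), tolerance = 1e-12)

  p2 <- zb_params(s = 0.998, sigma = 0.001)
  expect_equal(zb_log_partition(p2, 158, "infinite")$lnZ,
               158 * log(1.0306069), tolerance = 1e-5)

  # long-chain approaches exact as (c2/c1) exp(-N/xi) dies out
  xi <- zb_correlation_length(p2)
  for (N in c(200, 500, 2000)) {
    out <- zb_log_partition(p2, N)
    gap <- out$lnZ - zb_log_partition(p2, N, "long_chain")$lnZ
    expect_equal(gap, log(1 + out$c2 / out$c1 * exp(-N / xi)),
                 tolerance = 1e-9)
  }

  # at small N the long-chain form undershoots the exact one
  p3 <- zb_params(s = 1, sigma = 0.5)
  expect_equal(exp(zb_log_partition(p3, 3, "long_chain")$lnZ),
               0.5 * ((2 + sqrt(2)) / 2)^3, tolerance = 1e-12)
  expect_lt(zb_log_partition(p3, 3, "long_chain")$lnZ,
            zb_log_partition(p3, 3)$lnZ)
})

test_that("exact lnZ handles huge N without overflow and is monotone", {
  p <- zb_params(s = 0.998, sigma = 0.001)
  big <- zb_log_partition(p, 1e9)$lnZ
  expect_true(is.finite(big))
  expect_equal(big / 1e9, log(1.0306069), tolerance = 1e-5)

  # nondecreasing in N and in s
  draws <- draw_params(10, seed = 11L)
  for (i in seq_len(nrow(draws))) {
    p <- zb_params(s = draws$s[i], sigma = draws$sigma[i])
    lnZ <- zb_log_partition(p, c(1, 2, 5, 10, 50, 200))$lnZ
    expect_true(all(diff(lnZ) >= -1e-12))
  }
  s_grid <- seq(0.1, 3, length.out = 50)
  lnZ_s <- vapply(s_grid, function(s)
    zb_log_partition(zb_params(s = s, sigma = 0.01), 40)$lnZ, 0)
  expect_true(all(diff(lnZ_s) > 0))
})

test_that("zipper eigenvalues follow the first-order expansion", {
  ze <- zb_zipper_eigenvalues(zb_params(s = 0.5, sigma = 0.01))
  expect_equal(ze$lambda1, 1.01, tolerance = 1e-12)
  expect_equal(ze$lambda2, 0.49, tolerance = 1e-12)
  expect_equal(zb_zipper_eigenvalues(zb_params(s = 0.9, sigma = 0.001))$small_parameter,
               0.09, tolerance = 1e-12)
  # zeroth order: lambda -> (1, s) as sigma -> 0
  ze0 <- zb_zipper_eigenvalues(zb_params(s = 0.7, sigma = 1e-9))
  expect_equal(ze0$lambda1, 1, tolerance = 1e-8)
  expect_equal(ze0$lambda2, 0.7, tolerance = 1e-8)
  expect_error(zb_zipper_eigenvalues(zb_params(s = 1, sigma = 0.01)),
               "singular")
})

test_that("reduced zipper partition matches its closed anchors", {
  p <- zb_params(s = 1, sigma = 0.5)
  expect_equal(exp(zb_log_partition(p, 3, "zipper")$lnZ), 2.5,
               tolerance = 1e-12)
  # N = 3 admits no two disjoint helical runs, so zipper equals exact
  expect_equal(zb_log_partition(p, 3, "zipper")$lnZ,
               zb_log_partition(p, 3)$lnZ, tolerance = 1e-12)
  p2 <- zb_params(s = 1, sigma = 0.01)
  expect_equal(exp(suppressWarnings(zb_log_partition(p2, 10, "zipper"))$lnZ),
               1.45, tolerance = 1e-12)
  expect_equal(exp(zb_log_partition(zb_params(s = 2, sigma = 0.3), 1,
                                    "zipper")$lnZ), 1, tolerance = 1e-12)
})

test_that("zipper closed form, power sum and enumeration are one identity", {
  for (sigma in c(0.5, 0.01, 0.001)) {
    for (s in c(0.5, 0.9, 0.998, 1.0, 1.1)) {
      for (N in c(1, 2, 5, 20, 100, 200)) {
        z_closed <- exp(suppressWarnings(
          zb_log_partition(zb_params(s = s, sigma = sigma), N, "zipper")$lnZ))
        z_enum <- zb_enumerate_zipper(N, s, sigma)
        expect_equal(z_closed, z_enum, tolerance = 1e-12)
        if (s == 1) {
          expect_equal(z_closed, 1 + sigma * N * (N - 1) / 2,
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("unreduced and reduced zipper forms differ at second order in sigma", {
  zip_diff <- function(s, sigma, N) {
    p <- zb_params(s = s, sigma = sigma)
    abs(exp(suppressWarnings(zb_log_partition(p, N, "zipper_unreduced")$lnZ)) -
          exp(suppressWarnings(zb_log_partition(p, N, "zipper")$lnZ)))
  }
  sig <- c(1e-2, 5e-3, 2.5e-3)
  # inside the single-sequence regime (N*sigma*s/(1-s)^2 well below 1) the
  # difference is quadratic in sigma: halving sigma shrinks it fourfold
  for (case in list(c(0.5, 10), c(0.5, 50), c(0.9, 10))) {
    d <- vapply(sig, function(sg) zip_diff(case[1], sg, case[2]), 0)
    expect_equal(d[1] / d[2], 4, tolerance = 0.2)
    expect_equal(d[2] / d[3], 4, tolerance = 0.2)
  }
  # outside it (s = 0.9, N = 50: expansion parameter ~ 45) higher orders
  # dominate and the ratio only decays toward 4 as sigma shrinks
  d_out <- vapply(c(sig, 1.25e-3, 6.25e-4),
                  function(sg) zip_diff(0.9, sg, 50), 0)
  ratios <- d_out[-length(d_out)] / d_out[-1]
  expect_true(all(diff(ratios) < 0))
  expect_lt(abs(ratios[length(ratios)] - 4), 1)
})

test_that("zipper form warns beyond its validity window", {
  p <- zb_params(s = 0.998, sigma = 0.001)
  expect_warning(zb_log_partition(p, 200, "zipper"), "validity")
  expect_silent(zb_log_partition(p, 20, "zipper"))
})
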