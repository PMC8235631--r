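# Shared helpers for the suite.

# relative deviation |a/b - 1|
rel_dev <- function(a, b) abs(a / b - 1)

# quiet parameter construction (silences the s = 0 boundary message)
zbp <- function(...) suppressMessages(zb_params(...))

# fixed-seed random parameter draws in the physical region
draw_params <- function(n, seed = 421L) {
  withr::with_seed(seed, {
    tibble::tibble(
      s = runif(n, 0.05, 3),
      sigma = runif(n, 1e-4, 0.5)
    )
  })
}
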