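# zimmbragg

Finite-size thermodynamics of the helix–coil transition in the Zimm–Bragg
model, for people who work with oligo- and polypeptides (or other
helix-forming biopolymers) at chain lengths where the textbook
infinite-chain formulas quietly stop being true.

## The science

A chain of *N* repeat units with *Q* conformational states per unit (one
helical) and bond weight *W* = e^(U/T) is the Potts-like form of the
Zimm–Bragg model; the classical parameters are *s* = (W−1)/Q (helix
propagation) and *σ* = 1/Q (cooperativity). Its transfer matrix has two
non-trivial eigenvalues

    λ₁,₂ = (1 + s ± √((1−s)² + 4σs)) / 2,

and the exact open-chain partition function is

    Z = c₁λ₁ᴺ + c₂λ₂ᴺ = λ₁ᴺ (c₁ + c₂ e^(−N/ξ)),
    c₁ = (1−λ₂)/(λ₁−λ₂),  c₂ = (λ₁−1)/(λ₁−λ₂),

with ξ = 1/ln(λ₁/λ₂) the correlation (persistence) length — maximal near
the transition, where ξ_max ≈ 0.5 σ^(−1/2). The package provides, all in
stable log space at any *N*:

* the exact Z and its three limits — infinite chain (λ₁ᴺ), long chain
  (c₁λ₁ᴺ), and the single-sequence **zipper** form
  Z = 1 + σ Σⱼ (N−j) sʲ — with their measured validity windows
  (zipper ≲ 2ξ, long chain ≳ 10ξ, infinite ≳ 500ξ, and an
  approximation **gap** at 2–10 ξ where only the exact form works);
* the helicity degree θ in both the classical (1/N) ∂lnZ/∂ln s and the
  corrected definition ×(s+σ)/s — the latter equal to the bond-weight
  derivative and to the enumeration mean bond count;
* melting analysis: the finite-chain transition point as the inflection
  θ″(s\*) = 0, the interval Δs = 1/θ′(s\*), and the reduced temperatures
  Tm/U = 1/ln(1 + s\*/σ), ΔT/U = Δs(Tm/U)²/(s\*+σ);
* size-scaling scans showing Tm saturating by ~10 ξ_max but ΔT needing
  hundreds of correlation lengths;
* brute-force enumeration oracles over all Qᴺ spin chains for small *N*;
* a command-line interface over all of the above.

## Worked example

```r
library(zimmbragg)

p <- zb_params(s = 0.998, sigma = 0.001)   # at the transition point 1 - 2*sigma
zb_spectrum(p)
#> # A tibble: 1 × 10
#>       s sigma lambda1 lambda2    gap    xi Lambda1 Lambda2 ...
#> 1 0.998 0.001    1.03   0.967 0.0632  15.8   1031.    967. ...
```

ξ = 15.8 repeat units: chains up to ~30 units are "oligomers" here, and
only beyond ~150 units does the long-chain formula become safe:

```r
zb_log_partition(p, N = c(10, 100, 1000))
#> # A tibble: 3 × 5
#>       N regime     lnZ    c1    c2
#> 1    10 exact   0.0439 0.516 0.484
#> 2   100 exact   2.35   0.516 0.484
#> 3  1000 exact  29.5    0.516 0.484

zb_regime_classify(0.001, c(20, 100, 1000, 10000))
#> [1] "zipper"     "gap"        "long_chain" "infinite"
```

A 100-unit chain (≈ 6 correlation lengths) melts at a noticeably shifted,
broadened transition relative to the infinite chain:

```r
zb_find_transition(sigma = 0.001, N = 100)
#> <zb_transition>
#>   sigma = 0.001, N = 100, definition = corrected
#>   s* = 1.012651   theta(s*) = 0.4128   delta_s = 0.17839
#>   Tm/U = 0.144481   dT/U = 0.0036737
```

The inflection sits above s = 1 with helicity 0.41 (not 0.5), and the
interval Δs = 0.178 is ~40% wider than the infinite-chain 4√σ = 0.126.
`tidy()`/`glance()` give tibble views; `zb_size_dependence_scan()` +
`plot_size_dependence()` reproduce the saturation picture across σ and
N/ξ_max; `zb_melting_curve()` sweeps temperature at fixed U.

The CLI wraps the same functions:

```sh
Rscript inst/cli/zimmbragg.R spectrum --sigma 0.001 --s 0.998
Rscript inst/cli/zimmbragg.R oracle --N 3 --Q 2 --W 3        # exact: 20
Rscript inst/cli/zimmbragg.R scan-size --sigma 0.01,0.001 --out scan.csv
```

## Method notes

See the methods vignette (`vignettes/finite-size-helix-coil.Rmd`) for the
model, the boundary convention, numerical choices (why the zipper power
sum replaces the closed form for integer N, the inflection search scheme),
and known limitations.
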