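# lpbarcode

Planning, simulation and analysis tools for **combinatorial optical
barcoding of single cells with laser particles (LPs)** — micron-scale
semiconductor microdisk lasers whose sub-nanometer emission lines turn
each tagged cell into a sorted vector of photon energies
E = (E₁, …, E_m), its optical barcode. The package is for experimenters
and analysts who need to answer, before and after an experiment:

* How many cells can I tag at a given error tolerance, with how many LPs
  per cell, over how wide a spectral band?
* How should the matching gate δ be set, given measured spectral jitter?
* How well can cells be re-identified across two measurement runs, and
  how do barcodes survive cell division?

## The model in brief

With *l* discrete colors and multiplicity *m*, B = C(l, m) ≈ l^m/m!
barcodes exist, and N cells duplicate with probability
ε_dup = 1 − (1 − 1/B)^(N−1) ≈ N/B. For continuously distributed lines
with density g(E), barcodes follow G_m(E) = m!·∏g(E_i); two barcodes are
identical when their Chebyshev distance is ≤ δ, and

    ε_dup = 1 − ∫ G_m(E)·(1 − (2δ)^m·G_m(E))^(N−1) dE,

which for uniform g reduces to the discrete form with
B_eff = (Δ/2δ)^m/m!. Measurement jitter φ(E′) — Gaussian or generalized
Gaussian exp(−(|E′|/α)^β) — misidentifies a barcode with probability
ε_noise = 1 − (∫₋δ^δ φ)^m, and the compound error
ε_tot = ε_dup + ε_noise − ε_dup·ε_noise has an interior minimum in δ that
`optimize_delta()` / `lp_plan()` locate. Poisson tagging, dual-mode LPs
(correlated line pairs 50–70 meV apart), duplicate-as-loss planning,
multiplet inheritance across divisions, spectral peak extraction and
cross-run matching are built on top; the methods vignette
(`vignettes/lp-barcoding-methods.Rmd`) derives and discusses each piece.

## Worked example

Plan a pool of 10,000 cells tagged with 3 LPs each over a 300 meV uniform
band, with 0.1 meV Gaussian jitter:

```r
library(lpbarcode)
g <- spectral_distribution("uniform", delta_big = 300)
plan <- lp_plan(joint_barcode_distribution(g),
                noise_model("gaussian", sigma_phi = 0.1),
                tagging_mixture("fixed", m = 3), N = 1e4)
plan
#> LP barcoding plan
#>   N = 10,000 cells, m = 3 LPs/cell, eps0 = 0.01
#>   gate delta = 0.3987 meV
#>   eps_dup = 0.00113, eps_noise = 0.000201, eps_tot = 0.00133
#>   B_eff = 8.878e+06 unique barcodes
#>   max pool size at eps0: 114,919 cells
```

The optimal gate (0.40 meV) balances duplication against noise: at that
δ the band supports ~8.9 million effective barcodes, the total error for
10⁴ cells is 0.13%, and up to ~115k cells stay under the 1% budget.

Simulate a two-run flow-cytometry experiment (Poisson tagging λ = 6,
six-envelope library, flow-cytometer noise preset, 10% cell loss before
run 2) and re-identify cells:

```r
lib <- make_library(library_spec())
ex <- make_two_run_experiment(lib, tagging_mixture("poisson", lambda = 6),
                              noise_preset("flow"), N = 2000,
                              cell_dropout = 0.10, seed = 7)
ms <- match_pools(ex$c1, ex$c2)
ms
#> Cross-run barcode match set
#>   runs: 1997 vs 1837 cells; candidates: 186781 cross, 185566 self
#>   threshold: 2.125 (q = 1e-05); accepted matches: 1729 (94.1% of smaller run)
```

The threshold is the upper 1−10⁻⁵ quantile of the self-match score
distribution (chance alignments within one run); the 94% of run-2 cells
re-identified here are one-to-one, score-ranked matches.

Estimate the jitter model from repeated measurements of the same LPs
(156 LPs × 71 repeats, as in the microscope characterization):

```r
fit <- fit_noise(make_repeat_measurements(156, 71,
                 noise_preset("microscope"), seed = 3))
fit
#> Generalized-Gaussian noise fit
#>   alpha = 0.04648 meV, beta = 1.262  (11076 fluctuation samples, 156 LPs)
#>   log-likelihood: 18348.53
```

recovering the preset (α = 0.047 meV, β = 1.28) within a few percent.

A thin command-line wrapper over the same functions is installed at
`inst/cli/lpbc` (subcommands `plan`, `simulate`, `divide`, `extract`,
`match`, `fit-noise`, `synth`).

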