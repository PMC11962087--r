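---
title: "Error models and matching for combinatorial laser-particle barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error models and matching for combinatorial laser-particle barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpbarcode)
```

## The problem

Laser particles (LPs) are micron-scale semiconductor microdisk lasers that
emit sub-nanometer spectral lines. A cell carrying several LPs acquires an
optical barcode: the sorted list of its emission-line photon energies,
$\mathbf{E} = (E_1, \ldots, E_m)$ with $E_j > E_i$ for $j > i$. Because
linewidths and measurement jitter are approximately constant in frequency,
everything in this package works in photon energy (meV), with
$E(\mathrm{meV}) = 10^3 \cdot 1239.84198 / \lambda(\mathrm{nm})$.

Two error sources limit how many cells such barcodes can distinguish:

* **duplication** — two cells draw indistinguishable barcodes from the
  finite spectral band, and
* **noise misidentification** — two measurements of the *same* cell
  disagree beyond the matching tolerance.

`lpbarcode` implements the planning theory for both, a pool simulator that
validates it empirically, a spectral extraction pipeline, and a cross-run
matching algorithm.

## Counting barcodes

With $l$ discrete colors and $m$ LPs per cell the barcode count is
$B = \binom{l}{m} \approx l^m/m!$ (`count_unique_barcodes()`). For $N$
cells drawing uniformly from $B$ barcodes the duplicate probability is

$$\varepsilon_{dup} = 1 - (1 - 1/B)^{N-1} \approx N/B ,$$

so tagging $10^4$ cells below a 1% duplicate rate requires $B = 10^6$
(`min_unique_barcodes()`). Continuously tunable LPs are modeled by a line
density $g(E)$: uniform over a band of width $\Delta$, Gaussian (with
$\Delta = \sqrt{12}\sigma$ so both cases share a standard deviation), a
Gaussian mixture such as the six-envelope fabrication library, or a
measured density on a grid. An $m$-line barcode follows
$G_m(\mathbf{E}) = m! \prod_i g(E_i)$ on the sorted domain.

Two sorted barcodes are called identical when their Chebyshev distance
$\max_i |E_{A,i} - E_{B,i}|$ is at most a half-gap $\delta$; measurements
with different $m$ are presumed distinct. The continuous duplicate rate is

$$\varepsilon_{dup} = 1 - \int G_m(\mathbf{E})
  \bigl(1 - (2\delta)^m G_m(\mathbf{E})\bigr)^{N-1}\, d\mathbf{E},$$

which for a uniform $g$ collapses to the discrete form with
$B_{e\!f\!f} = (\Delta/2\delta)^m / m!$. Non-uniform densities are
integrated by Monte Carlo (`duplicate_rate_continuous()`), drawing
$\mathbf{E} \sim G_m$ with a mandatory explicit seed and always reporting
the standard error; the factor $(2\delta)^m G_m$ is a probability and is
clamped to $[0,1]$ before exponentiation, because near density peaks and
large $\delta$ the raw product can exceed 1.

Per-line measurement jitter $\varphi(E')$ is Gaussian
($\sigma_\varphi$) or generalized Gaussian,
$\varphi(E') \propto e^{-(|E'|/\alpha)^\beta}$, which captures the
Lorentzian-like tails of measured LP jitter; $\beta = 2$ recovers a
Gaussian with $\sigma_\varphi = \alpha/\sqrt 2$. The probability that a
remeasurement escapes the gate on at least one of $m$ lines is

$$\varepsilon_{noise} = 1 - \Bigl(\int_{-\delta}^{\delta} \varphi \Bigr)^m,$$

with the inner integral evaluated as an error function (Gaussian) or a
regularized lower incomplete gamma $P(1/\beta, (\delta/\alpha)^\beta)$.
Two presets carry the fitted jitter regimes of the two readout
instruments: `noise_preset("microscope")` ($\alpha = 0.047$ meV,
$\beta = 1.28$) and `noise_preset("flow")` ($\alpha = 0.25$ meV,
$\beta = 1.37$).

The compound error is $\varepsilon_{tot} = \varepsilon_{dup} +
\varepsilon_{noise} - \varepsilon_{dup}\varepsilon_{noise}$. Because
$\varepsilon_{dup}$ grows and $\varepsilon_{noise}$ shrinks with
$\delta$, $\varepsilon_{tot}(\delta)$ has an interior minimum
$\delta_{opt}$; `optimize_delta()` locates it with a 200-point log-spaced
grid over $[10^{-3}, \Delta/2]$ meV followed by golden-section refinement
in the best bracket. Unimodality is assumed (observed throughout the
parameter ranges of interest); the grid guards against mild violations.
`max_pool_size()` inverts $\varepsilon_{min}(N) \le \varepsilon_0$ by
integer bisection over $N \in [2, 10^{12}]$, relying on the monotonicity
of the duplicate rate in $N$.

```{r plan}
u300 <- spectral_distribution("uniform", delta_big = 300)
plan <- lp_plan(joint_barcode_distribution(u300),
                noise_model("gaussian", sigma_phi = 0.1),
                tagging_mixture("fixed", m = 3), N = 1e4)
plan
```

## Stochastic tagging and duplicates as loss

Random tagging gives Poisson-distributed multiplicities; untagged cells
($m = 0$) carry no barcode and are reported as tagging loss, never folded
into $\varepsilon_{dup}$. Since duplication is only possible within a
multiplicity class, each class $m \ge 1$ of weight $w_m$ (renormalized
over $m \ge 1$) forms a sub-pool of size $N w_m$, and the pool-level
rates are the weighted sums (`mixture_error_rates()`; classes are
enumerated up to cumulative Poisson mass $1 - 10^{-6}$). When duplicates
can be detected and simply discarded, the sensible operating point sets
the gate so the *noise* error sits exactly on the budget,
$\varepsilon_{noise}(\delta) = \varepsilon_0$, and reports the weighted
duplicate fraction at that gate as sample loss (`duplicate_loss()`).

## Dual-mode LPs

A small fraction of LPs lase on two whispering-gallery modes at once,
emitting a correlated line pair separated by the resonator's free
spectral range (50–70 meV here). This correlation shrinks the effective
barcode space, so the joint density becomes the mixture
$G_m = (1 - f_{dm}) G_{sm} + f_{dm} G_{dm}$, where $G_{dm}$ places
exactly one correlated pair among the $m$ sorted lines (barcodes with two
or more dual-mode LPs are neglected, valid for $f_{dm} \ll 1$). The
simulator instead applies dual-mode lasing per LP with probability
$f_{dm}$, which is the generative counterpart of the same approximation.

## The pool simulator

`sample_pool()` draws cells, multiplicities, lines and dual-mode pairs
from one seed; `apply_noise()` perturbs lines and re-sorts;
`count_duplicates()` flags barcodes with at least one same-multiplicity
Chebyshev neighbor within $\delta$. The neighbor search sorts each
multiplicity class by its first coordinate and scans a sliding window —
any Chebyshev neighbor must lie within $\delta$ on coordinate one — then
verifies the full distance; this is exact and avoids the exponential
neighborhood growth a grid hash would suffer at high multiplicity. The
brute-force $O(n^2)$ oracle remains available (`method = "brute"`) and
the two paths are required to agree exactly in the test suite.

`simulate_divisions()` follows multiplet tagging through mitosis:
$k$-plets ($k$ LPs bound into one physical unit) are inherited whole,
each plet independently going to either daughter with probability 1/2
(a configurable even-split alternative is provided; the inheritance rule
is a modeling choice, not a measured quantity). Line energies are drawn
once and never change; per generation the gate is re-set by the noise
budget rule above using the current multiplicity distribution, and a cell
is identifiable iff it holds at least one line and no same-multiplicity
neighbor within the gate. Dual-mode lines are off by default in division
runs. Singlet tagging dilutes rapidly — daughters keep ever-fewer lines
and low-$m$ barcodes collide — while 3- and 4-plets guarantee $m \ge 3$
lines per inherited unit and hold a stable identifiable population; an
initial *rise* in identifiable cells occurs because cells tagged with
several plets spawn daughters with distinct barcodes.

## Spectral extraction

`detect_peaks()` finds local maxima whose topographic prominence exceeds
`min_prominence_mads` (default 8) times the MAD of the spectrum and thins
them to a `min_separation` (default 1 meV); the published pipeline does
not state its thresholds, so these defaults are engineering choices and
are exposed everywhere. `refine_peak()` fits a Gaussian plus constant
baseline (Levenberg–Marquardt) in a ±5-point window for sub-grid line
centers, falling back to a flagged parabolic vertex at grid edges or on
singular fits. For imaging data, where one LP spans several pixels,
`cluster_pixel_peaks()` single-links pixel peaks within a Chebyshev pixel
radius *and* an energy tolerance and averages each cluster's centers;
LP-to-cell assignment is supplied as input (it was performed manually in
the source workflow). Lines closer than the separation threshold merge —
a documented failure mode, not an error.

## Cross-run matching

To re-identify cells between two measurement runs, every candidate pair
(sharing at least one line within the 1.5 meV gate, found through a
sorted line index rather than all $n_1 n_2$ pairs) is scored

$$s = \sum_{\text{matched pairs}} \Bigl(1 - \tfrac{|\Delta E|}{1.5\,\mathrm{meV}}\Bigr)
 - 0.25 \times (\text{unmatched lines}),$$

on the order-preserving alignment that maximizes matched pairs and then
minimizes total $|\Delta E|$ (dynamic programming, verified against
exhaustive enumeration). The published method states the 1.5 meV gate but
not the penalty magnitudes; the linear kernel with `gap_penalty = 0.25`
and `min_matched_lines = 2` is this package's concrete instantiation and
all three are configurable. Correct matches form a high-score population
present only in the cross-run score set $S_{cross}$; the self-match set
$S_{self}$ (within-run pairs, identities excluded) contains only chance
alignments, so the acceptance threshold is its upper $1-q$ quantile
(default $q = 10^{-5}$, floored at the observed maximum when $q$ is
below $1/|S_{self}|$). Accepted pairs are resolved one-to-one greedily by
descending score. Note the contract's limits: cells with fewer than
`min_matched_lines` lines can never be candidates, and in very dense
pools the self-score maximum can exceed the identity score of low-$m$
cells, so even noise-free identical pools only reach 100% matching when
multiplicities clear those bars.

`fit_noise()` estimates $(\alpha, \beta)$ by maximum likelihood from
repeated measurements of the same LPs, pooling per-LP deviations from the
per-LP mean; the scale has a closed-form profile
$\hat\alpha(\beta) = (\beta \overline{|x|^\beta})^{1/\beta}$, leaving a
1-D profile-likelihood search over $\beta$. Per-LP centering shrinks the
fluctuation scale by $\sqrt{1 - 1/r}$ for $r$ repeats — negligible at the
71-repeat design the presets mirror, but visible for $r \lesssim 10$.

## What the synthetic data emulates — and what it does not

The generators reproduce: the six-envelope library (centers 825–1075 meV
spaced 50 meV; the per-envelope width is not published, so a 15 meV sd
was chosen once to overlap the envelopes into a quasi-continuous ~300 meV
band), sub-meV generalized-Gaussian line jitter at the two fitted
instrument regimes, Poisson multiplicity, dual-mode pairs at 50–70 meV
spacing, cell dropout between runs and optional per-line dropout. They do
not model lasing physics (pump thresholds, mode competition), LP loss or
exchange during culture, intensity-dependent detection efficiency, or
correlated (drift-like) noise; passing tests therefore demonstrate the
algorithms' correctness under the stated statistical model, not
instrument-level fidelity.

## Numerical choices and known limitations

* Gaussian line densities are truncated at $\pm 6\sigma$ and renormalized
  (neglected mass $< 2\times 10^{-9}$); the integration domain for the
  Gaussian case is not stated in the source and this truncation is this
  package's choice.
* The duplicate-rate integrand treats $(2\delta)^m G_m(\mathbf{E})$ as
  the exact hit probability of a Chebyshev cube. For barcodes whose
  neighboring lines are closer than $2\delta$ the cube protrudes past the
  sorted-domain diagonal and the formula slightly *overstates*
  duplication; the effect is at the $10^{-3}$ absolute level only when
  duplicate rates themselves are tens of percent, and is invisible at the
  sub-10% rates the planning regime targets. The simulation cross-checks
  in the test suite are therefore run at the per-pool (binomial + Monte
  Carlo) error scale.
* The per-cell interpretation of $\varepsilon_{dup}$ — a cell is in error
  if *any* other cell sits within $\delta$ — follows the
  $(1-x)^{N-1}$ structure of the formula; pair-event counting would
  differ at second order.
* Monte-Carlo defaults: $10^5$ samples, explicit seed required, standard
  errors always reported. `optimize_delta()` reuses one sample across the
  whole $\delta$ grid (common random numbers), so its objective is smooth
  in $\delta$.
* Problem sizes in the bundled checks — 50-seed pools at $N \le 10^4$ for
  theory validation, one $10^4$-cell two-run matching benchmark, division
  runs to generation 7 — were chosen as the smallest sizes at which the
  claimed effects are statistically unambiguous.
* Matching provides no per-pair confidence calibration; scores order
  candidates but are not probabilities.
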