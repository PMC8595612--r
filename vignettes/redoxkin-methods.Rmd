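---
title: "Methods: kinetic and binding analyses for peroxidase-hydroperoxide systems"
author: "redoxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic and binding analyses for peroxidase-hydroperoxide systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxkin)
```

## Scope

`redoxkin` estimates rate constants and binding constants for the reactions of
hydroperoxides — hydrogen peroxide and the epimeric tryptophan-derived
hydroperoxides (here called the *cis* and *trans* hydroperoxides, with their
alcohol reduction products) — with the thiol and selenium peroxidases that
remove them: 2-Cys peroxiredoxins (Prx2, Prx4), glutathione peroxidase 4
(GPx4) and thioredoxin reductase (TrxR), and with the heme dioxygenase IDO1
that *produces* the cis hydroperoxide from H2O2 and L-tryptophan. Raw traces
for such experiments are rarely deposited in machine-readable form, so every
analysis stage is paired with a seeded generator
(`gen_*`) that forward-simulates the assay it analyzes. The package is
validated by parameter recovery: data generated at known constants must be
inverted back to those constants by the corresponding stage.

## Gel-densitometry kinetics

A reduced peroxiredoxin monomer reacting with a hydroperoxide forms an
interchain disulfide dimer, monitored by non-reducing gels. At oxidant excess
the monomer band decays exponentially,
$M(t) = A e^{-k_\mathrm{obs} t} + c$, and $k_\mathrm{obs}$ is linear in the
oxidant concentration with slope equal to the second-order rate constant.

Choices that the raw method leaves open:

* **Free offset.** The exponential fit retains a plateau term because real
  gels show residual monomer; a constant lane is returned as a flagged
  degenerate fit with $k_\mathrm{obs}=0$ rather than an error.
* **Free intercept.** The $k_\mathrm{obs}$-versus-concentration regression is
  not forced through the origin; the intercept absorbs background monomer
  loss (autoxidation) and is reported alongside the slope.
* **Fitting machinery.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with an
  analytic Jacobian. The reported standard error of $k_\mathrm{obs}$ is an
  HC3 sandwich estimate: gel intensities carry multiplicative noise, and the
  classical homoscedastic standard error under-covers by a wide margin in
  simulation (about 80 % achieved coverage for a nominal 95 % interval,
  versus about 95 % for the sandwich form).
* **Weighting.** When per-concentration standard errors are available the
  slope regression is inverse-variance weighted and its standard error is
  the more conservative of the residual-based and propagation-based
  estimates; with three or four concentrations the residual-based estimate
  alone has too few degrees of freedom to be reliable.
* **Excess guard.** `blot_rate_constant()` warns when the oxidant excess over
  the enzyme is below 4-fold. The published designs span 1–8-fold, and the
  pseudo-first-order treatment is applied there regardless — the package
  reproduces that analysis but says so.

The generator integrates the bimolecular system exactly (per-dimer
stoichiometry by default: one hydroperoxide consumed per disulfide, i.e. half
per monomer lost, with a per-thiol switch) and has a clamped-oxidant mode
(`pseudo_first_order = TRUE`) in which the excess assumption holds exactly.
Recovery tests and the acceptance script use the clamped mode: under exact
bimolecular depletion at the published design (enzyme 5 µM, oxidant from
equimolar to 8-fold excess) the exponential-fit pipeline recovers the
generating constant with about −5 % bias, which is a property of the
published analysis applied to a depleting oxidant, not of this
implementation. Single-time-point estimates (`single_point_k()`, used for
weakly reacting Prx4) use the initial-rate form $v = k[E][\mathrm{ROOH}]$
and are flagged unreliable beyond 20 % conversion; as conversion goes to
zero the estimate converges to the integrated second-order solution.

## Progression-curve (Dalziel) kinetics

GPx4 follows a ping-pong mechanism whose linearized steady-state rate law is
the simplified Dalziel equation

$$\frac{E}{v_0} = \phi_0 + \frac{\phi_1}{[\mathrm{ROOH}]} +
\frac{\phi_2}{[\mathrm{GSH}]},$$

with $\phi_0 = 0$ for glutathione peroxidases (a free-$\phi_0$ mode exists
for other enzymes) and $k_{+1} = 1/\phi_1$, $k_{+2} = 1/\phi_2$ the
second-order constants of the peroxidatic and reductive half-reactions.
Substrate consumption is read from NADPH absorbance at 340 nm
($\varepsilon = 6220\ \mathrm{M^{-1}cm^{-1}}$, 1:1 NADPH:ROOH through the
glutathione-reductase couple), and GSH is treated as constant within a curve
(regenerated enzymatically).

Rather than a single endpoint initial rate — which at these parameters
consumes a third of the substrate in 30 s and biases $E/v_0$ —
`dalziel_points()` cuts each curve into consecutive windows (default 5 s),
takes the local finite-difference rate at the window's midpoint substrate
concentration, and feeds all windows into one regression. This removes the
depletion bias entirely on noise-free data (recovery of $k_{+1}$ to 0.01 %)
and turns substrate depletion into useful design variation in
$1/[\mathrm{ROOH}]$, so a single hydroperoxide level with three GSH levels
already separates $\phi_1$ from $\phi_2$.

Numerical choices: log-linear windows are restricted to where the substrate
is at least 10 % of its initial value (the logarithm and the reciprocal both
blow up below that); with the default 0.002 AU read noise, wider windows
(15–20 s) and weights $v_0^2$ (the delta-method variance of $E/v_0$ is
$\propto v_0^{-4}$) are recommended — with them, replicate recovery of
$k_{+1}$ has single-digit-percent median error, and the delta-method
confidence interval is mildly anticonservative (about 85 % achieved coverage
at nominal 95 %), which the tests assert honestly rather than paper over.
The non-enzymatic GSH channel is handled as in the wet protocol: a
buffer-only curve is analyzed identically and its pseudo-first-order constant
subtracted (`correct_nonenzymatic()`), flagged when the background dominates.
The correction is exposed per substrate because one control substrate
(phosphatidylcholine hydroperoxide) needs none.

## Competition kinetics

Two scavengers competing for one oxidant partition its flux in proportion to
$k_i C_i$. `competitor_k_from_suppression()` inverts an observed signal
fraction $f$ (with competitor ÷ without) with the direction made explicit,
because the approach is used in both orientations: the unknown's own product
suppressed by a known scavenger (monitored-competitor; IDO1 products
suppressed by Prx2), or a known enzyme's rate suppressed by the unknown
(monitored-reference; TrxR rates suppressed by Prx2). $f = 1$ is returned as
a flagged upper bound — exactly the situation in which the original analysis
reports a "≤" value — and uncertainty in $f$ propagates by the delta method.

The simple inversion assumes both scavenger concentrations constant. In the
IDO1 assay the reference scavenger (Prx2, 4 µM, no reductant present) is
consumed 1:1 by the oxidant (2 µM H2O2) while IDO1 is catalytic, so
`refine_by_depletion()` solves the integrated conservation relation

$$\mathrm{Prod} + P_0\left(1 - e^{-k_\mathrm{ref}\,\mathrm{Prod} /
(k_c C)}\right) = H_0$$

for $k_c$ by bracketed root finding on $\log_{10} k$. On the printed
observation (12 % product yield) the simple inversion gives
$5.5\times10^5\ \mathrm{M^{-1}s^{-1}}$ and the depletion-aware form
$4.1\times10^5$; the original report states $\sim3.2\times10^5$ without
showing its arithmetic, so only the order of magnitude ($10^5$, which all
three share) is treated as checkable. Both estimators are exported; the
depletion-aware one matches the assay design and is the package's preferred
reading.

## Mass-action network simulation

`reaction_network()` / `simulate()` integrate deterministic mass-action
kinetics with `deSolve`'s stiff-capable `lsoda` (relative tolerance 1e-8,
absolute 1e-12 M). The H2O2-partitioning network between Prx2 and IDO1
(`ido_prx_network()`) is the minimal model consistent with the published
conditions: Prx2 stoichiometric 1:1 per peroxidatic thiol (4 µM = 4 µM
thiols; no reductive recycling, as no thioredoxin system is present), IDO1
catalytic with L-tryptophan (100 µM, non-limiting) folded into its rate
constant, and the two products pooled. Alternative compositions are expressed
in the network definition, not in code. `product_yield()` runs the network to
completion — terminating on a root at 0.1 % oxidant residual rather than
integrating the flat post-completion tail, where dense-output interpolation
degrades — and `invert_yield()` recovers a rate constant from a target yield
by Brent root finding, with monotonicity checked from the bracket endpoints.

The simulator agrees with the analytic conservation relation above to better
than 0.5 % across four decades of the competitor constant. One published
qualitative claim deserves a note: at the two printed constants
($3.2\times10^5$ versus $8.0\times10^3$) the yield ratio on this network is
34.8, and it is bounded above by the ratio of the constants (40) because
yields are sublinear in the competitor constant; a greater-than-40-fold
separation holds for the constant the package itself infers from the printed
12 % yield ($4.1\times10^5$, ratio 43.5), and that is the form the acceptance
tests assert.

## Native-MS dissociation constants

For a protein P and ligand L at total concentrations $[P]_0, [L]_0$, with
charge-state-summed ion abundances of unbound and bound protein under the
equal-response assumption, the dissociation constant follows from the
abundance ratio and solution totals (`kd_from_areas()`); with several ligands
the bound fractions share a common denominator over all bound species. The
formula is algebraically exact for 1:1 binding, which the tests verify
against the equilibrium quadratic (`equilibrium_bound()`, evaluated in the
numerically stable form) to machine precision, and it is invariant to how
areas split across charge states. The equal-response assumption is the one
real approximation: a bound:unbound response ratio $\rho \neq 1$ biases the
constant monotonically, so `response_ratio` is exposed for sensitivity
sweeps, and declaring the true ratio undoes the bias exactly. Replicates are
summarized as mean ± SEM (`kd_replicate_summary()`). Peak areas are inputs;
only a windowed-sum helper for synthetic spectra is provided, not a peak
picker.

## Assay arithmetic

Beer–Lambert conversions use a fixed coefficient table
(`extinction_coefficients()`): NADPH 6220 (340 nm), TNB 14,100 (412 nm; one
TNB counted per free thiol — counting two per DTNB would double-count),
triiodide 29,700 (358 nm), HRP compound I Δ54,000 (403 nm, a difference
coefficient), and the cis/trans hydroperoxides 2750/2460 (295 nm), all
M⁻¹cm⁻¹. Blanks are explicit and subtracted before conversion.
Thiol-per-protein preparation windows (2–3 for wild-type Prx2, 1–2 for the
C51S mutant, 3–4 for Prx4) are closed intervals on the real ratio, no
rounding. The tissue-concentration estimate converts an analyte content per
mg into µM via an explicit protein-mass-per-tissue-mass parameter defaulting
to 1000 mg/g — the only value under which the printed arterial glutathione
figure (~540 µM from 0.4 nmol/mg and a 74 % cell-volume fraction) follows
from the stated inputs; the underlying per-mg-protein versus per-mg-tissue
convention is genuinely ambiguous in the source, so the parameter is exposed
rather than guessed. Isotope-dilution amounts are flagged against the assay
LODs (0.0125 pmol GSH-NEM, 0.005 pmol GSSG).

## Synthetic data: what it does and does not emulate

Noise models: multiplicative lognormal for gel intensities (positive,
scale-dependent; default CV 5 %) and additive Gaussian for absorbance
(default 0.002 AU); neither magnitude is reported in the source, so these are
fixed at typical assay precision and not tuned. All generators are
deterministic given `seed` and restore the global RNG state.

The generators reproduce the *statistical structure the analyses assume* —
exponential or mass-action kinetics plus well-behaved noise. They do not
emulate gel-to-gel transfer variation, baseline drift, hyperoxidation of the
peroxidatic cysteine, the two-disulfide dimer sub-bands, spectral shifts on
ligand binding, or charge-state-dependent response. Passing recovery tests
therefore demonstrates that the estimators are correct and well calibrated
under their stated models, not that those models exhaust real gels and
spectra.

## Problem sizes

The validation suite uses the published designs directly: 4 oxidant
concentrations × 6–9 time points per blot recovery, 3 GSH levels × 180 s
curves at 1 s sampling for the Dalziel recovery, 3-point initial-rate series,
and single-spectrum peak sets; replicate studies use 25–200 seeded
repetitions. These sizes were chosen to match the experiments being emulated
and keep every recovery deterministic and exact.

## Known limitations

* Temperature is metadata: constants measured at 5 °C and 25 °C are reported
  at their temperatures, with no Arrhenius correction (none is described in
  the source protocol).
* The Dalziel delta-method confidence intervals are mildly anticonservative
  under windowed noise (see above).
* The competition estimators assume exactly two channels; additional sinks
  must be folded into the reference constant.
* `run_pipeline()` is a thin orchestrator for the common stages, not a
  workflow engine; staged analyses beyond it are expected to be scripted
  against the exported functions directly.
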