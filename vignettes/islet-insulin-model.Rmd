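---
title: "Modeling the intra-islet insulin microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the intra-islet insulin microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletins)
```

## Why model this at all

Insulin has autocrine and paracrine actions on the islet cells that secrete
it, with its most potent anti-apoptotic and mitogenic effects in the high
picomolar range. Whether that signaling is dynamic or permanently saturated
hinges on the concentration of *monomeric* insulin — the only
receptor-competent form — in the islet extracellular space, which no current
technique measures in vivo. Two features make the naive guess ("it must be
enormous next to the source") wrong. First, insulin is secreted as
zinc-stabilized hexamer crystals that dissolve to dimers and then monomers
on a slow timescale, so fresh secretion is not immediately active ligand.
Second, the systemic circulation constantly returns degraded-but-surviving
peripheral insulin to the islet with arterial blood. The package models both
routes and asks what monomer concentration a β-cell receptor actually sees.

## The model and its assumptions

Four pools (all in pM) evolve under a clamped glucose `G` (mM): hexamer
particles `h`, dimers `d`, newly secreted local monomer `m`, and returned
peripheral monomer `Ip`:

$$
\begin{aligned}
h' &= s(G)/6 - p\,(h - q d^3)\\
d' &= 3p\,(h - q d^3) - \hat p\,(d - \hat q m^2)\\
m' &= 2\hat p\,(d - \hat q m^2) - (c + d_i)\,m\\
I_p' &= k m - d_i I_p
\end{aligned}
$$

with $s(G) = \sigma G^\gamma / (\alpha^\gamma + G^\gamma)$ the Hill
secretion response. Assumptions worth stating explicitly:

- Secretion enters entirely as hexamers, hence the division of $s(G)$ by 6;
  the stoichiometric factors 3 and 2 keep monomer mass consistent (one
  hexamer → three dimers → six monomers).
- Dissolution is net of re-aggregation: the flux terms $h - qd^3$ and
  $d - \hat q m^2$ carry the aggregation corrections. At islet
  concentrations (pM) these corrections are vanishingly small — a
  documented test shows $qd^{*3} < 10^{-10}$ pM and
  $\hat q m^{*2} < 10^{-3}$ pM at 7 mM glucose — but they are kept because
  they matter at injection-site (nM–µM) concentrations where the rate
  constants were originally measured.
- Degradation $d_i$ applies equally to local and peripheral insulin.
- Local monomer is cleared both by degradation and by transfer to the
  circulation ($c$); the returned pool is fed proportionally to local
  monomer production ($k m$). `c` and `k` are kept distinct: hepatic
  extraction and transit degradation intervene between leaving the islet
  and coming back, so the two coefficients need not be equal.
- The islet is well mixed; spatial structure and the direction of
  intra-islet blood flow are out of scope.
- Glucose enters only as a piecewise-constant clamp; coupled
  glucose–insulin feedback (IVGTT/meal models) is out of scope.

The system is cooperative, so it has a unique globally asymptotically
stable equilibrium, available in closed form in dependency order:

$$
m^* = \frac{s(G)}{c + d_i},\quad
I_p^* = \frac{k}{d_i} m^*,\quad
d^* = \frac{s(G)}{2\hat p} + \hat q m^{*2},\quad
h^* = \frac{s(G)}{6p} + q d^{*3}.
$$

Two consequences drive everything downstream. The new-to-returned monomer
ratio $m^*/I_p^* = d_i/k$ is glucose-independent, and the equilibrium
monomer pools $m^*, I_p^*$ do not depend on $p, \hat p, q, \hat q$ at all:
at steady state the dissolution chain passes the full secretion flux
whatever its internal rates. The property suite asserts both numerically.

## Parameters, defaults, and where they come from

| Parameter | Default | Unit | Origin |
|---|---|---|---|
| $\sigma$ | 112.0 | pM/min | Least-squares fit to the packaged secretion table |
| $\alpha$ | 9.40 | mM | same fit |
| $\gamma$ | 3.15 | — | same fit |
| $d_i$ | $\ln 2 / 6$ ≈ 0.1155 | 1/min | 6-min circulating half-life (in vivo range 4–6 min) |
| $k$ | $3 d_i$ ≈ 0.3466 | 1/min | 75% equilibrium peripheral share ⇒ $k/d_i = 3$ |
| $c$ | 0.3845 | 1/min | total monomer clearance $c + d_i = 0.5$/min |
| $p$ | 0.5 | 1/min | hexamer dissolution, subcutaneous-absorption literature (same for fast and slow analogues) |
| $\hat p$ | 1.0 | 1/min | constrained $\hat p > p$; monomer equilibria insensitive |
| $q$ | 1.6×10⁻¹⁵ | L²/pmol² | Semilente formulation coefficient, converted from 7.6×10⁻² ml²/U² |
| $\hat q$ | 10⁻⁷ | L/pmol | order of magnitude from monomer–dimer association; negligible at pM |

`default_params()` assembles this set, refitting the Hill response at call
time (cached per session) and attaching a provenance string per parameter
(`param_provenance()`). All anchors are overridable through
`calibration_anchors()` or a YAML config via `read_anchors()`.

Choices that were genuinely open:

- **Unit bridge.** The aggregation-coefficient conversion uses
  1 U/ml = 6.94×10⁶ pM. This is the unique convention under which the
  Semilente, Actrapid and Lispro rows of the published coefficient table
  are mutually consistent to their printed two significant figures; the
  alternative 1 U = 6.00 nmol reproduces none of them. Comparisons with
  printed coefficients use 5% relative tolerance to absorb the rounding.
- **Fit protocol.** "Least squares" is read as *unweighted* residual sum of
  squares over all seven table rows, including the three author-estimated
  anchor rows — they are part of the published fitting design. Because the
  SSE surface is multimodal in the Hill exponent, the fit runs bounded
  Levenberg–Marquardt from a fixed 36-point start grid
  (σ ∈ {50,100,150} × α ∈ {5,10,15} × γ ∈ {1,2,3,4}) within box bounds
  σ ∈ (0,500], α ∈ (0,50], γ ∈ [1,6], keeps the best converged SSE, and
  breaks near-ties toward the smallest exponent. An independent
  grid-search oracle in the tests bounds the attainable SSE (≈103
  (pM/min)²) that the optimizer must match.
- **Calibrating `c` and `k`.** The two transfer coefficients are anchored
  to two published model *outputs*: the ~75% equilibrium peripheral share
  fixes $k = 3d_i$, and the validated peripheral dose response fixes
  $c + d_i \approx 0.5$/min, since $I_p^* = (k/d_i)\,s(G)/(c+d_i)$. The
  physiological recirculation argument — 50% hepatic first-pass survival
  decayed over a 25-s circulation gives a returning fraction ≈0.476
  (`return_fraction()`) — is implemented and exposed, but no mapping from
  that dimensionless fraction to a rate constant reproduces both printed
  anchors, so it is not used in the default calibration. This remains an
  unreconciled loose end, deliberately left visible.
- **σ's unit.** The sources print the maximum secretion rate as
  "pM/min/mM", which is dimensionally inconsistent with a saturating Hill
  output; σ is treated as pM/min, consistent with the secretion table's
  rate column.
- **"Reached a maximum".** The step-response trajectory is monotone and
  has no finite-time maximum; settling is operationalized as first entry
  into the ±10% band around $I_p^*$, with linear interpolation between
  solver outputs (`time_to_fraction()`).

## Numerical choices

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) with relative
tolerance 10⁻⁸ and absolute tolerance 10⁻¹⁰ pM; the default initial state
is the empty islet, which global stability makes innocuous. Solver failures
surface as errors carrying the `istate` diagnostic rather than silent NA
traces. Equilibria are never obtained by integration when the closed form
is available; the two routes are compared in tests (≤0.1% discrepancy at
t = 1000 min). Degenerate inputs fail loudly: negative states, glucose or
half-lives are rejected at the boundary, fitting needs at least three
distinct glucose values, and a total clearance not exceeding $d_i$ is an
error because it would make the transfer rate nonpositive.

## What the synthetic generator does and does not emulate

`gen_secretion_data()` draws secretion rates from a Hill curve at the
seven-point glucose design of the packaged table with additive Gaussian
noise truncated at zero, reproducibly under a seed. Additive (rather than
relative) noise was chosen because the table's rates span only two orders
of magnitude and the measurement error of secretion-rate estimates is
dominated by absolute deconvolution error, not proportional error. The
generator emulates the *statistical shape* of the fitting problem — design
sparsity, noise level, zero-truncation — and nothing about real islet
physiology: no inter-subject variability, no correlated errors, no model
misspecification. Passing recovery tests therefore show the estimator is
consistent under its own assumptions, not that the Hill form is the true
secretion response. `gen_initial_states()` draws uniform nonnegative
states (default bound 10⁴ pM, far above any physiological value) to probe
positivity and global convergence from arbitrary starting points;
`perturb_params()` applies log-uniform multiplicative perturbations for
sensitivity checks, refusing any draw that violates $\hat p > p$.

Problem sizes used in the shipped tests: 100 random initial states for the
stability suite (integrated to t = 1000 min), 200 replicates at noise
sd 3 pM/min for median-error recovery, 500 replicates at sd 5 pM/min for
the bias check. These sizes give Monte-Carlo error comfortably below the
asserted margins while keeping the full suite in the minutes range on a
single core.

## Validation and known limitations

With the default calibration, equilibrium peripheral insulin at 5, 7 and
16.5 mM glucose lands at 80.9, 190.2 and 573.9 pM — within 0.4–4.1% of the
published model predictions (77.7, 186.3, 571.5 pM) and in approximate
agreement with the observed dose response (57.0, 167.4, 567.4 pM);
disagreement with observation is largest at fasting glucose, where
secretion is smallest and the Hill fit least constrained. Total intra-islet
monomer stays within ~50–300 pM across the physiological 4–7 mM range, and
after a 0→10 mM step the peripheral pool settles within 10% of equilibrium
in ≈25.5 min.

Limitations to keep in mind: the model is deliberately non-spatial, so it
cannot resolve gradients between upstream and downstream cells along the
intra-islet vasculature; glucose is exogenous, so no feedback of insulin on
glucose is represented; the published transient figure for the
new-monomer pool (≈100 pM at a 15 mM clamp) is not reproducible under any
single (c, k) consistent with the validated dose response and the 75/25
split — the calibrated model's self-consistent value is
$m^*(15\,\mathrm{mM}) \approx 182$ pM, and the package stands behind that
number; and all rate constants for oligomer kinetics are borrowed from
insulin-analogue absorption studies at far higher concentrations, which is
defensible precisely because the monomer equilibria are insensitive to
them.
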