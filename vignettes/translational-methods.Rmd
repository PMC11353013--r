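---
title: "Translating drug-combination viability screens into in vivo and clinical dose predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating drug-combination viability screens into in vivo and clinical dose predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combotrans)
```

`combotrans` implements a translational analysis chain for two-drug
combinations — built around a panRAF inhibitor (belvarafenib) plus a MEK
inhibitor (cobimetinib) in melanoma — that connects checkerboard viability
assays to xenograft growth predictions and clinical dose selection. This
vignette documents the models, their assumptions, the tunable parameters,
and the design decisions behind the implementation. The numbered scripts
under `analysis/` run each stage end to end; everything they call lives in
the package and is unit-tested.

## Synergy scoring on checkerboard matrices

A `combination_matrix` holds relative viability $v$ (control-normalized,
untreated $(0,0)$ cell $= 1$) on two ascending micromolar dose axes that
include a zero dose. The analysis proceeds in three steps.

**Smoothing.** Raw matrices are de-noised by fitting a four-parameter
log-logistic curve
$$v(d) = \text{lower} + \frac{\text{upper} - \text{lower}}{1 + (d/\mathrm{EC}_{50})^{h}}$$
along drug A at every fixed dose of drug B, the same along drug B, and
averaging the two fitted surfaces. We apply this crossed sweep as an
*alternating projection*: the sweep is repeated on its own output until the
largest cell change falls below `tol` (default $5\times10^{-4}$, at most 4
sweeps). A single sweep leaves spatially coherent residual patches — a
noise realization that happens to tilt one slice's fitted $\mathrm{EC}_{50}$
moves a whole row — and those patches are exactly what a top-$k$ synergy
score picks up. Surfaces already consistent with log-logistic slices in
both directions (e.g. any separable surface $v_A(d_A)\,v_B(d_B)$) are fixed
points of the sweep, so iterating does not distort them; empirically the
extra sweeps cut the null-matrix score bias by roughly half while
attenuating a genuine localized synergy bump by under 3%.

**Null models and excess.** Smoothed viability is clipped to $[0,1]$ and
converted to fractional inhibition $r = 1 - v$, so positive excess means
synergy. With smoothed single-agent margins $r_A(i) = r(i,0)$ and
$r_B(j) = r(0,j)$, each cell is compared against Bliss independence,
$E^{\mathrm{Bliss}}_{ij} = r_A + r_B - r_A r_B$, and the highest single
agent, $E^{\mathrm{HSA}}_{ij} = \max(r_A, r_B)$.

**Scores.** The Bliss (HSA) score is the mean of the
$\lceil 0.1\,N_\text{cells} \rceil$ largest excess values across the
matrix, margins included (their excess is identically zero, so inclusion is
conservative). We take *exactly* $\lceil 0.1 N \rceil$ cells rather than
extending through ties: with tie extension a matrix of 99 zero cells and
one 0.5 cell would score 0.005 instead of the intended 0.05 (the single hot
cell averaged over the top decile).

Fitting uses Levenberg–Marquardt least squares (`minpack.lm`) in
$\log \mathrm{EC}_{50}$ with five deterministic multi-starts
($\mathrm{EC}_{50}$ at the 0.1–0.9 dose quantiles, Hill slope 1 or 2); the
three-parameter form pins the upper asymptote at 1 and is used when the
untreated margin is within 0.1 of 1. The absolute IC50 (viability crossing
0.5) is reported separately from the fitted $\mathrm{EC}_{50}$ and is
undefined when the fitted floor sits above 0.5; AUC is the mean fractional
inhibition of the fitted curve over the tested log-dose grid.

## GR metric and in-vitro-to-in-vivo translation

Endpoint viability after $T$ hours of treatment is converted to the
growth-rate-inhibition metric using the untreated doubling time $T_d$
(60 h for the NRAS-mutant line, assayed at $T = 120$ h):
$$\mathrm{GR} = 2^{\,1 + \log_2(v)\,T_d/T} - 1, \qquad
  r_{\mathrm{norm}} = \log_2(\mathrm{GR} + 1) = 1 + \log_2(v)\,T_d/T .$$
$\mathrm{GR} = 1$ is untreated growth, 0 complete cytostasis, negative
values net cell loss; $r_{\mathrm{norm}}$ is the treated-to-control
growth-rate ratio. GR is computed from the smoothed matrix by default (a
switch restores the raw matrix), and a floor of $10^{-4}$ is applied to
viability before the logarithm.

Nominal doses become free concentrations through the media fraction
unbound (10% FBS defaults: 0.034 for belvarafenib, 0.196 for cobimetinib;
5% FBS alternates 0.068/0.3 selectable in config). In vitro free
concentration is treated as directly comparable to in vivo free plasma
concentration (conversion factor 1, exposed as a config scalar). Surfaces
are queried by bilinear interpolation in log10-dose space
(`pracma::interp2` underneath); because zero dose has no logarithm, queries
below the smallest tested dose bridge linearly in *linear* dose between the
zero-dose margin and the lowest-dose value, and queries above the grid
clamp to the boundary with a warning.

Xenograft prediction multiplies the vehicle growth rate — $k =
\ln 2 / 18\,\text{d} = 0.0385\,\text{d}^{-1}$ from the measured 18-day
doubling — by $r_{\mathrm{norm}}$ at the measured free plasma exposures
(8, 20, and 3 nM for the three single-agent arms, treated as constant
effective exposures; no mouse PK time course is modeled) and integrates
exponential growth from the 240 mm³ group-mean baseline:
$V(t) = V_0 e^{k\,r_{\mathrm{norm}}\,t}$.

## Population PK simulation

The clinical PK stage uses a deliberately generic one-compartment
first-order-absorption model with dose superposition,
$$C(t) = \sum_{t_d \le t} \frac{D\,k_a}{V\,(k_a - k_e)}
  \left(e^{-k_e (t-t_d)} - e^{-k_a (t-t_d)}\right), \quad k_e = CL/V,$$
evaluated in closed form on a 0.25 h grid (the $k_a = k_e$ limit
$\tfrac{D}{V} k_a t e^{-k_a t}$ avoids the singularity). Interindividual
variability is lognormal, $\theta_i = \theta\,e^{\eta_i}$,
$\eta_i \sim N(0, \omega^2)$, independent per parameter and individual.
Each regimen (QD/BID/QOD; QOD doses every 48 h from day 1) is simulated
for 30 days and days 22–26 are kept as the steady-state analysis window.
Concentrations convert as free µM $= (\text{ng/mL} \,/\, \text{MW g/mol})
\times f_u$, with MW 478.93 and 531.3 g/mol and plasma $f_u$ 0.00258 and
0.052 for the two drugs.

The published mixed-effects models behind the real compounds are not
reproducible from printed information, so the typical values here
(belvarafenib $CL/F = 5$ L/h, $V/F = 100$ L, $k_a = 0.5$/h; cobimetinib
$CL/F = 13$ L/h, $V/F = 800$ L, $k_a = 0.5$/h; $\omega$ = 0.3/0.3/0.5 for
CL/V/$k_a$) are calibration anchors chosen once so that mid-regimen mean
steady-state free exposures land inside the in vitro free-dose grids —
they support the translation workflow and make no claim about the real
drugs. No covariates, residual error, or interoccasion variability are
modeled: the projection consumes true concentrations.

## Exposure projection and patient variability

Regimen-level projection evaluates the GR and Bliss-excess surfaces at the
population mean free exposure of each regimen pair. Patient-level
projection samples patients (profile $i$ of each drug is paired by index;
no between-drug PK correlation is modeled), reads free concentrations once
per hour over a 48 h window starting at day 23 (≥ 2 QD/BID cycles, one
full QOD cycle), projects each time point, and pools the samples into
5/25/50/75/95% quantiles; per-patient means are also emitted. GR and Bliss
surfaces are interpolated independently.

## MAPK signaling surrogate

The mechanistic stage is an explicitly coarse-grained ODE surrogate of a
much larger rule-based MAPK model. States are fractional: RAS-GTP $R$, RAF
dimers $D$, feedback-phosphorylated RAF $F_p$ (free RAF
$F_u = 1 - F_p - 2D$ by conservation), pMEK $m$, pERK $e$:
$$\begin{aligned}
\dot R &= k_{\text{act}}(1-R) - k_{\text{hyd}}\,\phi_{\text{hyd}}\,R, &
\dot D &= k_{\text{dim}}\,\phi_{\text{stab}}\,R\,F_u^2 - k_{\text{undim}} D,\\
\dot F_p &= k_{\text{fb}}\,e\,F_u - k_{\text{fb,rev}} F_p, &
\dot m &= k_{\text{mek}}\,a\,(1-m)\,(1-(1-\alpha) b_M) - k_{\text{mek,p}} m,\\
\dot e &= k_{\text{erk}}\,m\,(1-b_M)(1-e) - k_{\text{erk,p}} e,
\end{aligned}$$
with rapid-equilibrium drug binding $b_R = B/(B + K_{d,\text{RAFi}})$,
$b_M = C/(C + K_{d,\text{MEKi}})$ (justified by separation of timescales)
and active RAF $a = 2D(1-b_R)$ for the NRAS variants or $1-b_R$ for the
BRAF variant, which omits the RAS/dimer/feedback states entirely (a
constant monomer driver). The three variants map the source model's edits:
NRAS Q61 reduces RAS-GTP hydrolysis 10-fold ($\phi_{\text{hyd}} = 0.1$) and
dimer stability 5-fold ($\phi_{\text{stab}} = 0.2$); the no-feedback
variant sets $k_{\text{fb}} = 0$; inhibitor binding is non-cooperative
across protomers. $\alpha = 0.3$ lets RAF phosphorylate inhibitor-bound MEK
at a reduced rate, which reproduces the pMEK *decrease* under MEK
inhibition in the BRAF context while inhibitor-bound pMEK cannot
phosphorylate ERK.

Steady states integrate with `deSolve::lsoda` (relative tolerance
$10^{-8}$) in 4 h blocks until every state changes by less than 0.1% over
a block, erroring after $10^4$ simulated hours. Dose matrices use the
10×10 grids (0 plus 9 log-spaced doses, cobimetinib $10^{-2.75}$–$10^0$
µM, belvarafenib $10^{-2.25}$–$10^{0.5}$ µM), report pMEK/pERK relative to
the drug-free state, and score Bliss excess on pERK inhibition with the
same machinery as the viability matrices. Timecourses run 24 h drug-free
from steady state, then 8 h after adding cobimetinib 0.5 µM with 0 or
0.133 µM belvarafenib, sampled at 0.1 h.

Default rate constants were chosen by a randomized tuning pass so the
*directional* property suite holds: paradoxical pMEK rise under
single-agent MEK inhibition only in the feedback-active NRAS variant, its
reversal by 133 nM of the panRAF inhibitor, pMEK decline in the BRAF and
no-feedback variants, pERK monotone in both doses, and the Bliss-excess
ordering NRAS > no-feedback and NRAS > BRAF. The MEK and ERK steps run in
a weakly saturating regime, which keeps the single-pathway BRAF variant
near Bliss-independent (max excess ≈ 0.02), so the NRAS excess (≈ 0.05)
isolates the feedback contribution. A structural limitation is worth
stating plainly: with proportional feedback of this form the loop gain is
bounded (dimerization contributes at most a square in $F_u$), single-agent
pERK responses cannot flatten below roughly the cube root of the direct
effect, and the surrogate's maximum Bliss excess stays near 0.05 — the
source model's quantitative excess values are not reproducible here, only
the ordering and signs. Parameter searches across three orders of
magnitude in every rate constant did not move this cap.

## Clinical tumor-growth-inhibition model

Tumor size follows the biexponential model
$TS(t) = TS_0\,(e^{-K_S t} + e^{K_G t} - 1)$ with growth and shrinkage
constants in 1/week; the nadir sits at $t^* = \ln(K_S/K_G)/(K_S+K_G)$ for
$K_S > K_G > 0$. Population empirical-Bayes machinery is replaced by
independent per-subject nonlinear least squares on log size with
non-negativity bounds, an analytic gradient, and a 4×4 multi-start grid
over $(K_G, K_S)$; monotone series land on the $K_S = 0$ boundary and are
flagged. Cohort summaries are means of per-subject estimates, and group
trajectories are simulated for 52 weeks from the shared baseline
$TS_0 = 50$ (units inherited from the size measure; treated as arbitrary).

## Synthetic data: what it emulates and what it does not

Every stage has a generator that emits its ground truth alongside the
data, so recovery tests consume stored truth rather than re-deriving it.

* **Combination matrices**: separable log-logistic margins (exact Bliss
  independence on the inhibition scale) minus an isotropic Gaussian
  synergy bump in log10-dose space — zero on the margins, so single-agent
  curves stay exactly log-logistic — truncated at 0, times multiplicative
  lognormal noise (CellTiter-Glo-like heteroscedasticity). Default noise
  SD 0.05; criterion-level tests use 0.02.
* **Screen panel**: 43 lines in three groups (15 BRAF-like, 14 NRAS-like,
  14 wild-type-like) on 9×9 half-log grids from 10 µM (panRAF inhibitor)
  and 5 µM (MEK inhibitor) tops. BRAF-like lines get potent MEK-inhibitor
  margins (mean log10 IC50 −2.0) and near-zero bump amplitude
  (0.02 ± 0.01); NRAS-like lines get shallower MEK-inhibitor response
  (−1.2, higher floor) and a positive bump (0.30 ± 0.05) centered at
  (0.3, 0.05) µM with width 0.6 decades; wild-type-like lines sit between.
* **Xenograft volumes**: exponential growth observed twice weekly over 21
  days (days 0,3,7,10,14,17,21) with lognormal measurement noise.
* **TGI cohorts**: per-subject $(K_G, K_S)$ lognormal around group means
  (defaults: 0.03/0.25 and 0.06/0.12 per week), 4-weekly observations over
  a year.

The generators deliberately omit plate and edge effects, batch structure,
replicate correlation, and any PK–response coupling beyond what the
pipeline itself imposes; passing tests therefore demonstrate correctness
of the computational chain under its stated statistical assumptions, not
robustness to real-world assay artifacts.

## Numerical choices and degenerate inputs

* Dose-response fits refuse fewer than 4 distinct nonzero doses;
  non-convergent fits fall back to a flagged flat curve at the mean.
* Matrix smoothing substitutes observed values for slices whose fit fails
  and warns.
* The steady-state criterion (0.1% relative change over 4 h) is evaluated
  block-wise with at least two blocks, so an initial condition placed at
  the fixed point still integrates 8 h before returning.
* The PK simulator resamples non-finite lognormal draws (counted and
  reported) and uses closed-form superposition rather than ODE
  integration; the ODE route exists in the test suite as an oracle.
* Problem sizes in the default test run are scaled to the method, not the
  data: 100-seed loops for score-bias properties, 200 replicates for
  noise-bias recovery, 500 individuals per PK regimen, 75 patients per
  projection — each completing in seconds to a couple of minutes.

## Reproducibility

All randomness flows through explicit integer seeds; identical seeds give
bit-identical outputs (asserted in the tests). `scripts/acceptance.R`
re-runs the main pipeline from scratch under a caller-supplied seed and
writes the headline quantities as JSON.
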