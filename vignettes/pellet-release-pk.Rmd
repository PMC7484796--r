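---
title: "Methods: release kinetics, response surfaces and bioequivalence for coated pellets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: release kinetics, response surfaces and bioequivalence for coated pellets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletpk)
```

`pelletpk` implements the computational chain of a quality-by-design (QbD)
extended-release pellet development program: micromeritic and morphometric
characterization of the pellets, model-dependent and model-independent
analysis of their dissolution profiles, response-surface analysis of the
coating design, non-compartmental pharmacokinetics of the resulting
formulations, average bioequivalence, bioanalytical validation metrics and
shelf-life estimation. Every input table the chain consumes can be produced
by a seeded synthetic-data generator, so the whole pipeline is exercisable
and testable without access to laboratory or clinical raw data. This
vignette records the models, the defaults, and the numerical and design
decisions behind the implementation.

## Particle characterization

Flow properties are computed from mass, bulk and tapped volume: bulk and
tapped densities (g/ml), the Carr compressibility index
$CI = 100\,(V_o - V_f)/V_o$ and the Hausner ratio $HR = V_o / V_f$. The
flow grade uses the compendial bands ($CI \le 10$ and $HR \le 1.11$
excellent; $CI$ 11–15 and $HR \le 1.18$ good). The angle of repose is
computed from heap geometry as $\alpha = \arctan(h / (b/2))$ and returned
in degrees, because the acceptance bands for it (25–30 excellent, 31–35
good) are stated in degrees.

Shape descriptors start from image-analysis measurements (area $A$,
perimeter $P$, Feret diameters, breadth $b$ and length $l$) rather than
pixels: circularity $4\pi A/P^2$, projection sphericity $4A/(\pi d_L^2)$,
aspect ratio $d_{max}/d_{min}$, circle-equivalent diameter
$d_{ce} = \sqrt{4A/\pi}$, and the two-dimensional shape factor
$$ e_R = \frac{2\pi}{P}\,\frac{r_e}{f} - \sqrt{1 - (b/l)^2},
   \qquad f = 1.008 - 0.231\,(1 - b/l). $$
Two conventions had to be fixed here because the defining formulas leave
them open:

* **Mean radius $r_e$** is taken as $d_{ce}/2$, the radius of the
  area-equivalent circle. It is the only radius computable from the listed
  measurements, and it makes a perfect circle score $e_R = 1/1.008 \approx
  0.992$ — consistent with values near 0.99 reported for visibly spherical
  pellets. A perimeter-based mean radius would be equally defensible but is
  not reconstructible from the available descriptors.
* **Longest Feret $d_L$** in the projection-sphericity formula is taken
  equal to $d_{max}$, the standard convention.
* The literature limiting values, 0.6 for $e_R$ and 1.1 for the aspect
  ratio, are read directionally as $e_R \ge 0.6$ and $AR \le 1.1$: sphericity
  degrades downward in $e_R$ and upward in $AR$.

All shape factors are scale invariant, which the test suite asserts as a
property.

## Dissolution kinetics

Seven release laws are supported (`release_models()`): zero-order,
first-order, Higuchi, Hixson–Crowell, Baker–Lonsdale, Jander and
Korsmeyer–Peppas. Releases are cumulative percent of label claim, capped
at 100%. Three printed forms required interpretation:

* **First order** is implemented as $Q(t) = 100(1 - e^{-K_1 t})$, the
  asymptotic form dissolution-fitting software uses; the log-linear identity
  it is usually printed as has no explicit asymptote and an ambiguous
  $Q_0$.
* **Hixson–Crowell** is applied to the *remaining* amount
  $W = 100 - Q$: $100^{1/3} - W^{1/3} = K_{HC}t$. Subtracting cube roots of
  released amounts, as the law is sometimes printed, is inconsistent at
  $t = 0$.
* **Korsmeyer–Peppas** is $Q = K t^n$ with $K$ carrying percent units, so
  that $n = 0.5$ reduces it exactly to Higuchi at equal rate constant. This
  matches the convention under which the two models' constants are
  interchangeable in published fit tables.

Baker–Lonsdale and Jander are fractional-release laws; predicted release
inverts them for $Q$ at each time (Jander in closed form, Baker–Lonsdale by
bracketed root finding to $10^{-13}$, exploiting that its left-hand side is
strictly increasing from 0 to 0.5 on $x \in [0,1]$).

**Fitting** is nonlinear least squares in the direct release domain — not
linearized regression — so all models compete on the same residual scale.
Because the 100% cap flattens the objective at large rate constants (which
defeats golden-section search on a wide bracket), one-parameter models are
initialized by per-point inversion of the law (median across points) and
bracketed on a fixed 81-point log grid before Brent refinement; the
power-law model starts from the log–log regression line plus a fixed
exponent grid, refined by Nelder–Mead then BFGS in log-parameter space.
All starts are deterministic, so a given profile always produces the same
fit; ties between starts go to the lowest residual sum of squares, then the
smaller rate constant. The suite verifies that every model recovers its own
noiseless parameters to better than $10^{-6}$ relative error and that the
power-law fit beats a brute-force lattice search.

Models are ranked by adjusted $R^2$, ties broken in favour of fewer
parameters. Peppas fits use the full profile by default (an optional
truncation at 60% release is a documented convention elsewhere but is not
applied silently).

Model-independent summaries: mean dissolution time (midpoint-weighted mean
of incremental release, first interval anchored at $t=0$, release 0),
dissolution efficiency (trapezoidal area under the release curve relative
to instantaneous complete release), $T_{90}$ (linear interpolation between
bracketing points; reported censored as "> last time" when 90% is never
reached — censored values are *excluded* from response-surface fitting, not
imputed), and the similarity factor
$$ f_2 = 50 \log_{10}\!\Big(100 \big/ \sqrt{1 + \tfrac1n\sum_t (R_t-T_t)^2}\Big), $$
computed over all shared time points by default. The regulatory truncation
after both profiles exceed 85% is available as a flag but off by default,
because published $f_2$ values for extended-release profiles of this kind
are computed on full curves. Mismatched time grids are an error — no silent
interpolation.

## Response-surface analysis of the coating design

`ccrd_design()` generates the central composite rotatable design: $2^k$
factorial corners at ±1, $2k$ axial points at $\pm(2^k)^{1/4}$ (1.6818 for
three factors) and replicated center points; run order is fixed rather than
randomized so designs are reproducible artifacts. The built-in factor table
(polymer center 7 g step 1 g; plasticizer 0.875 g step 0.125 g; anti-tacking
talc 4.375 g step 0.625 g) reproduces the actual axial levels 8.682, 1.085
and 5.426 g of the reference coating study.

`fit_rsm()` is ordinary least squares on the coded design matrix for the
linear, two-factor-interaction, quadratic and cubic orders. Fit-summary
statistics follow response-surface software conventions: root-MSE as `sd`,
$PRESS = \sum_i (e_i/(1-h_{ii}))^2$ through the hat matrix (verified in the
tests against explicit leave-one-out refits, an exact algebraic identity),
and predicted $R^2 = 1 - PRESS/TSS$, which is deliberately allowed to go
negative for overfitted models. Aliased terms — the cubic order is always
partially aliased on a 20-run CCRD — are dropped by QR pivoting and
reported by name. If a retained observation has leverage 1 its
leave-one-out prediction is undefined and PRESS is reported as infinite
rather than silently skipped.

`rsm_fit_summary()` builds the sequential (Type-I) model comparison: each
order's F statistic tests the terms it adds over the previous order against
its own residual mean square, one F/p pair per order, which mirrors the
fit-summary table structure of the design software this workflow emulates.
The recommendation is the highest-order non-aliased model with sequential
p < 0.05, ties broken by lower PRESS then lower SD; a response with no
significant order recommends the mean model, and a censored response is not
fitted at all.

## Pharmacokinetics and bioequivalence

`nca()` is a standard single-dose non-compartmental analysis: Cmax/Tmax read
off the observed points (first occurrence on ties), linear-trapezoidal AUC
and AUMC to the last positive concentration, extrapolation through the
terminal slope, $MRT = AUMC/AUC$, apparent clearance $Cl/F = D/AUC_\infty$
and $V_z/F = (Cl/F)/\lambda_z$. Decisions where practice varies:

* The **linear** trapezoidal rule is the default (the rule used by the NCA
  software of the era this workflow reproduces); lin-up/log-down is a flag.
* **$\lambda_z$** is chosen by maximizing adjusted $R^2$ over contiguous
  terminal windows of the last 3..m positive post-peak points, excluding the
  Cmax point; ties within $10^{-4}$ prefer more points. The tests pin this
  to a brute-force enumeration of all candidate windows.
* The pre-dose sample at $t=0$ is forced to zero concentration for
  single-dose analysis.

Average bioequivalence follows the crossover ANOVA on log-transformed
parameters: fixed effects for sequence, subject within sequence, period and
treatment; sequence tested against the subject-within-sequence mean square,
period and treatment against the residual. The geometric mean ratio is the
exponentiated adjusted treatment contrast with
$CI_{90} = \exp(\Delta \pm t_{0.05,\,df}\,SE)$, and the two-one-sided-tests
decision passes when the whole interval lies inside 0.80–1.25 (closed
bounds). Tmax is analysed on the log scale like the other parameters —
nonstandard, but it is how the reference study reports Tmax ratios, and
fidelity wins here. Zero-residual datasets yield a degenerate point
interval with a warning instead of an error, because summary tables with
near-zero dispersion do occur in practice and the pipeline must pass
through them.

**Mean-ratio mode** (`mean_ratio_be()`) computes point estimates as ratios
of published arithmetic means. It exists because subject-level data for the
reference study were never published: only the point estimates of its
bioequivalence table can be reconstructed, and the function is labelled
summary-level so it is never mistaken for a subject-level GMR. Its inputs
(the published mean table) ship as a plain CSV with the package. The fed
Tmax mean is taken from the narrative text (5.5798 h) rather than the
summary table (5.117 h); only the former is consistent with the published
Tmax ratio of 1.0903.

## Validation metrics and shelf life

Precision is $100\,s/\bar{x}$ with the sample (n−1) standard deviation,
accuracy $100\,\bar{x}/\text{nominal}$, recovery the matrix-to-solvent
response ratio, and the signal-to-noise gates are ≥7 for the lower limit of
quantification and ≥3 for the limit of detection. "Gross mean degradation"
in published stability tables has no recoverable formula (the printed
values are inconsistent with the printed means they accompany), so
`degradation()` implements the plain percent-loss-versus-baseline
definition and documents it as this package's definition; the printed
degradation cells are not reproduced.

Shelf life uses the simplest ICH Q1E case: a single-batch OLS regression of
assay on storage time and the earliest time at which the one-sided lower
95% confidence bound on the *mean response* crosses the acceptance limit
(default 90% of label claim), located by grid pre-scan plus root refinement
and reported to 0.01-month resolution. With zero residual noise the bound
collapses onto the fitted line and the crossing is exactly
$(\text{intercept} - \text{limit})/|\text{slope}|$. Multi-batch
poolability testing is out of scope.

## What the generators emulate — and what they do not

The synthetic-data module produces every table the chain consumes, with the
statistical structure the analyses assume:

* **Plasma profiles** come from a one-compartment model with first-order
  absorption, sampled on the 14-point schedule (0–48 h) of the reference
  study. Defaults: dose 60 mg, $k_a$ 1.5 h⁻¹ (immediate release) or
  0.45 h⁻¹ (extended release), $k_e$ 0.12 h⁻¹, $V/F$ 400 l. These
  reproduce the reference study's clearance (≈48 l/h), terminal volume
  (≈400 l) and elimination constant; the implied noiseless IR Cmax
  (≈120 ng/ml) then sits somewhat above the reported 98 ng/ml — with
  apparent (dose/F) parameters the full reported set cannot be matched
  simultaneously, and the rate/volume scale was preferred because the NCA
  calibration checks are written against it. Slowing absorption at
  unchanged $k_e$ and $V/F$ delays Tmax and lowers Cmax while preserving
  AUC, which is exactly the qualitative extended-vs-immediate pattern the
  direction checks assert. Between-subject variability (default CV 25%) is
  log-normal on $k_a$, $k_e$, $V/F$, drawn once per subject and shared
  across periods; assay error (default CV 10%) is multiplicative
  log-normal. The reported summary tables give no usable variability
  estimates (their SDs are orders of magnitude below biological
  plausibility), so both CVs are plausibility choices, made once.
* **Dissolution curves** add Gaussian noise to a kinetic-model prediction,
  then clip to [0, 100] and monotonize by running maximum — a cumulative
  curve cannot decrease.
* **Design responses** are polynomial surfaces on the coded CCRD plus
  Gaussian noise; **QC replicates** are normal with a stated CV;
  **stability batches** decay linearly.

They do not emulate: food-effect mechanisms (a fed arm is just a parameter
shift), multi-compartment disposition, heteroscedastic assay error,
inter-occasion variability, or non-linear stability kinetics. Passing tests
therefore demonstrate the correctness of the *analysis machinery* under the
stated generative assumptions, not the behaviour of real formulations.

## Problem sizes and reproducibility

All generators take explicit seeds and restore the caller's RNG state, so
identical specifications reproduce tables bit-for-bit. The statistical
checks in the test suite and acceptance script use sizes chosen to make
Monte-Carlo error small relative to the asserted tolerance: 10,000
simulated 2×2 studies for the 90% CI coverage check (binomial SE ≈ 0.3%,
asserted band ±1%), 2,000 for the TOST size bound at the 1.25 boundary,
200 replicates for the response-surface coefficient calibration, and dense
0.25-h sampling for the NCA closed-form recovery. The end-to-end pipeline
(`run_pipeline()`) is deterministic given its configuration and writes
schema-validated CSVs for every stage.

## Known limitations

* Published per-run design responses, subject-level PK values and the ANOVA
  behind the published confidence intervals are unavailable, so those
  numbers are not reproduction targets; only the self-consistent summary
  arithmetic (mean ratios, design levels, validation cells) is.
* The cubic response-surface order on a 20-run CCRD is reported with its
  aliasing and possibly infinite PRESS rather than hidden; it is never
  recommended by the fit summary.
* `nca()` assumes single-dose profiles starting at a zero pre-dose sample;
  steady-state superposition and urinary data are out of scope, as are
  replicate-design and scaled bioequivalence approaches.
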