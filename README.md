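# pelletpk

Analysis toolkit for quality-by-design (QbD) development of coated
extended-release (ER) pellet formulations. It covers the full computational
chain of such a program, from powder to plasma:

* **Characterization** — bulk/tapped density, Carr index, Hausner ratio,
  angle of repose, friability, capsule fill weight; pellet morphometrics
  (circularity, projection sphericity, aspect ratio, circle-equivalent
  diameter, and the elongation-corrected two-dimensional shape factor
  *e*<sub>R</sub> with correction factor *f* = 1.008 − 0.231(1 − *b*/*l*)),
  with acceptance classification (*e*<sub>R</sub> ≥ 0.6, AR ≤ 1.1).
* **Dissolution kinetics** — the seven classical release laws (zero-order,
  first-order, Higuchi, Hixson–Crowell, Baker–Lonsdale, Jander,
  Korsmeyer–Peppas *Q* = *K t*<sup>*n*</sup>) fitted by direct nonlinear
  least squares with deterministic multi-start, ranked by adjusted R²;
  mean dissolution time, dissolution efficiency, T<sub>90</sub>, and the
  *f*₂ similarity factor
  (*f*₂ = 50 log₁₀(100 / √(1 + mean((R−T)²))), similar when ≥ 50).
* **Design of experiments** — central composite rotatable designs
  (α = (2^k)^¼), coded↔actual level mapping, polynomial response-surface
  fits with SD, adjusted/predicted R², hat-matrix PRESS, sequential
  (Type-I) model F-tests, aliasing reports, and constraint-based selection
  of the optimal formulation.
* **Pharmacokinetics** — non-compartmental analysis (Cmax, Tmax, AUC/AUMC
  by trapezoidal rule, terminal λ<sub>z</sub> by best-adjusted-R² window,
  MRT, Cl/F, Vz/F) per subject-period.
* **Bioequivalence** — 2×2 crossover ANOVA on log-transformed parameters
  (sequence / subject-within-sequence / period / treatment), geometric mean
  ratio with 90% CI and the TOST decision against 0.80–1.25; plus a
  summary-level mean-ratio mode for reconstructing published point
  estimates when subject-level data are unavailable.
* **Bioanalytical validation and stability** — accuracy, precision (CV%),
  recovery, linearity, S/N-based LLOQ (≥7) / LLOD (≥3) gates, degradation,
  and ICH-style shelf-life from the lower 95% confidence bound of a
  stability regression.
* **Synthetic data** — seeded generators for every input: one-compartment
  first-order-absorption crossover plasma studies on a 14-point 0–48 h
  schedule, noisy monotone dissolution curves, CCRD responses from known
  polynomial surfaces, QC replicates, and linear stability batches.

It is aimed at formulation scientists and pharmacometricians who want the
standard computations of an ER pellet program in one reproducible, tested
place.

## Worked example

Simulate a noisy zero-order ER dissolution profile, identify its kinetics,
and summarize it:

```r
library(pelletpk)

pr <- gen_dissolution("zero", 7.9, 1:12, noise_sd = 1.2, seed = 7,
                      formulation_id = "ER-6pct")
rank_release_models(pr)
#> Release-kinetics model ranking (best first):
#>   korsmeyer_peppas  adj r2 = 0.99754  rss = 18.93
#>   zero              adj r2 = 0.99692  rss = 26.28
#>   hixson_crowell    adj r2 = 0.93031  rss = 594.9
#>   first             adj r2 = 0.88355  rss = 994.1
#>   ...
unlist(profile_summary(pr))
#>        mdt_h       de_pct        t90_h t90_censored
#>      6.16576     47.67551     11.24895      0.00000
```

The generating zero-order law is effectively recovered (the two-parameter
power law edges it on adjusted R² with an exponent near 1, the classic
nesting behaviour); the profile reaches 90% release at ≈ 11.2 h with a
mean dissolution time of ≈ 6.2 h and dissolution efficiency ≈ 48% —
extended release over the 12-h window.

Reconstruct published bioequivalence point estimates from summary means
(ER test vs IR reference, 60 mg meclizine HCl pellets):

```r
means <- meclizine_pk_means()
mean_ratio_be(setNames(means$part1_ir, means$parameter),
              setNames(means$part1_er, means$parameter))
#>    parameter reference_mean test_mean    ratio
#> 1 cmax_ng_ml        98.0512   84.0517 0.857223
#> 2     tmax_h         3.0295    5.1163 1.688827
#> 3    auc_0_t      1169.9639 1181.2261 1.009626
#> 4  auc_0_inf      1253.4172 1265.1170 1.009334
```

The ER formulation lowers the peak (Cmax ratio 0.857), delays it (Tmax
ratio 1.689) and leaves total exposure essentially unchanged (AUC ratios
≈ 1.01) — the signature of a successful extended-release conversion.

The whole chain runs end-to-end on synthetic data:

```r
run_pipeline(pipeline_config(seed = 1))
#> Synthetic pellet study pipeline (seed 1 )
#>   dissolution: best model zero, f2 = 73.4
#>   doe: recommended quadratic model
#>   pk: Cmax GMR 0.798 (90% CI 0.750-0.849)
#>   validation: QC low CV 1.24 %; shelf life 25.75 months
```

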