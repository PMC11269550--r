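---
title: "Tensor scalar decomposition with phantom-validated group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor scalar decomposition with phantom-validated group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdti)
```

## The model

Diffusion tensor imaging models water displacement in each voxel as a
zero-mean Gaussian with a symmetric, ideally positive-definite 3×3
covariance-like tensor **D** (diffusivities in mm²/s; brain tissue lives
around 0.2–2 × 10⁻³ mm²/s). All scalar summaries used here are symmetric
functions of the eigenvalues λ₁ ≥ λ₂ ≥ λ₃:

$$\mathrm{MD} = \bar\lambda, \qquad
  L = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}, \qquad
  q = \sqrt{\textstyle\sum_i(\lambda_i-\bar\lambda)^2}, \qquad
  \mathrm{FA} = \sqrt{\tfrac32}\,\frac{q}{L}.$$

$L$ is the Frobenius norm of **D** (total diffusion magnitude) and $q$ the
norm of its anisotropic (deviatoric) part, so $q^2 + 3\,\mathrm{MD}^2 =
L^2$ holds as an algebraic identity and FA is the ratio of the two
components. The point of carrying $q$ and $L$ separately is that FA is
blind to proportional changes: a process that scales all eigenvalues down —
increased cellularity crowding the extracellular space, for instance —
moves $L$, $q$ and MD but leaves FA untouched. The package therefore treats
the pair $(q, L)$ as first-class outputs next to MD and FA.

Conventions adopted in the scalar core:

- FA at the zero tensor is defined as 0 (the limit along isotropic
  tensors; the expression is otherwise 0/0) and FA is clamped to [0, 1].
- Negative eigenvalues from noisy fits are *retained* for MD, L and q so
  that diffusivity summaries stay unbiased; the voxel is flagged
  `nonphysical` and only FA is clamped. Ordering ties need no tie-break
  because every metric is a symmetric function of the spectrum.
- All diffusivities are carried in mm²/s end to end; no unit rescaling
  happens inside the math core.

## Tensor estimation

Signals follow the monoexponential model $S = S_0 e^{-b\,g^\top D g}$. The
default estimator is ordinary least squares on log-signals — deterministic,
closed-form, and exact on noiseless data, which is what makes the
round-trip tests sharp. A one-pass weighted refinement
(`fit_tensor_wls()`, weights equal to squared predicted signals) is
available as the usual variance stabilization for log-transformed Rician
magnitudes; it reduces to the log-linear fit on clean data, and a paired
simulation in the test suite checks it does not do worse at SNR 20.
Signals are clipped below at $10^{-6}\,\hat S_0$ before the log; the clip
count is surfaced in fit results and in the run report. Voxels outside the
mask are never fitted. There is no outlier rejection and no constrained
positive-definite fitting: with those refinements the estimator would no
longer be exactly invertible on clean data, and the phantom studies here
operate at SNR 30 where the plain fit is adequate.

## What the phantom emulates — and what it does not

`generate_cohort()` mirrors a three-group longitudinal design: sham,
short-interval and long-interval injury groups (n = 6 each by default),
imaged at two timepoints ("day50", "day90"), with six box-shaped ROIs
standing in for the sensorimotor cortex, corpus callosum (CC), hippocampus,
medial CC, external capsule (EC) and internal capsule (IC). Base
eigenvalue profiles are tissue-typical (gray matter ≈ (1.05, 0.80, 0.70) ×
10⁻³ mm²/s, FA ≈ 0.21; white matter ≈ (1.55, 0.45, 0.35) × 10⁻³, FA ≈
0.70), each region with a fixed principal direction.

The default effect template encodes the signed group findings the design
emulates, as eigenvalue-profile transforms:

| group | ROI    | days        | transform                 | effect                  |
|-------|--------|-------------|---------------------------|-------------------------|
| short | cortex | 50 and 90   | anisotropy shrink, ×0.88  | q, FA down; MD kept     |
| long  | CC     | 50 and 90   | anisotropy stretch, ×1.12 | q, FA up; MD kept       |
| short | EC, IC | 90 only     | uniform scale, ×0.90      | L, q, MD down; FA kept  |

The "anisotropy" transform maps $\lambda_i \mapsto \bar\lambda +
c(\lambda_i - \bar\lambda)$; the "scale" transform multiplies all
eigenvalues by $c$. The two transforms are exactly the two directions the
$(q, L)$ decomposition separates, which is what makes the phantom a fair
test of the metrics. Effect magnitudes are free design parameters (the
emulated study reports its group differences only graphically); 10–12%
shifts against 3% between-subject variability were chosen once as
realistic-and-detectable at n = 6 — an a-priori standardized effect of
roughly 2–3, giving ~90% power for the day-90 per-day contrast at the
Bonferroni-corrected level. Day-50 and day-90 profiles are independent
configuration entries with no longitudinal drift model; profiles are
constant across days except where the template says otherwise.

Biological variability is a multiplicative per-subject, per-ROI,
per-eigenvalue jitter (Normal, SD 0.03, held constant across timepoints so
that the within-subject correlation a repeated-measures design exploits is
actually present). Noise is Rician: magnitudes $\sqrt{(S+\epsilon_1)^2 +
\epsilon_2^2}$ with Gaussian channels of SD σ, default $S_0/30$. Every
stochastic stage draws from a sub-seed derived deterministically from the
master seed and a purpose label (`derive_seed()`), so cohorts are
bit-reproducible and stages are independently replayable.

What the phantom deliberately does **not** model: ROI geometry (boxes, not
atlas shapes — the scalar metrics only see the tensors inside each label),
partial volume, motion, eddy currents, susceptibility distortion,
multi-compartment tissue, operator variability in ROI tracing. Passing
tests therefore validate the *computational chain* — metrics, fitting,
aggregation, statistics — under a faithful noise and design model; they do
not certify performance on real scanner data with registration error or
atlas-traced ROIs.

Synthetic histology: per-subject cell counts for GFAP (astrocytes), CD-68
(microglia) and NeuN (neurons) are drawn from per-(stain, ROI) linear
models on the subject's ground-truth ROI-mean q at the final timepoint,
$\text{count} = \mathrm{round}(\max(0, a + b\,q + \epsilon))$. GFAP and
CD-68 couple negatively to q; NeuN couples positively in gray matter (low
cortical q co-occurring with neuronal loss). Only a histology subgroup
(default 4 sham / 3 short / 4 long, n = 11) receives counts, so the
unequal-n Tukey–Kramer path is exercised by construction. For coupled
rows the count-noise SD is calibrated so the *population* correlation
equals the target (default −0.65 for GFAP): given slope $b$ and the spread
$s_q$ of q implied by the profiles, jitter and subgroup weights,
$\sigma_\epsilon = |b|\,s_q\sqrt{1/r^2-1}$. The spread is evaluated by a
fixed-seed Monte-Carlo draw internal to `default_ihc_coupling()`, making
the calibration deterministic. Note the acceptance check on the *mean
sample* correlation at n = 11 must allow for the standard small-sample
attenuation of sample r (≈ $\rho(1-\rho^2)/2n$ ≈ 0.017 here); the band of
±0.04 around −0.65 covers Monte-Carlo error plus that bias and was fixed
before any measurement.

## The statistical battery

Per ROI × metric, `rm_anova()` runs the classical split-plot decomposition
with group as the between-subjects factor and timepoint within: the group
effect is tested against the subject-within-group stratum, timepoint and
interaction against the subject × timepoint stratum (implemented on
`stats::aov()` error strata; an independent sums-of-squares oracle in the
test suite checks the F values to 10⁻¹⁰). With exactly two within-subject
levels sphericity holds trivially, so no correction is applied — this is a
property of the design, not an omission. Sums of squares are sequential
(group, timepoint, interaction), which coincides with Type III on the
balanced designs the generator produces; for unbalanced *groups* the group
test is unaffected (it is the only term in its stratum) but the
within-stratum terms are order-dependent, which is documented rather than
hidden. Effects whose sum of squares is zero by construction come back
from the QR as ~10⁻³⁰; anything below a relative floor of 10⁻¹² of the
total SS is reported as exactly F = 0, p = 1.

Post hocs compare all group pairs, by default separately at each timepoint
(matching how per-day findings are reported in this kind of study;
averaging over days is available as `mode = "averaged"`), declaring
significance at raw p < α/3 with the capped Bonferroni p alongside.
Histology counts get one-way ANOVA with Tukey HSD (`stats::TukeyHSD`,
Tukey–Kramer under unequal n; validated in the tests against a direct
numerical integration of the studentized-range distribution). The
metric–histology relationship uses the Pearson coefficient with a two-sided
t-based p and the least-squares line, pooling all groups — the regression
design of the emulated study. All tests are two-sided.

## Problem sizes and numerical choices

The validation studies run at sizes chosen to make their Monte-Carlo error
small relative to the property being checked while staying desk-scale:

- scalar identities: 10⁵ random physical tensors (uniform eigenvalues on
  0.1–2.2 × 10⁻³ mm²/s, Haar-random rotations); identity residuals are
  checked at 10⁻¹² (FA) and 10⁻¹⁸ (mm²/s)² (quadratic), far above
  round-off but far below any real effect;
- round trips: noiseless 30-direction, b = 1000 s/mm² schemes; recovery to
  10⁻⁸ relative;
- type-I calibration: 2,000 null cohorts (identical group profiles, Rician
  noise, full simulate → fit → test chain) on a 6×4×1 grid with the
  7-volume minimal scheme and n = 4 per group; the group-test rejection
  rate at α = 0.05 is required to land in [0.04, 0.06] (±2 binomial SE);
- effect recovery: 200 cohorts on a 24×24×2 grid with 30 directions at
  default noise; the detection event is the headline remote-WM contrast
  (short-interval EC q below sham at day 90, per-day Bonferroni level),
  required in ≥ 80%;
- coupling recovery: 500 seeds, ground-truth-only cohorts, mean sample r
  within 0.04 of −0.65 as motivated above.

`scripts/acceptance.R` re-runs the same studies at moderately reduced
replication (800 / 100 / 300) and prints each quantity with the n used.

Other numerical choices: gradient directions come from a spherical
Fibonacci spiral (rotated by a seed-derived rotation), except n = 6 which
uses the icosahedral vertex set — the 6-point spiral is degenerate in
quadratic-form space and would not identify the tensor; schemes are
validated by requiring design-matrix rank 7. Eigenvalues come from
LAPACK's symmetric solver per voxel. The box label map shrinks each block
by a one-voxel background margin when the grid allows it, guaranteeing
non-empty ROIs down to 6×4×1 grids.

## Known limitations

Box ROIs and single-direction tensors per region make ROI means noiseless
summaries of a single ground-truth tensor — real ROIs average
heterogeneous voxels. The log-linear fit is mildly biased under Rician
noise at low SNR; the phantom's default SNR 30 keeps this second-order,
and the bias is surfaced (not removed) by the Monte-Carlo fitting tests.
The rmANOVA assumes complete cases and refuses imputation. Nothing here
corrects for multiplicity *across* ROIs or metrics — intentionally, to
match the analysis style it emulates; treat per-cell significance
accordingly.
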