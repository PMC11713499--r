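---
title: "Methods: synthetic-CT validation with sctQA"
author: "sctQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-CT validation with sctQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The validation problem

MR-only radiotherapy planning replaces the planning CT (pCT) with a
synthetic CT (sCT) derived from MR images. Because dose is calculated
from electron density inferred from Hounsfield units (HU), any HU error
in the sCT can change the delivered dose. Validating an sCT algorithm
therefore has two coupled halves:

1. **Image quality** — how closely do the sCT's HU track the pCT's,
   summarized by ME, MAE, RMSE, PSNR and SSIM?
2. **Dosimetric agreement** — if the same treatment plan is recalculated
   on the sCT, do the dose–volume-histogram (DVH) metrics of targets and
   organs at risk move, and does a 3D gamma analysis of the two dose
   grids pass clinical criteria?

sctQA implements this chain and the statistics that join the two halves
(per-metric group tests, paired reference/evaluated tests, and the
Spearman correlation of image-quality metrics with gamma pass rates).
Because clinical DICOM cohorts cannot ship with a package, a digital
head-phantom generator stands in for patients: it produces pCT/sCT pairs
whose *error structure* is controlled, so every stage of the pipeline is
testable against known ground truth.

# Data model and coordinate conventions

All volumes are axis-aligned `ScalarVolume` objects: a 3D array plus
per-axis spacing (mm) and the world position of the **center** of voxel
(0,0,0). Voxel indices are 0-based and world = origin + index · spacing.
These choices make `worldToIndex`/`indexToWorld` exact inverses and put
voxel centers — the sampling points of every downstream metric — at
integer indices. Orientation handling is deliberately minimal: NIfTI
files with per-axis flips are normalized to positive spacing at load
time; oblique or permuted affines are rejected rather than silently
mishandled. Grid equality is tested with a 1e-6 mm tolerance so geometry
that has round-tripped through text headers still compares equal.

Displacement fields use *pull* (backward-warping) semantics: the
displacement stored at a reference voxel is **added** to that voxel's
world position to find the sampling location in the moving volume. This
matches how resampling filters consume transforms; the alternative
(push) convention cannot be resampled without scattering.

Resampling (`resampleToReference`) interpolates trilinearly, clamps CT
values below −1000 HU (air) and fills out-of-extent samples with the
same floor; dose resampling uses a floor of 0 Gy. Trilinear
interpolation is exact at voxel centers and bounded by the eight
surrounding voxel values, properties the test suite asserts.

# Preprocessing

Two conditioning steps precede any comparison:

- **Accessory removal** (`zeroOutsideBody`): couch and immobilization
  hardware are visible in the pCT but absent from MR-derived images, so
  voxels outside the BODY contour are overwritten. The default outside
  value is 0 HU, the water-equivalent convention used by existing
  accessory-removal workflows; −1000 HU (air) is arguably the more
  physical choice and is available via `outsideValue`. The package
  supports both because the two conventions change the full-grid MAE of
  a pair but not any BODY-restricted metric.
- **Grid alignment** (`alignPair`): the sCT is resampled onto the pCT
  grid, optionally through a displacement field that corrects
  positioning and organ-motion differences between the two acquisition
  sessions. Estimating that field is deliberately out of scope — the
  package consumes a DVF, it does not register images. The planning
  member is never modified.

# Image-quality metrics

ME keeps the sign (positive = sCT reads high), MAE the magnitude, RMSE
up-weights large deviations; `RMSE ≥ MAE ≥ |ME|` always, and the suite
checks this chain on every phantom pair. PSNR is `10·log10(peak²/MSE)`
dB with the peak defaulting to the sCT maximum over the ROI (an option
fixes it, e.g. at 3000 HU, when cross-case comparability matters more
than per-case fidelity); identical inputs return the `Inf` sentinel
rather than an arbitrary large number. SSIM uses the standard
stabilization constants `C1 = (0.01 L)²`, `C2 = (0.03 L)²` with `L`
defaulting to the observed pCT dynamic range over the ROI.

Two SSIM modes are provided because a single scalar per case can be
computed either way: **global** (the default) evaluates the formula once
from ROI-wide moments, which is what a one-number-per-case report
implies; **windowed** averages the formula over sliding cubic windows
(mask-aware box filters built from integral volumes), which is sensitive
to local structural disagreement that global moments wash out. An
optional joint min–max normalization to [0, 1] is available for both
PSNR and SSIM inputs; under it (with constants scaling with that range)
a common additive offset cancels exactly, which the suite tests in
windowed mode.

The comparison ROI defaults to the full common grid. This mirrors
whole-volume reporting practice but makes the error metrics depend on
how much surrounding air is included — air agrees trivially and dilutes
MAE. A BODY-restricted ROI (`roiMode = "body"`) is therefore offered and
is the right choice when comparing across cohorts with different fields
of view.

# DVH metrics

Structure membership is by voxel center with no partial-volume
weighting: the masks come either from rasterized contours or from the
phantom, and in both cases a voxel is in or out. The cumulative curve
reports, for each dose edge, the fraction of structure volume receiving
at least that dose; it is 1 at 0 Gy, 0 beyond the maximum, monotone
non-increasing, and refining the bin width (default 0.01 Gy) never
changes D-mean, D-max or any `V_x%`, because those are computed from the
voxel doses directly, not from the binned curve. D-max is the single
maximum voxel dose (a true point dose), not a small-volume surrogate
like D0.03cc.

`diffMetrics` reports evaluated − reference differences both absolutely
and normalized as `100·(evaluated − reference)/reference`. The
normalized form is defined relative to the reference (planning-CT) value
— the natural baseline when the pCT is ground truth — and is flagged
`NA` whenever the reference is (numerically) zero, which happens
routinely for V110% when neither plan has hot spots. Flagging rather
than zeroing keeps "no information" distinct from "no difference".
Structures with empty masks raise a "structure absent" error; the
cohort pipeline catches it, logs the exclusion with its reason, and
continues — real cohorts routinely miss contours (resected organs,
targets far from an OAR), and silent drops would bias group statistics.

# Gamma analysis

For each reference voxel at or above the low-dose threshold, the gamma
index is the minimum over evaluated-dose sample points of
`sqrt(Δr²/δr² + ΔD²/tol²)`. Design choices, each configurable:

- **Normalization**: global by default — the dose tolerance is
  `δD%` of the maximum reference dose in the analyzed region, matching
  common commissioning practice; local mode (`δD%` of the local
  reference dose) is stricter in low-dose regions and is provided for
  sensitivity analyses.
- **Low-dose threshold**: applied to the *reference* dose (default 10%
  of the normalization dose); sub-threshold voxels are excluded from
  the pass-rate denominator entirely, so the rate describes clinically
  relevant dose only. Raising the threshold can only shrink the
  analyzed set, which the suite asserts.
- **Search bound**: candidates are examined out to 3·δr. A candidate
  beyond 3·δr contributes γ > 3 from its distance term alone, so it can
  only matter for voxels whose true γ exceeds 3 — voxels that have
  failed by a factor of three and whose exact value carries no clinical
  information. The oracle-equivalence tests validate the truncation on
  the fields where it could bite.
- **Sampling and refinement**: the evaluated dose is interpolated
  trilinearly on a sub-voxel lattice of step `0.1·δr`, visited in order
  of increasing distance with early termination (once the distance term
  alone exceeds the current best, no further candidate can win). The
  coarse minimum is then refined by two shrinking local lattice passes
  (step/5, then /25), which removes the lattice-discretization error
  that would otherwise dominate per-voxel accuracy in regions of steep
  dose gradient.
- **Direction**: reference = planning-CT dose, evaluated =
  synthetic-CT dose. Gamma is not symmetric in its arguments and the
  package does not pretend it is.

Voxels excluded by the threshold carry the sentinel −1 in the returned
gamma field, keeping the field a plain finite array.

`gammaBruteForce` is an independently written oracle: it scans a dense
fixed lattice (step δr/20) covering the whole evaluated extent with no
search-radius truncation. For tractability it skips only samples that
an exact envelope bound proves irrelevant: any sample at distance d has
γ ≥ d/δr, so samples beyond δr·γ₀ — where γ₀ is the voxel's own
zero-offset gamma, attained by an included candidate — cannot change
the minimum. The skip is algebraically lossless; the oracle's result is
identical to the full scan. Acceptance testing compares the two engines
per voxel (|Δγ| ≤ 0.02) and on pass rates (≤ 0.5 pp) across seeded
random smooth dose pairs, and closed-form cases (flat-field scaling,
shifted linear ramps) pin both to analytic values.

The criteria trio 3%/3 mm, 2%/2 mm, 1%/1 mm is proportional — both
tolerances scale together — so pass rates are necessarily ordered by
stringency; the suite checks this ordering on every tested pair.

# The phantom generator and toy dose engine

`buildAnatomy` constructs the simplest geometry that exercises every
failure mode an sCT validation must detect: an ellipsoidal soft-tissue
head (default semi-axes 95 × 75 × 85 mm, 30 HU) wrapped in a constant
thickness skull shell (8 mm, 1000 HU) over a −1000 HU air background,
with sinus-like air cavities in the anterior soft tissue. Structures
are the BODY mask (everything above air + 50 HU), a spherical PTV, and
spherical OARs (a brainstem-like posterior-inferior sphere and a small
anterior lens-like sphere by default).

`applyErrorModel` derives the sCT from the pCT inside BODY, in a fixed
order chosen so each term's effect is identifiable: bone-compartment
morphology first (on clean HU), then the global bias, Gaussian noise,
the voxel-quantized contour shift, and the metal-artifact void.

- **Global bias** emulates the systematic HU offset synthetic CTs show
  (tens of HU in head cohorts); by construction ME over BODY equals the
  bias exactly when every other term is zero — the parameter-recovery
  identity the acceptance suite checks.
- **Noise** adds i.i.d. N(0, σ²) inside BODY; MAE then converges to
  σ·√(2/π) (the half-normal mean), giving a second closed-form recovery
  check.
- **Bone dilation/erosion** misclassifies the bone–soft-tissue
  interface, the dominant error mode of MR-derived CT (cortical bone's
  short T2 makes it ambiguous against air and tissue). A spherical
  structuring element of the given radius is applied to the thresholded
  bone compartment (> 200 HU); reassigned voxels take representative
  bone/soft values estimated from the image itself.
- **Contour shift** translates the body surface along one axis
  (quantized to whole voxels), emulating facial-contour distortion when
  immobilization differs between the two scans.
- **Metal artifact** carves a spherical signal void, emulating
  susceptibility dropout near dentures or implants.

`computeToyDose` is an explicitly declared toy: a parallel beam along
one axis deposits `entrance · exp(−μ_eff · radiological depth)` at each
body voxel, integrating relative density `ρ(HU) = max(0, 1 + HU/1000)`
from the body surface to the voxel center (so the first voxel sees half
its own thickness). Defaults: 60 Gy entrance, μ_eff = 0.004/mm at water
density. It is not a clinical dose algorithm — no scatter, no beam
model, no heterogeneity correction beyond path attenuation — but it
preserves the single property the QA pipeline must detect: **HU errors
along the beam path perturb the delivered dose monotonically**, which
is exactly what couples the image-quality and dosimetric halves of the
validation. The prescription is set to 95% of the mean reference PTV
dose, putting target coverage at realistic V93/V100 levels.

What the phantom does *not* emulate — realistic anatomy and texture,
MR acquisition artifacts, deformable anatomy changes between sessions,
clinical beam arrangements — bounds what passing tests show: they
validate the *measurement machinery* (metrics, DVH, gamma, statistics)
and the *propagation logic* (image error → dose error → pass-rate
degradation), not the clinical performance of any particular sCT
algorithm.

# Statistics

The test wrappers enforce the contracts the pipeline relies on:
Shapiro–Wilk rejects constant samples and out-of-range n; the
independent t-test (classic pooled-variance form) errors on degenerate
variance instead of returning NaN; the Wilcoxon signed-rank test drops
zero differences before ranking, uses exact enumeration for n ≤ 25
without ties and the tie-corrected normal approximation otherwise, and
returns a *not-applicable* flag when every difference is zero — the
honest answer for a metric that is identical in both plans. Spearman
uses average-rank tie handling. Bonferroni families default to one
family per comparison table (5 image-quality metrics; one per gamma
criterion set) and are configurable, since family choice is a reporting
convention, not a property of the data. All alternatives are two-sided.

Under seeded null simulations (n = 15 per group, 2000 replicates) both
the t-test and the signed-rank test are required to reject at 5% ± 1.5%
— a calibration harness, not a power study.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on generated
data at sizes chosen for completeness per unit time: 32³-voxel phantom
cases at 6 mm spacing (a coarse but fully featured head), 12³-voxel
dose pairs at 2.5 mm for the oracle-equivalence sweep (small enough for
the exhaustive oracle, large enough for thousands of analyzed voxels),
a 168 × 136 × 152 phantom at 1.2 mm only where the half-normal MAE
recovery needs ≥ 10⁶ ROI voxels, and 2000-replicate calibration runs.
Key numerical conventions: gamma sentinel −1 for unanalyzed voxels,
PSNR `Inf` for identical inputs, grid tolerance 1e-6 mm, gamma
minimization ties resolved by value only (the argmin location is not
reported), and every random draw flows from explicit integer seeds — no
global RNG state is consumed implicitly.

# Known limitations

- Axis-aligned geometry only; oblique acquisitions must be resampled
  upstream.
- DICOM series/RTDOSE/RTSTRUCT parsing is not included; volumes enter
  via NIfTI (or in memory), and structure sets via plain polygon
  contours (`rasterizeContours`, even-odd fill per slice).
- The toy dose engine is a stand-in: absolute dose values are not
  clinically meaningful, only their paired differences are.
- Windowed SSIM uses cubic uniform windows, not the Gaussian weighting
  some image-processing pipelines prefer.
- `gammaBruteForce` is guarded to ≤ 25³ analyzed voxels by design; it
  is a verification oracle, not a production path.
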