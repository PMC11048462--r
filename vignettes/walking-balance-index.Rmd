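---
title: "Quantifying walking balance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying walking balance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbi)
```

## The problem

Clinical balance instruments (Berg Balance Scale, Tinetti) are coarse
ordinal scores: healthy adults saturate them even when an external
disturbance measurably degrades their gait. `wbi` implements a
quantitative alternative: a per-stride composite score — the Walking
Balance Index (WBI) — built from instrumented-treadmill recordings. The
package takes synchronized force-plate channels (3-axis forces and
moments) and body-segment centroid trajectories with segment masses,
and needs two recordings per subject: one relatively balanced condition
and one relatively unbalanced (perturbed) condition. Smaller WBI values
indicate better balance; the index is reported stride by stride, so both
its level and its stride-to-stride fluctuation are informative.

## The fourteen balance metrics

With x the progression (sagittal) axis, y the lateral (coronal) axis and
z vertical, the instantaneous metric channels are:

* **COPx, COPy** — center of pressure from the force plate,
  `COPx = (-h*Fx - My)/Fz`, `COPy = (h*Fy - Mx)/Fz`, with `h` the
  belt-to-plate-origin height offset. The zero-moment point coincides
  with the COP for flat-foot treadmill walking, so no separate channel
  is kept.
* **VCOPx, VCOPy** — COP velocities (first finite differences).
* **COMx, COMy, COMz** — whole-body center of mass, the mass-weighted
  mean of the segment centroids.
* **ACOMx, ACOMy, ACOMz, ACOM** — COM accelerations per axis (second
  differences) and their Euclidean resultant.
* **COP_CMP** — planar distance between the COP and the centroidal
  moment pivot `CMP = (COMx - Fx/Fz*COMz, COMy - Fy/Fz*COMz)`; it
  grows with the moment the body must generate about its COM.
* **MOS** — margin of stability: velocity-extrapolated COP minus
  velocity-extrapolated COM, `(COP + VCOP/w0) - (COM + VCOM/w0)` with
  the inverted-pendulum frequency `w0 = sqrt(g/l)`.
* **AANG** — angular acceleration of the trunk inclination.

Three choices here were genuinely open and are worth recording:

* **MOS axis.** The margin of stability can be reported per axis, as a
  planar magnitude, or as a signed distance to a base-of-support
  boundary. The package computes it per axis and defaults to the
  coronal (y) axis, because lateral stability is the canonical MOS
  use-case and lateral adjustments dominate balance responses on a
  treadmill; `mos_axis = "x"` switches to sagittal. The COM height `l`
  is the trial-mean COM height above the belt.
* **Trunk angle.** Only pelvis and chest landmarks are assumed, so the
  trunk inclination is defined as the (unsigned) angle between the
  pelvis-to-chest vector and the vertical. An unsigned angle kinks if
  the trunk passes exactly through vertical; in practice walking
  posture keeps a constant forward lean, which the synthetic generator
  reproduces.
* **Support validity.** The COP and CMP equations divide by `Fz` and
  are singular in swing. Samples with `Fz` at or below a support
  threshold (default 30 N) are marked invalid rather than divided
  through, and per-stride features of COP-derived metrics are computed
  over stance-valid samples only (not zero-padded to the full stride):
  padding would dilute stance dynamics with artificial zeros.

## Signal path

Force-plate channels (nominally 1000 Hz) and kinematics (nominally
100 Hz) are low-pass filtered with a zero-phase 4th-order Butterworth —
15 Hz for forces, 6 Hz for kinematics, both configurable — and the
filtered forces are then decimated onto the kinematics grid, where every
metric is computed. The source recordings never state filter cut-offs
for this class of data unambiguously; the defaults are standard gait-lab
practice, and the COM terms are band-limited well below 6 Hz anyway.
Differentiation always follows smoothing: a second difference at 100 Hz
amplifies raw marker noise by four orders of magnitude, so the filter is
what makes the acceleration channels usable. Heel strikes, when not
supplied, are detected as upward 30 N crossings of the vertical GRF with
a refractory interval; strides run heel-strike to heel-strike.

## Features and selection

Each stride of each metric is reduced to RMS, sample variance (n−1
denominator, matching mainstream statistical software) and range,
giving 14 × 3 = 42 features per stride. Features are compared between
the balanced and perturbed conditions with a gated two-sample test:

1. Lilliefors normality test on each sample (gate level 0.05);
2. if both pass, Bartlett's variance-homogeneity test decides between
   the pooled-variance Student t-test and Welch's corrected t-test;
3. any normality failure falls through to the Wilcoxon rank-sum test.

All tests are two-sided; a feature is *effective* when `p < 0.01`. The
strict per-feature level stands in place of an explicit multiplicity
correction — with 42 simultaneous tests it bounds the expected number of
false selections under the null at about 0.4 features — and a
Benjamini–Hochberg option is available but off by default. The gate
level 0.05 is a conventional choice, distinct from the 0.01 selection
level; both are configurable. The Lilliefors p-value is computed from a
seeded Monte-Carlo null (default 1000 draws) rather than an analytic
approximation, and because the null distribution depends only on the
sample size, one table is shared across all 42 features of a
comparison. The rank-sum p-value is exact by enumeration for combined
samples up to 12 and uses the tie- and continuity-corrected normal
approximation beyond that.

Strides are treated as independent observations. That is an
approximation — consecutive strides of real gait are weakly correlated —
and it is the main caveat when interpreting the selection level on real
recordings.

## Index construction

The selected features are made dimensionless (positions by height,
velocities by `sqrt(g*height)`, linear accelerations by `g`, angular
accelerations by `g/height`; variance features by the squared factor —
no selected feature carries force units, so body mass enters only
through the record of the model), z-scored on the pooled strides of
both conditions, and checked with the Kaiser–Meyer–Olkin statistic.
KMO is advisory: a value below 0.5 triggers a warning, not a refusal,
since the procedure reports adequacy rather than acting on it. The
pooled covariance of the standardized features (equivalently their
correlation matrix) is eigendecomposed; the smallest leading set of
components whose cumulative contribution reaches 85% is retained; and
the index is the weighted sum of retained component scores,

    WBI = sum_i w_i * y_i,    y_i = sum_j c_ij * z_j

Two conventions resolve ambiguities inherent in this construction:

* **Component weights.** The eigenvalue-based weight is implemented in
  two normalizations: `lambda_i / sum(lambda_j)` (default; weights sum
  to 1) and `lambda_i / sqrt(sum(lambda_j^2))` (`weight_norm = "l2"`).
  Both reduce to weight 1 with a single retained component; the
  variance-proportional default is the standard composite-index
  reading.
* **Signs.** PCA signs are arbitrary, so each component is oriented to
  make its largest-magnitude coefficient positive, and a global
  orientation sign is chosen so that the perturbed fitting condition
  scores at or above the balanced one — fixing the convention that a
  larger WBI means worse balance.

Scoring new strides — including another subject's — is a pure
transfer: the model's own scaling anthropometry, standardization
parameters and coefficients are applied unchanged. This is what makes a
"general" index possible: fit on one subject, score others, and compare
relative changes between conditions rather than absolute levels.

## The synthetic-gait generator

No public dataset accompanies this method, so the package ships a
seeded generator that emulates the statistical structure the pipeline
assumes, and it is the basis of every calibration result below:

* vertical GRF as a stance-confined double-bump curve
  (`sin(pi*u)*(1 + 0.5*cos(2*pi*u))` over the stance fraction, peak
  about 1.1 body weight, mid-stance valley about 65% of the peak);
  braking/propulsion and lateral shear sinusoids scaled to body weight;
* force-plate moments obtained by *inverting* the COP equations from a
  prescribed COP trajectory (heel-to-toe progression, one lateral
  excursion per stride), so the generator has analytic ground truth;
* eight segments (trunk+head, pelvis, two thighs, shanks, feet) with
  fixed mass fractions summing to one, swaying about a mean posture
  with stride-boundary-vanishing oscillations; legs swing in
  antiphase so their contribution cancels in the COM;
* stride-to-stride natural variability as per-stride Gaussian
  amplitude jitter (4% coefficient of variation), plus measurement
  noise (2 N forces, 0.5 N·m moments, 0.3 mm positions at the default
  `noise_sd = 1`);
* two sampling rates (1000 / 100 Hz) to exercise the resampling path.

The perturbed condition multiplies a per-stride standard-normal draw by
`perturb_gain`, a half-sine window confined to stance (the support
phase, the first 60% of the cycle) and a per-channel amplitude, and adds
it to the source channels driving the targeted metrics — trajectory
channels for COP/COM targets, shear forces for the COP-CMP offset,
trunk sway for AANG. Defaults: gain 2 on five metrics (COPy, VCOPy,
ACOMy, COMz, AANG), a lateral-dominant disturbance. The magnitudes are
free parameters chosen once to be physiologically plausible (COP bumps
of centimetres, COM shifts of about a centimetre, trunk sway of about
3 degrees); no quantitative effect sizes exist to calibrate them
against. With `perturb_gain = 0` the perturbed generator is
*bit-identical* to the balanced one under the same seed — the null is
embedded exactly, which is what makes the type-I calibration of the
selection stage meaningful.

What the generator does **not** emulate: stride-to-stride
autocorrelation, asymmetry between left and right steps, double-support
force sharing between two plates, foot-clearance kinematics,
musculoskeletal dynamics, or any mechanistic model of the disturbance
hardware. Passing tests therefore show that the pipeline recovers known
structure of this idealized family, not that it is validated on human
data.

Perturbing one metric's source channel necessarily moves metrics that
are computed from the same channel: a lateral-COP perturbation also
shifts VCOPy, the coronal MOS and the COP-CMP distance. Tests of
selection specificity therefore check only channels that are
computationally independent of the perturbed source.

## Numerical choices

* Finite differences: central in the interior, one-sided at ends;
  derivatives of COP-dependent channels are `NA` wherever the stencil
  touches an invalid sample.
* PCA via singular value decomposition of the centered matrix;
  eigenvalues are exactly the covariance eigenvalues, and an
  independent `eigen()` route is used as the oracle in the test suite.
* The Lilliefors Monte-Carlo p-value uses the add-one estimator
  `(1 + #{D* >= D})/(n_mc + 1)`, never exactly zero and monotone in
  the statistic.
* Degenerate inputs: constant samples short-circuit the normality gate
  to the rank-sum branch; zero-variance feature columns are an error at
  standardization (they cannot be z-scored); a singular correlation
  matrix in the KMO step falls back to a ridge-regularized inverse with
  a warning; strides with fewer than two valid samples for any metric
  are dropped with a reported count.
* The dimensionless-scaling step is guarded by a `scaled` flag because
  the operation is not idempotent.

## Problem sizes used in the shipped checks

The calibration and recovery experiments in the test suite and the
acceptance script use 50-stride conditions (40 for the retention sweep)
at the default rates: 200 replicate condition pairs for the null
selection-rate estimate, 20 seeded fits for the retention bound, and 20
fit/held-out/transfer triples for condition recovery, with the transfer
subject at 1.60 m / 53 kg against the fitting subject's 1.75 m / 68 kg.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping a full run in minutes on one core.

## Known limitations

* Stride independence is assumed throughout; no repeated-measures or
  mixed-model variant is provided.
* The selection stage compares exactly two conditions; multi-condition
  designs must be run pairwise (the fit always uses one pair).
* KMO below 0.5 warns but does not block; with near-duplicate features
  (e.g. RMS and Range of the same quiet channel) the correlation matrix
  can be near-singular, which the ridge fallback tolerates at the cost
  of an approximate KMO value.
* Scores are comparable only through a common model: refitting changes
  the feature set, weights and orientation, so only relative
  differences between conditions under one model are meaningful.
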