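---
title: "Propagating measurement uncertainty to knee joint angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating measurement uncertainty to knee joint angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jcsuncert)
```

## The problem

Clinical gait analysis reports knee kinematics as three joint angles —
flexion–extension, adduction–abduction (varus–valgus) and
internal–external rotation — extracted from the relative rotation of the
shank with respect to the thigh. Every ingredient of that computation is
uncertain: the joint motion itself varies between repetitions (*intrinsic*
variability of the rotation angle and rotation axis), and the anatomical
axes used to interpret the motion are mislocated by marker placement,
soft-tissue artifact and calibration error (*extrinsic* variability).
A well-known symptom is *cross-talk*: when the flexion axis used for
interpretation is misaligned with the true motion axis, part of the large
flexion motion leaks into the two small angles.

`jcsuncert` implements an analytical first-order model of how such input
uncertainties propagate to the three knee angles, together with the tools
needed to exercise and verify it: exact rotation algebra, a Monte-Carlo
oracle, a synthetic multi-session gait generator and inter-/intra-session
variability (RMSD) analysis.

## The model

### Attitude vector and joint coordinate system

The relative rotation `R` (columns: shank X, Y, Z axes in the thigh frame)
is a ZXY Cardan sequence, \(R = R_z(\theta_1) R_x(\theta_2) R_y(\theta_3)\).
Equivalently it is described by its *attitude vector* \(\theta \mathbf{k}\)
(rotation angle and unit axis, the helical-axis description), which is
coordinate-free and hence insensitive to cross-talk. The joint coordinate
system (JCS) is the non-orthogonal triad

* \(\mathbf{e}_1 = [0,0,1]^T\), the thigh Z (flexion) axis,
* \(\mathbf{e}_3\), the shank Y axis = second column of `R`,
* \(\mathbf{e}_2 = (\mathbf{e}_3 \times \mathbf{e}_1)/\lVert \mathbf{e}_3
  \times \mathbf{e}_1 \rVert\), the floating axis.

The clinical angles are the non-orthogonal projection of the attitude
vector on this triad,
\[
\theta_1 = \frac{(\mathbf{e}_2 \times \mathbf{e}_3)\cdot \mathbf{k}}
                {(\mathbf{e}_1 \times \mathbf{e}_2)\cdot \mathbf{e}_3}\,\theta,
\qquad
\theta_2 = \frac{(\mathbf{e}_3 \times \mathbf{e}_1)\cdot \mathbf{k}}
                {(\mathbf{e}_1 \times \mathbf{e}_2)\cdot \mathbf{e}_3}\,\theta,
\qquad
\theta_3 = \frac{(\mathbf{e}_1 \times \mathbf{e}_2)\cdot \mathbf{k}}
                {(\mathbf{e}_1 \times \mathbf{e}_2)\cdot \mathbf{e}_3}\,\theta,
\]
the unique decomposition \(\theta_1\mathbf{e}_1 + \theta_2\mathbf{e}_2 +
\theta_3\mathbf{e}_3 = \theta\mathbf{k}\); this identity is enforced to
1e-9 throughout the test suite. For a pure hinge (rotation about
\(\mathbf{e}_1\)) projected and Cardan angles coincide exactly; in general
they differ by a second-order cross term, approximately
\(\theta_1 \cdot (\theta_2, \theta_3)/2\) in radians — about 2.4° at 60°
of flexion with a 5° rotation offset — which is why the two notations
agree closely in stance and diverge at peak swing flexion.

### Independent parameters and variance propagation

Unit-norm constraints leave seven independent parameters per pose:
\(\theta, k_x, k_y, e_{1x}, e_{1y}, e_{3x}, e_{3z}\), with the main
directions recovered as \(k_z = \sqrt{1-k_x^2-k_y^2}\),
\(e_{1z} = \sqrt{1-e_{1x}^2-e_{1y}^2}\),
\(e_{3y} = \sqrt{1-e_{3x}^2-e_{3z}^2}\) (the knee convention: rotation and
flexion axes point along +Z of the thigh, the shank long axis along +Y; the
model is undefined for poses that leave this domain, and such frames are
flagged and skipped). Each output \(y \in \{\theta_1,\theta_2,\theta_3\}\)
is a quotient \(f/g\) with the common denominator
\(g = (\mathbf{e}_1 \times \mathbf{e}_2)\cdot\mathbf{e}_3\), and its
squared standard uncertainty follows the first-order rule for uncorrelated
inputs,
\[
u^2(y) = \frac{1}{g^4}\sum_{i=1}^{7}
  \Bigl(g\,\tfrac{\partial f}{\partial x_i}
  - f\,\tfrac{\partial g}{\partial x_i}\Bigr)^2 u^2(x_i).
\]
Axis-orientation uncertainty is given as a cone half-angle \(\alpha\)
about the nominal direction and mapped to the standard uncertainty
\(\tan\alpha\) of each of the two free components, independently and
without covariance; \(u(\theta)\) enters directly (radians internally,
degrees at every interface).

The 42 partial derivatives of \(f_1, f_2, f_3, g\) were derived once
symbolically and frozen as generated code
(`data-raw/generate_sensitivities.py` → `R/sensitivity-exact.R`); the test
suite revalidates all of them against central finite differences at
hundreds of random poses.

Because the rule is additive in squared contributions, the four source
groups \(\{\theta\}, \{k\}, \{\mathbf{e}_1\}, \{\mathbf{e}_3\}\) satisfy
\(u^2_{\text{combined}} = \sum_s u_s^2\) exactly, and the per-source
breakdown reported by `propagate_sequence()` equals propagating each input
alone.

```{r}
hinge <- c(theta = 60, kx = 0, ky = 0, e1x = 0, e1y = 0, e3x = 0, e3z = 0)
propagate(hinge, uncertainty_inputs(u_theta = 5, alpha_k = 0,
                                    alpha_e1 = 0, alpha_e3 = 0))$combined
```

On a hinge pose a 5° rotation-angle uncertainty maps one-to-one onto the
flexion angle and not at all onto the other two; tilting \(\mathbf{k}\) or
\(\mathbf{e}_1\) instead produces adduction–abduction uncertainty that
scales with \(\theta\) — the analytic face of cross-talk, with
\(\partial\theta_2/\partial k_x = -\partial\theta_2/\partial e_{1x} =
\theta\) at the reference pose.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `u_theta` | SD of the rotation angle (deg) | 5 | the level reported to match experimental gait variability; 2 is the community's "optimal" threshold, 10 a deliberately unacceptable level |
| `alpha_k`, `alpha_e1`, `alpha_e3` | cone half-angles of axis-direction uncertainty (deg) | 5 | same rationale; swept over 2/5/10 by `propagate_sweep()` |
| degeneracy threshold | rotation angle below which `k` is unidentifiable | 1° | axis terms are reported as zero with a flag; below ~1° the axis direction is numerical noise |
| `stance_fraction` | stance share of the cycle | 0.616 | typical adult value |

## The synthetic gait generator

No real capture data ships with the package; `generate_dataset()` emulates
a five-session, eight-trials-per-session single-subject reproducibility
design:

* **Template**: a two-bump flexion profile (raised cosine over stance
  peaking at 18°, an asymmetric raised cosine in swing peaking at 60° at
  72% of the cycle) with constant 2° varus and 5° internal-rotation
  offsets, composed through the ZXY sequence. These are conventional
  normal-gait magnitudes, not any particular subject's curve.
* **Intrinsic noise (per trial)**: a smooth periodic rotation-angle offset
  curve — a constant plus first Fourier harmonic with weights
  \(\sqrt{0.5}\) each, giving a per-frame SD of exactly `sd_theta` — and a
  fixed per-trial tilt of the rotation axis (`cone_k`). A smooth
  low-frequency curve was chosen over independent knot values because
  knot-interpolation makes the per-frame SD dip between knots, and over
  white noise because per-frame noise would be averaged away by
  time-normalization in a way real gait variation is not.
* **Extrinsic noise (per session)**: one fixed tilt of the thigh frame
  (`cone_e1_session`) and one of the shank frame (`cone_e3_session`),
  shared by all trials of the session the way marker placement is constant
  within a session, applied as `R' = t(A) R B`.

A deliberate consequence of modelling extrinsic error as *frame* tilts is
that the generated data contain a constant angle-offset channel (a thigh
tilt about its anterior axis shifts the varus reading at every flexion
angle) in addition to the flexion-scaled cross-talk channel that the
projection model describes. Real marker-placement error has both; the
analytical model only the latter. Passing parameter-recovery tests
therefore show that the model's channels dominate where the model says
they should, not that the generator and model are the same thing. The
generator also does not emulate soft-tissue-artifact waveforms,
event-detection error, or time-warping between trials, so agreement on
synthetic data does not certify those aspects of real data.

## Monte-Carlo oracle

`empirical_output_uncertainty()` draws the seven parameters from
independent Gaussians matching the variance inputs, pushes every draw
through the exact (non-linearized) projection equations, and compares
empirical SDs with the analytic values; draws that leave the unit-norm
domain or give degenerate axes are rejected and resampled, with an error
if more than half are rejected. Gaussian perturbations were chosen over
uniform-on-cone because the propagation rule is a variance rule agnostic
to distribution shape, and Gaussians make the SD semantics exact. At 2°
inputs the analytic and empirical values agree within ~1.5% on the hinge
template; the mismatch grows with input size (first-order nature of the
model).

## Numerical choices

* Angles are degrees at all interfaces and files, radians internally.
* Attitude extraction uses the quaternion (Shepperd) decomposition, stable
  near 0° and 180°; round-trips reconstruct `R` to 1e-8 or better.
* The sign ambiguity \((\theta,\mathbf{k}) \sim (-\theta,-\mathbf{k})\) is
  resolved per cycle: consecutive axes keep positive dot products, frames
  with \(|\theta| < 1°\) take an axis interpolated from neighbours, and
  the global sign is fixed so the mean axis has \(k_z > 0\) (without this,
  a trial whose angle starts negative adopts a flipped convention and
  corrupts cross-trial statistics).
* Degeneracy tolerances: 1e-6 on \(\lVert\mathbf{e}_3\times\mathbf{e}_1\rVert\)
  (true gimbal proximity), 1e-9 on orthonormality (numerical noise).
* Finite-difference validation of the frozen partials uses step 1e-6 with
  an absolute floor of 1e-3 in the relative-error denominator: `f` and `g`
  are O(1), so central differences carry ~1e-10 absolute roundoff and
  cannot certify sub-1e-6 *relative* accuracy of partials that are
  themselves below ~1e-4; those are compared on the problem's absolute
  scale instead.
* RMSD definitions (inter about the grand per-frame mean over all trials;
  intra about per-session per-frame means, pooled over sessions) follow
  common gait-reproducibility practice and guarantee inter ≥ intra
  structurally when session-level error is present. Axis-orientation RMSD
  is the RMS angular deviation from the respective mean direction.
  Aggregate rows use the population (divisor *n*) SD.
* Linearization along a cycle happens at the across-trials mean pose
  (`mean_cycle()`: arithmetic mean of \(\theta\), normalized mean
  directions for the axes), frame by frame.
* Qualitative agreement labels compare phase means of analytic and
  experimental curves with ratio bands 0.5/0.8/1.25/2 for
  `--`/`-`/`0`/`+`/`++`; phases follow the stance/early-swing/late-swing
  split at 61.6%/85% of the cycle.

## Problem sizes

The shipped tests and the acceptance script run the Monte-Carlo oracle
with \(10^5\) draws per frame at 11 frames of the hinge template, validate
the partials at 200 random poses, and use 5×8-trial synthetic datasets
(the recovery quantities in the acceptance report are pooled over five
replicate datasets, since a single smooth-noise dataset carries only a few
effective degrees of freedom per trial and its one-shot RMSD estimate is
itself ±15% dispersed).

## Known limitations

* First-order propagation only: no Hessian terms, so accuracy degrades as
  inputs grow (10° is noticeably worse than 2°).
* Input uncertainties are constant along the gait cycle and uncorrelated.
* The parameterization requires \(k_z, e_{1z}, e_{3y} > 0\); near-zero
  flexion with large axial offsets can leave this domain, and such frames
  are skipped with a warning rather than extrapolated. Just inside the
  boundary the model is valid but ill-conditioned: at a pose with
  \(k_z \approx 0.02\) (e.g. zero flexion with a 5° rotation offset) the
  dependent component's sensitivity \(\partial k_z/\partial k_y =
  -k_y/k_z\) is huge, so the flexion-angle uncertainty from an axis cone
  legitimately blows up (tens of degrees on the default template's
  heel-strike frame) and the Monte-Carlo sampler's rejection guard fires
  at 5° cones. This mirrors the physical statement that attributing the
  rotation to "flexion" is ill-defined when the rotation axis is almost
  transverse.
* The generator's flexion profile and dispersion mechanisms are stylized;
  see the generator section for what they do and do not emulate.
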