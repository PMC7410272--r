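---
title: "Methods: models, assumptions and numerical choices in oiload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and numerical choices in oiload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oiload)
```

## The mechanical model

`oiload` estimates the intersegmental force and moment at the plane where a
transhumeral percutaneous osseointegrated endoprosthesis meets the residual
humerus. Because every trial uses a **locked elbow**, the entire chain distal
to the interface plane is a single rigid body sharing one angular velocity
`omega` and acceleration `alpha`. The interface load is then a plain
Newton-Euler sum over the distal bodies:

* force: `F = sum_i m_i (a_i - g)`,
* moment about the interface point `p`:
  `M = sum_i [(r_i - p) x m_i (a_i - g) + I_i alpha + omega x I_i omega]`,

with a handheld object (briefcase, jug) entering as a point mass at (or
distally offset from) the hand COM. Loads are resolved against the humeral
long-axis unit vector `u` (pointing proximally) into the three modalities
reported clinically: axial pullout `F . u` (tensile positive), torsion
`|M . u|` and bending `|M - (M . u) u|`. By construction
`bending^2 + torsion^2 = |M|^2`.

### Segments and geometry

The intact arm is three segments: upper arm (shoulder to elbow joint centre),
forearm, hand. Masses are fixed fractions of body mass — 0.028, 0.016 and
0.006 — chosen because they reproduce, to the printed 2 decimal places, the
forearm/hand masses attributed to the smallest (44.1 kg: 0.71/0.26 kg) and
largest (123.7 kg: 1.98/0.74 kg) subjects of the study design the package
emulates. Virtual amputation splits the upper arm into four contiguous
quarter-segments of equal mass (uniform density), so the residual mass
proximal to a cut at fraction `level` is exactly `level` times the upper-arm
mass; the interface plane sits at `level x upper_arm_length` from the
shoulder. Prosthetic substitution removes the native segments distal to the
plane and appends:

* a **pylon** spanning plane to elbow (length `(1 - level) x upper_arm_length`),
  mass `pylon_linear_density x length`, COM at mid-span on the long axis —
  omitted at the 75% level, where only the pyramid **adapter** (a point mass
  at the plane) connects the limb;
* the prosthetic **forearm** (which includes the elbow unit) and **hand**
  with the preset class-specific masses, widths and hand lengths.

### Inertia

Segments are uniform solid cylinders: transverse inertia
`m (3 r^2 + L^2) / 12`, axial spin inertia `m r^2 / 2`, radius = half the
relevant joint width (pylon radius 15 mm default). The source material for
this kind of analysis never states its inertia model; cylinders are the
standard anthropometric simplification, and two package properties depend
only on the *rod* limit (`r = 0`), which the tests set explicitly:

* **torsion level-invariance** — segments whose COM lies on the humeral axis
  (residual quarters, pylon, adapter) contribute no torsion, because their
  moment arm from the interface point is parallel to `u` and their
  axisymmetric inertia terms are orthogonal to `u`; torsion then comes only
  from the (level-independent) forearm/hand/handheld geometry, so the torsion
  series is identical at the 25/50/75% planes;
* **oracle equivalence** (below) — a line of point masses cannot represent
  the `3 r^2 / 12` and `m r^2 / 2` terms.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| segment mass fractions | 0.028 / 0.016 / 0.006 | — | reproduce the printed subject masses (above) |
| intact COM offsets | 0.43 / 0.43 / 0.50 | fraction from proximal end | standard anthropometric values; never printed in the source material |
| prosthetic COM offsets | 0.45 / 0.45 | fraction | "proximal of centre", exact values unpublished; config-exposed |
| forearm length | 0.146 x stature | m | needed for geometry but absent from the anthropometry contract; de Leva-style scaling |
| pylon linear density | 1.0 | kg/m | typical aluminium tube + clamps; unpublished, config-exposed |
| adapter mass | 0.10 | kg | typical pyramid adapter; unpublished |
| handheld masses | briefcase 4.5, jug 3.8 | kg | a loaded briefcase and a full ~1 US gal jug; unpublished |
| locked elbow angle | 0 (jug lift, briefcase carry), pi/2 (others) | rad | jug lift is performed elbow-straight; carrying is arm-down; unpublished |
| filter cutoff | 6 | Hz | conventional low-pass for limb motion capture |
| angular-velocity cap | 20 | rad/s | plausibility gate for the generator |
| axial peak convention | tensile | — | pullout is the clinically feared direction; absolute-max available |

None of these were revisited after the acceptance checks were first run.

## The synthetic kinematics generator

The generator replaces a 40-subject motion-capture corpus. Each trial is a
humerus pose series (shoulder position + orientation quaternion) at 100 Hz
for 5 s. Orientation is composed as intrinsic rotations
`Rx(abduction) Ry(flexion) Rz(axial rotation)`; each angle is a sum of 1-3
decaying harmonics whose base amplitude is drawn once per trial from a
per-activity normal law, with a per-trial speed factor (SD 8%) — this gives
smooth, twice-differentiable, cyclic/ballistic trajectories with
inter-subject variability. Activity templates fix which axis dominates
(ab/adduction for jumping jack, axial rotation for rapid internal rotation,
small arm-down oscillations plus a 4.5 kg handheld mass for briefcase carry,
an elbow-straight elevation arc plus a 3.8 kg jug for jug lift). Subjects
are drawn with stature uniform on 1.6-1.9 m and body mass on 44.1-123.7 kg,
positively correlated with stature, spanning exactly the printed extremes.

What the generator does **not** emulate: recorded joint-angle waveforms,
marker-level noise, soft-tissue artifact, inter-activity correlation within
a subject, or amputee compensation strategies. Consequently a green
cohort-level test establishes the *qualitative* structure of the results —
the ranked order of loads across prosthesis classes, decreasing bending and
axial loads with more distal amputation, torsion level-invariance — and the
correctness of the arithmetic, not any published cohort value. The published
peak table is shipped as a reference *input*
(`inst/extdata/reference_peak_loads.csv`) and is what the failure-margin
worked arithmetic uses.

## Numerical choices

**Filtering.** No DSP package is assumed: the package implements a 2nd-order
Butterworth biquad (bilinear design) applied forward and backward (zero
phase, effective 4th order) on top of `stats::filter`'s C-level recursion,
with odd-reflection padding and DC-steady-state initial conditions, so
constants and linear trends pass through unchanged.

**Differentiation.** Central differences with 2nd-order one-sided end
formulas. Angular velocity comes from the quaternion derivative
(`omega = 2 qdot q*` on sign-continuous, renormalized, filtered
quaternions); angular acceleration from differencing `omega`; COM
accelerations from the rigid-body relation
`a_i = a_shoulder + (skew(alpha) + skew(omega)^2) R c_i`. The last choice
matters: differentiating filtered rotation-matrix entries directly makes the
kinematics internally inconsistent (low-pass filtering does not commute with
the quadratic products in `Rdot R^T`), which showed up as a ~3e-3
implementation-vs-oracle disagreement; the rigid-body-consistent form
brings the two independent load routes to ~1e-8 agreement while changing
the physical estimates negligibly.

**The point-mass oracle.** `point_mass_oracle()` re-derives `F` and `M` by
summing `m (a - g)` and `(r - p) x m (a - g)` over `n_points` point masses
per segment — no inertia tensors anywhere. Points are spaced uniformly along
the segment axis but centred on the segment COM, so the discretized mass
distribution matches the model's first moment for any `com_offset` and its
second moment to `O(1/n^2)`. Both routes consume the same kinematic state,
as the oracle's contract requires; what is independent is the entire
force/moment summation.

**Degenerate inputs and tie-breaks.** Straight-elbow activities put every
COM on the humeral axis, making torsion ~0; comparisons therefore use
norm-scaled (not per-component-relative) error metrics. The peak-activity
label in the summary table is `which.max` over activity means (first maximum
wins — ties are measure-zero under the generator). A singular mixed-model
fit falls back to fixed-effects-only `lm` with a warning.

## Statistical model

Peaks are extracted per trial (tensile maximum for axial), averaged over the
three trials (mean-of-peaks, never peak-of-means), and compared on the log
scale: per modality, `log(peak) ~ model_variant * level * activity +
(1 | subject)` via `lme4::lmer`, with prosthetic-vs-intact contrasts
exponentiated to percent differences (Wald intervals). The original
"multivariate" (tri-variate) formulation is simplified to three per-modality
models: the reported quantities are the per-modality contrasts, and the
joint covariance structure is not published. p-values are reported raw; the
threshold test is a one-sided one-sample Wilcoxon signed-rank (exact for
n <= 25, normal approximation with continuity correction beyond).

## Design decisions on open questions

* **"50% proximal / 50% distal" COM shifts** are interpreted as +/-50% of the
  COM's current distance from the proximal joint (`com_offset x (1 + s)`),
  because that reproduces the observation that proximal shifts have the
  smaller effect when COMs start proximal of mid-segment; the
  half-segment-length reading is available as `mode = "segment_fraction"`.
* **Mass-scaling sensitivity** scales the handheld mass with the
  forearm/hand (configurable): only then do weighted activities scale
  coherently, matching the published exact 0.5x/1.5x behaviour. With the
  connectors held fixed, the strict "between k and 1" damping applies to
  bending and axial; the on-axis pylon contributes essentially no torsion,
  so the torsion ratio stays ~k (its residual spin-inertia term is ~1e-4 of
  the total and can be anti-phase).
* **Failure envelopes** are shipped as a versioned JSON preset with source
  labels. The published level x screws factorial is incomplete; the
  "with screws" torsion row is a labelled synthetic reconstruction (yield
  10.2, ultimate 42.2 N.m — the upper ends of the aggregate ranges, which
  the narrative attributes to the screw-stabilized condition). The default
  exceedance policy compares against the *lower* bound of each published
  mean range — conservative for the patient — with `bound = "hi"` available.
* **Amputation levels** are measured from the shoulder (0.25 = proximal,
  short residual); only 0.25/0.75 map to the cadaveric proximal/distal test
  counterparts, and 0.50 deliberately errors in that mapping.

## Known limitations

* Synthetic trajectories are qualitative stand-ins; per-activity kinematic
  magnitudes (ROM, speeds) were chosen as plausible, not fitted.
* External loads are limited to gravity plus the handheld mass; no muscle or
  joint-contact decomposition, no ground-reaction coupling.
* The cylinder inertia model and the COM offsets are conventional defaults,
  not subject-specific measurements.
* The mixed-model contrasts use Wald (normal) inference; for the small-n
  replicate sizes used in the coverage checks this is mildly anti-
  conservative, which the tests account for by bounding the coverage ratio
  rather than requiring exact nominal coverage.
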