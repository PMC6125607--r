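---
title: "Measuring diastolic function from cardiac MRI: methods and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diastolic function from cardiac MRI: methods and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DiastoleMRI)
```

# Scope and model

This package measures the standard diastolic-function parameters from
cardiac MR series: the mitral-annular early-diastolic tissue velocity e′
(cm/s) by feature tracking of a four-chamber cine, the transmitral inflow
peaks E and A (m/s) by in-plane phase-contrast velocimetry, the peak
filling rate PFR (mL/s) from short-axis volumetry, left-atrial volume and
ejection fraction by the area-length method, the atrial
late-gadolinium-enhancement (LGE) burden as a percentage of a 2.1 mm wall
shell, and the agreement statistics (Pearson bands, Bland–Altman,
ICC(2,1)) with which such measurements are validated against reference
modalities and invasive pressures.

Clinical image sets of this kind are generally not shareable, so the
package treats synthetic phantoms as first-class objects: every stage of
the pipeline has a generator producing inputs whose answer is known in
closed form, and all tests and the acceptance script run against those.

# Conventions

* Image arrays are `(row, col, frame)` with physical position
  `(index − 1) × spacing`; times are seconds from the R-wave, frame 1 is
  end-diastole.
* Phase-contrast phase is stored in radians; velocity = phase/π × VENC.
  Vendor integer scalings are normalized to radians on load (the scaling
  convention of any given export is a declared input, since exports vary).
  Velocities beyond VENC are flagged as wraparound, never unwrapped: VENC
  is chosen at acquisition to avoid wrap, and unwrapping is out of scope.
* Annular displacement is the signed distance from the fixed end-diastolic
  annular line (through the two seed points), negative toward the apex, so
  the systolic descent is negative and the diastolic return has positive
  velocity. e′ is reported as a positive magnitude, matching
  echocardiographic convention. The annular plane is kept fixed at its
  end-diastolic definition rather than re-derived per frame; the
  alternative (a plane that follows the annulus) would fold annular tilt
  into the velocity estimate.

# The waveform engine behind the phantoms

All time-resolved phantoms are built from flat-topped velocity lobes: a
quintic-smoothstep ramp up, a constant plateau at the prescribed peak, and
a symmetric ramp down. Three properties motivated this choice over simpler
raised-cosine lobes:

1. the running integral (displacement, volume) is available in closed
   form, so true e′, E, A and PFR are exact parameters, not fitted values;
2. the plateau makes the peak exactly resolvable at the 30-frame cine
   rate: a central finite difference of the sampled truth recovers the
   peak without sampling loss;
3. the smoothstep ramps make the velocity C²-continuous, so spline
   smoothing of the sampled curve neither rings nor overshoots the
   plateau. With half-cosine ramps (C¹ only) a near-interpolating spline
   overshoots the peak by several percent, which would contaminate every
   recovery experiment with a generator artifact.

Cycle closure is enforced analytically: the systolic lobe area equals the
summed diastolic lobe areas, so displacement and volume return exactly to
their end-diastolic values. Lobe timing uses a systole fraction of 0.35
with the early lobe in the first half of diastole and the atrial lobe just
before the next R-wave, the ordering seen in normal annular and
transmitral waveforms.

The cine phantom renders two band-pass-textured patches (septal and
lateral annular points) translating along the long axis by the analytic
displacement, using bilinear resampling so sub-pixel motion is smooth, and
refuses configurations whose per-frame motion exceeds half the tracking
search radius ("temporal undersampling"). Defaults mirror a typical
breath-hold cine: 30 frames over one RR interval (~36 ms temporal
resolution), 1.4 × 1.4 mm pixels. The phase-contrast phantom uses
1.9 × 1.9 mm pixels, a circular inflow jet at angle α from the encode
axis, a constant phase offset everywhere, and a stationary-tissue block
that carries exactly that offset. The LGE phantom voxelizes an ellipsoidal
atrial blood pool at the interpolated 0.7 × 0.7 × 1.5 mm resolution, grows
the wall shell with the same physical-ball dilation the analysis uses, and
enhances a contiguous angular cap covering the requested fraction of wall
voxels; bimodal intensities get optional Gaussian noise.

What the phantoms deliberately do **not** emulate: MR physics (coil
sensitivities, k-space sampling, parallel-imaging artifacts, navigator
gating), realistic anatomy or motion beyond rigid patch translation,
through-plane motion, flow-related signal loss, and intensity
non-uniformity across the field of view. Passing the phantom suite
therefore demonstrates that the measurement chain is correct and unbiased
on well-posed inputs — not that it is robust to every artifact of clinical
acquisitions; on clinical data the manual-override path for tracking and
subject-specific LGE thresholds exist precisely because those artifacts
occur.

# Tracking and the spline derivative

Tracking is sequential frame-to-frame normalized cross-correlation block
matching: an 11 × 11 px template around each point, a ±8 px search window,
sub-pixel refinement, and a template update every frame. Two numerical
details matter:

* **Sub-pixel refinement** evaluates the true NCC at bilinearly resampled
  fractional shifts (coordinate descent with step halving down to 1/16 px),
  seeded by the usual quadratic fit of the correlation surface. The
  quadratic estimate alone is biased by interpolation blur; descending on
  the real correlation removes that bias.
* **Template anchoring.** The updated template is always extracted on the
  integer pixel grid at the rounded current position, with the fractional
  remainder carried forward explicitly. Resampling the template at
  fractional positions instead blurs it a little every frame, and the
  correlation maximum then creeps systematically — on a static series the
  track drifts ~0.02 px per frame, which accumulates to a visible error
  over a cycle. With integer anchoring a static series tracks exactly.

A drift check exploits the cyclicity of cardiac motion: the final-frame
position must return near the seed, otherwise a warning flag is raised.
Tracking failures (correlation below 0.5) are flagged per frame, never
silently accepted. Manual corrections are represented as inputs (seed
positions are always caller-supplied), not as an interactive editor.

Displacement, and likewise the LV volume curve, are differentiated by a
cubic smoothing spline with periodic boundary handling: the one-cycle
samples are tiled over three consecutive cycles and the analytic
derivative of the central cycle is used, which removes end-point
artifacts. The smoothing level is expressed as equivalent degrees of
freedom per cycle, default 8. Physiological displacement and volume
curves carry little energy above roughly the fourth harmonic, so 8 dof
preserves the early-diastolic peak while suppressing the sample-level
ringing a near-interpolating fit exhibits; the default recovers the peak
derivative of a pure sinusoid at 30 samples/cycle to better than 1% and
is exposed (`dfPerCycle`, or `spar` directly) for data with different
noise. A residual-targeted rule ("smooth until residuals reach the
expected tracking noise") was considered and rejected: the residual scale
is proportional to the excursion amplitude, so a fixed-residual target
over-smooths low-excursion curves and under-smooths large ones.

e′ is read from the velocity curve in an early-diastolic window running
from the time of peak annular excursion (the displacement extremum, an
end-systole surrogate that avoids valve-event detection) to the midpoint
between that time and cycle end; the earliest local peak in the window is
e′ and a later one, if present, is a′. PFR uses the same window logic
anchored at the ESV time. Peak detection compresses runs of equal values
first so a flat-topped lobe counts as one peak, and applies a prominence
floor of 10% of the window maximum to reject ripple while keeping small
atrial waves.

# Flow quantification choices

The ROI is circular with a default area of 10 cm² (the standard static
inflow-tract region); its pixel radius follows from r = √(area/π) and the
pixel spacing. V<sub>max</sub> is the signed velocity of largest magnitude
in the ROI, not a mean. The phase-offset estimate is the median encoded
velocity over the stationary mask across all frames; a mask whose regional
mean varies over time (SD above 2 cm/s) is flagged as probably covering
moving tissue.

For the inflow-angle correction both algebraic forms are implemented. The
default, `component_to_true`, divides the encoded component by cos α: with
in-plane encoding along one axis, the measured value is the projection of
the inflow velocity onto that axis, so recovering the true inflow speed
requires division. The multiplicative form (`as_printed`) is provided for
comparability with reports that state v = V<sub>max</sub>·cos α; at a
typical α ≈ 46° the two differ by a factor cos²α ≈ 0.48, and the identity
v_printed = v_true·cos²α is asserted in the tests. Division is the
geometrically correct default; published validations of in-plane inflow
velocimetry report biases against Doppler far smaller than the ~50%
discrepancy the multiplicative form would imply, which is consistent with
division being the operative convention in practice.

# LA and LGE choices

The wall shell grows outward from the endocardial surface (dilation by a
physical-distance ball of the wall-thickness radius, minus the blood
pool): enhancement lies in the wall outside the pool, and an outward shell
keeps blood-pool signal out of the denominator. Enhanced volume is
tabulated per axial slice and summed — numerically identical to voxel
counting (asserted in the tests) but auditable slice by slice. The burden
is reported both as a percentage and as √%, the variance-stabilizing scale
on which such burdens are approximately normal. The threshold is always
recorded in the result for audit; when none is supplied, an Otsu split of
the wall-voxel histogram is suggested. A wall whose histogram shows no
clear bimodality (best between-class variance fraction below 0.8 — a
unimodal Gaussian reaches ~0.64, well-separated bimodal walls exceed 0.9)
is flagged "no clear enhancement", and the cohort pipeline then reports
zero burden rather than thresholding noise; subject-specific manual
thresholds, the clinical practice, bypass the suggestion entirely.

The area-length volume uses the single-view degenerate form A₁ = A₂ by
default, since four-chamber planimetry is often the only view available;
a second view, when provided, gives the full biplane form, which is exact
for any ellipsoid sharing the measured long axis. The single-view form is
exact for spheroids and errs by the hidden-axis ratio on triaxial
chambers — within 8% for realistic atrial asymmetry.

LV mass uses the standard myocardial density of 1.05 g/mL. A short-axis
slice contributes to the volume whenever its mask is non-empty; no
partial-slice correction is applied (the simplest auditable convention).

# Cohort simulator and statistics

The cohort generator draws a single latent severity factor per subject and
maps it to observables through linear loadings plus independent Gaussian
noise, so every pairwise population correlation is available in closed
form from the loadings and noise variances. The default loadings emulate a
mixed clinical diastolic cohort — fibrosis burden on the √% scale with
marginal mean 8.7 and SD 10, wedge pressure 15 ± 6 mmHg, an implied
fibrosis–pressure correlation of 0.80, a mildly negatively loaded e′
(9 ± 3 cm/s) and a positively loaded E/e′ (10 ± 4). Gaussianity and
conditional independence given the latent are simplifications: real
cohorts are censored (burden cannot be negative), skewed, and
multifactorial. Where the simulated table feeds image phantoms, negative
draws are censored at zero enhancement and pressures floored at a small
positive value, which slightly attenuates the realized correlation — the
end-to-end check therefore compares the recovered correlation against the
generating value within the Fisher-z sampling interval at the simulated n.

The statistics layer is deliberately thin: Pearson r via `cor.test` with
the conventional strength bands (boundaries 0.3/0.5/0.7/0.9 assigned to
the upper band, with a 10⁻¹² tolerance so a floating-point value sitting
at a printed boundary lands in the band the convention names);
Bland–Altman limits as bias ± 1.96·SD of the differences (limits of
agreement, not confidence intervals of the bias, which is the standard
reading of such plots); and ICC(2,1) — two-way random effects, absolute
agreement, single measure — from ANOVA mean squares, the appropriate form
when both raters and subjects are treated as random and systematic rater
offsets should count against agreement. The form label is always carried
in the result, since "ICC" alone is ambiguous. Missing data are handled by
pairwise-complete deletion, so each correlation reports its own n.

# Problem sizes and determinism

The test suite and the acceptance script run the recovery experiments at
the sizes the study conditions imply: 20 cine phantoms spanning e′ from 4
to 16 cm/s at 30 frames, 20 phase-contrast phantoms with angles between
20° and 70° and offsets within ±8 cm/s, 10 volume-curve phantoms with PFR
from 150 to 600 mL/s, LGE phantoms at the interpolated 0.7 × 0.7 × 1.5 mm
grid, and a 20-subject end-to-end cohort; the statistical oracles use
n = 500–10 000 simulated observations. All generators are deterministic
given their seed: identical seeds produce bit-identical phantoms, and a
cohort rerun under a fixed configuration reproduces its CSV outputs byte
for byte (log files carry wall-clock timestamps).

# Known limitations

* Tracking assumes the annular landmarks remain within ±8 px frame to
  frame and that local texture persists; large through-plane motion in a
  real four-chamber cine violates both, which is why flags and manual
  seed overrides exist.
* The e′/PFR windows use excursion/ESV surrogates for end-systole; fusion
  of E and A at high heart rates (or atrial fibrillation) collapses the
  biphasic pattern, and A is then reported missing by design.
* The LGE threshold suggestion is a histogram split, not a reproduction of
  any operator protocol; subject-specific thresholds remain inputs.
* DICOM ingestion is a narrow reader for uncompressed explicit-VR
  little-endian single-frame series carrying TriggerTime; anything else
  should be converted to the NIfTI + JSON-sidecar dialect first.
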