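# DiastoleMRI

Quantification of left-ventricular diastolic function from cardiac MRI,
with digital phantoms that carry analytic ground truth for every stage.

Diastolic dysfunction — impaired relaxation and increased stiffness of the
left ventricle — is normally graded by transthoracic echocardiography, but
the same physiological quantities can be extracted from routinely acquired
cardiac MR series. This package implements that measurement chain for
researchers validating MRI-based diastolic assessment:

- **e′, annular tissue velocity** — the septal and lateral mitral-annular
  insertion points are tracked through a four-chamber cine by normalized
  cross-correlation block matching with sub-pixel refinement; the
  perpendicular displacement from the fixed end-diastolic annular plane is
  smoothed with a periodic spline and differentiated, and e′ is the
  early-diastolic peak of that velocity curve (cm/s).
- **E and A, transmitral inflow** — from an in-plane phase-contrast series:
  phase maps linearly to velocity (full-scale phase ↔ ±VENC), a
  stationary-tissue region estimates the phase-offset error, the per-frame
  maximum velocity V<sub>max</sub> is read from a static 10 cm² circular
  ROI in the inflow tract, and the inflow angle α is corrected for
  (default v = V<sub>max</sub>/cos α, back-projecting the encoded component
  onto the inflow direction; the literal v = V<sub>max</sub>·cos α form is
  available as a mode). E and A are the early and late diastolic peaks
  (m/s).
- **PFR, peak filling rate** — short-axis endocardial masks are summed
  slice-by-slice into V(t); PFR is the early-diastolic maximum of dV/dt
  (mL/s). LV EF and myocardial mass (1.05 g/mL) come from the same masks.
- **Left-atrial assessment** — LA volume and EF by the biplane area-length
  method V = (8/3π)·A₁·A₂/L (single-view degenerate form A₁ = A₂ when only
  the four-chamber cine exists); atrial wall shell of 2.1 mm around the
  blood pool; LGE fibrosis burden by threshold segmentation of wall voxels
  with axial slice summation, reported as % and √% of wall volume.
- **Agreement statistics** — Pearson r with the conventional strength bands
  (0.3/0.5/0.7/0.9), Bland–Altman bias ± 1.96·SD limits of agreement, and
  ICC(2,1) (two-way random effects, absolute agreement, single measure)
  from ANOVA mean squares.

Because clinical images of this kind are rarely shareable, the package
includes first-class phantom generators — cine with known annular motion,
phase-contrast with known E/A/angle/offset, LV mask stacks with known
V(t), 3D LA LGE volumes with a known enhanced fraction, and a latent-factor
cohort simulator with closed-form implied correlations — so the entire
pipeline is testable against analytic truth.

## Worked example

```r
library(DiastoleMRI)

## cine phantom with true e' = 10 cm/s, then the full e' chain
ph <- makeAnnulusCine(motionModel(ePrime = 10, aPrime = 5), textureSeed = 42)
ph$cine
#> CineSeries (four_chamber): 96 x 96 px, 30 frames, 1.40 x 1.40 mm, RR ~ 1000 ms

tr   <- trackPoints(ph$cine, list(septal = c(58, 32), lateral = c(58, 64)))
disp <- perpendicularDisplacement(tr)
vel  <- displacementToVelocity(disp$times, disp$septal, label = "septal")
extractEPrime(vel, displacementMm = disp$septal)$ePrime
#> [1] 10.08105

## phase-contrast phantom: E = 1.0 m/s, A = 0.6 m/s, 46-degree inflow angle,
## 4 cm/s phase offset -- offset estimation, ROI Vmax, angle correction
fm   <- flowModel(E = 1.0, A = 0.6, alpha = 46, phaseOffset = 4, venc = 250)
pcph <- makePCPhantom(fm)
off  <- estimatePhaseOffset(pcph$pc, pcph$truth$stationaryMask)$offset  # 4.00
vmax <- roiVmaxCurve(pcph$pc, pcph$truth$jetCenterPx, offset = off)
detectEA(angleCorrect(vmax, 46))[c("E", "A", "EoverA")]
#> $E      [1] 1
#> $A      [1] 0.6
#> $EoverA [1] 1.666667
```

The recovered e′ is within 1% of the phantom's true 10 cm/s, and the
transmitral peaks are exact on this noiseless phantom after the offset and
angle corrections. `eOverEprime(1.0, 10.08, 10.08)` then gives the E/e′
filling-pressure surrogate (9.9 here).

A thin command-line front end over the same functions is installed at
`inst/cli/diastole-mri.R` (`eprime`, `inflow`, `la`, `phantom-cine`,
`stats` subcommands operating on NIfTI + JSON-sidecar files).

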