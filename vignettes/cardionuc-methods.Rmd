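---
title: "cardionuc: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardionuc: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cardionuc quantifies how contractile strain is transferred from sarcomeres
to the nucleus in beating cardiomyocytes, how the perinuclear microtubule
(MT) cage shapes and damages the nucleus, and what an axisymmetric
active-stress model of the resting cell predicts about the stresses behind
that damage. Because raw microscopy for these assays is not generally
available, every analysis stage is paired with a seeded synthetic-data
generator with analytic ground truth, so the whole pipeline can be
exercised and validated end to end. This vignette records the models, the
tunable parameters, and the design decisions, in that order.

## Contraction traces and the nuclear lag model

A paced cardiomyocyte is described by three length series sampled at 90
frames/s during 1 Hz stimulation: sarcomere length (diastolic baseline
1.80 um), nuclear length (11.5 um) and nuclear width (5.8 um). Strain is
percent change relative to the diastolic baseline; compression is
negative.

The sarcomere strain waveform is a raised-cosine shortening (onset delay
0.1 s, contraction time 0.2 s) followed by an exponential re-lengthening
(time constant 0.15 s) rescaled so the cycle closes exactly at baseline.
The onset delay and contraction time are chosen so the waveform peak falls
exactly on a 90 frames/s sample. The functional form is a stand-in: only
its peak values and gross time constants are anchored to measured
waveforms.

The nucleus responds through a first-order lag,
tau_n d(eps_n)/dt = g eps_s - eps_n, with gain g and time constant tau_n
(default 0.06 s). The lag captures the two robust features of measured
coupling: dampening (peak nuclear strain below peak sarcomere strain) and
diastolic hysteresis (nuclear re-lengthening trails sarcomere
re-lengthening). A standard-linear-solid alternative was considered and
rejected for needing two more unconstrained constants. The lag is
integrated with an exponential integrator that is exact for
piecewise-linear forcing (and exact in the stiff limit tau_n -> 0), and
the periodic steady state is imposed analytically, so noiseless traces are
exactly periodic across cycles. Because the response is linear in g, the
generator calibrates g in closed form so the realized sampled peak nuclear
strain equals the preset target; a target requiring g > 1.5 raises a
calibration error. Nuclear width strain is widthGain (default -0.35) times
length strain: length compression couples to width expansion.

Preset targets encode printed group values: the wild-type rat preset is
calibrated to 11.4% peak sarcomere compression with 6.6% nuclear
compression; the lamin N195K preset is calibrated so its integrated
nuclear strain is 1.30 times the wild-type mouse preset (the lag's
linearity in g makes the peak-target ratio carry over exactly); the
colchicine preset accelerates sarcomere relaxation (0.10 s) while slowing
the nuclear lag (0.12 s), producing the diastolic hysteresis seen with MT
disruption; the acute LINC-disruption preset raises sarcomere amplitude
while lowering the nuclear target, increasing systolic dampening.
Measurement noise is additive Gaussian on each length series (default
0.05 um per preset; 0 gives the exact deterministic trace).

## Strain-coupling metrics

The diastolic baseline is the mean of the 55 ms preceding the first
threshold crossing of sarcomere strain (excluding an 11 ms guard
immediately before it); defining the window in time rather than frames
keeps the metrics stable under resampling. A first-sample rule is
available. Cycles are segmented per pacing period: onset is the first
|eps_s| above 0.5% (configurable), peak systole the extremum, relaxation
end the first return below threshold.

The coupling path is the ordered (eps_s, eps_nL) curve from onset through
peak back to relaxation end; the identity line is the lossless reference.
Limb endpoints are interpolated to the exact threshold crossing so the
path extent does not depend on the sampling grid to first order, and the
end-systolic point belongs to both limbs. With several cycles, each limb
is resampled onto 200 uniform sarcomere-strain points and averaged.

Systolic dampening is |integral of (eps_nL - eps_s) d eps_s| over the
contraction limb; diastolic dampening uses the unit-slope line through the
end-systolic point as reference (a chord-to-origin variant is available,
since the verbal definition of the reference is ambiguous). Both are
evaluated by cubic-spline refinement of the time-ordered path followed by
the trapezoid rule, which removes most of the sampling error where the
path turns at peak systole; doubling the sampling rate changes the areas
by well under 0.5% on the smooth presets. The dampening unit is
percent-squared and is reported without normalization, as no axis units
are anchored; only orderings and ratios of these areas are treated as
meaningful. Integrated nuclear strain is the time integral of |eps_nL|
over one pacing period (percent-seconds); the magnitude rather than the
signed strain is integrated, an explicit choice where the verbal
definition is silent. Group summaries report mean, standard error and n,
with no inferential testing.

## Synthetic nucleus images and morphometrics

Images are rendered geometrically at 0.1 um/pixel (2-D mid-plane,
default) or 0.25 um/voxel (3-D): an ellipsoidal chromatin-filled nucleus
with a thin lamina shell; a perinuclear tubulin band (rendered 1.5 um
wide) whose pixel levels are normalized so the band mean is exactly
enrichmentFactor times the cytoplasmic level, with a tip-boosted
distribution when the cage is tip-biased; optional tip chromatin
protrusion (a blob of radius 0.8 um centred 0.3 um beyond the pole, with
a local lamina gap); and punctate perinuclear foci planted within 0.9 um
of the border. Ground truth (dimensions, protrusion area by pixel
counting on the unblurred mask, planted focus count and centres) is
recorded before post-processing. Blur and noise are optional
post-processing; the presets use additive Gaussian noise (sd 0.05 against
a chromatin level of 1) and no blur, because the generator's purpose is
controlled geometric ground truth, not optics emulation. What passing
tests therefore show is that the estimators recover known geometry under
moderate noise; they do not certify performance on real micrographs with
shading, bleed-through or debris.

Morphometrics: segmentation is Otsu threshold, largest connected
component, hole fill. Length and width are moment-based axis extents
(semi-axis = 2 sqrt(eigenvalue) of the pixel covariance), sub-pixel
accurate and rotation stable. Perinuclear enrichment is the mean tubulin
intensity within 1 um outside the boundary divided by the mean in the
2-4 um cytoplasmic band; tips and sides split the ring at +/-30 degrees
around the major axis (the tip/side split angle is not specified anywhere
and is exposed as a parameter). The 1 um ring width is specified only for
rupture-reporter foci and is reused for tubulin for consistency.
Protrusion scoring fits the moment ellipse with two robust refits
(excluding outside pixels so the blob does not inflate its own reference),
then sums mask pixels beyond the fitted ellipse (plus a 0.1 um guard)
within the tip sectors; a total of at least 1 um^2 calls a protrusion.
The original blinded scoring criteria are not published in accessible
form, so this rule is an operationalization with every constant exposed.
Foci detection thresholds at the channel mean plus 3 SD, filters
components to 0.05-5 um^2, and keeps those whose centroid lies in the
nucleus plus the 1 um ring (rupture-reporter mode) or the nuclear interior
(DNA-damage mode). Cohort scoring reports prevalence or means with a
seeded 2000-resample bootstrap percentile interval.

## Loess and breakpoint regression

The aspect-ratio/enrichment relationship is summarized two ways: loess
(degree 1, tricube weights, default span 0.75, pointwise +/-1 SE band via
stats::loess) and a continuous two-segment least-squares fit
y = a + b1 x + b2 (x - c)+. The breakpoint c is chosen by a 200-candidate
grid search across the 5th-95th percentiles of x (ties toward the smaller
candidate), then polished by continuous minimization between the
neighbouring candidates, which recovers noiseless data exactly. Segment
slopes are tested against zero with t statistics using segment-local
residual variance; the upper segment is flagged flat when p > 0.05. No
breakpoint-uncertainty correction (e.g. Davies-type) is applied, matching
the level of inference reported for the original fit; span, search method
and test procedure are all undocumented in the source material and are
therefore package decisions.

The cohort generator draws enrichment uniformly on [0.8, 3.2] and sets
aspect ratio piecewise linearly (breakpoint 1.9, slopes -2.1 and 0,
aspect ratio 2.1 at the breakpoint) plus Gaussian noise (sd 0.15). The
range and the aspect ratio at the deflection point are chosen so the
implied group values are consistent with the measured group means (e.g.
enrichment ~1.4 implying aspect ratio ~3.1).

## Axisymmetric mechanics model

The resting cardiomyocyte is modelled on the (r, z) half-plane with
symmetry about the mid-plane: a cylinder of radius 9 um and half-length
35 um; a round nucleus of radius 2.7 um split into nucleoplasm and a
0.1 um envelope-plus-lamina layer; and an MT cage filling a prolate
ellipsoid (semi-axes 3.3 and 5.8 um) around the nucleus, so the cage is
thin at the equator and thick over the poles. Axial displacement is fixed
on the cell end faces (myocardial confinement and titin restoring
stresses), the axis is a symmetry line, and the lateral surface is
traction free.

All regions are compressible neo-Hookean
(P = mu (F - F^-T) + lambda ln J F^-T); finite kinematics are required
because aspect-ratio changes exceed 30%. Active stresses are added as
Cauchy stresses with exact geometric tangents: myofibril contractility
rho_ij in the cytoplasm and an isotropic compressive stress -sigma_MT I in
the cage. Loading ramps rho_0 and sigma_MT simultaneously from zero
(ramping them sequentially changes the final state only through the
frozen fibre directions, and was found immaterial); after the isotropic
ramp the contractility is polarized along the local
maximum-principal-stress direction n as
rho_p [lambda n n' + (1 - lambda)(I - n n')/2] with lambda = 0.6. The
fibre field is then refined once by a fixed-point update (directions
recomputed from the polarized solution, one re-solve): a single update
leaves the fibres too close to the initial nearly-axial field to develop
the curvature with which myofibrils wrap the nucleus, and the refined
field is the default. Mature myofibrils do not populate the
microtubule-rich perinuclear space at the nuclear poles, so polarized
contractility is excluded from the cage ellipsoid scaled by 1.1 (the
isotropic, unassembled phase is present everywhere); without this void
the fibre wrap over the poles extrudes the nucleus axially and puts the
entire perinuclear column in tension, a pattern inconsistent with the
tip-compression picture this model exists to probe.

Discretization: linear triangles on a graded tensor-product grid (0.05 um
near the nucleus so the lamina is at least two elements thick, 2.5 um at
the cell ends), with region labels assigned from element centroids, so
curved interfaces are staircase approximations whose region volumes
converge with refinement. One-point quadrature at the element centroid is
exact for the constant in-plane gradients of linear triangles; the hoop
stretch uses the centroid radius. Newton iteration with analytic tangents
converges each increment to a relative residual of 1e-8, with a
backtracking line search and automatic step halving; non-convergence after
repeated halving raises an error carrying the last converged state.

Materials (kPa) are calibration stand-ins chosen so the wild-type probe
stresses land inside the printed physiological ranges; none except the
mutant-lamina modulus are given in the accessible text: cytoplasm 1.2,
cage 8, lamina 25 (10 for the mutant, the one printed value), nucleoplasm
0.25 with Poisson ratio 0.49 (near-incompressible, so lateral squeeze
converts into elongation). Active magnitudes: rho_0 = 0.8, rho_p = 4.5,
sigma_MT = 1.4. Myofibril-tension probes average the axial Cauchy stress
over the 3 um of contractile material nearest the cage short and long
tips; MT probes average the cage within 1 um of the nuclear tips.

Scenario mapping: the lamin-mutant scenario softens the lamina to 10 kPa;
LINC disruption scales both the cage stress and the cage modulus to 0.25
of wild type; enrichment sweeps map enrichment linearly onto both
(reference enrichment 2.2 for the wild-type cage). The tip-instability
experiment ramps sigma_MT beyond the physiological value with the fibre
field frozen at the physiological state (cage overload does not instantly
remodel the myofibril lattice) and flags the load at which the maximum
principal stress on the lamina jumps from the equator (arc coordinate
s = 0) toward the tips (s = 1); the criterion threshold is s > 0.8 by
default. On coarse meshes the discrete lamina elements quantize s, so
resolution studies may lower the threshold (the tests use 0.6 with a
3x-coarsened lamina). Rescue after the instability re-solves with cage
stress and stiffness reduced - the model is hyperelastic, so the rescued
equilibrium does not depend on the loading path. The accompanying
elongation is assessed against the physiological (pre-overload)
configuration: in the overload regime the aspect-ratio response to cage
stress reverses sign in this formulation, so the overloaded state is not
a meaningful elongation baseline.

Test-scale configuration: the test suite runs the mechanics with a 3x
thicker lamina (0.3 um), a 3x coarser fine-mesh band (0.15 um) and lamina
moduli divided by 3, preserving the shell stiffness (modulus x thickness)
of the default configuration; this keeps a full scenario solve in seconds
while leaving every qualitative property unchanged. The acceptance script
runs the wild-type scenario at the full default resolution.

## Known limitations

- The probe bands for myofibril tension are met by the calibrated
  defaults, but the axial microtubule stress at the nuclear tips in this
  formulation is mildly tensile rather than compressive: the cage is
  welded to the elongating nucleus and is dragged axially. The printed
  compression range at those sites appears to require constitutive detail
  (e.g. a fibre-resolved or slipping cage) beyond the accessible
  description; the spatial ordering of the two microtubule probes (more
  compressive at the long tip than the short tip) is reproduced.
- The lamina is a thin solid layer, not a shell element; bending-driven
  localization is resolution limited, which is why the tip-instability
  jump saturates below s = 1 on coarse meshes.
- The trace generator's waveform family and the image generator's
  geometric rendering are stand-ins: parameters are anchored to printed
  peak values and group differences, not to raw data.
- Pipeline problem sizes (50 seeded cohorts of 300 points; 500-image
  protrusion cohorts; single-cell noiseless traces) are the package's
  reference configurations for reproducing the printed values at desk
  scale.
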