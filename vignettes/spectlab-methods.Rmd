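---
title: "Simulating and scoring liver-lesion detectability in In-111 octreotide SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring liver-lesion detectability in In-111 octreotide SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Small liver lesions in In-111 octreotide SPECT sit at the edge of
visibility: a ~0.35 cm^3 sphere at a tumor-to-normal concentration (TNC)
ratio of 8 can vanish entirely in a reconstructed image, because the
reconstruction resolution spreads its signal over a neighbourhood the size
of several voxels (the partial volume effect) while the surrounding liver
uptake is itself nonuniform (anatomical noise) and the counts are Poisson
(statistical noise). Whether such a lesion is detectable therefore depends
jointly on its local surroundings and on the reconstruction chain —
in particular on whether scatter and the collimator-detector response
(CDR) are modelled, and on how aggressively the image is smoothed.

`spectlab` rebuilds this experiment end to end with synthetic data: it
generates abdominal phantoms, simulates raw projection data by Monte Carlo
photon transport, inserts lesions *in the raw data domain* (the hybrid
scheme: a lesion-only sinogram is simulated through the patient's
attenuation and summed with the patient sinogram, so the background is
fully realistic), reconstructs with three arms, and scores detectability.

# Study design emulated

Three arms reconstruct the identical counts sinogram per case:

| arm | model | iterations x subsets | post filter |
|-----|-------|----------------------|-------------|
| `fAC_OSEM` | attenuation only | 2 x 10 | 3-D Butterworth low-pass, power 2, 0.048 cycles/mm |
| `fMC_OSEM` | attenuation + scatter + CDR | 5 x 10 | 3-D Gaussian, sigma 3 mm |
| `MC_OSEM`  | attenuation + scatter + CDR | 5 x 10 | none |

The default design is 37 cases, 26 of which receive one lesion (radius
1 voxel = 4 voxels = 0.35 cm^3 at 4.42 mm pitch, TNC 8 relative to the
local mean concentration in a control sphere of radius 3 voxels), giving
3 x 37 = 111 images to read. Detection rate (% of positives found with
correct coordinates), accuracy (% of correctly classified cases),
TNC ratio, SNR and a 1-6 rating-scale ROC are the endpoints, each under
two truth scenarios: AL ("all lesions") and DL ("detectable lesions",
which reclassifies lesions hidden in low-uptake pockets as negatives).

# The phantom and its anatomical noise

Real anatomy is replaced by parametric geometry — an elliptical-cylinder
body, an ellipsoidal liver, two ellipsoidal kidneys and a bone-like spine
insert in the pseudo-CT — because the analysis needs a liver-like region
with *controlled* anatomical noise, not anatomical realism. Organ
concentrations default to 10 / 45 / 120 kBq/ml (background / liver /
kidneys), which puts the field-of-view total near 120 MBq, inside the
clinical 110-220 MBq range one day post injection.

Liver heterogeneity is a multiplicative log-normal random field with mean
exactly 1: a Gaussian random field with autocorrelation
`exp(-d^2 / (2 L^2))` is generated by FFT convolution of white noise with
a Gaussian kernel, scaled to unit variance, and exponentiated with the
log-normal moment correction. Defaults `CV = 0.3`, `L = 15 mm` were
chosen once so that a TNC-8 lesion is *sometimes* masked by a low-uptake
pocket — the "disappearing lesion" phenomenon — while most lesions remain
visible in the sharper arms. No quantitative liver-texture measurements
informed these values; they are model knobs, and results should be read
as conditional on them.

The pseudo-CT maps to attenuation through a bilinear HU-to-mu curve with
anchors at air (-1000, 0), water (0, mu_water(E)) and bone
(1000, mu_bone(E)); defaults are mu_water = 0.0144 / 0.0127 per mm and
mu_bone = 0.0264 / 0.0229 per mm at 171 / 245 keV.

# Forward models

**Analytic projector.** A rotation-based parallel-beam projector: for each
angle the activity is resampled into the ray frame by mass-conserving
bilinear splatting (so projection totals are angle-independent), the
attenuation map by bilinear interpolation, and each bin accumulates
`activity x voxel_size x exp(-optical path to the detector)`, optionally
blurring each constant-depth slab with the distance-dependent Gaussian
CDR, `FWHM(d) = fwhm_intrinsic + fwhm_slope x d` (defaults 4.5 mm and
0.045 mm/mm, medium-energy collimator territory). The back projector is
the exact matrix transpose (verified by inner-product tests), which makes
the attenuation-only pair a matched pair for OSEM. The model is valid for
bodies inside the cylinder inscribed in the grid — attenuation in the grid
corners is invisible to the rotated frame — which clinical orbits satisfy
by construction.

**Monte Carlo projector.** Emission points are sampled proportional to
activity; each photon draws one of the two photopeaks (171 / 245 keV,
abundances 0.907 / 0.941) and is tracked by Woodcock delta-tracking
through the attenuation maps, with photoelectric absorption (probability
`1 - compton_fraction`, default 0.01 per interaction) and Klein-Nishina
Compton scattering (rejection sampling of the angular law; the scattered
energy follows the Compton relation). Attenuation between the photopeak
maps is interpolated log-linearly in energy and clamped below 100 keV;
for detector scoring, the attenuation *line integrals* are precomputed at
the two photopeaks and interpolated the same way — an approximation
(interpolation does not commute with the integral) that is accurate for
tissue-like spectra. Detection is scored by forced detection: every
emission and scatter vertex deposits its expected contribution at every
requested angle, weighted by the direction probability relative to an
isotropic baseline, the attenuation to the detector, and the
energy-window acceptance (two 20% windows at 171 and 245 keV, summed into
one sinogram; Gaussian energy resolution of 10% FWHM). The CDR is applied
as a sampled Gaussian offset in the detector plane. An analog mode — naive
tracking to escape with a binary acceptance cone per angle, binned by the
last-vertex ray — is retained as the reference estimator for unbiasedness
tests: in the scatter-free configuration both modes agree with the
analytic projector (forced mode to ~0.1%, analog within counting
statistics).

A scalar `sensitivity` absorbs geometric efficiency and crystal response;
its default is calibrated so a default acquisition (120 x 30 s clinical,
60 x 30 s desk) collects on the order of 2 million counts, a clinical
count level. Counts are drawn binwise Poisson.

# Reconstruction

The OSEM engine is the classic multiplicative update with pluggable
forward/adjoint pairs and interleaved angle subsets (stride-S ordering;
the number of projections must divide evenly). Numerical safeguards,
all recorded in `osem_config()`:

* forward projections are floored at `nonneg_floor = 1e-12`, and `0/0`
  ratios are defined as 0;
* the data/model ratio is capped at `1e4`;
* for the Monte Carlo arm, near-empty forward bins are floored at
  `floor_frac = 0.02` times the positive-bin mean. A stochastic forward
  projection makes `1/forward` a heavy-tailed quantity whose expectation
  exceeds the inverse expectation (Jensen); without this floor the
  multiplicative iteration drifts upward and can diverge. With it, the
  per-subset modelled totals settle at the data totals.

The MC arm follows the in-the-loop design: Monte Carlo forward projection
with fresh seeds per update (unbiased but noisy — the reconstructed noise
level stays visibly high, as expected for this class of method) paired
with the CDR-corrected analytic attenuated back projection, an unmatched
pair by design. Initialization is a uniform positive constant scaled to
the total counts. Iterates are nonnegative by construction and asserted.
The Butterworth post filter can undershoot slightly (Gibbs); the filtered
activity estimate is clipped at zero.

The Butterworth dialect is `H(f) = (1 + (f/fc)^(2n))^(-1/2)` in 3-D
radial frequency (cycles/mm), so `|H(fc)| = 1/sqrt(2)`; a `squared`
dialect is available, as vendors differ. Both filters act isotropically in
3-D; whether the clinical filter was 2-D per slice is unknown, and the
3-D choice is the documented default.

# Lesion insertion conventions

The sphere centre lives on an edge-midpoint lattice (midway between voxel
centres in x and y, on a voxel centre in z) — the unique symmetric
convention for which a radius-1-voxel sphere contains exactly 4 voxel
centres (a 2 x 2 x 1 block). Placement is uniform over the lattice sites
whose control sphere fits inside the liver. The control-VOI mean excludes
the prospective tumor voxels. Insertion is additive in projection space
(patient + lesion sinograms are summed), so the normal tissue under the
lesion remains; in activity-map terms the effective voxel ratio is
therefore 9:1 under strict addition, while the *inserted* concentration is
exactly 8x the local mean, which is the quantity the design prescribes.

# Metrics

The 34-voxel normal-tissue VOI is underdetermined by its verbal
description; the implemented rule is: candidates at Chebyshev distance
exactly 2 from the tumor block (hence never adjacent to it) lying in one
of the three orthogonal voxel planes through the block; of these 76
candidates, keep the 34 nearest the sphere centre, with a lexicographic
tie-break. The rule is deterministic and translation-equivariant, and is a
convention of this package, not a published definition.

SNR is the tumor-VOI mean divided by the standard deviation of the means
of 20 randomly placed tumor-sized liver VOIs (uniform over eligible block
origins, non-overlapping with the tumor, seeded). Case classification
uses a coordinate tolerance of 2 voxels (8.84 mm, configurable): positive
call within tolerance = TP; outside = misplaced (a lesion-level false
positive *and* a positive call for ROC); negatives are FP/TN as usual.
Under scenario DL, undetectable positives become negatives first, so a
misplaced call on such a case becomes a case-level false positive.
Detection rate and accuracy are exact rational percentages, rounded to
one decimal only for display. The 1-6 rating maps (no, certain) to 1 up
through (yes, certain) at 6 — the unique monotone-in-suspicion ordering —
and the ROC area is the empirical Mann-Whitney statistic with a seeded
percentile bootstrap; a fitted binormal curve is deliberately not
implemented.

The package's "detectable" flag for a simulated lesion is a generation
rule, chosen here: a lesion is flagged undetectable when its local
concentration falls below 0.7 of the liver mean, the same low-uptake
mechanism that hid lesions in the original design. The scripted readout
observer (background-subtract with a broad Gaussian, robust z-score in
the eroded liver, threshold 2.5, confidence binned by z) exists so the
evaluation layer is testable end to end without a human; it is *not* a
validated model observer, and its absolute detection rates are not
comparable to a human reader's.

# Problem sizes and what the tests show

The test suite and the acceptance script run two profiles chosen by this
package: a 32 x 32 x 16 grid with 20 projections for pipeline mechanics
(including the full 111-image, 37-case design) and the compact profile —
48 x 48 x 32 at 4.42 mm with proportionally scaled organs, 40
projections, 1e6 photons per acquisition, 3e4 photons per OSEM forward
update, cohort 14 with 10 positives — for the cohort-level claims:
reconstructed TNC far below the inserted 8 in every arm (partial-volume
contraction), cohort-mean TNC ordered MC > filtered-MC >
attenuation-only (paired one-sided test at the 5% level), DL detection
never below AL detection, and — in a paired within-phantom comparison —
a lesion at the lowest-uptake eligible site losing reconstructed
contrast relative to one at the highest-uptake site, the mechanism that
hides lesions in low-uptake pockets. The larger desk profile
(64 x 64 x 48, 60 projections, cohort sizes 10-20) shows the same
pattern with weaker contrasts (per-arm means 1.20 / 1.25 / 1.33 in a
10-case run) and is the default for interactive use. Passing these shows
the pipeline reproduces the *pattern* of the detectability study on
synthetic data of the stated structure; it does not validate the phantom
against real livers, the transport model against a full physics code (no
coherent scatter, no septal penetration, no detector backscatter), or
the scripted readout against a human observer.

# Known limitations

* One isotropic grid serves both activity and attenuation; CT-grade
  resolution and slice-thickness mismatches are out of scope.
* The MC-in-the-loop photon budgets are small; reconstruction noise in
  the MC arm is correspondingly high (intentionally so).
* Detector physics is collapsed into a scalar sensitivity plus Gaussian
  energy resolution; no dead time, septal stars, or non-circular-orbit
  calibration.
* The scripted observer is a convenience, not a psychophysical model;
  absolute detection rates from `run_experiment()` characterize the
  pipeline, not human performance.
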