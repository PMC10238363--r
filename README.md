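# spectlab

Simulation and evaluation of liver-lesion detectability in In-111
octreotide SPECT.

## The problem

Somatostatin-receptor SPECT with In-111 octreotide is widely used to stage
neuroendocrine tumors, and the liver is a prime site for metastases. Small
lesions sit at the edge of visibility: reconstruction resolution spreads a
~0.35 cm^3 sphere's signal over its neighbourhood (the partial volume
effect), the surrounding liver uptake is itself nonuniform, and counts are
Poisson. Whether scatter and collimator-detector response (CDR) modelling
in the reconstruction — versus plain attenuation-corrected OSEM with a
smoothing filter — actually buys detectability is a quantitative question.

`spectlab` is a toolkit for studying that question with synthetic data.
It provides, as composable R functions:

* **Phantoms** — parametric abdominal activity/attenuation phantoms with a
  spatially correlated log-normal liver-uptake field (the anatomical noise
  that can hide a lesion), high-uptake kidneys, and a pseudo-CT mapped to
  attenuation at the 171/245 keV photopeaks.
* **Forward models** — a rotation-based attenuated analytic projector with
  distance-dependent Gaussian CDR (exact adjoint pair), and a Monte Carlo
  photon-transport projector (Woodcock tracking, Klein-Nishina Compton
  scatter, photopeak energy windows, forced-detection scoring).
* **Hybrid lesion insertion** — a sphere of radius 1 voxel (4 voxels,
  0.35 cm^3) placed uniformly in the liver, calibrated to a tumor-to-normal
  concentration (TNC) ratio of 8 against a 3-voxel-radius control sphere,
  simulated through the patient attenuation and *summed with the patient
  raw data* in sinogram space.
* **Reconstruction** — an OSEM engine (`osem()`, returning a classed fit
  object with `print`/`summary`/`plot`/`fitted`/`residuals`/`simulate`
  methods) with three pre-wired arms: attenuation-corrected OSEM
  (2 it x 10 ss + Butterworth 0.048 cycles/mm), Monte-Carlo-based OSEM
  (5 it x 10 ss, scatter + CDR in the forward model), and its
  Gaussian-filtered variant (sigma 3 mm).
* **Evaluation** — TNC ratio against a 34-voxel normal-tissue VOI, SNR
  against 20 random liver VOIs, case classification with coordinate
  checking (TP / misplaced / FP / TN / FN), detection rate and accuracy
  under the "all lesions" (AL) and "detectable lesions" (DL) scenarios,
  1-6 rating-scale empirical ROC AUC with bootstrap CI, and a scripted
  readout observer so the whole chain runs without a human reader.

## Worked example

Insert one lesion into one synthetic patient and compare the arms:

```r
library(spectlab)

cfg  <- experiment_config(profile = "desk")   # 64 x 64 x 48, 60 projections
geom <- cfg$geom
case <- generate_phantom(cfg$phantom, seed = 11)
case
#> phantom_case case_000011: 64x64x48 @ 4.42 mm, 121.7 MBq total, liver 7478 voxels

# acquire, then add a TNC-8 lesion in the raw data
ex     <- mc_forward(case$activity, case$mu_171, case$mu_245, geom, case$grid,
                     n_photons = 2e6, seed = 3)
counts <- sample_counts(ex, seed = 5)
ctr    <- sample_position(case$masks$liver, case$grid, lesion_spec(), seed = 21)
src    <- make_lesion_source(case, ctr)
src$truth
#> lesion_truth case_000011: centre (-35.4, 0, 28.7) mm, 4 voxels,
#>   local 58619 Bq/ml, inserted 468955 Bq/ml (TNC 8)
counts <- insert_lesion(counts, case, src$activity, geom, n_photons = 2e5, seed = 31)

# reconstruct and score
rec_fac <- reconstruct_arm(counts, case, "fAC_OSEM", geom, seed = 41)
rec_mc  <- reconstruct_arm(counts, case, "MC_OSEM",  geom, seed = 42)
nv <- build_normal_voi(src$truth$voxels, case$grid)
tnc_ratio(rec_fac$values, src$truth$voxels, nv, case$grid)
#> [1] 1.035
tnc_ratio(rec_mc$values,  src$truth$voxels, nv, case$grid)
#> [1] 1.126
```

The inserted ratio of 8 contracts to ~1.0-1.7 after reconstruction — the
partial volume effect that limits detectability — and the Monte Carlo arm
recovers visibly more contrast than the attenuation-only arm. A full
simulated study (cohort, three arms per case, AL/DL summaries, ROC) is one
call: `run_experiment(experiment_config(...), seed)`.

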