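# pulsedti

Cardiac-cycle pulsatile motion displaces brainstem and cerebellar tissue at
peak velocities around 1.5 mm/s during systole. In diffusion-weighted MRI
this bulk motion dephases the signal of volumes whose encoding gradient
aligns with the motion, producing localized signal dropouts that bias
diffusion-tensor parameters of the corticospinal tract (CST) — unless the
acquisition is cardiac-gated into diastole. `pulsedti` is an R package for
studying that chain quantitatively on synthetic data with known ground
truth. It is aimed at diffusion-MRI methods researchers and pipeline
developers who need a controlled test bed for gating, artefact-QC and
tractometry decisions.

The package provides:

* a **digital phantom**: an anisotropic CST-like tube (ground-truth
  eigenvalues (1.7, 0.3, 0.2)×10⁻³ mm²/s, FA ≈ 0.836) through isotropic
  tissue, CSF, and brainstem/cerebellar pulsatile zones;
* an **acquisition simulator**: S(g, b) = S₀·exp(−b·gᵀDg) over a 30-direction
  b = 1000 s/mm² scheme, 5 repetitions per gating mode, with a systolic
  attenuation artefact exp(−κ·v·|g·m|) in the pulsatile zones (non-gated
  only) and Rician noise;
* **gradient-table tools** including the subspace angle
  arccos(g·a / |g||a|) and selection of the encoding directions closest
  to / farthest from the z-axis;
* a **log-linear tensor fit** (`dtifit`-style) with FA/MD/eigenvalue/
  eigenvector maps;
* **artefact QC**: repetition-SD maps, gated/non-gated difference-SD maps,
  ROI-dropout flagging and the occurrence ratio
  100·n_flagged/(n_subjects·n_repetitions);
* **deterministic FACT-style tractography** with two-include/-exclude ROI
  filtering and rasterized tract objects;
* **tract metrics**: volumes, along-tract 5 mm slab profiles (21 slabs:
  brainstem 1–5, PLIC 6–10, corpus callosum 11–13, cingulum 14–18, motor
  cortex 19–21), eigenvector z-angle maps, the five-sample generalized
  Jaccard distance JD = 1 − |∩Mᵢ|/|∪Mᵢ|, and paired t-tests;
* a **study pipeline** (`run_study`) orchestrating all of the above for a
  22-subject gated vs non-gated design with fully seeded reproducibility.

## Worked example

```r
library(pulsedti)

# 1. gradient geometry: which encoding directions are closest to / farthest
#    from the z-axis (the pulsatile motion is mostly caudal)?
gt <- default_gradient_table()
ex <- select_extreme_volumes(gt, axis = c(0, 0, 1))
cat(sprintf("volume %d at %.2f deg (min), volume %d at %.2f deg (max)\n",
            ex$min_index, ex$min_angle, ex$max_index, ex$max_angle))
#> volume 2 at 12.78 deg (min), volume 31 at 89.72 deg (max)

# 2. simulate one subject non-gated and flag artefacted repetitions in the
#    brainstem for the near-axial volume
ph <- build_phantom()
pm <- pulsatile_model()
ng <- simulate_acquisition(ph, pm, acquisition_protocol(gt, 5, "non_gated",
                                                        1000 / 30, rng_seed = 11))
flag_artifacts(ng, ex$min_index, ph$pulsatile_zones$brainstem)
#> volume 2: 2 of 5 repetitions flagged (threshold 15%)

# 3. fit tensors on one repetition and compare tract FA with ground truth
fit <- dti_fit(ng$repetitions[[1]], gt, mask = ph$masks$brain,
               voxel_size = ph$voxel_size)
fa <- fa_map(dti_eigen(fit))
cat(sprintf("tract FA: fitted %.3f vs truth %.3f\n",
            mean(fa[ph$masks$tract]), ph$fa_truth[ph$masks$tract][1]))
#> tract FA: fitted 0.843 vs truth 0.836

# 4. reconstruct the tract and measure volume and overlap with the truth
sls <- apply_roi_filters(
  seed_and_track(fit, ph$masks$tract),
  roi_set(list(ph$rois$include_inferior, ph$rois$include_superior),
          list(ph$rois$exclude)))
tract <- rasterize_tract(sls, gating = "non_gated", repetition = 1)
tract
#> Tract object: 1211 voxels, 9.69 cm^3 (non_gated)
dice_coefficient(tract$mask, ph$masks$tract)
#> [1] 0.89

# 5. the artefact occurrence ratio for 13 flagged data sets out of 22 x 5
occurrence_ratio(13, 22, 5)
#> [1] 11.82
```

The two flagged repetitions are exactly the ones whose cardiac phase fell in
the systolic window for that volume; the slight FA over-shoot in a single
artefacted repetition and the sub-truth tract volume illustrate the biases
the full study quantifies. A complete 22-subject study is one call:

```r
report <- run_study(study_config(master_seed = 1))
print(report)
render_report(report, "report_out")   # table2.tsv + slab_profiles.pdf
```

`report` contains per-subject tract volumes, Jaccard distances (whole tract
and BS/PLIC/SC), artefact occurrence ratios, group SD-difference maps and
slab-wise paired tests. A thin CLI over the same functions is installed at
`inst/cli/pulsedti.R` (`simulate`, `run-study`, `report` subcommands).

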