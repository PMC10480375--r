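# augvol — semiautomatic volumetry of bone augmentation from intraoral surface scans

Bone augmentation procedures (onlay block grafts, split-block and shell
techniques with particulate filler) reshape the alveolar ridge before implant
placement. Quantifying how much volume a graft actually added is usually done
by manually annotating the augmented region slice by slice — precise but
labour intensive. `augvol` implements an automated alternative that works
directly on the triangulated surface scans (STL) an intraoral scanner
exports: it registers each post-augmentation scan onto the baseline scan,
turns both open surfaces into watertight solids, subtracts them inside a
region of interest, and reports the grafted volume in cm³, together with the
equivalence and reliability statistics used to validate such a workflow. The
intended users are researchers in oral and cranio-maxillofacial surgery who
need objective, scriptable volume outcomes from scan pairs.

## The method

Given a baseline scan and an augmented scan of the same anatomy (mm units):

1. **Registration.** A coarse three-point landmark alignment is refined by
   weighted iterative closest point (ICP) matching. Each iteration
   corresponds the weighted moving vertices to their nearest points on the
   fixed surface and solves the weighted least-squares rigid transform

   argmin over (R, t) of Σᵢ wᵢ ‖R sᵢ + t − tᵢ‖²

   in closed form by the Kabsch algorithm (SVD of the weighted
   cross-covariance, determinant-corrected). Vertices on the augmented
   region get weight 0 so the graft cannot bias the alignment; a numeric
   quality gate on the final weighted RMS replaces visual inspection.
2. **Trimming and solidification.** Superfluous geometry is cropped, the
   single open boundary loop of each patch is extruded by a fixed depth
   along the inward surface normal, and the opening is capped, producing
   watertight solids.
3. **Dual region of interest.** A user-supplied ROI solid (typically a box)
   is intersected with the baseline solid; a copy scaled down by a factor
   s (default 0.98) is intersected with the augmented solid. The size
   offset guarantees the baseline walls fully cover the augmented walls, so
   the Boolean subtraction `augmented − baseline` leaves exactly the graft.
   Free-floating particulate fragments are then removed by connected-
   component filtering. Booleans run on a robust voxel lattice (ray-parity
   point-in-solid classification, 0.1 mm default pitch).
4. **Volume.** The enclosed volume of the watertight difference mesh is
   V = (1/6) |Σ_faces v₀ · (v₁ × v₂)| per component, reported in mm³ and
   cm³. A slice-based oracle (0.25 mm cross-section summation, the manual
   protocol's computation) cross-validates every measurement.
5. **Statistics.** Paired TOST equivalence tests (margin ±0.15 cm³, 90% CI),
   NHST t tests, two-way mixed-effects single-measure intraclass
   correlation ICC(A,1) with F-based 95% CI for test–retest reliability,
   and Wilcoxon signed-rank comparisons.

Because no scan data are distributed, the package ships a phantom generator
(`generate_baseline()`, `generate_augmented()`, `generate_study()`) that
produces ridge-like synthetic scan pairs for three augmentation geometries at
realistic volume scales (≈0.35 / 0.76 / 0.82 cm³), with scanner-like noise,
a known rigid misalignment and an analytically known ground-truth added
volume, so the entire pipeline is testable end to end.

## Worked example

Generate a three-specimen synthetic study of block augmentations, measure
every scan twice (the second pass with jittered ROI placement and
registration initialization, emulating an independent reading session), and
test the measured volumes for equivalence against the known truth:

```r
library(augvol)

study <- file.path(tempdir(), "demo_study")
manifest <- generate_study(3, study, techniques = "B", seed = 42,
                           spec_overrides = list(noise_sd = 0.03))
measurements <- run_study(study, n_runs = 2, seed = 43)
measurements[, c("specimen", "technique", "timepoint", "volume_cm3",
                 "slice_volume_cm3", "truth_cm3", "registration_rms")]
#>   specimen technique timepoint volume_cm3 slice_volume_cm3 truth_cm3 registration_rms
#> 1        1         B        t0     0.4806           0.4810    0.4813          0.03580
#> 2        1         B        t1     0.4806           0.4810    0.4813          0.03581
#> 3        2         B        t0     0.4046           0.4048    0.4056          0.03638
#> 4        2         B        t1     0.4045           0.4059    0.4056          0.03638
#> 5        3         B        t0     0.3306           0.3307    0.3302          0.03683
#> 6        3         B        t1     0.3306           0.3307    0.3302          0.03683
```

Each row is one measurement: the pipeline volume (`volume_cm3`), the
slice-oracle cross-check (`slice_volume_cm3`), the constructive ground truth
of the phantom (`truth_cm3`), and the final weighted registration RMS in mm.
Recovery is within a few tenths of a percent and the two volume computations
agree to comparable precision.

```r
comparison <- rbind(
  data.frame(specimen = measurements$specimen, technique = measurements$technique,
             timepoint = measurements$timepoint, method = "semiautomatic",
             volume_cm3 = measurements$volume_cm3),
  data.frame(specimen = measurements$specimen, technique = measurements$technique,
             timepoint = measurements$timepoint, method = "ground_truth",
             volume_cm3 = measurements$truth_cm3))
summarize_table(comparison, margin = 0.15)
#>   technique timepoint n_pairs mean_a mean_b mean_difference ci90_lower ci90_upper   tost_p equivalent
#> 1         B        t0       3  0.406  0.405        0.000452  -0.000778    0.00168 3.96e-06       TRUE
#> 2         B        t1       3  0.406  0.405        0.000474  -0.000798    0.00175 4.24e-06       TRUE
```

`mean_difference` is the paired semiautomatic-minus-truth difference in cm³
with its 90% CI; `tost_p` is the larger of the two one-sided p values, so
both timepoints are declared statistically equivalent to the truth within
±0.15 cm³.

A thin command-line front end over the same functions is installed at
`inst/cli/augvol.R` (`register`, `solidify`, `diff`, `volume`,
`phantom-study`, `run`, `stats` subcommands).

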