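# cartstrain

Kinematics-driven articular cartilage contact-strain mapping and voxelwise
T2\* relaxometry, as one reusable, fully testable R pipeline.

## Who this is for

Researchers studying how joint loading shapes cartilage health measure two
things on the same joint: (1) **contact strain** during gait, from
marker-based motion capture of the bones plus image-derived 3D bone and
cartilage models, and (2) **T2\* relaxation time**, a quantitative-MRI
proxy for collagen integrity and hydration. Regional changes in the two,
before and after an intervention that redistributes load, are then
correlated. `cartstrain` implements that entire measurement chain — and,
because no such data sets are publicly deposited, it also ships a
first-class synthetic-data module that generates every input with known
ground truth (conforming ball-and-socket joint, periodic 6-DOF gait with
realistic stride variability, multi-echo MR volumes, a two-block accuracy
phantom, coupled pre/post scenarios).

## The core quantities

* **Contact strain** at a surface point: overlap depth of the rigidly posed
  cartilage layers divided by the undeformed combined thickness,
  `strain = ov / (t_scap + t_hum)`, with contact declared where
  `ov > 0.25 mm`. Per-frame maps over a representative gait cycle are
  cumulated (per-vertex maximum; union of contact areas).
* **T2\***: per voxel, least-squares fit of `S(TE) = S0 * exp(-TE/T2*)`;
  voxels with `T2* > 50 ms` are removed as synovial fluid; valid values are
  projected onto the cartilage surface through the layer thickness.
* **Representative cycle**: strides are segmented at mean-level crossings of
  the dominant DOF, resampled to 0–100 %, and filtered with the pointwise
  mean ± 1 SD band (a cycle is dropped when any DOF exceeds the band on
  more than 5 % of samples); retained cycles are averaged.
* **Statistics**: Pearson correlation of regional (20° bands) Δstrain vs
  ΔT2\*; ICC(2,1) with F-based CI and RMS differences for reliability;
  phantom bias/precision propagated to strain and contact-area errors.

## Worked example

```r
library(cartstrain)

sh <- make_shoulder(shoulder_spec(seed = 1))
sh
#> ShoulderModel: head radius 10.0 mm, mean thickness 0.818 mm (humeral) / 0.783 mm (scapular)

thickness_map(sh$humerus$subchondral, sh$humerus$cartilage)
#> ThicknessMap [humeral]: mean 0.818 mm (sd 0.076), 1153/1153 vertices defined

# pose the head 0.35 mm into the socket and map contact strain
res <- strain_over_cycle(sh, list(rigid_pose(translation = c(0, 0, 0.35))))
res$cumulative
#> CumulativeMap (max over 1 frames): contact area 214.8 mm^2 (35.4%), mean strain 19.96%

# multi-echo volume -> voxelwise T2* with the 50 ms fluid cutoff
v <- make_multiecho_volume(echo_spec(voxel_size = rep(0.5, 3), seed = 1), sh)
map_volume(v)
#> T2StarMap: 5066/59823 valid voxels, mean T2* 23.19 ms (sd 7.70), cutoff 50 ms

# accuracy phantom at 30 degrees, 0.1 mm marker noise
ph <- make_phantom(30, noise_sd = 0.1, n_frames = 500, seed = 1)
bias_precision(measure_phantom(ph), configuration = "30")
#>             quantity configuration        bias precision_plus precision_minus
#> 1 center_distance_mm            30 0.001414013      0.1102863       0.1102863
#> 2    block_angle_deg            30 0.006173819      0.1159159       0.1159159
```

Reading the numbers: the generated cartilage averages 0.82 mm thick and the
ray-cast thickness map reproduces the generator's ground truth; a 0.35 mm
compression of a conforming 10.8 mm ball produces ~20 % mean contact strain
over a 215 mm² contact patch; the voxel fit recovers cartilage T2\* near
its 25 ms ground truth while fluid voxels fall to the cutoff; and the
phantom audit shows sub-0.01 mm/deg bias with ~0.11 mm / 0.12° precision —
the error scale that the propagation stage turns into strain/area error
envelopes.

A full pre/post study (simulate → track → representative cycle → strain →
T2\* → regions → correlation) is one call:

```r
res <- run_study(run_config(seed = 11), out_dir = "study_out")
res$correlation[c("r", "p", "n")]
```

## Command line

```sh
Rscript inst/cli/cartstrain.R simulate shoulder --seed 1 --out-dir out
Rscript inst/cli/cartstrain.R phantom --angle 30 --frames 2000 --noise-mm 0.1
Rscript inst/cli/cartstrain.R run-study --seed 1 --out-dir study_out
```

## Layout

* `R/` — synthetic generators (`make_shoulder`, `make_gait`,
  `make_multiecho_volume`, `make_phantom`, `make_coupled_scenario`),
  kinematics (`estimate_rigid_pose`, `align_by_subchondral`,
  `relative_dof`, `segment_cycles`, `reject_outlier_cycles`), contact
  mechanics (`thickness_map`, `overlap_depth`, `contact_strain`,
  `cumulate`), relaxometry (`fit_t2star`, `map_volume`,
  `project_to_surface`), regional statistics (`bin_regions`, `pearson`,
  `icc`, `rms_difference`), phantom validation and the pipeline driver.
* `src/` — C++ ray/mesh intersection and closest-point kernels.
* `vignettes/cartstrain-methods.Rmd` — models, assumptions, parameter
  choices, and what the synthetic world does and does not emulate.
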