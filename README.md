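# slotpipe

Simulation, reconstruction and correlative analysis for Scanning Laser
Optical Tomography (SLOT).

SLOT images whole cleared, resin-embedded specimens — a rodent lung lobe,
say — by scanning a weakly focused laser through the rotating sample and
simultaneously recording transmitted light (absorption) and fluorescence.
Filtered back projection turns the two projection sets into isotropic 3D
volumes in which arbitrary virtual reslices can be computed and matched
against sections from other modalities (multi-photon mosaics, histology,
TEM). That correlative step is what lets dense, remodeled "fibrotic"
regions be found at whole-organ scale and then targeted at high
resolution.

`slotpipe` is for scientists and tool builders who need that computational
chain as a tested, scriptable library: acquisition planning, a two-channel
forward projector (parallel and fan-like beam), sinogram preprocessing
including de-shearing of fan-beam data, FBP reconstruction,
three-landmark reslice alignment, tiled-mosaic stitching with linear
blending, and watershed-based density screening — all validated on
synthetic lung-lobe phantoms generated by the package itself, so no
external data are required.

## The core models

* **Planning.** Depth of field `2·n·λ/NA²` (the whole sample must fit
  inside it), lateral resolution `λ/(2NA)`, and the CT sampling rule that
  the number of projections over 360° equal the number of lateral
  samples (increment `360/N`). Mosaic and axial bookkeeping reproduce
  tile/pixel counts and the index-mismatch z-step calibration.
* **Forward model.** Per detector row, a 2D Radon transform:
  transmission `I = i0·exp(−Σ μ·Δl)` (Beer–Lambert), fluorescence
  `Σ f·Δl` without self-absorption (cleared sample). The f-theta lens fan
  is modelled to first order: column *x* sees effective angle
  `φ + s·(x − x₀)`.
* **Correction + reconstruction.** De-shearing shifts each sinogram
  column along φ by the negative of its beam tilt (circular, linearly
  interpolated), restoring sinus-like traces; standard FBP
  (ramp/Shepp-Logan/Hann filters, `π/(2N)` normalization) reconstructs
  slice by slice.
* **Alignment.** From three landmarks: `n = normalize((p2−p1)×(p3−p1))`,
  then `α_x = asin(n₂)`, `α_y = atan2(−n₁, n₃)` so that
  `R_x(α_x)·R_y(α_y)·n = e_z`, satisfying the relation
  `α_y = asin(n₁/cos α_x)`.
* **Stitching.** Two iteratively refined translation vectors (column and
  row steps) estimated by normalized cross-correlation of predicted
  overlap strips; linear pre-weighting blend masks whose ramps partition
  unity; z-stacking with the measured (index-scaled) step.
* **Screening.** Perona–Malik gradient anisotropic diffusion → gradient
  magnitude → marker-based priority-flood watershed → region
  classification by mean density.

See the methods vignette (`vignettes/slot-pipeline-methods.Rmd`) for
assumptions, parameter defaults and numerical conventions.

## Worked example

Plan the acquisition for a lung-lobe scan and mosaic:

```r
library(slotpipe)
plan_acquisition(optics_params(n_imm = 1.556, wavelength_nm = 532, na = 0.013),
                 n_lateral = 1500,
                 tile_um = 350, overlap_fraction = 0.05, px_um = 0.3295,
                 extent_um = c(6515, 14965),
                 nominal_z_step_um = 2, z_scale_factor = 1.36, n_z_slices = 146)
#> dof_mm: 9.796355
#> dof_mm_rounded: 10.0
#> lateral_resolution_um: 20.4615385
#> lateral_resolution_um_rounded: 20.0
#> n_projections_required: 1500
#> angular_increment_deg: 0.24
#> tile_px: 1062
#> mosaic_px:
#> - 19772
#> - 45417
#> ...
#> measured_z_step_um: 2.72
#> total_depth_um: 397.12
```

So: a 10 mm depth of field covers the lobe at NA 0.013 with 20 µm beams;
1500 lateral samples demand 1500 projections at 0.24°; 350 µm tiles map
to 1062 px and the 6515 µm mosaic axis to 19772 px; 146 slices at the
calibrated 2.72 µm step span 397 µm.

Simulate, reconstruct and screen a phantom:

```r
ph   <- make_lobe_phantom(phantom_params(fibrosis_fraction = 0.1, seed = 3))
geom <- acquisition_geometry(128, 96, 96, pixel_um = 20)
proj <- forward_project(ph, geom)                       # two channels
rec  <- fbp_volume(proj$fluorescence, recon_params(filter = "ramp"))

mask <- ph$truth_labels$data > 0
cor(rec$data[mask], ph$fluorescence$data[mask])
#> [1] 0.9569095

rc <- segment_fibrosis(ph$fluorescence)
truth <- ph$truth_labels$data == 4
2 * sum(fibrotic_mask(rc) & truth) / (sum(fibrotic_mask(rc)) + sum(truth))
#> [1] 0.9976579
```

The reconstruction correlates with the ground-truth fluorescence at
r ≈ 0.96 inside the lobe, and the screening pipeline recovers the planted
fibrotic patches with a Dice overlap of ≈ 0.998 at the shipped defaults.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "slotpipe", package = "slotpipe")`, with subcommands
`phantom`, `plan`, `simulate`, `preprocess`, `reconstruct`, `reslice`,
`stitch` and `segment`.

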