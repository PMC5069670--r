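---
title: "Methods: simulation, reconstruction and correlative analysis for SLOT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, reconstruction and correlative analysis for SLOT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slotpipe)
```

## The imaging problem

Scanning Laser Optical Tomography (SLOT) images optically cleared,
resin-embedded specimens of millimeter-to-centimeter extent by scanning a
weakly focused laser through the rotating sample and recording, for every
scan position and viewing angle, the transmitted light (absorption
contrast, photodiode) and the emitted fluorescence (photomultiplier). A
full revolution yields two projection data sets that are reconstructed
slice-by-slice into isotropic 3D volumes by filtered back projection
(FBP). Because the volumes are isotropic, arbitrary virtual reslices can
be computed and matched against sections imaged with other modalities
(multi-photon mosaics, histology, electron microscopy), which is the basis
of correlative screening: find dense, remodeled ("fibrotic") regions in
the whole-organ volume, then target them with higher-resolution methods.

`slotpipe` implements this computational chain as a tested library plus a
thin command-line interface, exercised entirely on synthetic phantoms: no
external data are needed to validate any stage.

## The synthetic lobe phantom

`make_lobe_phantom()` emulates a cleared rodent lung lobe at the scale the
scanner sees it:

* an **ellipsoidal lobe** (default semi-axes 850 x 900 x 780 um in a 96^3
  grid of 20 um voxels) with a thin, denser **pleural shell** (40 um);
* **alveolar voids**: spheres of 60 um diameter — three times a 20 um
  focal beam width, the alveolar scale of the rat lung — placed by
  Poisson-disc sampling (minimum spacing 1.2 diameters) so the parenchyma
  gets a vesicular texture without anatomical modelling;
* an **airway tree** of 2–3 levels of tapering cylinders grown from a
  single stem, enough tubular structure to exercise oblique reslicing; no
  claim of airway realism is made;
* optional **fibrotic patches**: sums of anisotropic Gaussian blobs
  thresholded at half maximum. The blob widths are rescaled iteratively
  (at most 20 iterations, absolute tolerance 0.03) until the patch volume
  hits the requested fraction of lobe voxels. Since no quantitative
  density contrast between fibrotic and normal tissue is established, the
  contrast ratio is a configuration parameter (`fibrosis_contrast`,
  default 2.5).

Absorption (1/um) and fluorescence (arbitrary units) are piecewise
constant per tissue class: background resin is nearly transparent, the
pleura slightly denser and brighter than parenchyma, alveolar voids nearly
empty, fibrosis `fibrosis_contrast` times the parenchyma in both channels.
All randomness flows from the single `seed` in `phantom_params()` (scoped
with `withr::with_seed()`, so the global RNG state is untouched), and
identical parameters give bit-identical phantoms.

What the phantom deliberately does **not** model: vasculature, anatomical
airway branching statistics, detector noise, scattering, refraction at
residual index mismatch, or the point-spread function of the real beam.
Passing tests therefore demonstrate the correctness of the computational
chain, not instrument-level realism.

## Acquisition planning

The planner collects the closed-form scan arithmetic:

* **Depth of field** `2 n lambda / NA^2` (mm). The whole sample thickness
  must sit inside the DoF, which is why SLOT uses a very small NA: with
  n = 1.556, lambda = 532 nm, NA = 0.013 the DoF is 9.8 mm, i.e. about
  10 mm at the mm rounding the instrument context uses.
* **Lateral resolution** `lambda / (2 NA)` (um): 20.5 um, reported as
  20 um, for the same parameters.
* **Angular sampling**: FBP needs as many projections over the full
  revolution as there are lateral samples, the classical CT rule;
  1500 lateral samples demand 1500 projections at 360/1500 = 0.24 deg.
* **Mosaic bookkeeping**: tile pixels use `floor(tile_um / px_um)` (a tile
  cannot exceed its physical field), mosaic pixels use rounding, and the
  grid is the minimal tile count covering the extent at step
  `tile * (1 - overlap)`. With 350 um tiles at 0.3295 um/px this gives
  1062 px tiles, and a 6515 um extent maps to 19772 px.
* **Axial calibration**: an index-mismatched objective displaces the focal
  plane inside the sample by more than the mechanical step; the measured
  step is `nominal x scale` (2 um x 1.36 = 2.72 um), and the recorded
  total depth follows the convention `n_slices x scaled_step` (146 slices
  of 2.72 um = 397.12 um, 397 at um rounding) — each slice represents one
  full step of sample, which is the only convention that reproduces that
  total.

A note on two published inconsistencies the planner does not try to
resolve: a printed sampling rate of 8.69 um/px is not reproducible from a
13 mm field over 1500 samples (8.67), and mosaic extents printed alongside
a 5% overlap imply roughly 7% overlap. `plan_mosaic()` follows its own
consistent rule and treats the overlap as a free parameter.

## Forward projection

The projector treats each detector row y (the rotation axis is vertical)
as an independent 2D Radon problem in the xz-plane. For each viewing
angle, rays are sampled at unit-voxel steps with bilinear interpolation;
the transmission channel applies Beer–Lambert,
`I = i0 exp(-sum mu dl)`, and the fluorescence channel records the plain
line integral `sum f dl`. Fluorescence is projected without
self-absorption — the cleared-sample assumption under which the two
channels are independent projection sets. Angles are bin centers starting
at 0 deg on the half-open interval [0, 360).

The f-theta scan lens makes beams in the xz-plane fan out: the beam at
detector column x propagates at an in-plane angle
`beta(x) = shear_rate * (x - center_x)`. `fan_project()` models this to
first order by evaluating column x at the effective angle `phi + beta(x)`,
which is exactly what shears the sinusoid traces in the sinogram. The fan
angle of the real lens is not quantified anywhere usable, so the default
test geometry uses a worst-case tilt of 2 deg at the field edge — enough
to displace traces by several angle samples and exercise the correction.
Tilts beyond 45 deg are rejected as outside the model's validity.

## Sinogram preparation

* `transmission_to_line_integral()` applies `-log(I / i0)`; nonpositive
  intensities are a data error reported with the offending pixel count.
* `deshear()` shifts every detector column along the angle axis by the
  negative of its beam tilt, circularly (a full revolution is 360-deg
  periodic) with linear interpolation between angle samples. It is the
  exact inverse of the fan model, restores sinus-like traces, and requires
  uniform angular spacing. Linear-in-x shear is the first-order f-theta
  model; whether the original correction used a lens-calibrated nonlinear
  offset is unknown, so linear is what is implemented. Circular
  interpolation preserves per-column sums exactly, which the property
  tests check.
* `check_angular_sampling()` flags sinograms with fewer projections than
  lateral samples; reconstruction proceeds with a warning rather than an
  error, since undersampled previews are routine practice.

## Filtered back projection

`fbp_slice()` filters each projection in the frequency domain (projections
are zero-padded to twice the detector width at the next power of two to
suppress circular convolution) and backprojects with bilinear
interpolation, scaling by `pi / (2 n_angles)`. With that constant a
unit-density disk reconstructs at unit value, which the tests verify
(within a few percent: voxelized disk edges bias the discrete line
integrals). Filters: pure ramp (Ram-Lak), Shepp-Logan, and ramp with a
Hann window. The default is the Hann-windowed ramp — standard practice on
measured data, where the pure ramp amplifies high-frequency noise — but on
noise-free synthetic projections the pure ramp is the faithful choice and
is what the round-trip quality metrics use. The exact filter used by the
external reconstruction programs in the field is generally not stated,
which is why it is configurable. `circle_mask` (default on) zeroes voxels
outside the inscribed cylinder, the region the detector actually covers at
all angles. `fbp_volume()` divides by the pixel pitch so absorption comes
back in 1/um and fluorescence as density.

## Correlative reslice alignment

Three landmarks picked on corresponding structures define the reslice
plane: `normal = normalize((p2 - p1) x (p3 - p1))`, support point `p1`.
The normal's sign is canonicalized to a non-negative z-component (ties
resolved toward non-negative y, then x) — how the original sign ambiguity
was broken is unstated, so this is the package's convention, stated once.

The rotation that maps the unit normal `(n1, n2, n3)` onto the stack axis
is the pair `R_x(alpha_x) R_y(alpha_y)` with

* `alpha_x = asin(n2)`,
* `alpha_y = atan2(-n1, n3)`,

which satisfies `R_x R_y n = e_z` to machine precision and reproduces the
printed relation `alpha_y = asin(n1 / cos(alpha_x))` up to sign
convention. This rotation order is the unique two-axis decomposition
consistent with that relation. A normal along the y-axis makes `alpha_y`
undefined (gimbal degeneracy) and is an error rather than a silent branch
choice.

`rotate_volume()` resamples under this rotation about the volume center
with trilinear interpolation (nearest-neighbour is selectable for label
volumes, which must never be averaged), growing the output box to the
rotated footprint and zero-filling outside. Flat reslices interpolate
linearly between slabs at fractional indices; curved reslices follow an
arc-length-parameterized polyline at unit-voxel steps on the half-open
interval [0, L) (output width `ceil(L)`), swept across the through-plane
axis with trilinear sampling.

Internally all coordinates are 1-based voxel-center positions, the natural
R convention; the CSV interfaces use 0-based coordinates and the readers
convert, so file-level interoperability follows the common convention of
image-processing tools.

## Mosaic stitching

Tile grids are described by two step vectors: `u` between column
neighbours and `v` between row neighbours. A tilt between the mechanical
stage and the optical scan axes makes them non-axis-aligned and
non-integer, so `estimate_basis()` refines them iteratively: each
iteration predicts every overlap strip from the current basis, finds the
residual displacement maximizing the normalized cross-correlation of the
strips (integer search with per-shift clipping, then a quadratic subpixel
peak fit), and applies the median residual over pairs — the median
resists occasional low-contrast tiles. Iteration stops when the largest
update drops below `tol_px`. If every pair's correlation peak stays below
`min_corr` the data simply do not constrain the basis and estimation
aborts.

Blending uses a pre-weighting mask: weight 1 in the tile interior, linear
ramps to zero across the overlap margins, the 2D mask being the separable
product of per-axis ramps. Ramps of abutting tiles are complementary by
construction, so summed weights partition unity strictly inside the
mosaic (to 1e-9 in the tests). `assemble_mosaic()` places tiles at
continuous positions with bilinear splatting — with an integer basis the
splat collapses to exact placement and the zero-noise fixture inverts
exactly; with subpixel bases a few percent of smoothing error in overlap
zones is inherent to double resampling. Vignetting is *not* corrected
beyond blending. `stack_mosaics()` stacks the 2D mosaics with the
index-scaled z-step described under planning.

## Density-based screening

The screening chain replaces an interactive brush tool with a batch
pipeline while keeping the published filter chain: gradient anisotropic
diffusion, gradient magnitude, watershed.

* **Diffusion** is Perona–Malik with conductance
  `g = exp(-(|grad| / kappa)^2)`, explicit 6-neighbour updates with
  face-wise fluxes (conservative, so the global mean is preserved to
  1e-6 relative) and Neumann boundaries. The von Neumann stability bound
  for the 3D 6-neighbour Laplacian is 1/6; the default time step 0.15
  keeps a margin, and steps above 0.25 are rejected.
* **Gradient magnitude** uses central differences scaled by the voxel
  spacing (one-sided at borders).
* **Watershed** floods from markers in order of increasing gradient with
  a priority queue; ties break by insertion order with markers seeded in
  linear-index order, so results are fully deterministic and on a uniform
  gradient the flooding degenerates to nearest-marker (city-block)
  partitioning. Markers come either from the caller or from the
  6-connected components of a low-gradient flood level.
* **Classification**: a region is "fibrotic" when its mean intensity
  reaches the density threshold — dense remodeled tissue is precisely
  what has elevated signal in both channels. The adaptive default takes
  the midpoint between the median and the maximum of per-region means,
  which lands between the modes of a bimodal dense/normal mixture.

No diffusion or watershed parameter values are published for the original
interactive analysis; the shipped defaults (`segment_defaults()`:
kappa = 0.4, 10 iterations, dt = 0.15, flood level at 10% of the maximum
gradient) were chosen on the phantom and are declared as such, with no
claim that they match the original analysis. On ten seeded phantoms at
10% fibrosis the median Dice overlap between recovered and planted
fibrosis exceeds 0.99; on real, noisy data the margin would be smaller.

## Numerical choices and problem sizes

* Projection and backprojection step lengths are one voxel; rotation is
  by coordinate resampling with bilinear/trilinear interpolation (clarity
  over speed; the kernels are compiled).
* FBP normalization `pi / (2 N)`; frequency filter defined on
  `|f| <= 0.5` cycles/sample.
* TIFF pages store affinely rescaled values (the format's float samples
  live in [0, 1]); the YAML sidecar is authoritative for the rescaling,
  spacing, angles and channel roles, since TIFF tags cannot carry them at
  um precision. Data round-trip to 32-bit float precision; label volumes
  round-trip exactly as 16-bit integers. MRC output is mode 2 (float32)
  with cell dimensions `shape x spacing`.
* The test and acceptance suites use 96^3 phantoms with 128 projections,
  128-sample detectors, 3 x 3 tile grids from 512^2 sources, and 1e4
  random normals — sizes chosen so the full validation runs in a few
  minutes on one CPU while every stage is still exercised at meaningful
  scale. The printed-arithmetic checks use the published parameters
  themselves (1500 projections, 350 um tiles, 146 slices).

## Known limitations

* No scattering, refraction, beam divergence within the depth of field,
  or detector noise in the forward model; the fan model is linear in x.
* Shear parameters come from configuration/ground truth; automatic shear
  estimation is out of scope.
* Stitching estimates one global basis, not per-tile positions (no bundle
  adjustment), and performs no flat-field correction.
* The segmentation defaults are phantom-tuned; real data will need their
  own thresholds, and the interactive refinement step of the original
  workflow has no batch equivalent here.
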