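#' Illumination optics parameters
#'
#' @param n_imm refractive index of the immersion medium / cleared sample
#'   (dimensionless).
#' @param wavelength_nm laser wavelength in nanometres.
#' @param na numerical aperture of the weakly focused scanning beam; must be
#'   smaller than `n_imm`.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(n_imm, wavelength_nm, na) {
  if (any(c(n_imm, wavelength_nm, na) <= 0))
    stop("all optics parameters must be positive")
  if (na >= n_imm) stop("na must be smaller than the immersion index")
  structure(list(n_imm = n_imm, wavelength_nm = wavelength_nm, na = na),
            class = "optics_params")
}

#' Depth of field of the scanning beam
#'
#' DoF = 2 * n * lambda / NA^2, returned in millimetres. In projection
#' tomography with a scanned weakly focused beam the whole sample thickness
#' must sit inside this axial range, so the NA is chosen small. The
#' quadratic NA dependence is the standard Rayleigh-range scaling of a
#' focused Gaussian beam.
#'
#' @param p an [optics_params()].
#' @return Depth of field in mm.
#' @examples
#' depth_of_field(optics_params(1.556, 532, 0.013)) # ~9.8 mm, "approx 10 mm"
#' @export
depth_of_field <- function(p) {
  stopifnot(inherits(p, "optics_params"))
  if (p$na == 0) stop("na must be nonzero")
  # 2 * n * lambda / NA^2; lambda nm -> mm is 1e-6
  2 * p$n_imm * p$wavelength_nm * 1e-6 / p$na^2
}

#' Lateral optical resolution
#'
#' Delta-x = lambda / (2 NA), returned in micrometres: the theoretical focal
#' beam thickness (FWHM) of the scanning beam, which sets the in-plane
#' resolution of the tomogram.
#'
#' @param p an [optics_params()].
#' @return Lateral resolution in um.
#' @examples
#' lateral_resolution(optics_params(1.556, 532, 0.013)) # ~20 um
#' @export
lateral_resolution <- function(p) {
  stopifnot(inherits(p, "optics_params"))
  if (p$na == 0) stop("na must be nonzero")
  p$wavelength_nm / (2 * p$na) * 1e-3
}

#' Projections required by the angular sampling theorem
#'
#' For filtered back projection the number of projections over a full
#' revolution should equal the number of lateral sampling points, the
#' classical CT sampling rule.
#'
#' @param n_lateral_samples lateral sample count of each projection.
#' @return Required number of projections (equal to the input).
#' @export
required_projections <- function(n_lateral_samples) {
  n <- as.integer(n_lateral_samples)
  if (n < 1L) stop("n_lateral_samples must be >= 1")
  n
}

#' Angular increment of a full-revolution scan
#'
#' @param n_projections number of projections over 360 degrees.
#' @return Step angle in degrees, `360 / n_projections`.
#' @export
angular_increment <- function(n_projections) {
  n <- as.integer(n_projections)
  if (n < 1L) stop("n_projections must be >= 1")
  360 / n
}

#' Refractive-index scaling of the axial step
#'
#' When the objective is index-mismatched to the sample the mechanical
#' z-step of the focus drive corresponds to a larger optical displacement of
#' the focal plane inside the sample; the measured step is the nominal step
#' times a calibration factor.
#'
#' @param nominal_step_um mechanical step in um.
#' @param scale_factor dimensionless measured/nominal ratio.
#' @return Measured (optical) step in um.
#' @examples
#' axial_step_scale(2, 1.36) # 2.72 um
#' @export
axial_step_scale <- function(nominal_step_um, scale_factor) {
  if (nominal_step_um <= 0 || scale_factor <= 0)
    stop("step and scale factor must be positive")
  nominal_step_um * scale_factor
}

#' Plan a tiled mosaic acquisition
#'
#' Pixel and tile bookkeeping for a tiled 2D mosaic: tile pixels are
#' `floor(tile_um / px_um)` (a tile cannot exceed its physical field),
#' mosaic pixels per axis are `round(extent / px_um)` (half away from zero),
#' and the grid is the minimal number of tiles at step
#' `tile_um * (1 - overlap_fraction)` covering each axis.
#'
#' @param extent_um numeric length 1 or 2, mosaic extent per axis in um.
#' @param tile_um physical tile size (square tiles) in um.
#' @param overlap_fraction fractional overlap between adjacent tiles,
#'   in `[0, 1)`.
#' @param px_um pixel pitch in um.
#' @return List with `tile_px`, `mosaic_px` (per axis), `grid` (tiles per
#'   axis) and `n_tiles`.
#' @export
plan_mosaic <- function(extent_um, tile_um, overlap_fraction, px_um) {
  if (px_um <= 0) stop("px_um must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  extent_um <- as.numeric(extent_um)
  if (any(tile_um > extent_um)) stop("tile larger than the extent")
  tile_px <- floor(tile_um / px_um)
  # round half away from zero, matching printed pixel counts
  mosaic_px <- floor(extent_um / px_um + 0.5)
  step <- tile_um * (1 - overlap_fraction)
  # minimal n with tile_um + (n-1)*step >= extent
  grid <- pmax(1, ceiling((extent_um - tile_um) / step - 1e-9) + 1)
  list(tile_px = as.integer(tile_px), mosaic_px = as.integer(mosaic_px),
       grid = as.integer(grid), n_tiles = as.integer(prod(grid)))
}

#' Full acquisition planning report
#'
#' Combines the closed-form planning formulas into one report, with display
#' rounding matching the instrument conventions (mm for depth of field, um
#' for resolutions and depths).
#'
#' @param optics an [optics_params()].
#' @param n_lateral lateral sampling points per projection.
#' @param tile_um,overlap_fraction,px_um,extent_um mosaic parameters
#'   (see [plan_mosaic()]); optional.
#' @param nominal_z_step_um,z_scale_factor,n_z_slices axial mosaic
#'   parameters; optional.
#' @return A list of class `planner_report`.
#' @export
plan_acquisition <- function(optics, n_lateral,
                             tile_um = NULL, overlap_fraction = 0.05,
                             px_um = NULL, extent_um = NULL,
                             nominal_z_step_um = NULL, z_scale_factor = 1,
                             n_z_slices = NULL) {
  n_proj <- required_projections(n_lateral)
  rep <- list(
    dof_mm = depth_of_field(optics),
    dof_mm_rounded = round(depth_of_field(optics)),
    lateral_resolution_um = lateral_resolution(optics),
    lateral_resolution_um_rounded = round(lateral_resolution(optics)),
    n_projections_required = n_proj,
    angular_increment_deg = angular_increment(n_proj)
  )
  if (!is.null(tile_um) && !is.null(px_um) && !is.null(extent_um))
    rep <- c(rep, plan_mosaic(extent_um, tile_um, overlap_fraction, px_um))
  if (!is.null(nominal_z_step_um) && !is.null(n_z_slices)) {
    step <- axial_step_scale(nominal_z_step_um, z_scale_factor)
    rep$measured_z_step_um <- step
    rep$total_depth_um <- n_z_slices * step
    rep$total_depth_um_rounded <- round(n_z_slices * step)
  }
  structure(rep, class = "planner_report")
}

#' @export
print.planner_report <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
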