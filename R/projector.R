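#' Forward-project a phantom under parallel-beam geometry
#'
#' Simulates simultaneous two-channel acquisition: per viewing angle phi and
#' detector row y, the transmission channel records
#' `i0 * exp(-sum(mu * dl))` along the beam (Beer-Lambert, photodiode) and
#' the fluorescence channel records the plain line integral `sum(f * dl)`
#' (photomultiplier), with `dl` one voxel. The beam propagates along z, the
#' sample rotates about y, and the lateral scan axis is x, so each y-row is
#' an independent 2D Radon transform of the corresponding xz-slice.
#' Fluorescence is projected without self-absorption (cleared-sample
#' assumption); the two channels are independent projection sets.
#'
#' @param phantom a `phantom_pair` (or a list with `absorption` and
#'   `fluorescence` `volume3d` elements).
#' @param geom an [acquisition_geometry()]; its `fan` slot must be absent or
#'   have zero shear rate (use [fan_project()] otherwise). `detector_y` must
#'   match the volume's y extent and `detector_x` must cover the lateral
#'   footprint; `pixel_um` must equal the voxel pitch.
#' @return List with `transmission` and `fluorescence` [sinogram()]s.
#' @export
forward_project <- function(phantom, geom) {
  if (!is.null(geom$fan) && geom$fan$shear_rate != 0)
    stop("geometry has a nonzero fan; use fan_project()")
  .project_channels(phantom, geom, fan = NULL)
}

#' Forward-project under fan-like beam geometry
#'
#' As [forward_project()], but the beam at detector column x propagates at
#' an in-plane angle `beta(x) = shear_rate * (x - center_x)` (degrees)
#' relative to the optical axis, the first-order model of an f-theta scan
#' lens. Each sinogram column x is then the parallel projection at effective
#' angle `phi + beta(x)`, which shears the sinusoid traces of point objects
#' along the angle axis.
#'
#' @inheritParams forward_project
#' @return List with `transmission` and `fluorescence` [sinogram()]s.
#' @export
fan_project <- function(phantom, geom) {
  if (is.null(geom$fan)) stop("geometry has no fan parameters")
  beta_max <- geom$fan$shear_rate *
    max(abs(c(1, geom$detector_x) - geom$fan$center_x))
  if (abs(beta_max) > 45)
    stop("fan tilt exceeds 45 degrees; model not valid")
  .project_channels(phantom, geom, fan = geom$fan)
}

.project_channels <- function(phantom, geom, fan) {
  mu <- phantom$absorption; fl <- phantom$fluorescence
  stopifnot(inherits(mu, "volume3d"), inherits(fl, "volume3d"))
  d <- dim(mu$data)
  if (!all(dim(fl$data) == d)) stop("channel volumes differ in shape")
  if (geom$detector_y != d[2])
    stop(sprintf("detector_y (%d) must equal the volume y extent (%d)",
                 geom$detector_y, d[2]))
  if (geom$detector_x < max(d[1], d[3]))
    stop("detector_x does not cover the phantom footprint")
  if (abs(geom$pixel_um - mu$spacing[1]) > 1e-9)
    stop("detector pixel_um must equal the voxel pitch")
  line_mu <- .line_integrals(mu, geom, fan)
  line_fl <- .line_integrals(fl, geom, fan)
  list(transmission = sinogram(geom$i0 * exp(-line_mu), geom, "transmission"),
       fluorescence = sinogram(line_fl, geom, "fluorescence"))
}

.effective_angles <- function(geom, fan) {
  ang <- geom$angles * pi / 180
  if (is.null(fan)) return(matrix(ang, geom$n_projections, geom$detector_x))
  beta <- fan$shear_rate * (seq_len(geom$detector_x) - fan$center_x) * pi / 180
  outer(ang, rep(1, geom$detector_x)) + outer(rep(1, geom$n_projections), beta)
}

.line_integrals <- function(v, geom, fan) {
  eff <- .effective_angles(geom, fan)
  cpp_project(v$data, dim(v$data), eff, geom$detector_x) * v$spacing[1]
}

#' Project a single-channel volume
#'
#' Line integrals (`sum(value * dl)`) of one volume under the given
#' geometry; the building block used for oracle tests and for projecting
#' arbitrary densities.
#'
#' @param v a [volume3d()].
#' @param geom an [acquisition_geometry()].
#' @return A [sinogram()] with channel `line_integral`.
#' @export
project_volume <- function(v, geom) {
  stopifnot(inherits(v, "volume3d"))
  d <- dim(v$data)
  if (geom$detector_y != d[2] || geom$detector_x < max(d[1], d[3]))
    stop("detector does not cover the volume")
  sinogram(.line_integrals(v, geom, geom$fan), geom, "line_integral")
}
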