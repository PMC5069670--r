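#' 3D scalar volume with physical voxel spacing
#'
#' Lightweight container for a 3D image grid. The array is indexed
#' `[x, y, z]`; `y` is the tomographic rotation axis, `z` the beam
#' propagation axis and `x` the lateral scan axis. Spacing is in micrometres
#' per voxel along each axis. `channel` records what the values mean
#' (absorption coefficient in 1/um, fluorophore density, reconstructed
#' intensity, or integer labels).
#'
#' @param data numeric 3D array, dim `c(nx, ny, nz)`.
#' @param spacing numeric length-3, um per voxel along x, y, z.
#' @param channel character scalar describing the channel role.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), channel = "intensity") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (um/voxel)")
  structure(list(data = data, spacing = spacing, channel = channel),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d [%d x %d x %d] channel=%s spacing=%.4g/%.4g/%.4g um\n",
              d[1], d[2], d[3], x$channel,
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

as_volume3d <- function(x, template = NULL, channel = NULL) {
  if (inherits(x, "volume3d")) return(x)
  sp <- if (is.null(template)) c(1, 1, 1) else template$spacing
  ch <- if (is.null(channel)) "intensity" else channel
  volume3d(x, spacing = sp, channel = ch)
}

#' Acquisition geometry for a projection scan
#'
#' Describes one full-revolution scan: number of projections, their angles
#' (degrees, strictly increasing in `[0, 360)`), detector size, detector
#' pixel pitch, incident intensity for the transmission channel, and an
#' optional fan-beam model (`fan_geometry`).
#'
#' @param n_projections number of viewing angles.
#' @param detector_x,detector_y detector samples (lateral, along rotation
#'   axis).
#' @param pixel_um detector pixel pitch in um (equals the reconstruction
#'   voxel size).
#' @param angles viewing angles in degrees; default uniform bin centers
#'   starting at 0 on the half-open interval `[0, 360)`.
#' @param i0 incident intensity for the transmission channel.
#' @param fan optional [fan_geometry()].
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(n_projections, detector_x, detector_y,
                                 pixel_um = 1,
                                 angles = seq(0, 360, length.out = n_projections + 1)[-(n_projections + 1)],
                                 i0 = 1, fan = NULL) {
  n_projections <- as.integer(n_projections)
  if (n_projections < 1L) stop("n_projections must be >= 1")
  if (length(angles) != n_projections)
    stop("length(angles) must equal n_projections")
  if (any(diff(angles) <= 0) || angles[1] < 0 || angles[length(angles)] >= 360)
    stop("angles must be strictly increasing within [0, 360)")
  if (!is.null(fan) && !inherits(fan, "fan_geometry"))
    stop("`fan` must be a fan_geometry or NULL")
  if (i0 <= 0) stop("i0 must be positive")
  structure(list(n_projections = n_projections, angles = as.numeric(angles),
                 detector_x = as.integer(detector_x),
                 detector_y = as.integer(detector_y),
                 pixel_um = as.numeric(pixel_um), i0 = as.numeric(i0),
                 fan = fan),
            class = "acquisition_geometry")
}

#' Fan-like beam geometry
#'
#' First-order model of the f-theta scan lens: the beam launched at detector
#' column `x` propagates at an in-plane angle `beta(x) = shear_rate *
#' (x - center_x)` (degrees) relative to the optical axis. `shear_rate = 0`
#' degenerates to parallel geometry.
#'
#' @param shear_rate degrees of beam tilt per detector pixel.
#' @param center_x detector column (1-based, may be fractional) where the
#'   tilt crosses zero.
#' @return An object of class `fan_geometry`.
#' @export
fan_geometry <- function(shear_rate, center_x) {
  if (!is.finite(shear_rate) || !is.finite(center_x))
    stop("fan parameters must be finite")
  structure(list(shear_rate = as.numeric(shear_rate),
                 center_x = as.numeric(center_x)),
            class = "fan_geometry")
}

#' Sinogram container
#'
#' Projection data as a 3D array `[angle, y, x]` plus the geometry it was
#' recorded with. `channel` is one of `"transmission"` (detector intensity
#' in `(0, i0]`), `"fluorescence"` or `"line_integral"`.
#'
#' @param data numeric array `[angle, y, x]`.
#' @param geometry an [acquisition_geometry()].
#' @param channel channel role.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(data, geometry, channel) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("sinogram data must be a 3D array [angle, y, x]")
  d <- dim(data)
  if (d[1] != geometry$n_projections || d[2] != geometry$detector_y ||
      d[3] != geometry$detector_x)
    stop("sinogram dimensions do not match geometry")
  channel <- match.arg(channel, c("transmission", "fluorescence",
                                  "line_integral"))
  structure(list(data = data, geometry = geometry, channel = channel),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("sinogram [%d angles x %d rows x %d det] channel=%s%s\n",
              d[1], d[2], d[3], x$channel,
              if (is.null(x$geometry$fan)) "" else " (fan)"))
  invisible(x)
}

# Normalized RMS error, normalized by the dynamic range of the reference.
#' Normalized root-mean-square error
#'
#' `sqrt(mean((a - ref)^2)) / diff(range(ref))`, the normalization used for
#' all reconstruction-fidelity checks in this package.
#'
#' @param a,ref numeric arrays of identical shape.
#' @return Scalar NRMSE.
#' @export
nrmse <- function(a, ref) {
  r <- diff(range(ref))
  if (r == 0) stop("reference has zero dynamic range")
  sqrt(mean((as.numeric(a) - as.numeric(ref))^2)) / r
}
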