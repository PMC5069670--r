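#' Reconstruction parameters for filtered back projection
#'
#' @param filter frequency filter: `"hann"` (ramp with Hann window, the
#'   default; damps the noise amplification of the pure ramp),
#'   `"ramp"` (Ram-Lak) or `"shepp-logan"`.
#' @param output_size reconstructed image side in voxels; defaults to the
#'   detector width and may not exceed it.
#' @param circle_mask set voxels outside the inscribed circle (the region
#'   actually covered by the detector at all angles) to zero.
#' @param interpolation backprojection interpolation, `"linear"` or
#'   `"nearest"`.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(filter = c("hann", "ramp", "shepp-logan"),
                         output_size = NULL, circle_mask = TRUE,
                         interpolation = c("linear", "nearest")) {
  structure(list(filter = match.arg(filter),
                 output_size = output_size,
                 circle_mask = isTRUE(circle_mask),
                 interpolation = match.arg(interpolation)),
            class = "recon_params")
}

# Frequency-domain ramp-family filter of projections.
# proj: [n_angles, det_x]; returns same shape. Projections are zero-padded
# to at least twice the detector width (next power of two) to suppress the
# circular-convolution artifact of the DFT.
.filter_projections <- function(proj, filter) {
  det_x <- ncol(proj)
  p <- 2^ceiling(log2(2 * det_x))
  padded <- matrix(0, nrow(proj), p)
  padded[, seq_len(det_x)] <- proj
  f <- c(seq(0, p / 2), seq(p / 2 - 1, 1)) / p   # cycles/sample, |f| <= 0.5
  filt <- 2 * f                                   # ramp, |omega| response
  if (filter == "hann") {
    w <- 0.5 * (1 + cos(pi * f / 0.5))
    filt <- filt * w
  } else if (filter == "shepp-logan") {
    nz <- f > 0
    filt[nz] <- filt[nz] * sin(pi * f[nz]) / (pi * f[nz])
  }
  ft <- t(mvfft(t(padded)))
  ft <- sweep(ft, 2, filt, "*")
  re <- Re(t(mvfft(t(ft), inverse = TRUE))) / p
  re[, seq_len(det_x), drop = FALSE]
}

#' Reconstruct one slice by filtered back projection
#'
#' Standard parallel-beam FBP: each projection is filtered in the frequency
#' domain with a ramp-family filter, then smeared back across the image
#' along its acquisition direction, and the sum is scaled by
#' `pi / (2 * n_angles)`. With that constant a sinogram of line integrals in
#' pixel-length units reconstructs densities in the same per-pixel units
#' (a unit-density disk comes back at unit value).
#'
#' @param sino_2d matrix `[angle, x]` of line integrals.
#' @param angles_deg viewing angles in degrees, uniformly spaced.
#' @param params a [recon_params()].
#' @return Reconstructed 2D image `[x, z]` of side `output_size`.
#' @export
fbp_slice <- function(sino_2d, angles_deg, params = recon_params()) {
  stopifnot(is.matrix(sino_2d))
  if (length(angles_deg) != nrow(sino_2d))
    stop("length(angles_deg) must match nrow(sino_2d)")
  det_x <- ncol(sino_2d)
  out_size <- if (is.null(params$output_size)) det_x else params$output_size
  if (out_size > det_x) stop("output_size may not exceed detector_x")
  filt <- .filter_projections(sino_2d, params$filter)
  if (params$interpolation == "nearest") {
    img <- cpp_backproject_nearest(filt, angles_deg * pi / 180, out_size,
                                   params$circle_mask)
  } else {
    img <- cpp_backproject(filt, angles_deg * pi / 180, out_size,
                           params$circle_mask)
  }
  img * pi / (2 * nrow(sino_2d))
}

#' Reconstruct a volume by slice-wise filtered back projection
#'
#' Applies [fbp_slice()] independently to every y-row of the sinogram. The
#' transmission channel must be converted with
#' [transmission_to_line_integral()] first; passing it directly is an
#' error. If the angular sampling rule is violated a warning (not an error)
#' is emitted. In-plane voxel spacing equals the detector pixel pitch.
#' Reconstructed values are divided by the pixel pitch so that absorption
#' sinograms come back as coefficients per um and fluorescence sinograms as
#' densities.
#'
#' @param s a [sinogram()] with channel `line_integral` or `fluorescence`.
#' @param params a [recon_params()].
#' @return A [volume3d()] of dim `c(out, ny, out)`.
#' @export
fbp_volume <- function(s, params = recon_params()) {
  stopifnot(inherits(s, "sinogram"))
  if (s$channel == "transmission")
    stop("transmission channel: convert with transmission_to_line_integral() first")
  chk <- check_angular_sampling(s)
  if (!chk$adequate)
    warning(sprintf("angular undersampling: %d projections < %d lateral samples",
                    chk$actual, chk$required))
  d <- dim(s$data)
  out_size <- if (is.null(params$output_size)) d[3] else params$output_size
  vol <- array(0, c(out_size, d[2], out_size))
  for (y in seq_len(d[2])) {
    vol[, y, ] <- fbp_slice(s$data[, y, , drop = TRUE], s$geometry$angles,
                            params)
  }
  vol <- vol / s$geometry$pixel_um
  volume3d(vol, rep(s$geometry$pixel_um, 3), "reconstruction")
}
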