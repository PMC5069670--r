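#' Shear model of the fan-like beam in sinogram space
#'
#' In the sinogram representation the fan-like beam shears the sinusoid
#' trace of every object along the angle axis by
#' `beta(x) = shear_rate * (x - center_x)` degrees at detector column x.
#' This linear-in-x model is the first-order f-theta approximation; its
#' parameters come from calibration/ground truth, not estimation.
#'
#' @param shear_rate degrees per detector pixel.
#' @param center_x detector column (1-based) of zero tilt.
#' @return An object of class `shear_model`.
#' @export
shear_model <- function(shear_rate, center_x) {
  if (!is.finite(shear_rate) || !is.finite(center_x))
    stop("shear parameters must be finite")
  structure(list(shear_rate = as.numeric(shear_rate),
                 center_x = as.numeric(center_x)),
            class = "shear_model")
}

#' Convert transmission intensities to absorption line integrals
#'
#' Applies `-log(I / i0)` pixelwise, turning Beer-Lambert detector readings
#' into the line integrals of the absorption coefficient that filtered back
#' projection requires.
#'
#' @param s a transmission-channel [sinogram()].
#' @param i0 incident intensity; defaults to the geometry's `i0`.
#' @return A [sinogram()] with channel `line_integral`.
#' @export
transmission_to_line_integral <- function(s, i0 = s$geometry$i0) {
  stopifnot(inherits(s, "sinogram"))
  if (s$channel != "transmission")
    stop("input sinogram is not a transmission channel")
  bad <- sum(s$data <= 0)
  if (bad > 0)
    stop(sprintf("%d nonpositive intensities; cannot take the log", bad))
  sinogram(-log(s$data / i0), s$geometry, "line_integral")
}

#' Remove fan-beam shearing along the angle axis
#'
#' Shifts each detector column x of every y-row sinogram along the angle
#' axis by `-shear_rate * (x - center_x)` degrees, circularly (full
#' 360-degree scans are periodic in phi), with linear interpolation between
#' angle samples. This restores the sinus-like traces of a parallel-beam
#' scan, after which standard FBP applies. It is the exact inverse of the
#' column-wise angular offset introduced by [fan_project()].
#'
#' @param s a [sinogram()] with at least 2 uniformly spaced angles.
#' @param model a [shear_model()].
#' @return A de-sheared [sinogram()] whose geometry carries no fan.
#' @export
deshear <- function(s, model) {
  stopifnot(inherits(s, "sinogram"), inherits(model, "shear_model"))
  n_ang <- dim(s$data)[1]
  if (n_ang < 2) stop("deshear needs at least 2 angles")
  dphi <- diff(s$geometry$angles)
  if (max(abs(dphi - dphi[1])) > 1e-9)
    stop("deshear supports uniform angular spacing only")
  if (model$shear_rate == 0) {
    out <- s
    out$geometry$fan <- NULL
    return(out)
  }
  dphi <- dphi[1]
  det_x <- dim(s$data)[3]
  # column x was acquired at effective angle phi + beta(x); resample it at
  # phi - (-beta) so index phi holds the parallel projection at phi
  beta <- model$shear_rate * (seq_len(det_x) - model$center_x)
  shift_idx <- beta / dphi                      # angle samples
  out <- s$data
  for (j in seq_len(det_x)) {
    idx <- (seq_len(n_ang) - 1 - shift_idx[j]) %% n_ang
    i0 <- floor(idx)
    f <- idx - i0
    i1 <- (i0 + 1) %% n_ang
    out[, , j] <- (1 - f) * s$data[i0 + 1, , j] + f * s$data[i1 + 1, , j]
  }
  g <- s$geometry
  g$fan <- NULL
  sinogram(out, g, s$channel)
}

#' Check the angular sampling rule
#'
#' Full angular coverage for FBP requires the number of projections to be
#' at least the number of lateral sampling points (the classical CT
#' sampling-theorem rule).
#'
#' @param s a [sinogram()].
#' @return List with `adequate` (flag), `required` and `actual` counts.
#' @export
check_angular_sampling <- function(s) {
  stopifnot(inherits(s, "sinogram"))
  required <- s$geometry$detector_x
  actual <- s$geometry$n_projections
  list(adequate = actual >= required, required = required, actual = actual)
}
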