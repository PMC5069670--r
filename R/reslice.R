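#' Three landmark points in a volume
#'
#' Continuous voxel-center coordinates (1-based, R convention) of three
#' non-collinear points picked on corresponding structures of a reslice and
#' an external comparison image. File-based landmark CSVs use the 0-based
#' convention and are converted on read (see [read_landmarks()]).
#'
#' @param p1,p2,p3 numeric xyz positions.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(p1, p2, p3) {
  pts <- rbind(as.numeric(p1), as.numeric(p2), as.numeric(p3))
  if (ncol(pts) != 3) stop("landmarks must be xyz positions")
  cr <- .cross3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])
  if (sqrt(sum(cr^2)) <= 1e-9 * max(1, max(abs(pts))))
    stop(sprintf("collinear landmarks: (%s), (%s), (%s)",
                 toString(pts[1, ]), toString(pts[2, ]), toString(pts[3, ])))
  structure(list(p1 = pts[1, ], p2 = pts[2, ], p3 = pts[3, ]),
            class = "landmarks")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Plane through three landmarks
#'
#' Normal form of the reslice plane: the normal is the normalized cross
#' product of the two edge vectors `(p2 - p1) x (p3 - p1)` and the support
#' point is `p1`. The normal's sign is canonicalized to a non-negative
#' z-component (ties: non-negative y, then x).
#'
#' @param l a [landmarks()].
#' @return List of class `plane_spec` with unit `normal` and `point`.
#' @export
plane_from_landmarks <- function(l) {
  stopifnot(inherits(l, "landmarks"))
  n <- .cross3(l$p2 - l$p1, l$p3 - l$p1)
  n <- n / sqrt(sum(n^2))
  if (n[3] < 0 || (n[3] == 0 && (n[2] < 0 || (n[2] == 0 && n[1] < 0))))
    n <- -n
  structure(list(point = l$p1, normal = n), class = "plane_spec")
}

#' Rotation matrices about the coordinate axes
#'
#' Right-handed rotation matrices about the x and y axes.
#'
#' @param a angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_x <- function(a) {
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotation_x
#' @export
rotation_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' Alignment angles mapping a plane normal onto the stack axis
#'
#' Computes the rotation pair `(alpha_x, alpha_y)` such that
#' `R_x(alpha_x) %*% R_y(alpha_y) %*% normal == c(0, 0, 1)`: rotating the
#' volume by these angles makes reslices parallel to the landmark plane.
#' For a canonical unit normal `(n1, n2, n3)` (with `n3 >= 0`) the solution
#' is `alpha_x = asin(n2)` and `alpha_y = atan2(-n1, n3)`, which satisfies
#' the printed relation `|sin(alpha_y)| == |n1 / cos(alpha_x)|`. A normal
#' lying along the y axis leaves `alpha_y` undefined (gimbal degeneracy) and
#' is an error.
#'
#' @param plane a `plane_spec` (see [plane_from_landmarks()]), or any list
#'   with a unit `normal`.
#' @return List of class `alignment_angles` with `alpha_x`, `alpha_y`
#'   (radians).
#' @export
alignment_angles <- function(plane) {
  n <- plane$normal
  if (abs(sqrt(sum(n^2)) - 1) > 1e-12) stop("plane normal must be unit length")
  if (n[3] < 0) n <- -n
  cos_ax <- sqrt(n[1]^2 + n[3]^2)
  if (cos_ax < 1e-12)
    stop("gimbal degeneracy: normal along the y axis; alpha_y undefined")
  alpha_x <- asin(max(-1, min(1, n[2])))
  alpha_y <- atan2(-n[1], n[3])
  structure(list(alpha_x = alpha_x, alpha_y = alpha_y),
            class = "alignment_angles")
}

#' Rotate a volume by alignment angles
#'
#' Resamples the volume under `R_x(alpha_x) %*% R_y(alpha_y)` about the
#' volume center. The output bounding box is grown to contain the rotated
#' input footprint; voxels that map outside the input are zero. Trilinear
#' interpolation by default; nearest-neighbour for label volumes (labels
#' must never be averaged).
#'
#' @param v a [volume3d()].
#' @param a an [alignment_angles()].
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param inverse apply the inverse rotation `R^-1 = R_y(-alpha_y) %*%
#'   R_x(-alpha_x)` instead (undoes a previous [rotate_volume()] up to
#'   interpolation error).
#' @return The rotated [volume3d()].
#' @export
rotate_volume <- function(v, a, interpolation = c("trilinear", "nearest"),
                          inverse = FALSE) {
  stopifnot(inherits(v, "volume3d"), inherits(a, "alignment_angles"))
  interpolation <- match.arg(interpolation)
  R <- rotation_x(a$alpha_x) %*% rotation_y(a$alpha_y)
  if (inverse) R <- t(R)
  d <- dim(v$data)
  if (a$alpha_x == 0 && a$alpha_y == 0) return(v)
  # output box: extents of the rotated input corners
  corners <- as.matrix(expand.grid(x = c(0, d[1] - 1), y = c(0, d[2] - 1),
                                   z = c(0, d[3] - 1)))
  c_in <- (d - 1) / 2
  rot <- t(R %*% t(sweep(corners, 2, c_in)))
  out_dim <- as.integer(ceiling(apply(rot, 2, max) - apply(rot, 2, min) + 1))
  c_out <- (out_dim - 1) / 2
  # resampler maps output -> input, so pass the inverse rotation
  dat <- cpp_resample3d(v$data, d, t(R), c_in, c_out, out_dim,
                        if (interpolation == "nearest") 1L else 0L)
  volume3d(dat, v$spacing, v$channel)
}

#' Extract an axis-perpendicular reslice
#'
#' Returns the xy-plane at depth `z_index` (1-based). A fractional index
#' interpolates linearly between the two bracketing slabs.
#'
#' @param v a [volume3d()].
#' @param z_index slice index, possibly fractional, in `[1, nz]`.
#' @return Matrix `[x, y]`.
#' @export
extract_reslice <- function(v, z_index) {
  stopifnot(inherits(v, "volume3d"))
  nz <- dim(v$data)[3]
  if (z_index < 1 || z_index > nz)
    stop(sprintf("z_index %.3f out of range [1, %d]", z_index, nz))
  k <- floor(z_index)
  f <- z_index - k
  if (f == 0) return(v$data[, , k])
  (1 - f) * v$data[, , k] + f * v$data[, , k + 1]
}

#' Polyline path for a curved reslice
#'
#' An ordered polyline in the xy-plane of an aligned stack; the curved
#' reslice sweeps this path across the through-plane (z) axis, emulating a
#' virtual section that retraces the cutting line of a physical section.
#'
#' @param vertices numeric matrix with columns x, y (1-based voxel-center
#'   coordinates), at least two rows, consecutive vertices distinct.
#' @return An object of class `polyline_path`.
#' @export
polyline_path <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 2)
    stop("polyline needs >= 2 xy vertices")
  seg <- diff(vertices)
  if (any(rowSums(seg^2) == 0)) stop("consecutive vertices must be distinct")
  structure(list(vertices = vertices), class = "polyline_path")
}

#' Curved reslice along a polyline
#'
#' Resamples the volume along the arc-length parameterization of the path
#' (unit-voxel steps on the half-open interval `[0, L)`) crossed with the
#' full z extent. Output is `[ceil(L), nz]`: each column of the path sweep
#' is one depth. Trilinear sampling throughout.
#'
#' @param v a [volume3d()].
#' @param path a [polyline_path()].
#' @return Matrix `[arc position, z]`.
#' @export
curved_reslice <- function(v, path) {
  stopifnot(inherits(v, "volume3d"), inherits(path, "polyline_path"))
  d <- dim(v$data)
  vert <- path$vertices
  for (i in seq_len(nrow(vert))) {
    if (vert[i, 1] < 1 || vert[i, 1] > d[1] || vert[i, 2] < 1 ||
        vert[i, 2] > d[2])
      stop(sprintf("path vertex %d (%.2f, %.2f) outside the volume", i,
                   vert[i, 1], vert[i, 2]))
  }
  seg <- diff(vert)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  n_s <- ceiling(total)
  arc <- (seq_len(n_s) - 1)                     # samples at 0, 1, ..., < L
  cum <- c(0, cumsum(seg_len))
  si <- findInterval(arc, cum, rightmost.closed = TRUE)
  si <- pmin(si, nrow(seg))
  t <- (arc - cum[si]) / seg_len[si]
  px <- vert[si, 1] + t * seg[si, 1]
  py <- vert[si, 2] + t * seg[si, 2]
  pts <- cbind(rep(px, d[3]), rep(py, d[3]),
               rep(seq_len(d[3]), each = n_s))
  vals <- cpp_sample3d(v$data, d, pts - 1, 0L)  # kernel is 0-based
  matrix(vals, n_s, d[3])
}
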