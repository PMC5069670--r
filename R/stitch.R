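#' Iteratively estimate the two inter-tile translation vectors
#'
#' Refines the column step `u` and row step `v` of a tile grid from the
#' image content. Each iteration predicts the overlap strip of every
#' column-adjacent (for `u`) and row-adjacent (for `v`) tile pair from the
#' current basis, finds the residual displacement that maximizes the
#' normalized cross-correlation of the strips (integer search plus
#' quadratic subpixel peak fit), and applies the median residual across
#' pairs (robust to occasional low-contrast tiles). Stops when the largest
#' update falls below `tol_px` or after `max_iter` iterations.
#'
#' @param ts a `tile_set` (see [make_tile_fixture()] or [read_tile_index()]).
#' @param init initial [translation_basis()], within half a tile of truth.
#' @param max_iter maximum refinement iterations.
#' @param tol_px convergence tolerance in pixels.
#' @param search_px half-width of the integer residual search.
#' @param min_corr minimum acceptable correlation peak; if every pair falls
#'   below it the estimation aborts (low-signal error).
#' @return A [translation_basis()] with attribute `convergence` (iterations,
#'   final update, per-iteration max residual).
#' @export
estimate_basis <- function(ts, init, max_iter = 10, tol_px = 0.05,
                           search_px = 10, min_corr = 0.3) {
  stopifnot(inherits(ts, "tile_set"), inherits(init, "translation_basis"))
  rows <- max(ts$grid$row); cols <- max(ts$grid$col)
  if (rows < 2 || cols < 2)
    stop("basis estimation needs at least 2 rows and 2 columns of tiles")
  u <- init$u; v <- init$v
  updates <- numeric(0)
  for (it in seq_len(max_iter)) {
    du <- .pair_residuals(ts, u, "col", search_px, min_corr)
    dv <- .pair_residuals(ts, v, "row", search_px, min_corr)
    if (all(is.na(du[, 1])) && all(is.na(dv[, 1])))
      stop("correlation peak below threshold on all tile pairs (low signal)")
    step_u <- apply(du, 2, median, na.rm = TRUE)
    step_v <- apply(dv, 2, median, na.rm = TRUE)
    step_u[is.na(step_u)] <- 0; step_v[is.na(step_v)] <- 0
    u <- u + step_u; v <- v + step_v
    upd <- max(abs(c(step_u, step_v)))
    updates <- c(updates, upd)
    if (upd < tol_px) break
  }
  out <- translation_basis(u, v)
  attr(out, "convergence") <- list(iterations = length(updates),
                                   final_update = updates[length(updates)],
                                   history = updates)
  out
}

# Residual displacements (dx, dy) for all adjacent pairs along one grid
# direction, NA rows where the correlation peak is too weak.
.pair_residuals <- function(ts, step, direction, search_px, min_corr) {
  g <- ts$grid
  res <- matrix(NA_real_, 0, 2)
  for (i in seq_len(nrow(g))) {
    r <- g$row[i]; c <- g$col[i]
    j <- if (direction == "col") which(g$row == r & g$col == c + 1)
         else which(g$row == r + 1 & g$col == c)
    if (length(j) != 1) next
    d <- .strip_offset(ts$tiles[[i]], ts$tiles[[j]], step, search_px, min_corr)
    res <- rbind(res, d)
  }
  res
}

# Residual between the current basis step (x, y) and the offset of tile B
# relative to tile A that best aligns their overlap strips: integer NCC
# search in a (2w+1)^2 window around the predicted offset, with the overlap
# region clipped per candidate shift, then a quadratic subpixel peak fit.
.strip_offset <- function(A, B, step, w, min_corr) {
  tp <- nrow(A)
  sx <- round(step[1]); sy <- round(step[2])
  cc <- matrix(NA_real_, 2 * w + 1, 2 * w + 1)
  for (dy in -w:w) {
    dyc <- sy + dy
    ay0 <- max(1, 1 + dyc); ay1 <- min(tp, tp + dyc)
    if (ay1 - ay0 < 2) next
    for (dx in -w:w) {
      dxc <- sx + dx
      ax0 <- max(1, 1 + dxc); ax1 <- min(tp, tp + dxc)
      if (ax1 - ax0 < 2) next
      a <- A[ay0:ay1, ax0:ax1]
      b <- B[(ay0:ay1) - dyc, (ax0:ax1) - dxc]
      cc[dy + w + 1, dx + w + 1] <- .ncc(a, b)
    }
  }
  if (all(is.na(cc)) || max(cc, na.rm = TRUE) < min_corr)
    return(c(NA_real_, NA_real_))
  pk <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  dy <- pk[1] - w - 1; dx <- pk[2] - w - 1
  fx <- 0; fy <- 0
  if (cc[pk[1], pk[2]] < 1 - 1e-12) {   # perfect peak needs no subpixel fit
    sub <- function(y0, y1, y2) {
      if (is.na(y0) || is.na(y2)) return(0)
      den <- y0 - 2 * y1 + y2
      if (den >= 0) return(0)
      max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
    }
    if (pk[2] > 1 && pk[2] < ncol(cc))
      fx <- sub(cc[pk[1], pk[2] - 1], cc[pk[1], pk[2]], cc[pk[1], pk[2] + 1])
    if (pk[1] > 1 && pk[1] < nrow(cc))
      fy <- sub(cc[pk[1] - 1, pk[2]], cc[pk[1], pk[2]], cc[pk[1] + 1, pk[2]])
  }
  # absolute refined offset minus the current step = residual update
  c(sx + dx + fx - step[1], sy + dy + fy - step[2])
}

.ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Linear pre-weighting blend mask
#'
#' Per-tile weight image: 1 in the interior, ramping linearly to zero
#' across each overlap margin; the 2D mask is the separable product of the
#' per-axis ramps. With matching margins on abutting tiles the ramps are
#' complementary, so blended tiles merge seamlessly and the summed weights
#' partition unity across the overlap.
#'
#' @param tile_shape `c(rows, cols)` of the tile in pixels.
#' @param margin_px margins in pixels: a scalar, or length 4
#'   `c(left, right, top, bottom)`. Must be below half the tile extent.
#' @return Matrix of weights in `[0, 1]`.
#' @export
blend_mask <- function(tile_shape, margin_px) {
  tile_shape <- as.integer(tile_shape)
  if (length(tile_shape) == 1) tile_shape <- rep(tile_shape, 2L)
  m <- as.integer(margin_px)
  if (length(m) == 1) m <- rep(m, 4L)
  if (length(m) != 4 || any(m < 0)) stop("margin_px must be 1 or 4 counts >= 0")
  if (m[1] + m[2] >= tile_shape[2] || m[3] + m[4] >= tile_shape[1])
    stop("margins must be below half the tile extent")
  ramp <- function(n, lo, hi) {
    w <- rep(1, n)
    if (lo > 0) w[seq_len(lo)] <- (seq_len(lo) - 0.5) / lo
    if (hi > 0) w[n + 1 - seq_len(hi)] <- pmin(w[n + 1 - seq_len(hi)],
                                               (seq_len(hi) - 0.5) / hi)
    w
  }
  wx <- ramp(tile_shape[2], m[1], m[2])
  wy <- ramp(tile_shape[1], m[3], m[4])
  outer(wy, wx)
}

#' Assemble a mosaic from tiles
#'
#' Places tile `(r, c)` at the continuous position `(r-1)*v + (c-1)*u`,
#' splatting bilinearly for subpixel positions, accumulating
#' `tile * blend_mask` and the mask itself, and normalizing by the summed
#' weights wherever they are positive (zero elsewhere). The canvas is sized
#' automatically to the placed extent.
#'
#' @param ts a `tile_set`.
#' @param basis a [translation_basis()].
#' @param margin_px blend margins passed to [blend_mask()]; defaults to the
#'   tile set's nominal overlap.
#' @return Matrix `[y, x]`, the blended mosaic.
#' @export
assemble_mosaic <- function(ts, basis, margin_px = ts$overlap_px) {
  stopifnot(inherits(ts, "tile_set"), inherits(basis, "translation_basis"))
  if (any(!is.finite(c(basis$u, basis$v)))) stop("non-finite basis")
  tp <- ts$tile_px
  g <- ts$grid
  pos <- cbind(x = (g$col - 1) * basis$u[1] + (g$row - 1) * basis$v[1],
               y = (g$col - 1) * basis$u[2] + (g$row - 1) * basis$v[2])
  pos <- sweep(pos, 2, apply(pos, 2, min))      # anchor min corner at 0
  W <- ceiling(max(pos[, "x"])) + tp + 1
  H <- ceiling(max(pos[, "y"])) + tp + 1
  acc <- matrix(0, H, W)
  wgt <- matrix(0, H, W)
  mask <- blend_mask(c(tp, tp), margin_px)
  for (i in seq_len(nrow(g))) {
    x0 <- pos[i, "x"]; y0 <- pos[i, "y"]
    bx <- floor(x0); by <- floor(y0)
    fx <- x0 - bx; fy <- y0 - by
    tw <- ts$tiles[[i]] * mask
    for (oy in 0:1) {
      for (ox in 0:1) {
        wsp <- (if (ox) fx else 1 - fx) * (if (oy) fy else 1 - fy)
        if (wsp == 0) next
        ys <- by + oy + seq_len(tp); xs <- bx + ox + seq_len(tp)
        acc[ys, xs] <- acc[ys, xs] + wsp * tw
        wgt[ys, xs] <- wgt[ys, xs] + wsp * mask
      }
    }
  }
  out <- matrix(0, H, W)
  nz <- wgt > 0
  out[nz] <- acc[nz] / wgt[nz]
  out
}

#' Stack 2D mosaics into a volume with scaled z-spacing
#'
#' The z-spacing is the nominal focus-drive step times the refractive-index
#' calibration factor; the recorded total depth follows the slice-thickness
#' convention `n_slices * scaled_step` (each slice represents one full
#' step of sample).
#'
#' @param slices list of equally shaped mosaic matrices, ordered by z.
#' @param nominal_z_step_um mechanical z step in um.
#' @param z_scale_factor measured/nominal step ratio.
#' @param pixel_um lateral pixel pitch in um.
#' @return A [volume3d()] with attribute `z_extent_um`.
#' @export
stack_mosaics <- function(slices, nominal_z_step_um, z_scale_factor = 1,
                          pixel_um = 1) {
  if (!length(slices)) stop("no slices")
  d1 <- dim(slices[[1]])
  for (i in seq_along(slices)) {
    if (!all(dim(slices[[i]]) == d1))
      stop(sprintf("slice %d has shape %s, expected %s", i,
                   toString(dim(slices[[i]])), toString(d1)))
  }
  step <- axial_step_scale(nominal_z_step_um, z_scale_factor)
  # mosaics are [y, x]; volume axes are [x, y, z]
  vol <- array(0, c(d1[2], d1[1], length(slices)))
  for (i in seq_along(slices)) vol[, , i] <- t(slices[[i]])
  v <- volume3d(vol, c(pixel_um, pixel_um, step), "intensity")
  attr(v, "z_extent_um") <- length(slices) * step
  v
}
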