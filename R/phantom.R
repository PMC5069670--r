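#' Parameters of the synthetic lung-lobe phantom
#'
#' The phantom emulates a cleared, resin-embedded accessory lung lobe: an
#' ellipsoidal lobe with a thin bright pleural shell, vesicular alveolar
#' voids, a few levels of branching tubular airways and, optionally, dense
#' "fibrotic" patches of elevated absorption and fluorescence. The default
#' alveolus diameter of 60 um is three times a 20 um scanning-beam width,
#' the alveolar-scale ratio of the rat lung.
#'
#' @param shape voxel counts per axis `c(nx, ny, nz)`.
#' @param voxel_size_um isotropic voxel pitch in um.
#' @param lobe_radii_um ellipsoid semi-axes in um (x, y, z).
#' @param pleura_thickness_um thickness of the pleural shell in um.
#' @param alveolus_diameter_um diameter of the spherical alveolar voids.
#' @param airway_levels branching depth of the airway tree (1 = stem only).
#' @param fibrosis_fraction target fraction of lobe voxels inside dense
#'   patches, in `[0, 1]`.
#' @param fibrosis_contrast ratio of fibrotic to normal parenchyma
#'   absorption and fluorescence (free parameter; no quantitative contrast
#'   is established for real tissue).
#' @param seed integer RNG seed; all randomness flows from it.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(96, 96, 96), voxel_size_um = 20,
                           lobe_radii_um = c(850, 900, 780),
                           pleura_thickness_um = 40,
                           alveolus_diameter_um = 60,
                           airway_levels = 3,
                           fibrosis_fraction = 0,
                           fibrosis_contrast = 2.5,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stop("shape must be 3 counts >= 8")
  if (voxel_size_um <= 0) stop("voxel_size_um must be positive")
  if (fibrosis_fraction < 0 || fibrosis_fraction > 1)
    stop("fibrosis_fraction must be in [0, 1]")
  if (alveolus_diameter_um <= voxel_size_um)
    stop("alveolus_diameter_um must exceed the voxel size")
  if (fibrosis_contrast <= 1) stop("fibrosis_contrast must exceed 1")
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 lobe_radii_um = as.numeric(lobe_radii_um),
                 pleura_thickness_um = pleura_thickness_um,
                 alveolus_diameter_um = alveolus_diameter_um,
                 airway_levels = as.integer(airway_levels),
                 fibrosis_fraction = fibrosis_fraction,
                 fibrosis_contrast = fibrosis_contrast,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Tissue optical properties (absorption mu in 1/um, fluorophore density in
# arbitrary units). Background is the clear embedding resin.
.phantom_mu <- c(background = 5e-5, parenchyma = 6e-4, airway = 1e-4,
                 pleura = 9e-4, void = 1e-4)
.phantom_fluor <- c(background = 0, parenchyma = 1.0, airway = 0.02,
                    pleura = 1.3, void = 0.05)

# Squared-ellipsoid field (x/a)^2+(y/b)^2+(z/c)^2 on the voxel grid (um
# coordinates about the volume center).
.ellipsoid_field <- function(shape, voxel, radii) {
  ax <- ((seq_len(shape[1]) - (shape[1] + 1) / 2) * voxel / radii[1])^2
  ay <- ((seq_len(shape[2]) - (shape[2] + 1) / 2) * voxel / radii[2])^2
  az <- ((seq_len(shape[3]) - (shape[3] + 1) / 2) * voxel / radii[3])^2
  outer(outer(ax, ay, "+"), az, "+")
}

# Greedy Poisson-disc sampling: candidates in random order, accepted if at
# least min_dist from every prior acceptance.
.poisson_disc <- function(candidates, min_dist) {
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  acc <- matrix(0, n, 3)
  k <- 0L
  d2 <- min_dist^2
  for (i in seq_len(n)) {
    p <- candidates[i, ]
    if (k == 0L ||
        min((acc[seq_len(k), 1] - p[1])^2 + (acc[seq_len(k), 2] - p[2])^2 +
              (acc[seq_len(k), 3] - p[3])^2) >= d2) {
      k <- k + 1L
      acc[k, ] <- p
    }
  }
  acc[seq_len(k), , drop = FALSE]
}

# Carve/flag all voxels within radius of a point (um coords); returns linear
# indices into the volume.
.sphere_indices <- function(shape, voxel, center_um, radius_um) {
  ctr <- center_um / voxel + (shape + 1) / 2   # 1-based voxel coords
  r <- radius_um / voxel
  rng <- function(c, n) max(1L, floor(c - r)):min(n, ceiling(c + r))
  xs <- rng(ctr[1], shape[1]); ys <- rng(ctr[2], shape[2]); zs <- rng(ctr[3], shape[3])
  if (!length(xs) || !length(ys) || !length(zs)) return(integer(0))
  g <- expand.grid(x = xs, y = ys, z = zs)
  keep <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2
  g <- g[keep, , drop = FALSE]
  g$x + shape[1] * (g$y - 1 + shape[2] * (g$z - 1))
}

# Tapering-capsule rasterizer: voxels within the linearly interpolated
# radius of segment p0->p1 (um coords). Returns linear indices.
.capsule_indices <- function(shape, voxel, p0, p1, r0, r1) {
  a0 <- p0 / voxel + (shape + 1) / 2
  a1 <- p1 / voxel + (shape + 1) / 2
  rmax <- max(r0, r1) / voxel
  lo <- pmax(1, floor(pmin(a0, a1) - rmax))
  hi <- pmin(shape, ceiling(pmax(a0, a1) + rmax))
  if (any(lo > hi)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  d <- a1 - a0
  len2 <- sum(d^2)
  t <- ((g$x - a0[1]) * d[1] + (g$y - a0[2]) * d[2] + (g$z - a0[3]) * d[3]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a0[1] + t * d[1]; py <- a0[2] + t * d[2]; pz <- a0[3] + t * d[3]
  r <- (r0 + t * (r1 - r0)) / voxel
  keep <- (g$x - px)^2 + (g$y - py)^2 + (g$z - pz)^2 <= r^2
  g <- g[keep, , drop = FALSE]
  g$x + shape[1] * (g$y - 1 + shape[2] * (g$z - 1))
}

# Recursive airway tree: tapering cylinders from a single stem entering at
# the top of the lobe along -y. Jittered branching directions come from the
# active RNG stream.
.airway_segments <- function(params) {
  radii <- params$lobe_radii_um
  segs <- list()
  grow <- function(p0, dir, len, rad, level) {
    p1 <- p0 + dir * len
    segs[[length(segs) + 1]] <<- list(p0 = p0, p1 = p1,
                                      r0 = rad, r1 = rad * 0.75)
    if (level >= params$airway_levels) return(invisible())
    # two children, splayed about the parent direction
    for (sgn in c(-1, 1)) {
      ang <- (35 + runif(1, -8, 8)) * pi / 180 * sgn
      # rotate parent direction in the plane spanned by dir and a lateral axis
      lat <- if (level %% 2 == 1) c(1, 0, 0) else c(0, 0, 1)
      lat <- lat - sum(lat * dir) * dir
      lat <- lat / sqrt(sum(lat^2))
      child_dir <- cos(ang) * dir + sin(ang) * lat
      grow(p1, child_dir / sqrt(sum(child_dir^2)), len * 0.65,
           rad * 0.75, level + 1)
    }
  }
  stem_top <- c(0, radii[2] * 0.92, 0)
  grow(stem_top, c(0, -1, 0), radii[2] * 0.55, 110, 1)
  segs
}

#' Generate a synthetic lung-lobe phantom
#'
#' Builds a deterministic two-channel phantom (absorption coefficient in
#' 1/um and fluorophore density in arbitrary units) together with a
#' ground-truth label volume with classes 0 background, 1 parenchyma,
#' 2 airway, 3 pleura, 4 fibrosis. Alveoli are spherical voids placed by
#' Poisson-disc sampling inside the parenchyma (labelled parenchyma, but
#' with void optical properties); airways are tapering cylinders grown from
#' a single stem; fibrotic patches are sums of anisotropic Gaussian blobs
#' thresholded at half maximum, with blob widths rescaled iteratively (at
#' most 20 iterations, tolerance 0.03) so the patch volume hits
#' `fibrosis_fraction` of the lobe.
#'
#' @param params a [phantom_params()].
#' @return List of class `phantom_pair` with `volume3d` elements
#'   `absorption`, `fluorescence` and `truth_labels`, plus the `params`.
#' @export
make_lobe_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  withr::with_seed(params$seed, .make_lobe_phantom_impl(params))
}

.make_lobe_phantom_impl <- function(params) {
  shape <- params$shape; voxel <- params$voxel_size_um
  radii <- params$lobe_radii_um
  E <- .ellipsoid_field(shape, voxel, radii)
  E_in <- .ellipsoid_field(shape, voxel, radii - params$pleura_thickness_um)
  lobe <- E <= 1
  interior <- E_in <= 1
  pleura <- lobe & !interior

  labels <- array(0L, shape)
  labels[interior] <- 1L
  labels[pleura] <- 3L

  # airway tree
  airway_idx <- integer(0)
  if (params$airway_levels >= 1) {
    for (seg in .airway_segments(params)) {
      airway_idx <- c(airway_idx,
                      .capsule_indices(shape, voxel, seg$p0, seg$p1,
                                       seg$r0, seg$r1))
    }
    airway_idx <- unique(airway_idx)
    airway_idx <- airway_idx[labels[airway_idx] == 1L]
    labels[airway_idx] <- 2L
  }

  # alveolar voids (Poisson disc, min spacing 1.2 x diameter)
  d_alv <- params$alveolus_diameter_um
  lobe_vol_um3 <- 4 / 3 * pi * prod(radii)
  n_cand <- min(20000L, as.integer(4 * lobe_vol_um3 / (1.2 * d_alv)^3))
  cand <- cbind(runif(n_cand, -radii[1], radii[1]),
                runif(n_cand, -radii[2], radii[2]),
                runif(n_cand, -radii[3], radii[3]))
  margin <- (radii - params$pleura_thickness_um - d_alv) / radii
  inside <- rowSums((cand / rep(radii, each = n_cand))^2 /
                      rep(margin^2, each = n_cand)) <= 1
  cand <- cand[inside, , drop = FALSE]
  centers <- .poisson_disc(cand, 1.2 * d_alv)
  void <- array(FALSE, shape)
  for (i in seq_len(nrow(centers))) {
    idx <- .sphere_indices(shape, voxel, centers[i, ], d_alv / 2)
    idx <- idx[labels[idx] == 1L]
    void[idx] <- TRUE
  }

  # fibrotic patches: half-maximum threshold on summed anisotropic Gaussian
  # blobs, widths rescaled iteratively to hit the target fraction
  fib <- array(FALSE, shape)
  if (params$fibrosis_fraction > 0) {
    n_lobe <- sum(lobe)
    target <- params$fibrosis_fraction
    n_blob <- max(3L, as.integer(round(target * n_lobe / 3000)))
    ok <- E_in <= 0.55            # keep patch cores well inside the lobe
    ctr_idx <- sample(which(ok), n_blob)
    ctr <- arrayInd(ctr_idx, shape)
    sig0 <- matrix(runif(3 * n_blob, 4, 9), ncol = 3)   # voxels, anisotropic
    scale <- (target * n_lobe / (n_blob * 4 / 3 * pi *
                                   prod(colMeans(sig0) * 1.1774)))^(1 / 3)
    for (iter in seq_len(20)) {
      field <- array(0, shape)
      sig <- sig0 * scale
      for (b in seq_len(n_blob)) {
        s <- sig[b, ]
        lo <- pmax(1, floor(ctr[b, ] - 3 * s))
        hi <- pmin(shape, ceiling(ctr[b, ] + 3 * s))
        gx <- exp(-((lo[1]:hi[1]) - ctr[b, 1])^2 / (2 * s[1]^2))
        gy <- exp(-((lo[2]:hi[2]) - ctr[b, 2])^2 / (2 * s[2]^2))
        gz <- exp(-((lo[3]:hi[3]) - ctr[b, 3])^2 / (2 * s[3]^2))
        field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
          field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
          outer(outer(gx, gy), gz)
      }
      fib <- field >= max(field) / 2 & lobe
      frac <- sum(fib) / n_lobe
      if (abs(frac - target) <= 0.03) break
      scale <- scale * (target / max(frac, 1e-6))^(1 / 3)
    }
    fib <- fib & labels == 1L      # dense remodeling of parenchyma only
  }

  mu <- array(.phantom_mu[["background"]], shape)
  fl <- array(.phantom_fluor[["background"]], shape)
  mu[labels == 1L] <- .phantom_mu[["parenchyma"]]
  fl[labels == 1L] <- .phantom_fluor[["parenchyma"]]
  mu[labels == 3L] <- .phantom_mu[["pleura"]]
  fl[labels == 3L] <- .phantom_fluor[["pleura"]]
  mu[labels == 2L] <- .phantom_mu[["airway"]]
  fl[labels == 2L] <- .phantom_fluor[["airway"]]
  keep_void <- void & labels == 1L & !fib
  mu[keep_void] <- .phantom_mu[["void"]]
  fl[keep_void] <- .phantom_fluor[["void"]]
  if (any(fib)) {
    mu[fib] <- params$fibrosis_contrast * .phantom_mu[["parenchyma"]]
    fl[fib] <- params$fibrosis_contrast * .phantom_fluor[["parenchyma"]]
    labels[fib] <- 4L
  }

  sp <- rep(voxel, 3)
  structure(list(
    absorption = volume3d(mu, sp, "absorption"),
    fluorescence = volume3d(fl, sp, "fluorescence"),
    truth_labels = volume3d(labels, sp, "label"),
    params = params), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  tab <- table(factor(x$truth_labels$data, levels = 0:4,
                      labels = c("background", "parenchyma", "airway",
                                 "pleura", "fibrosis")))
  cat(sprintf("phantom_pair [%s] voxel %.3g um, seed %d\n",
              paste(dim(x$absorption$data), collapse = " x "),
              x$params$voxel_size_um, x$params$seed))
  print(tab)
  invisible(x)
}

#' Translation basis of a tile grid
#'
#' The two step vectors of a tiled mosaic: `u` is the (x, y) pixel offset
#' between column-adjacent tiles and `v` the offset between row-adjacent
#' tiles. A tilt between translation stage and optical scan axes makes them
#' non-axis-aligned and, in general, non-integer.
#'
#' @param u,v numeric (x, y) vectors in pixels.
#' @return An object of class `translation_basis`.
#' @export
translation_basis <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != 2 || length(v) != 2 || any(!is.finite(c(u, v))))
    stop("u and v must be finite (x, y) vectors")
  if (abs(u[1] * v[2] - u[2] * v[1]) < 1e-9)
    stop("u and v must not be parallel")
  structure(list(u = u, v = v), class = "translation_basis")
}

#' Cut a tiled-mosaic fixture from an image
#'
#' Crops a `rows x cols` grid of square tiles from a source image, tile
#' `(r, c)` anchored at `(r-1)*v + (c-1)*u` relative to a common origin,
#' with optional additive Gaussian noise and a radially symmetric intensity
#' falloff (vignetting). The true basis and origin are recorded as ground
#' truth so stitching can be validated against an exact inverse.
#'
#' Images are matrices indexed `[y, x]`; fractional tile positions are cut
#' with bilinear interpolation, integer positions are exact crops.
#'
#' @param image source matrix `[y, x]`.
#' @param rows,cols grid size.
#' @param basis a [translation_basis()] (ground truth steps).
#' @param overlap_px overlap between adjacent tiles in pixels; the tile side
#'   is `round(max(|u_x|, |v_y|)) + overlap_px`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param falloff relative intensity drop at the tile corner, in `[0, 1)`.
#' @param seed RNG seed for the noise.
#' @return An object of class `tile_set`.
#' @export
make_tile_fixture <- function(image, rows, cols, basis, overlap_px = 5,
                              noise_sd = 0, falloff = 0, seed = 1L) {
  stopifnot(is.matrix(image), inherits(basis, "translation_basis"))
  if (falloff < 0 || falloff >= 1) stop("falloff must be in [0, 1)")
  tile_px <- as.integer(round(max(abs(basis$u[1]), abs(basis$v[2]))) + overlap_px)
  if (tile_px > min(dim(image))) stop("image smaller than one tile")
  if (max(abs(c(basis$u, basis$v))) >= tile_px)
    stop("basis steps must be smaller than the tile extent")
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  pos <- cbind(x = (grid$col - 1) * basis$u[1] + (grid$row - 1) * basis$v[1],
               y = (grid$col - 1) * basis$u[2] + (grid$row - 1) * basis$v[2])
  origin <- c(x = -min(pos[, "x"]), y = -min(pos[, "y"]))  # anchor at (0, 0)
  pos <- sweep(pos, 2, -origin)
  if (max(pos[, "x"]) + tile_px > ncol(image) ||
      max(pos[, "y"]) + tile_px > nrow(image))
    stop("tiles do not fit inside the image")
  mask <- 1
  if (falloff > 0) {
    cc <- (tile_px - 1) / 2
    r2 <- outer(((seq_len(tile_px) - 1) - cc)^2,
                ((seq_len(tile_px) - 1) - cc)^2, "+")
    mask <- 1 - falloff * r2 / (2 * cc^2)
  }
  tiles <- withr::with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      x0 <- pos[i, "x"]; y0 <- pos[i, "y"]
      if (abs(x0 - round(x0)) < 1e-12 && abs(y0 - round(y0)) < 1e-12) {
        t <- image[round(y0) + seq_len(tile_px), round(x0) + seq_len(tile_px)]
      } else {
        xs <- x0 + seq_len(tile_px); ys <- y0 + seq_len(tile_px)
        t <- .bilinear_crop(image, ys, xs)
      }
      t <- t * mask
      if (noise_sd > 0) t <- t + matrix(rnorm(length(t), 0, noise_sd), tile_px)
      t
    })
  })
  structure(list(tiles = tiles, grid = grid, tile_px = tile_px,
                 overlap_px = as.integer(overlap_px),
                 truth = list(basis = basis, origin = origin,
                              noise_sd = noise_sd, falloff = falloff)),
            class = "tile_set")
}

# bilinear crop of a matrix at fractional 1-based row/col positions
.bilinear_crop <- function(image, ys, xs) {
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  m00 <- image[cl(y0, nrow(image)), cl(x0, ncol(image)), drop = FALSE]
  m01 <- image[cl(y0, nrow(image)), cl(x0 + 1, ncol(image)), drop = FALSE]
  m10 <- image[cl(y0 + 1, nrow(image)), cl(x0, ncol(image)), drop = FALSE]
  m11 <- image[cl(y0 + 1, nrow(image)), cl(x0 + 1, ncol(image)), drop = FALSE]
  wy <- matrix(fy, length(ys), length(xs))
  wx <- matrix(fx, length(ys), length(xs), byrow = TRUE)
  (1 - wy) * ((1 - wx) * m00 + wx * m01) + wy * ((1 - wx) * m10 + wx * m11)
}
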