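test_that("plane from landmarks: unit axes, orthogonality, degeneracy", {
  pl <- plane_from_landmarks(landmarks(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(pl$normal, c(0, 0, 1))
  expect_equal(pl$point, c(0, 0, 0))
  expect_error(landmarks(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
  set.seed(21)
  for (i in 1:25) {
    p <- matrix(rnorm(9, sd = 20), 3)
    l <- tryCatch(landmarks(p[1, ], p[2, ], p[3, ]), error = function(e) NULL)
    if (is.null(l)) next
    pl <- plane_from_landmarks(l)
    expect_lt(abs(sum(pl$normal * (l$p2 - l$p1))), 1e-9 * 20)
    expect_lt(abs(sum(pl$normal * (l$p3 - l$p1))), 1e-9 * 20)
    expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
    expect_gte(pl$normal[3], 0)
  }
})

test_that("alignment angles map the normal onto the stack axis", {
  a0 <- alignment_angles(list(normal = c(0, 0, 1)))
  expect_equal(c(a0$alpha_x, a0$alpha_y), c(0, 0))
  # worked example: normal (0.3, 0.4, sqrt(1 - 0.25))
  n <- c(0.3, 0.4, sqrt(1 - 0.09 - 0.16))
  a <- alignment_angles(list(normal = n))
  expect_equal(abs(a$alpha_x), asin(0.4), tolerance = 1e-12)
  expect_equal(abs(a$alpha_y), asin(0.3 / cos(a$alpha_x)), tolerance = 1e-12)
  res <- rotation_x(a$alpha_x) %*% rotation_y(a$alpha_y) %*% n
  expect_equal(as.numeric(res), c(0, 0, 1), tolerance = 1e-12)
  expect_error(alignment_angles(list(normal = c(0, 1, 0))), "gimbal")
})

test_that("random normals satisfy the rotation and the printed relation", {
  set.seed(22)
  m <- matrix(rnorm(3 * 2000), ncol = 3)
  m <- m / sqrt(rowSums(m^2))
  for (i in seq_len(nrow(m))) {
    n <- m[i, ]
    if (sqrt(n[1]^2 + n[3]^2) < 1e-6) next
    a <- alignment_angles(list(normal = n))
    if (n[3] < 0) n <- -n
    res <- rotation_x(a$alpha_x) %*% rotation_y(a$alpha_y) %*% n - c(0, 0, 1)
    expect_lt(sqrt(sum(res^2)), 1e-9)
    expect_lt(abs(abs(sin(a$alpha_y)) - abs(n[1] / cos(a$alpha_x))), 1e-9)
  }
})

test_that("volume rotation: identity, round trip, planted plane slab", {
  set.seed(23)
  v <- volume3d(array(rnorm(32^3), c(32, 32, 32)))
  id <- alignment_angles(list(normal = c(0, 0, 1)))
  expect_identical(rotate_volume(v, id)$data, v$data)

  # smooth volume round trip (double interpolation)
  sm <- volume3d(array(0, c(40, 40, 40)))
  xs <- 1:40
  sm$data <- array(outer(outer(sin(xs / 5), cos(xs / 7), "+"), sin(xs / 6), "+"),
                   c(40, 40, 40))
  nrm <- c(0.25, 0.2, sqrt(1 - 0.25^2 - 0.2^2))
  a <- alignment_angles(list(normal = nrm))
  fwd <- rotate_volume(sm, a)
  back <- rotate_volume(fwd, a, inverse = TRUE)
  # compare on the interior (borders lose support to zero-padding)
  c_b <- (dim(back$data) - 1) / 2; c_s <- (dim(sm$data) - 1) / 2
  core <- 13:28
  sub_back <- back$data[core + round(c_b[1] - c_s[1]),
                        core + round(c_b[2] - c_s[2]),
                        core + round(c_b[3] - c_s[3])]
  expect_lt(nrmse(sub_back, sm$data[core, core, core]), 0.02)

  # bright plane with known normal collapses to a thin z-slab
  d <- c(64, 64, 64)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(x = 1:64, y = 1:64, z = 1:64))
  dist <- abs((g[, 1] - ctr[1]) * nrm[1] + (g[, 2] - ctr[2]) * nrm[2] +
                (g[, 3] - ctr[3]) * nrm[3])
  vol <- array(0, d); vol[dist <= 0.5] <- 1
  rv <- rotate_volume(volume3d(vol), a)
  zs <- which(apply(rv$data > 0.5, 3, any))
  expect_lte(diff(range(zs)) + 1, 2)
})

test_that("flat reslices: exact slab, fractional interpolation, range check", {
  set.seed(24)
  arr <- array(rnorm(16^3), c(16, 16, 16))
  v <- volume3d(arr)
  expect_identical(extract_reslice(v, 7), arr[, , 7])
  lin <- volume3d(array(rep(1:16, each = 256), c(16, 16, 16)))
  expect_equal(extract_reslice(lin, 7.5),
               (lin$data[, , 7] + lin$data[, , 8]) / 2)
  expect_error(extract_reslice(v, 17), "out of range")
})

test_that("landmark noise still recovers the plane within 2 degrees", {
  set.seed(25)
  for (rep in 1:5) {
    nrm <- c(rnorm(2, 0, 0.3), 1); nrm <- nrm / sqrt(sum(nrm^2))
    ctr <- c(32, 32, 32)
    basis <- svd(diag(3) - nrm %o% nrm)$u[, 1:2]
    pts <- lapply(list(c(22, 0), c(-14, 18), c(-12, -19)), function(ab)
      as.numeric(ctr + basis %*% ab + rnorm(3, 0, 0.5)))
    pl <- plane_from_landmarks(landmarks(pts[[1]], pts[[2]], pts[[3]]))
    expect_lt(axis_angle_deg(pl$normal, nrm), 2)
  }
})

test_that("planted plane pattern survives the full align-and-reslice chain", {
  set.seed(26)
  d <- c(64, 64, 64); ctr <- (d + 1) / 2
  nrm <- c(0.3, 0.25, sqrt(1 - 0.3^2 - 0.25^2))
  # oblique plane carrying a smooth in-plane pattern, with a smooth (tent)
  # through-plane profile so resampling is not confounded by voxelization
  basis <- svd(diag(3) - nrm %o% nrm)$u[, 1:2]
  g <- as.matrix(expand.grid(x = 1:64, y = 1:64, z = 1:64))
  rel <- sweep(g, 2, ctr)
  dist <- abs(rel %*% nrm)
  uv <- rel %*% basis
  pattern <- (2 + sin(uv[, 1] / 4) + cos(uv[, 2] / 5))
  vol <- array(pattern * pmax(0, 1.5 - dist), d)
  a <- alignment_angles(list(normal = nrm))
  rv <- rotate_volume(volume3d(vol), a)
  # mass-centroid slab holds the planted pattern
  mass <- apply(rv$data, 3, sum)
  zc <- sum(seq_along(mass) * mass) / sum(mass)
  sl <- extract_reslice(rv, zc)
  # compare against the in-plane pattern evaluated on the same grid
  d2 <- dim(rv$data)
  c2 <- (d2 + 1) / 2
  g2 <- as.matrix(expand.grid(x = 1:d2[1], y = 1:d2[2]))
  R <- rotation_x(a$alpha_x) %*% rotation_y(a$alpha_y)
  # in-plane coordinates of rotated grid points: map back to input frame
  rel2 <- cbind(g2[, 1] - c2[1], g2[, 2] - c2[2], zc - c2[3]) %*% R
  uv2 <- rel2 %*% basis
  pred <- 2 + sin(uv2[, 1] / 4) + cos(uv2[, 2] / 5)
  rad <- sqrt((g2[, 1] - c2[1])^2 + (g2[, 2] - c2[2])^2)
  m <- rad < 24 & sl > 0.1
  expect_gt(cor(sl[m], pred[m]), 0.95)
})

test_that("curved reslice: straight degenerate, arc bookkeeping, oracle", {
  set.seed(27)
  arr <- array(rnorm(20 * 20 * 6), c(20, 20, 6))
  v <- volume3d(arr)
  cr <- curved_reslice(v, polyline_path(rbind(c(3, 7), c(14, 7))))
  expect_equal(cr, arr[3:13, 7, ])
  crL <- curved_reslice(v, polyline_path(rbind(c(3, 3), c(10, 3), c(10, 9))))
  expect_identical(nrow(crL), as.integer(ceiling(7 + 6)))
  # random path vs an independent per-point trilinear evaluator
  p <- rbind(c(2.3, 4.1), c(9.7, 12.2), c(15.1, 6.4))
  cr2 <- curved_reslice(v, polyline_path(p))
  tri <- function(x, y, z) {
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      xx <- min(max(x0 + dx, 1), 20); yy <- min(max(y0 + dy, 1), 20)
      zz <- min(max(z0 + dz, 1), 6)
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
      acc <- acc + w * arr[xx, yy, zz]
    }
    acc
  }
  seg <- diff(p); lens <- sqrt(rowSums(seg^2)); cum <- c(0, cumsum(lens))
  for (i in c(1, 5, 9, nrow(cr2))) {
    l <- i - 1
    si <- min(findInterval(l, cum, rightmost.closed = TRUE), 2)
    t <- (l - cum[si]) / lens[si]
    px <- p[si, 1] + t * seg[si, 1]; py <- p[si, 2] + t * seg[si, 2]
    for (z in c(1, 4)) {
      expect_equal(cr2[i, z], tri(px, py, z), tolerance = 1e-6)
    }
  }
  expect_error(curved_reslice(v, polyline_path(rbind(c(1, 1), c(25, 1)))),
               "outside")
})
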