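test_that("blend mask: no-margin identity, complementary ramps, corner product", {
  expect_true(all(blend_mask(c(50, 50), 0) == 1))
  m <- 8; tp <- 64
  w <- blend_mask(c(tp, tp), m)
  # two tiles abutting at offset tp - m: ramps sum to 1 across the overlap
  ov <- w[30, (tp - m + 1):tp] + w[30, 1:m]
  expect_equal(ov, rep(1, m), tolerance = 1e-12)
  # corner follows the separable product rule (per-pixel loop oracle)
  for (i in 1:4) for (j in 1:4) {
    ry <- (i - 0.5) / m; rx <- (j - 0.5) / m
    expect_equal(w[i, j], ry * rx, tolerance = 1e-12)
  }
  expect_error(blend_mask(c(16, 16), 9), "half the tile")
})

test_that("blend weights partition unity strictly inside a regular mosaic", {
  tp <- 60; m <- 6; step <- tp - m
  w <- blend_mask(c(tp, tp), m)
  H <- 2 * step + tp
  acc <- matrix(0, H, H)
  for (r in 0:2) for (c in 0:2) {
    ys <- r * step + 1:tp; xs <- c * step + 1:tp
    acc[ys, xs] <- acc[ys, xs] + w
  }
  interior <- acc[(m + 1):(H - m), (m + 1):(H - m)]
  expect_lt(max(abs(interior - 1)), 1e-9)
})

test_that("constant tiles blend to a constant mosaic", {
  ts <- make_tile_fixture(matrix(5, 300, 300), 2, 2,
                          translation_basis(c(95, 0), c(0, 95)),
                          overlap_px = 5)
  mos <- assemble_mosaic(ts, translation_basis(c(95, 0), c(0, 95)))
  cov <- mos != 0
  expect_equal(range(mos[cov]), c(5, 5), tolerance = 1e-12)
})

test_that("basis estimation recovers the fixture ground truth", {
  set.seed(31)
  img <- matrix(runif(512 * 512), 512)
  b <- translation_basis(c(95, 2), c(-2, 95))
  ts <- make_tile_fixture(img, 3, 3, b, overlap_px = 5, noise_sd = 0)
  init <- translation_basis(c(92, 5), c(-5, 92))
  est <- estimate_basis(ts, init)
  expect_lt(max(abs(est$u - b$u)), 0.5)
  expect_lt(max(abs(est$v - b$v)), 0.5)

  # fixed point: init at truth converges with zero update in iteration 1
  est0 <- estimate_basis(ts, b)
  conv <- attr(est0, "convergence")
  expect_equal(conv$history[1], 0)
  expect_identical(est0$u, b$u)

  # SNR 10 noise: still within 1 px componentwise
  tsn <- make_tile_fixture(img, 3, 3, b, overlap_px = 5,
                           noise_sd = sd(img) / 10, seed = 5)
  estn <- estimate_basis(tsn, init)
  expect_lt(max(abs(c(estn$u - b$u, estn$v - b$v))), 1)
})

test_that("estimation accuracy degrades monotonically with noise (median)", {
  set.seed(32)
  img <- matrix(runif(360 * 360), 360)
  b <- translation_basis(c(95, 2), c(-2, 95))
  init <- translation_basis(c(93, 4), c(-4, 93))
  err_at <- function(noise) {
    e <- vapply(1:7, function(s) {
      ts <- make_tile_fixture(img, 2, 2, b, overlap_px = 5,
                              noise_sd = noise, seed = s)
      est <- estimate_basis(ts, init)
      max(abs(c(est$u - b$u, est$v - b$v)))
    }, numeric(1))
    median(e)
  }
  errs <- vapply(c(0.3, 0.05, 0), err_at, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("estimation error cases", {
  set.seed(33)
  img <- matrix(runif(300 * 300), 300)
  b <- translation_basis(c(95, 0), c(0, 95))
  ts1 <- make_tile_fixture(img, 1, 2, b, overlap_px = 5)
  expect_error(estimate_basis(ts1, b), "2 rows")
  flat <- make_tile_fixture(matrix(1, 300, 300), 2, 2, b, overlap_px = 5)
  expect_error(estimate_basis(flat, b), "low signal")
})

test_that("mosaic stacking applies the axial calibration", {
  slices <- replicate(146, matrix(0, 4, 4), simplify = FALSE)
  v <- stack_mosaics(slices, 2, 1.36, pixel_um = 0.3295)
  expect_equal(v$spacing[3], 2.72)
  expect_equal(attr(v, "z_extent_um"), 397.12)
  expect_equal(round(attr(v, "z_extent_um")), 397)
  v1 <- stack_mosaics(slices[1:2], 5, 1, pixel_um = 1)
  expect_equal(v1$spacing[3], 5)
  expect_equal(attr(v1, "z_extent_um"), 10)   # n_slices x scaled step
  bad <- c(slices[1:3], list(matrix(0, 5, 4)))
  expect_error(stack_mosaics(bad, 2, 1), "slice 4")
})

test_that("subpixel basis assembly stays close to the source image", {
  set.seed(34)
  xs <- seq_len(420)
  img <- outer(sin(xs / 9), cos(xs / 11)) + 2   # smooth content
  b <- translation_basis(c(95.4, 1.7), c(-1.6, 95.3))
  ts <- make_tile_fixture(img, 3, 3, b, overlap_px = 5)
  mos <- assemble_mosaic(ts, b)
  cov <- mos != 0
  err <- abs(mos - img[seq_len(nrow(mos)), seq_len(ncol(mos))])
  # subpixel positions are resampled twice (bilinear crop, then bilinear
  # splat) and blended strips mix slightly different fractional phases, so
  # a few percent of the dynamic range is the expected ceiling
  expect_lt(max(err[cov & !is.na(err)]) / diff(range(img)), 0.06)
})
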