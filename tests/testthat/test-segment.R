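test_that("diffusion identities: zero iterations, uniform input, mean", {
  set.seed(41)
  arr <- array(rnorm(16^3), c(16, 16, 16))
  v <- volume3d(arr)
  expect_identical(anisotropic_diffusion(v, diffusion_params(iterations = 0))$data,
                   arr)
  u <- volume3d(array(3.7, c(12, 12, 12)))
  expect_equal(anisotropic_diffusion(u, diffusion_params(iterations = 15))$data,
               u$data, tolerance = 1e-12)
  sm <- anisotropic_diffusion(v, diffusion_params(iterations = 12))
  expect_lt(abs(mean(sm$data) - mean(arr)) / abs(mean(arr)), 1e-6)
  expect_error(diffusion_params(time_step = 0.3), "time_step")
})

test_that("diffusion preserves edges where Gaussian smoothing cannot", {
  set.seed(42)
  n <- 32
  vol <- array(0, c(n, n, n)); vol[(n / 2 + 1):n, , ] <- 1
  v <- volume3d(vol + array(rnorm(n^3, 0, 0.1), c(n, n, n)))
  p <- diffusion_params(conductance = 0.4, iterations = 20, time_step = 0.15)
  sm <- anisotropic_diffusion(v, p)
  contrast <- function(a) mean(a[n / 2 + 2, , ]) - mean(a[n / 2 - 1, , ])
  flatvar <- function(a) var(as.numeric(a[5:(n / 2 - 4), , ]))
  expect_gt(contrast(sm$data) / contrast(v$data), 0.9)
  expect_lt(flatvar(sm$data) / flatvar(v$data), 0.5)
  # Gaussian blur at matched (or stronger) noise reduction loses the edge
  target <- flatvar(sm$data) / flatvar(v$data)
  f <- function(sigma) {
    r <- ceiling(4 * sigma); k <- dnorm(-r:r, 0, sigma); k <- k / sum(k)
    sum(k^2)^3 - target
  }
  sig <- uniroot(f, c(0.2, 6))$root
  r <- ceiling(4 * sig); k <- dnorm(-r:r, 0, sig); k <- k / sum(k)
  conv1 <- function(a, ax) {
    d <- dim(a); out <- array(0, d); idx <- seq_len(d[ax])
    for (off in -r:r) {
      src <- pmin(pmax(idx + off, 1), d[ax])
      out <- out + k[off + r + 1] *
        (if (ax == 1) a[src, , ] else if (ax == 2) a[, src, ] else a[, , src])
    }
    out
  }
  g <- conv1(conv1(conv1(v$data, 1), 2), 3)
  expect_lt(contrast(g) / contrast(v$data), 0.9)
})

test_that("gradient magnitude matches closed forms and a loop oracle", {
  u <- volume3d(array(2, c(10, 10, 10)))
  expect_true(all(gradient_magnitude(u)$data == 0))
  ramp <- volume3d(array(rep(3 * (1:12), times = 144), c(12, 12, 12)),
                   spacing = c(2, 2, 2))
  gm <- gradient_magnitude(ramp)
  expect_equal(gm$data[2:11, , ], array(3 / 2, c(10, 12, 12)),
               tolerance = 1e-12)
  set.seed(43)
  arr <- array(rnorm(6^3), c(6, 6, 6))
  gm2 <- gradient_magnitude(volume3d(arr, spacing = c(1.5, 2, 2.5)))
  # independent per-voxel finite-difference loop
  for (i in 2:5) for (j in 2:5) for (k in 2:5) {
    gx <- (arr[i + 1, j, k] - arr[i - 1, j, k]) / (2 * 1.5)
    gy <- (arr[i, j + 1, k] - arr[i, j - 1, k]) / (2 * 2)
    gz <- (arr[i, j, k + 1] - arr[i, j, k - 1]) / (2 * 2.5)
    expect_equal(gm2$data[i, j, k], sqrt(gx^2 + gy^2 + gz^2),
                 tolerance = 1e-9)
  }
})

test_that("watershed floods basins deterministically", {
  n <- 16
  xs <- 1:n
  ridge <- array(rep(max((xs - 8.5)^2) - (xs - 8.5)^2, times = n * n),
                 c(n, n, n))
  mk <- array(0L, c(n, n, n)); mk[2, 8, 8] <- 1L; mk[15, 8, 8] <- 2L
  ws <- watershed_regions(volume3d(ridge), markers = mk)
  expect_identical(sort(unique(as.integer(ws$data))), c(1L, 2L))
  expect_true(all(ws$data[1:8, , ] == 1L))
  expect_true(all(ws$data[9:16, , ] == 2L))
  # every voxel gets exactly one label; region count <= marker count
  expect_false(any(ws$data == 0L))

  mk1 <- array(0L, c(n, n, n)); mk1[3, 3, 3] <- 1L
  expect_true(all(watershed_regions(volume3d(ridge), markers = mk1)$data == 1L))

  # uniform gradient degenerates to nearest-marker (L1) flooding
  mk2 <- array(0L, c(n, n, n)); mk2[4, 4, 4] <- 1L; mk2[12, 12, 12] <- 2L
  ws2 <- watershed_regions(volume3d(array(0, c(n, n, n))), markers = mk2)
  idx <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  d1 <- rowSums(abs(sweep(idx, 2, c(4, 4, 4))))
  d2 <- rowSums(abs(sweep(idx, 2, c(12, 12, 12))))
  strict <- d1 != d2
  expect_true(all((ws2$data[idx][strict] == 1L) == (d1 < d2)[strict]))

  expect_error(watershed_regions(volume3d(ridge)), "markers or a flood_level")
})

test_that("region classification by mean intensity", {
  set.seed(44)
  n <- 24
  inten <- array(rnorm(n^3, 1, 0.05), c(n, n, n))
  inten[4:9, 4:9, 4:9] <- rnorm(216, 3, 0.05)        # dense planted blob
  lab <- array(1L, c(n, n, n))
  lab[4:9, 4:9, 4:9] <- 2L
  lab[n, n, n] <- 0L                                  # keep a background voxel
  rc <- classify_regions(lab, inten, density_threshold = 2)
  expect_identical(unname(rc$class_map["2"]), "fibrotic")
  expect_identical(unname(rc$class_map["1"]), "parenchyma")
  expect_true(all(fibrotic_mask(rc) == (lab == 2L)))
  # threshold above the global max: nothing fibrotic
  rc2 <- classify_regions(lab, inten, density_threshold = max(inten) + 1)
  expect_false(any(rc2$report$class == "fibrotic"))
  # adaptive midpoint rule lands between the two modes
  rc3 <- classify_regions(lab, inten, density_threshold = NULL)
  expect_gt(rc3$density_threshold, 1.2)
  expect_lt(rc3$density_threshold, 3)
  expect_identical(unname(rc3$class_map["2"]), "fibrotic")
  expect_error(classify_regions(lab, inten[1:10, , ]), "differ")
})

test_that("full screening pipeline recovers planted fibrosis", {
  ph <- tiny_phantom(seed = 3, fibrosis = 0.1)
  rc <- segment_fibrosis(ph$fluorescence)
  d <- dice_coef(fibrotic_mask(rc), ph$truth_labels$data == 4L)
  expect_gt(d, 0.7)
})
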