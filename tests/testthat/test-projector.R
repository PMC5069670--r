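test_that("empty and slab phantoms follow Beer-Lambert closed forms", {
  n <- 64
  zero <- list(absorption = slab_volume(matrix(0, n, n)),
               fluorescence = slab_volume(matrix(0, n, n)))
  geom <- acquisition_geometry(16, n, 1, pixel_um = 1, i0 = 2)
  pr <- forward_project(zero, geom)
  expect_true(all(pr$transmission$data == 2))
  expect_true(all(pr$fluorescence$data == 0))

  # uniform disk, mu = 0.01/um, central chord 100 um -> I = i0 e^-1 at
  # every angle (Beer-Lambert closed form)
  n2 <- 129
  mu <- 0.01 * disk_image(n2, 50)
  ph <- list(absorption = slab_volume(mu), fluorescence = slab_volume(mu))
  g0 <- acquisition_geometry(12, n2, 1, pixel_um = 1, i0 = 1)
  pr2 <- forward_project(ph, g0)
  center <- pr2$transmission$data[, 1, (n2 + 1) / 2]
  expect_equal(center, rep(exp(-1), 12), tolerance = 0.02)
})

test_that("a point object traces the expected sinusoid", {
  n <- 128
  img <- matrix(0, n, n); img[90, 70] <- 1
  v <- slab_volume(img)
  geom <- acquisition_geometry(128, n, 1, pixel_um = 1)
  s <- project_volume(v, geom)
  trace <- apply(s$data[, 1, ], 1, which.max)
  xc <- (n + 1) / 2
  r <- sqrt((90 - xc)^2 + (70 - xc)^2)
  phi0 <- atan2(70 - xc, 90 - xc)
  pred <- xc + r * cos(geom$angles * pi / 180 - phi0)
  expect_lt(max(abs(trace - pred)), 1)
})

test_that("fluorescence channel is linear and mass-conserving", {
  set.seed(8)
  n <- 64
  a <- gaussian_slab(n, 9)
  b <- slab_volume(matrix(runif(n * n), n) * disk_image(n, n / 4))
  geom <- acquisition_geometry(32, n, 1, pixel_um = 1)
  pa <- project_volume(a, geom)$data
  pb <- project_volume(b, geom)$data
  comb <- a
  comb$data <- 2 * a$data + 0.5 * b$data
  pc <- project_volume(comb, geom)$data
  expect_equal(pc, 2 * pa + 0.5 * pb, tolerance = 1e-10)

  # per-angle mass: sum over x constant across angles within 0.5 %
  sums <- apply(pa, 1, sum)
  expect_lt(diff(range(sums)) / mean(sums), 0.005)
  expect_equal(mean(sums), sum(a$data), tolerance = 0.005)
})

test_that("transmission stays in (0, i0] and the log recovers line integrals", {
  ph <- tiny_phantom(seed = 3, shape = c(48, 48, 48))
  geom <- acquisition_geometry(24, 48, 48, pixel_um = 20, i0 = 3)
  pr <- forward_project(ph, geom)
  expect_true(all(pr$transmission$data > 0))
  expect_true(all(pr$transmission$data <= 3))
  li <- transmission_to_line_integral(pr$transmission)
  direct <- project_volume(ph$absorption, geom)
  expect_equal(li$data, direct$data, tolerance = 1e-6)
})

test_that("fan projection degenerates to parallel and shifts traces by beta", {
  n <- 96; det <- 97                      # odd detector: integer center
  img <- matrix(0, n, n); img[70, 40] <- 1
  v <- slab_volume(img)
  cx <- (det + 1) / 2
  g_par <- acquisition_geometry(96, det, 1, pixel_um = 1)
  g_fan0 <- acquisition_geometry(96, det, 1, pixel_um = 1,
                                 fan = fan_geometry(0, cx))
  ph <- list(absorption = v, fluorescence = v)
  expect_identical(fan_project(ph, g_fan0)$fluorescence$data,
                   forward_project(ph, g_par)$fluorescence$data)

  # column-x trace shifted in phi by -beta(x) relative to the parallel trace
  sr <- 0.5
  g_fan <- acquisition_geometry(96, det, 1, pixel_um = 1,
                                fan = fan_geometry(sr, cx))
  sf <- fan_project(ph, g_fan)$fluorescence$data[, 1, ]
  sp <- forward_project(ph, g_par)$fluorescence$data[, 1, ]
  dphi <- 360 / 96
  checked <- 0
  circ_lag <- function(a, b, lags) {
    # lag of b relative to a maximizing circular correlation
    sc <- vapply(lags, function(l)
      sum(a * b[((seq_along(b) - 1 + l) %% length(b)) + 1]), numeric(1))
    lags[which.max(sc)]
  }
  for (col in seq(15, 85, by = 10)) {
    if (max(sp[, col]) < 0.3) next
    # the whole column trace shifts rigidly by beta(x) in phi:
    # F(phi) = P(phi + beta), so sf[i] matches sp[i + beta/dphi]
    lag <- circ_lag(sf[, col], sp[, col], -8:8)
    pred <- sr * (col - cx) / dphi
    expect_lt(abs(lag - pred), 1.5)
    checked <- checked + 1
  }
  expect_gte(checked, 3)

  # zero tilt at the fan center column
  expect_equal(sf[, cx], sp[, cx], tolerance = 1e-10)
  # model validity limit
  g_bad <- acquisition_geometry(8, det, 1, pixel_um = 1,
                                fan = fan_geometry(2, cx))
  expect_error(fan_project(ph, g_bad), "45")
})

test_that("geometry validation catches mismatches", {
  ph <- tiny_phantom(seed = 3, shape = c(48, 48, 48))
  expect_error(forward_project(ph, acquisition_geometry(8, 48, 40,
                                                        pixel_um = 20)),
               "detector_y")
  expect_error(forward_project(ph, acquisition_geometry(8, 32, 48,
                                                        pixel_um = 20)),
               "footprint")
  expect_error(forward_project(ph, acquisition_geometry(8, 48, 48,
                                                        pixel_um = 10)),
               "pixel_um")
})
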