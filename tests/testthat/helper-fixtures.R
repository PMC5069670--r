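# Shared fixture builders; everything is generated in code under fixed
# seeds, nothing is read from disk.

# single-slice volume holding a 2D xz-image (ny = 1)
slab_volume <- function(img2d, spacing = 1) {
  n <- nrow(img2d)
  volume3d(array(img2d, c(n, 1, ncol(img2d))), rep(spacing, 3), "density")
}

# centered disk image of radius r on an n x n grid
disk_image <- function(n, r, value = 1) {
  xs <- (1:n) - (n + 1) / 2
  value * outer(xs, xs, function(x, z) as.numeric(x^2 + z^2 <= r^2))
}

# small standard phantom used across modules (fast to build)
tiny_phantom <- function(seed = 3, fibrosis = 0.1, shape = c(96, 96, 96)) {
  make_lobe_phantom(phantom_params(shape = shape, fibrosis_fraction = fibrosis,
                                   seed = seed))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# angle between two direction vectors, degrees, sign-insensitive
axis_angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# smooth blob phantom for mass-conservation style checks
gaussian_slab <- function(n, sigma) {
  xs <- (1:n) - (n + 1) / 2
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  slab_volume(g)
}
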