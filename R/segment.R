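#' Parameters for gradient anisotropic diffusion
#'
#' Perona-Malik diffusion with conductance `exp(-(|grad I| / kappa)^2)`:
#' smooths within quasi-uniform regions while preserving strong edges,
#' the standard pre-filter before gradient-magnitude watershed
#' segmentation. The explicit 6-neighbour scheme is stable for time steps
#' up to 1/6; the default 0.15 keeps a safety margin below the von Neumann
#' bound.
#'
#' @param conductance edge threshold kappa, in intensity units per voxel
#'   step (gradients well below it diffuse, well above it are preserved).
#' @param iterations number of explicit update steps.
#' @param time_step step size, in `(0, 0.25]`.
#' @return An object of class `diffusion_params`.
#' @export
diffusion_params <- function(conductance = 0.4, iterations = 10,
                             time_step = 0.15) {
  if (conductance <= 0) stop("conductance must be positive")
  if (iterations < 0) stop("iterations must be >= 0")
  if (time_step <= 0 || time_step > 0.25)
    stop("time_step must be in (0, 0.25]")
  structure(list(conductance = conductance,
                 iterations = as.integer(iterations),
                 time_step = time_step),
            class = "diffusion_params")
}

# shift an array by one voxel along an axis, replicating the boundary
# (Neumann: zero flux across the border)
.shift1 <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] - dir, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx))
}

#' Gradient anisotropic diffusion (Perona-Malik)
#'
#' Explicit conservative scheme: per iteration each voxel receives the sum
#' of the six face fluxes `g(|dI|) * dI` scaled by the time step, with the
#' conductance `g(x) = exp(-(x / kappa)^2)` evaluated on the face
#' difference and Neumann (zero-flux) boundaries. Because fluxes are
#' antisymmetric across faces the global mean is preserved.
#'
#' @param v a [volume3d()] (or plain 3D array).
#' @param p a [diffusion_params()].
#' @return The diffused [volume3d()].
#' @export
anisotropic_diffusion <- function(v, p = diffusion_params()) {
  stopifnot(inherits(p, "diffusion_params"))
  vv <- as_volume3d(v)
  a <- vv$data
  k2 <- p$conductance^2
  for (it in seq_len(p$iterations)) {
    upd <- 0
    for (axis in 1:3) {
      for (dir in c(-1L, 1L)) {
        d <- .shift1(a, axis, dir) - a
        upd <- upd + exp(-d^2 / k2) * d
      }
    }
    a <- a + p$time_step * upd
  }
  volume3d(a, vv$spacing, vv$channel)
}

#' Gradient magnitude of a volume
#'
#' Central differences along each axis scaled by the voxel spacing
#' (one-sided at the borders), combined as the Euclidean norm; units are
#' intensity per um.
#'
#' @param v a [volume3d()] (or plain 3D array).
#' @return A [volume3d()] of gradient magnitudes.
#' @export
gradient_magnitude <- function(v) {
  vv <- as_volume3d(v)
  a <- vv$data
  g2 <- 0
  for (axis in 1:3) {
    fwd <- .shift1(a, axis, -1L)
    bwd <- .shift1(a, axis, 1L)
    # central differences; the replicated border collapses to one-sided,
    # where the effective spacing is one voxel instead of two
    n <- dim(a)[axis]
    denom <- array(2, dim(a))
    idx <- lapply(dim(a), seq_len)
    for (edge in c(1L, n)) {
      ii <- idx; ii[[axis]] <- edge
      denom <- do.call(`[<-`, c(list(denom), ii, list(1)))
    }
    g2 <- g2 + ((fwd - bwd) / (denom * vv$spacing[axis]))^2
  }
  volume3d(sqrt(g2), vv$spacing, "gradient")
}

#' Marker-based watershed on a gradient image
#'
#' Priority-flooding watershed: marked voxels flood outward in order of
#' increasing gradient value, each unlabeled voxel joining the basin that
#' reaches it first (6-connectivity; ties broken deterministically by
#' insertion order, so for fronts seeded together the lowest marker id
#' wins). Markers may be given explicitly as a label array, or implicitly
#' as a flood level: the 6-connected components of
#' `{gradient <= flood_level}` then seed the basins.
#'
#' @param gradient a [volume3d()] of non-negative values (or array).
#' @param markers integer array of marker labels (0 = unlabeled), or `NULL`.
#' @param flood_level numeric level used to derive markers when `markers`
#'   is `NULL`.
#' @return A [volume3d()] of integer region labels (channel `"label"`).
#' @export
watershed_regions <- function(gradient, markers = NULL, flood_level = NULL) {
  gv <- as_volume3d(gradient)
  if (min(gv$data) < 0) stop("gradient must be non-negative")
  if (is.null(markers)) {
    if (is.null(flood_level))
      stop("either markers or a flood_level must be supplied")
    markers <- cpp_label_components(gv$data <= flood_level, dim(gv$data))
  } else {
    if (inherits(markers, "volume3d")) markers <- markers$data
    if (!all(dim(markers) == dim(gv$data)))
      stop("markers and gradient shapes differ")
    storage.mode(markers) <- "integer"
  }
  if (!any(markers > 0)) stop("no marker voxels")
  lab <- cpp_watershed(gv$data, dim(gv$data), markers)
  volume3d(lab, gv$spacing, "label")
}

#' Classify watershed regions by mean intensity
#'
#' Dense ("fibrotic") regions are those whose mean intensity reaches the
#' density threshold; all other nonzero regions are normal parenchyma;
#' label 0 stays background. If `density_threshold` is `NULL` it defaults
#' to the midpoint between the median and the maximum of the per-region
#' means, an adaptive rule for bimodal dense-vs-normal intensity mixtures.
#'
#' @param labels a label [volume3d()] (or integer array).
#' @param intensity a [volume3d()] (or array) aligned with `labels`.
#' @param density_threshold intensity threshold for the dense class, or
#'   `NULL` for the adaptive midpoint rule.
#' @return List of class `region_classification`: `labels` (input labels),
#'   `class_map` (named character vector region id -> class), `report`
#'   (data frame: id, voxels, mean intensity, class) and the threshold
#'   used. `fibrotic_mask()` turns it into a logical array.
#' @export
classify_regions <- function(labels, intensity, density_threshold = NULL) {
  lv <- as_volume3d(labels)
  iv <- as_volume3d(intensity)
  if (!all(dim(lv$data) == dim(iv$data)))
    stop("labels and intensity shapes differ")
  lab <- as.integer(lv$data)
  inten <- as.numeric(iv$data)
  fg <- lab > 0L
  sums <- tapply(inten[fg], lab[fg], sum)
  cnts <- tapply(rep(1, sum(fg)), lab[fg], sum)
  ids <- as.integer(names(sums))
  means <- as.numeric(sums) / as.numeric(cnts)
  if (is.null(density_threshold))
    density_threshold <- (median(means) + max(means)) / 2
  cls <- ifelse(means >= density_threshold, "fibrotic", "parenchyma")
  report <- data.frame(id = ids, voxels = as.integer(cnts),
                       mean_intensity = means, class = cls,
                       stringsAsFactors = FALSE)
  structure(list(labels = lv, class_map = setNames(cls, ids),
                 report = report, density_threshold = density_threshold),
            class = "region_classification")
}

#' Logical mask of one class from a region classification
#'
#' @param rc a `region_classification` from [classify_regions()].
#' @param class class name, default `"fibrotic"`.
#' @return Logical array over the volume.
#' @export
fibrotic_mask <- function(rc, class = "fibrotic") {
  stopifnot(inherits(rc, "region_classification"))
  ids <- as.integer(names(rc$class_map)[rc$class_map == class])
  array(rc$labels$data %in% ids, dim(rc$labels$data))
}

#' Shipped default parameters of the density-screening pipeline
#'
#' Defaults used by [segment_fibrosis()]: diffusion settings, the rule
#' deriving the watershed flood level from the gradient image (a fraction
#' of its maximum), and the adaptive density threshold (see
#' [classify_regions()]). Chosen on the synthetic phantom; no claim is made
#' that they match any interactive analysis of real data.
#'
#' @return Named list of defaults.
#' @export
segment_defaults <- function() {
  list(diffusion = diffusion_params(conductance = 0.4, iterations = 10,
                                    time_step = 0.15),
       flood_level_fraction = 0.10,
       density_threshold = NULL)
}

#' Density-based screening for dense (fibrotic) regions
#'
#' Batch emulation of interactive ROI screening: gradient anisotropic
#' diffusion, gradient magnitude, marker-based watershed (markers from a
#' flood level on the gradient unless supplied), then region classification
#' by mean intensity against a density threshold.
#'
#' @param v intensity [volume3d()] (e.g. reconstructed fluorescence).
#' @param diffusion a [diffusion_params()].
#' @param markers optional explicit marker array.
#' @param flood_level_fraction flood level as a fraction of the maximum
#'   gradient magnitude (ignored when `markers` given).
#' @param density_threshold see [classify_regions()].
#' @return A `region_classification` (with the watershed `labels` inside).
#' @export
segment_fibrosis <- function(v, diffusion = segment_defaults()$diffusion,
                             markers = NULL,
                             flood_level_fraction = segment_defaults()$flood_level_fraction,
                             density_threshold = segment_defaults()$density_threshold) {
  sm <- anisotropic_diffusion(v, diffusion)
  gr <- gradient_magnitude(sm)
  lab <- if (is.null(markers)) {
    watershed_regions(gr, flood_level = flood_level_fraction * max(gr$data))
  } else {
    watershed_regions(gr, markers = markers)
  }
  classify_regions(lab, sm, density_threshold)
}
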