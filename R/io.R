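#' Write a volume as multipage TIFF with a YAML sidecar
#'
#' One TIFF page per z-slab (32-bit float; 16-bit unsigned for label
#' channels). Physical metadata (voxel spacing, channel role) lives in the
#' `<path>.yaml` sidecar, which is authoritative: TIFF resolution tags are
#' too lossy for um-precision spacing.
#'
#' @param path output TIFF path.
#' @param v a [volume3d()].
#' @return Invisibly, `path`.
#' @export
write_volume <- function(path, v) {
  stopifnot(inherits(v, "volume3d"))
  d <- dim(v$data)
  label <- v$channel == "label"
  # TIFF sample values live in [0, 1]; the affine rescaling is recorded in
  # the sidecar and undone on read
  off <- min(v$data)
  sc <- max(v$data) - off
  if (label || sc == 0) { off <- 0; sc <- if (label) 65535 else 1 }
  pages <- lapply(seq_len(d[3]), function(k) t(v$data[, , k] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = if (label) 16L else 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(kind = "volume3d", shape = as.integer(d),
                        spacing_um = as.numeric(v$spacing),
                        channel = v$channel, label = label,
                        value_offset = off, value_scale = sc),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; `<path>.yaml` must exist (the sidecar carries the
#'   spacing and channel; without it only unit spacing could be assumed).
#' @return A [volume3d()].
#' @export
read_volume <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = isTRUE(meta$label))
  if (is.list(pages) && length(pages) && length(dim(pages[[1]])) > 2)
    stop("format error: RGB/multi-channel TIFF is not a grayscale volume")
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$shape)
  vol <- array(0, d)
  for (k in seq_along(pages)) vol[, , k] <- t(pages[[k]])
  if (isTRUE(meta$label)) {
    vol <- round(vol)
    storage.mode(vol) <- "integer"
  } else {
    vol <- vol * meta$value_scale + meta$value_offset
  }
  volume3d(vol, meta$spacing_um, meta$channel)
}

#' Write / read MRC (mode 2, 32-bit float) volumes
#'
#' Minimal MRC-2014 interchange: 1024-byte header with the grid size, mode
#' 2, cell dimensions equal to `shape * spacing`, axis order x, y, z and
#' data statistics, followed by little-endian float32 voxels. This is the
#' tomogram interchange format of common reconstruction tool chains.
#'
#' @param path MRC file path.
#' @param v a [volume3d()].
#' @return Invisibly `path` (write); a [volume3d()] (read).
#' @export
write_mrc <- function(path, v) {
  stopifnot(inherits(v, "volume3d"))
  d <- dim(v$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                        # nx ny nz
  wi(2)                        # mode 2 = float32
  wi(c(0, 0, 0))               # nxstart
  wi(d)                        # mx my mz
  wf(d * v$spacing)            # cella (Angstrom-agnostic: um here)
  wf(c(90, 90, 90))            # cellb
  wi(c(1, 2, 3))               # mapc mapr maps
  wf(c(min(v$data), max(v$data), mean(v$data)))
  wi(c(0, 0))                  # ispg, nsymbt
  writeBin(raw(100), con)      # extra
  wf(c(0, 0, 0))               # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(v$data)))                 # rms
  wi(0)                        # nlabl
  writeBin(raw(800), con)      # labels
  writeBin(as.numeric(v$data), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("format error: only MRC mode 2 (float32) is supported")
  ri(3)            # nxstart
  m <- ri(3)       # mx my mz
  cella <- rf(3)
  seek(con, 1024)
  vol <- array(rf(prod(d)), d)
  volume3d(vol, cella / m, "intensity")
}

#' Write / read a sinogram (multipage TIFF + mandatory YAML sidecar)
#'
#' One page per angle (rows = detector y, cols = detector x); the sidecar
#' records angles, channel, detector geometry, `i0` and fan parameters and
#' is required for reading.
#'
#' @param path TIFF path.
#' @param s a [sinogram()].
#' @return Invisibly `path` (write); a [sinogram()] (read).
#' @export
write_sinogram <- function(path, s) {
  stopifnot(inherits(s, "sinogram"))
  d <- dim(s$data)
  off <- min(s$data)
  sc <- max(s$data) - off
  if (sc == 0) { off <- 0; sc <- 1 }
  pages <- lapply(seq_len(d[1]),
                  function(a) (s$data[a, , , drop = TRUE] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  g <- s$geometry
  yaml::write_yaml(list(kind = "sinogram", angles_deg = g$angles,
                        channel = s$channel,
                        value_offset = off, value_scale = sc,
                        detector_x = g$detector_x, detector_y = g$detector_y,
                        pixel_um = g$pixel_um, i0 = g$i0,
                        fan = if (is.null(g$fan)) NULL else
                          list(shear_rate = g$fan$shear_rate,
                               center_x = g$fan$center_x)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) stop("missing sinogram sidecar: ", side)
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$angles_deg))
    stop(sprintf("sidecar lists %d angles but TIFF has %d pages",
                 length(meta$angles_deg), length(pages)))
  dat <- array(0, c(length(pages), meta$detector_y, meta$detector_x))
  for (a in seq_along(pages))
    dat[a, , ] <- pages[[a]] * meta$value_scale + meta$value_offset
  fan <- if (is.null(meta$fan)) NULL else
    fan_geometry(meta$fan$shear_rate, meta$fan$center_x)
  geom <- acquisition_geometry(length(pages), meta$detector_x,
                               meta$detector_y, pixel_um = meta$pixel_um,
                               angles = meta$angles_deg, i0 = meta$i0,
                               fan = fan)
  sinogram(dat, geom, meta$channel)
}

#' Read landmarks from CSV
#'
#' The file must have a header with exactly the columns x, y, z and three
#' numeric rows, in 0-based voxel-center coordinates; they are converted to
#' the package's internal 1-based convention.
#'
#' @param path CSV path.
#' @return A [landmarks()] object.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path)
  if (!identical(sort(names(df)), c("x", "y", "z")))
    stop("landmark CSV must have exactly the columns x, y, z")
  if (nrow(df) != 3)
    stop(sprintf("landmark CSV must have 3 rows, found %d", nrow(df)))
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("landmark CSV contains non-numeric cells")
  m <- as.matrix(df[, c("x", "y", "z")]) + 1   # 0-based file -> 1-based
  landmarks(m[1, ], m[2, ], m[3, ])
}

#' Read a polyline path from CSV
#'
#' Header columns x, y (0-based, converted to 1-based), one vertex per row.
#'
#' @param path CSV path.
#' @return A [polyline_path()].
#' @export
read_polyline <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("polyline CSV must have columns x, y")
  polyline_path(as.matrix(df[, c("x", "y")]) + 1)
}

#' Read a tile set from a directory + CSV index
#'
#' The index must have header columns file, row, col (and optionally z);
#' grid indices must be unique. Tiles are single-page grayscale TIFFs of
#' identical size.
#'
#' @param index_csv path to the index CSV.
#' @param dir directory containing the tile files; defaults to the CSV's
#'   directory.
#' @param z optional z index to select when the index has a z column.
#' @return A `tile_set`.
#' @export
read_tile_index <- function(index_csv, dir = dirname(index_csv), z = NULL) {
  df <- read.csv(index_csv, stringsAsFactors = FALSE)
  need <- c("file", "row", "col")
  if (!all(need %in% names(df)))
    stop("tile index CSV must have columns file, row, col")
  if (!is.null(z) && "z" %in% names(df)) df <- df[df$z == z, , drop = FALSE]
  if (anyDuplicated(df[, c("row", "col")]))
    stop("duplicated grid index in tile CSV")
  df$row <- df$row - min(df$row) + 1L
  df$col <- df$col - min(df$col) + 1L
  tiles <- lapply(file.path(dir, df$file), function(f) {
    m <- tiff::readTIFF(f)
    if (length(dim(m)) > 2)
      stop("format error: tile ", f, " is not grayscale")
    m
  })
  tp <- dim(tiles[[1]])
  for (t in tiles) if (!all(dim(t) == tp)) stop("tiles differ in shape")
  if (tp[1] != tp[2]) stop("tiles must be square")
  structure(list(tiles = tiles, grid = df[, c("row", "col")],
                 tile_px = tp[1], overlap_px = NA_integer_, truth = NULL),
            class = "tile_set")
}
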