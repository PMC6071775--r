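#' @useDynLib nemorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile median sd cor.test kruskal.test aov TukeyHSD
#'   shapiro.test rnorm runif p.adjust pnorm ptukey qnorm
#' @importFrom utils read.csv write.csv head
NULL

# Axis order is (z, y, x) everywhere: dim(data) = c(nz, ny, nx), voxel_size
# and origin are (z, y, x) in nm, and the physical center of voxel index
# (i, j, k) (1-based) is origin + (index - 1) * voxel_size.

#' 3D intensity volume with physical voxel size
#'
#' A `voxel_grid` wraps a 3D numeric array together with its per-axis
#' physical voxel size (nm) and origin, so downstream measurements are always
#' made in physical units. Axis order is (z, y, x).
#'
#' @param data 3D numeric array, dimensions (nz, ny, nx).
#' @param voxel_size numeric length-3 (z, y, x) voxel size in nm, or a single
#'   number for isotropic voxels. All components must be positive.
#' @param origin physical coordinate (z, y, x) in nm of the center of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @return An object of class `voxel_grid` with fields `data`, `voxel_size`,
#'   `origin`.
#' @export
voxel_grid <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("'data' must have exactly 3 axes (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (z, y, x) in nm")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("'origin' must have length 3")
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x)\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g nm\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  extent:     %.4g x %.4g x %.4g nm\n",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3]))
  cat(sprintf("  intensity:  [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' 3D integer label volume
#'
#' Integer labels aligned to a [voxel_grid()] (same shape contract and axis
#' order). Label 0 is background; `legend` maps every nonzero label id
#' present to a structure name.
#'
#' @param labels 3D integer array.
#' @param voxel_size (z, y, x) nm, as in [voxel_grid()].
#' @param legend named integer vector, e.g. `c(NE = 1, vesicle = 2)`. Must
#'   cover every nonzero label present in `labels`.
#' @param origin see [voxel_grid()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size,
                         legend = c(NE = 1L, vesicle = 2L),
                         origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L)
    stop("'labels' must have exactly 3 axes (z, y, x)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (z, y, x) in nm")
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  if (length(present) && !all(present %in% as.integer(legend)))
    stop("legend does not cover all nonzero labels present: missing ",
         paste(setdiff(present, as.integer(legend)), collapse = ", "))
  structure(list(labels = labels, voxel_size = voxel_size,
                 legend = legend, origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z,y,x)\n",
              d[1], d[2], d[3]))
  tab <- table(factor(x$labels[x$labels != 0],
                      levels = as.integer(x$legend),
                      labels = names(x$legend)))
  for (nm in names(tab))
    cat(sprintf("  %-12s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Physical voxel-center coordinates along one axis
#' @param grid a `voxel_grid` or `label_volume`.
#' @param axis 1 = z, 2 = y, 3 = x.
#' @return numeric vector of coordinates in nm.
#' @keywords internal
voxel_centers <- function(grid, axis) {
  n <- dim(grid)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$voxel_size[axis]
}

## ---------------------------------------------------------------------------
## Readers / writers
## ---------------------------------------------------------------------------

#' Read a 3D volume from multi-page TIFF or MRC
#'
#' TIFF carries no reliable 3D voxel size, so for TIFF input the voxel size
#' must be supplied; for MRC the header cell spacing wins when present and
#' nonzero, otherwise `voxel_size_override` is used. The function fails
#' rather than silently assuming 1 nm voxels.
#'
#' @param path file path ending in `.tif`/`.tiff` or `.mrc`/`.rec`/`.st`.
#' @param voxel_size_override optional (z, y, x) nm voxel size.
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("volume must be 3D: TIFF has fewer than 2 pages")
    d <- dim(pages[[1]])
    arr <- array(0, dim = c(length(pages), d[1], d[2]))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
    if (is.null(voxel_size_override))
      stop("TIFF carries no 3D voxel size; supply voxel_size_override ",
           "(z, y, x) in nm")
    voxel_grid(arr, voxel_size_override)
  } else if (ext %in% c("mrc", "rec", "st", "map")) {
    read_mrc(path, voxel_size_override)
  } else {
    stop("unsupported volume format: .", ext,
         " (expected TIFF or MRC)")
  }
}

#' Write a 3D volume to multi-page TIFF or MRC
#'
#' Integer data round-trips bit-exactly through both formats. Floating-point
#' data must be written as MRC (mode 2); the TIFF backend stores intensities
#' clamped to a unit range and would not preserve arbitrary floats.
#'
#' @param grid a [voxel_grid()] or [label_volume()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  data <- if (inherits(grid, "label_volume")) grid$labels else grid$data
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    is_int <- all(data == round(data))
    if (!is_int)
      stop("TIFF output supports integer volumes only; use MRC for floats")
    if (min(data) < 0 || max(data) > 65535)
      stop("integer TIFF output requires values in [0, 65535]")
    bps <- if (max(data) <= 255) 8L else 16L
    scale <- 2^bps - 1
    pages <- lapply(seq_len(dim(data)[1]),
                    function(k) data[k, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = bps)
  } else if (ext %in% c("mrc", "rec", "st", "map")) {
    vx <- if (inherits(grid, "label_volume")) grid$voxel_size else
      grid$voxel_size
    write_mrc(data, vx, path)
  } else {
    stop("unsupported volume format: .", ext)
  }
  invisible(path)
}

# Minimal MRC2014 reader: modes 0 (int8), 1 (int16), 2 (float32), 6 (uint16).
# Header cell dimensions are in Angstrom; converted to nm.
read_mrc <- function(path, voxel_size_override = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 3, size = 4, endian = "little")     # nstart
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  nx <- nxyz[1]; ny <- nxyz[2]; nz <- nxyz[3]
  if (nz < 2L) stop("volume must be 3D: MRC has nz < 2")
  n <- as.numeric(nx) * ny * nz
  seek(con, 1024 + nsymbt)
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode))
  # MRC stores x fastest, then y, then z; internal order is (z, y, x).
  arr <- aperm(array(vals, dim = c(nx, ny, nz)), c(3, 2, 1))
  vs_a <- cella / pmax(mxyz, 1L)             # Angstrom per voxel, (x, y, z)
  if (all(is.finite(vs_a)) && all(vs_a > 0)) {
    voxel <- rev(vs_a) / 10                  # -> nm, (z, y, x)
  } else if (!is.null(voxel_size_override)) {
    voxel <- voxel_size_override
  } else {
    stop("MRC header has no voxel size; supply voxel_size_override")
  }
  voxel_grid(arr, voxel)
}

write_mrc <- function(data, voxel_size, path) {
  d <- dim(data)                              # (nz, ny, nx)
  is_int <- all(data == round(data))
  mode <- if (is_int && min(data) >= -32768 && max(data) <= 32767) 1L else 2L
  con <- file(path, "wb")
  on.exit(close(con))
  nxyz <- as.integer(c(d[3], d[2], d[1]))
  writeBin(nxyz, con, size = 4, endian = "little")
  writeBin(mode, con, size = 4, endian = "little")
  writeBin(integer(3), con, size = 4, endian = "little")        # nstart
  writeBin(nxyz, con, size = 4, endian = "little")              # mx my mz
  cella <- as.numeric(rev(voxel_size) * nxyz * 10)              # Angstrom
  writeBin(cella, con, size = 4, endian = "little")
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")     # cellb
  writeBin(1:3, con, size = 4, endian = "little")               # mapc/r/s
  writeBin(as.numeric(c(min(data), max(data), mean(data))), con,
           size = 4, endian = "little")                         # dmin/max/mean
  writeBin(integer(2), con, size = 4, endian = "little")        # ispg, nsymbt
  writeBin(raw(100), con)                                       # extra
  writeBin(numeric(3), con, size = 4, endian = "little")        # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)              # machst (LE)
  writeBin(as.numeric(sd(data)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                # nlabl
  writeBin(raw(800), con)
  flat <- as.vector(aperm(data, c(3, 2, 1)))                    # x fastest
  if (mode == 1L) {
    writeBin(as.integer(flat), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(flat), con, size = 4, endian = "little")
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Grid operations
## ---------------------------------------------------------------------------

#' Bin a volume by block averaging
#'
#' Each output voxel is the mean of a `factor`^3 block; the voxel size is
#' multiplied by `factor`. Trailing partial blocks are discarded, not padded.
#'
#' @param grid a [voxel_grid()].
#' @param factor integer >= 1; each axis length must be >= factor.
#' @return a binned [voxel_grid()].
#' @export
bin_volume <- function(grid, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be a positive integer")
  d <- dim(grid$data)
  if (any(d < factor)) stop("each axis length must be >= factor")
  if (factor == 1L) return(grid)
  nd <- d %/% factor
  a <- grid$data[seq_len(nd[1] * factor),
                 seq_len(nd[2] * factor),
                 seq_len(nd[3] * factor), drop = FALSE]
  # bin along each axis in turn: reshape so the block index is first,
  # column-mean it away, then rotate axes.
  for (ax in 1:3) {
    da <- dim(a)
    dim(a) <- c(factor, length(a) / factor)
    a <- colMeans(a)
    dim(a) <- c(da[1] / factor, da[2], da[3])
    a <- aperm(a, c(2, 3, 1))
  }
  voxel_grid(a, grid$voxel_size * factor,
             origin = grid$origin + (factor - 1) / 2 * grid$voxel_size)
}

#' Window a volume to 8-bit dynamic range
#'
#' Intensities are clipped to the `low_pct`/`high_pct` percentiles and
#' linearly mapped to 0..255. A constant volume (zero range) maps to all
#' zeros with a warning.
#'
#' @param grid a [voxel_grid()].
#' @param low_pct,high_pct window percentiles, `0 <= low_pct < high_pct <= 100`.
#'   Defaults 0.5 / 99.5.
#' @return a [voxel_grid()] with values in 0..255.
#' @export
to_uint8 <- function(grid, low_pct = 0.5, high_pct = 99.5) {
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("require 0 <= low_pct < high_pct <= 100")
  q <- quantile(grid$data, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant volume: zero dynamic range, mapping to all zeros")
    out <- array(0, dim = dim(grid$data))
  } else {
    x <- pmin(pmax(grid$data, q[1]), q[2])
    out <- round((x - q[1]) / (q[2] - q[1]) * 255)
  }
  g <- voxel_grid(out, grid$voxel_size, grid$origin)
  attr(g, "window") <- q
  g
}

## ---------------------------------------------------------------------------
## Result tables and config
## ---------------------------------------------------------------------------

#' Write a result table as CSV with a sidecar JSON of column units
#'
#' @param df data frame, one row per measured object; column names unique.
#' @param path CSV output path; units are written next to it as
#'   `<path>.units.json`.
#' @param units named character vector mapping column name to unit string.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, units = character()) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(names(df))) stop("column names must be unique")
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(units), paste0(path, ".units.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path CSV path.
#' @return data frame with a `units` attribute when the sidecar exists.
#' @export
read_result_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".units.json")
  if (file.exists(sidecar))
    attr(df, "units") <- unlist(jsonlite::read_json(sidecar))
  df
}

#' Read a YAML analysis configuration
#'
#' Expected keys include `voxel_size_nm` (z, y, x), `windows` (percentiles),
#' `thresholds` and `seeds`; all keys are passed through untouched.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
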