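#' Extract vesicle candidates from a label volume
#'
#' One record per 3D connected component (26-connectivity) of the vesicle
#' label. Axis extents are physical bounding-box extents per axis; the
#' centroid is the physical center of mass of the component's voxels.
#'
#' @param labels a [label_volume()].
#' @param vesicle_label integer label id; defaults to the legend entry named
#'   `"vesicle"`. An absent label yields an empty table, not an error.
#' @return data frame of class `vesicle_records`: `id`, centroid
#'   (`z_nm`, `y_nm`, `x_nm`), axis extents (`dz_nm`, `dy_nm`, `dx_nm`),
#'   `diameter_nm` (mean of the three extents), `equiv_diameter_nm`
#'   (equivalent-sphere diameter from voxel volume), `n_voxels`, `accepted`
#'   (NA until the sphericity filter runs), `reject_reason`.
#' @export
extract_candidates <- function(labels, vesicle_label = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(vesicle_label)) {
    if (!"vesicle" %in% names(labels$legend))
      stop("no 'vesicle' entry in legend; pass vesicle_label explicitly")
    vesicle_label <- labels$legend[["vesicle"]]
  }
  d <- dim(labels$labels)
  mask <- labels$labels == vesicle_label
  empty <- data.frame(id = integer(0), z_nm = numeric(0), y_nm = numeric(0),
                      x_nm = numeric(0), dz_nm = numeric(0),
                      dy_nm = numeric(0), dx_nm = numeric(0),
                      diameter_nm = numeric(0), equiv_diameter_nm = numeric(0),
                      n_voxels = integer(0), accepted = logical(0),
                      reject_reason = character(0))
  class(empty) <- c("vesicle_records", "data.frame")
  if (!any(mask)) return(empty)
  comp <- label_components_3d(as.vector(mask), d)
  idx <- which(comp > 0L)
  cid <- comp[idx]
  iz <- ((idx - 1) %% d[1]) + 1
  iy <- ((idx - 1) %/% d[1]) %% d[2] + 1
  ix <- ((idx - 1) %/% (d[1] * d[2])) + 1
  vx <- labels$voxel_size
  org <- labels$origin
  agg <- function(v, f) as.numeric(tapply(v, cid, f))
  nvox <- as.integer(tapply(cid, cid, length))
  rec <- data.frame(
    id = sort(unique(cid)),
    z_nm = org[1] + (agg(iz, mean) - 1) * vx[1],
    y_nm = org[2] + (agg(iy, mean) - 1) * vx[2],
    x_nm = org[3] + (agg(ix, mean) - 1) * vx[3],
    dz_nm = (agg(iz, max) - agg(iz, min) + 1) * vx[1],
    dy_nm = (agg(iy, max) - agg(iy, min) + 1) * vx[2],
    dx_nm = (agg(ix, max) - agg(ix, min) + 1) * vx[3],
    n_voxels = nvox)
  rec$diameter_nm <- (rec$dz_nm + rec$dy_nm + rec$dx_nm) / 3
  rec$equiv_diameter_nm <- 2 * (3 * nvox * prod(vx) / (4 * pi))^(1 / 3)
  rec$accepted <- NA
  rec$reject_reason <- ""
  rec <- rec[, c("id", "z_nm", "y_nm", "x_nm", "dz_nm", "dy_nm", "dx_nm",
                 "diameter_nm", "equiv_diameter_nm", "n_voxels",
                 "accepted", "reject_reason")]
  class(rec) <- c("vesicle_records", "data.frame")
  rec
}

#' Apply the sphericity filter to vesicle candidates
#'
#' A candidate is accepted when its longest and shortest bounding-box axis
#' extents differ by at most `max_axis_ratio` ("similar x, y and z
#' diameter"); elongated components are rejected as tubule-like.
#'
#' @param records output of [extract_candidates()].
#' @param max_axis_ratio ratio limit, >= 1. Default 1.5.
#' @param ignore_z_axis when TRUE, sphericity uses only the in-plane (x, y)
#'   extents: with section pitches larger than the object, a vesicle spans a
#'   single section and its z extent is a section count, not a diameter.
#' @return `records` with `accepted`/`reject_reason` filled in.
#' @export
apply_sphericity_filter <- function(records, max_axis_ratio = 1.5,
                                    ignore_z_axis = FALSE) {
  if (max_axis_ratio < 1) stop("'max_axis_ratio' must be >= 1")
  ext <- cbind(records$dz_nm, records$dy_nm, records$dx_nm)
  if (ignore_z_axis) ext <- ext[, 2:3, drop = FALSE]
  ratio <- apply(ext, 1, function(e) max(e) / min(e))
  records$accepted <- ratio <= max_axis_ratio
  records$reject_reason <- ifelse(records$accepted, "", "tubule-like")
  records
}

#' Summarize accepted vesicle diameters
#'
#' Diameter is the arithmetic mean of the three bounding-box axis extents.
#' Reports the mean and standard error of the mean, plus a 5 nm-binned
#' histogram.
#'
#' @param records vesicle records; rows with `accepted == FALSE` are dropped
#'   (rows with `accepted` NA are kept, so the unfiltered pipeline also
#'   works).
#' @param bin_width histogram bin width in nm, default 5.
#' @return list of class `vesicle_summary`: `n`, `mean_nm`, `sem_nm`,
#'   `sem_undefined` (TRUE when n = 1, where the SEM is reported as 0),
#'   `histogram` (data frame `bin_low_nm`, `bin_high_nm`, `count`),
#'   `diameters_nm`.
#' @export
summarize_diameters <- function(records, bin_width = 5) {
  keep <- is.na(records$accepted) | records$accepted
  di <- records$diameter_nm[keep]
  if (length(di) < 1) stop("zero accepted records")
  m <- mean(di)
  undef <- length(di) == 1L
  sem <- if (undef) 0 else sd(di) / sqrt(length(di))
  lo <- floor(min(di) / bin_width) * bin_width
  hi <- ceiling(max(di) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.integer(table(cut(di, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(list(n = length(di), mean_nm = m, sem_nm = sem,
                 sem_undefined = undef,
                 histogram = data.frame(bin_low_nm = breaks[-length(breaks)],
                                        bin_high_nm = breaks[-1],
                                        count = counts),
                 diameters_nm = di),
            class = "vesicle_summary")
}

#' @export
print.vesicle_summary <- function(x, ...) {
  cat(sprintf("<vesicle_summary> n = %d accepted vesicles\n", x$n))
  cat(sprintf("  mean diameter: %.1f +/- %.1f nm (mean +/- SEM%s)\n",
              x$mean_nm, x$sem_nm,
              if (x$sem_undefined) "; SEM undefined for n = 1" else ""))
  cat(sprintf("  histogram: %d bins of %g nm\n", nrow(x$histogram),
              x$histogram$bin_high_nm[1] - x$histogram$bin_low_nm[1]))
  invisible(x)
}

#' @export
#' @importFrom graphics barplot
plot.vesicle_summary <- function(x, ...) {
  barplot(x$histogram$count,
          names.arg = sprintf("%g", x$histogram$bin_low_nm),
          xlab = "diameter (nm)", ylab = "count", ...)
}

#' Phantom-based vesicle sizing study
#'
#' Generates a telophase phantom with `n` vesicles drawn from the stated
#' truth distribution on a noise-free label volume, runs detection,
#' sphericity filtering and sizing, and returns the recovered summary next
#' to the truth. Used by the recovery tests and the acceptance script.
#'
#' @param n vesicle count.
#' @param mean_nm,sd_nm,min_nm truth diameter distribution (truncated
#'   normal).
#' @param voxel_size nm (single value for isotropic voxels).
#' @param seed integer seed for the scene.
#' @param max_axis_ratio sphericity limit, default 1.5.
#' @param volume_shape optional (nz, ny, nx); when NULL a shape is chosen to
#'   hold `n` vesicles at a moderate packing fraction.
#' @return list: `summary` ([summarize_diameters()] output), `records`,
#'   `truth` (the generator's vesicle table).
#' @export
simulate_vesicle_study <- function(n, mean_nm = 57, sd_nm = 8, min_nm = 20,
                                   voxel_size = 4.5, seed = 1L,
                                   max_axis_ratio = 1.5,
                                   volume_shape = NULL) {
  if (is.null(volume_shape)) {
    # distance band 100-1000 nm both sides of the sheet gives ~2/3 of the
    # volume as placeable space; aim for a <10% packing fraction.
    side <- max(900, ceiling((n * (mean_nm + 3 * sd_nm)^3 * 12)^(1 / 3)))
    volume_shape <- c(round(side / 2 / voxel_size),
                      round(2300 / voxel_size),
                      round(side * 2 / voxel_size))
  }
  spec <- scene_spec(volume_shape = volume_shape, voxel_size = voxel_size,
                     vesicle_count = n, vesicle_diameter_mean = mean_nm,
                     vesicle_diameter_sd = sd_nm, vesicle_diameter_min = min_nm,
                     noise_sd = 0, blur_sigma = 0, tortuosity_amp = 0,
                     seed = seed)
  scene <- make_telophase_scene(spec)
  rec <- extract_candidates(scene$labels)
  rec <- apply_sphericity_filter(rec, max_axis_ratio)
  list(summary = summarize_diameters(rec), records = rec,
       truth = scene$truth$vesicles)
}
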