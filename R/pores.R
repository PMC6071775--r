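# Pore clips keep the cropped/binned/windowed base grid plus the cumulative
# object rotation; every view is resampled once from the base with the
# composed matrix, so rotations never stack interpolation error.

new_pore_clip <- function(base, center, provenance) {
  structure(list(base = base, grid = base, rot = diag(3),
                 applied_rotations = list(), center = center,
                 perpendicular = FALSE, provenance = provenance),
            class = "pore_clip")
}

clip_apply_rotation <- function(clip, axis, degrees) {
  clip$rot <- rot3_axis(axis, degrees) %*% clip$rot
  clip$applied_rotations <- c(clip$applied_rotations,
                              list(list(axis = axis, degrees = degrees)))
  clip$grid <- resample_rotated(clip$base, clip$rot)
  clip
}

#' @export
print.pore_clip <- function(x, ...) {
  d <- dim(x$base)
  cat(sprintf("<pore_clip> %d x %d x %d voxels at %.3g nm, center (%g, %g, %g) nm\n",
              d[1], d[2], d[3], x$base$voxel_size[1],
              x$center[1], x$center[2], x$center[3]))
  if (length(x$applied_rotations)) {
    for (r in x$applied_rotations)
      cat(sprintf("  rotated %+.2f deg about %s\n", r$degrees, r$axis))
  } else cat("  no rotations applied\n")
  if (x$perpendicular) cat("  in perpendicular view\n")
  invisible(x)
}

#' Extract a 3D clip around a nuclear pore
#'
#' Crops a cube of half-extent `half_extent_nm` around `center_nm` from the
#' volume, after binning the volume by `bin_factor` (the working grid is
#' ~3 nm voxels) and windowing to 8 bit. A pore whose clip extends outside
#' the volume is not completely enclosed and raises an error.
#'
#' @param volume a [voxel_grid()].
#' @param center_nm (z, y, x) nm.
#' @param half_extent_nm clip half extent, nm; must allow the pore plus a
#'   margin of at least twice the rim diameter.
#' @param bin_factor binning applied to the whole volume before cropping
#'   (default 4, per the working-resolution protocol; use 1 for volumes
#'   already at working resolution).
#' @param window percentile window for [to_uint8()].
#' @param provenance identifier of the source volume.
#' @return a `pore_clip`.
#' @export
extract_clip <- function(volume, center_nm, half_extent_nm,
                         bin_factor = 4, window = c(0.5, 99.5),
                         provenance = "volume") {
  stopifnot(inherits(volume, "voxel_grid"))
  if (bin_factor > 1) volume <- bin_volume(volume, bin_factor)
  volume <- to_uint8(volume, window[1], window[2])
  lo_idx <- (center_nm - half_extent_nm - volume$origin) / volume$voxel_size + 1
  hi_idx <- (center_nm + half_extent_nm - volume$origin) / volume$voxel_size + 1
  lo <- ceiling(lo_idx - 1e-9)
  hi <- floor(hi_idx + 1e-9)
  d <- dim(volume)
  if (any(lo < 1) || any(hi > d))
    stop("pore not completely enclosed: clip extends outside the volume")
  sub <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  base <- voxel_grid(sub, volume$voxel_size,
                     origin = volume$origin + (lo - 1) * volume$voxel_size)
  new_pore_clip(base, center_nm, provenance)
}

#' Align the envelope membranes to the x axis
#'
#' Estimates the dominant planar dark structure from the principal axes of
#' below-threshold (Otsu) voxels and rotates the clip about z so the
#' membrane normal has no x component: the membranes then run along x and
#' the remaining tilt lies in the y-z plane, where the en-face search
#' operates. Errors when no planar structure is detectable.
#'
#' @param clip a `pore_clip`.
#' @param planarity_max maximum allowed ratio of the smallest to middle
#'   principal-axis eigenvalue (default 0.35); above it the dark voxels are
#'   not plate-like.
#' @return the rotated `pore_clip`; the applied rotation is recorded.
#' @export
align_envelope_to_x <- function(clip, planarity_max = 0.35) {
  stopifnot(inherits(clip, "pore_clip"))
  g <- clip$grid
  thr <- threshold_otsu(g$data)
  idx <- which(g$data < thr)
  if (length(idx) < 30) stop("no planar structure detectable: too few dark voxels")
  d <- dim(g)
  iz <- ((idx - 1) %% d[1]) + 1
  iy <- ((idx - 1) %/% d[1]) %% d[2] + 1
  ix <- ((idx - 1) %/% (d[1] * d[2])) + 1
  P <- cbind(x = (ix - 1) * g$voxel_size[3],
             y = (iy - 1) * g$voxel_size[2],
             z = (iz - 1) * g$voxel_size[1])
  ev <- eigen(stats::cov(P), symmetric = TRUE)
  if (ev$values[3] / ev$values[2] > planarity_max)
    stop("no planar structure detectable: planarity score below threshold")
  n <- ev$vectors[, 3]                     # (x, y, z) membrane normal
  if (n[2] < 0) n <- -n
  ang <- atan2(n[1], n[2]) * 180 / pi      # rotation about z zeroing n_x
  if (abs(ang) < 0.05) {
    # identity within measurement resolution: record and keep the base view
    clip$applied_rotations <- c(clip$applied_rotations,
                                list(list(axis = "z", degrees = 0)))
    return(clip)
  }
  clip_apply_rotation(clip, "z", ang)
}

#' Search for the en-face angle of a pore
#'
#' Rotates the aligned clip about the x axis over a `step_deg` grid covering
#' [0, 180) and projects a central slab along the membrane-normal (y) axis.
#' At each angle the pore aperture -- the bright region fully enclosed by
#' dark membrane in the minimum-intensity projection, i.e. the set of
#' viewing paths that traverse the channel unobstructed -- is extracted by
#' Otsu thresholding. The aperture is largest and roundest exactly en face,
#' and its area falls off steeply with residual tilt, so the returned angle
#' maximizes the aperture area (ties broken toward the smaller angle); the
#' isoperimetric circularity 4*pi*A/P^2 of the aperture is reported
#' alongside in the profile. (Circularity alone is nearly invariant under
#' small foreshortening at the working voxel size and cannot resolve the
#' optimum; see the methods vignette.)
#'
#' For a phantom tilted by t about x the recovered angle is t to within half
#' the grid step.
#'
#' @param clip an aligned `pore_clip`.
#' @param step_deg grid step, default 10 (the protocol's increment).
#' @param slab_half_nm half thickness of the projected slab, default 30.
#' @param refine when TRUE, a 1-degree local refinement around the grid
#'   optimum is appended (off by default so the default behavior is the
#'   10-degree protocol).
#' @return list: `angle` (degrees, modulo 180), `profile` (data frame
#'   `angle_deg`, `aperture_area_nm2`, `circularity`).
#' @export
find_en_face_angle <- function(clip, step_deg = 10, slab_half_nm = 30,
                               refine = FALSE) {
  stopifnot(inherits(clip, "pore_clip"))
  angles <- seq(0, 180 - step_deg, by = step_deg)
  sc <- vapply(angles, function(a) en_face_score(clip, a, slab_half_nm),
               c(area = 0, circularity = 0))
  if (all(is.na(sc["area", ]))) stop("no enclosed lumen found at any angle")
  score <- sc["area", ]
  score[is.na(score)] <- -Inf
  best <- angles[which.max(score)]       # which.max takes the first maximum
  if (refine) {
    fine <- seq(best - step_deg + 1, best + step_deg - 1, by = 1)
    cf <- vapply(fine, function(a)
      en_face_score(clip, a %% 180, slab_half_nm)["area"], 0)
    if (!all(is.na(cf))) best <- (fine[which.max(cf)]) %% 180
  }
  px <- clip$base$voxel_size[1] * clip$base$voxel_size[3]
  list(angle = best %% 180,
       profile = data.frame(angle_deg = angles,
                            aperture_area_nm2 = sc["area", ] * px,
                            circularity = sc["circularity", ]))
}

en_face_score <- function(clip, angle, slab_half_nm) {
  R <- rot3_x(-angle) %*% clip$rot
  img <- project_slab_y(clip$base, R, slab_half_nm, stat = "min")
  mask <- enclosed_bright_mask(img)
  if (is.null(mask)) return(c(area = NA_real_, circularity = NA_real_))
  c(area = sum(mask), circularity = circularity_of_mask(mask))
}

#' Rotate a clip back to the perpendicular view
#'
#' From the en-face angle, the clip is rotated back by 90 degrees about x so
#' the pore axis lies along the viewing stack and the membranes appear as
#' two dark bands, interrupted by the pore, in the central axial slice.
#' Applying the operation twice is flagged as misuse.
#'
#' @param clip a `pore_clip`.
#' @param en_face_angle degrees from [find_en_face_angle()].
#' @return the rotated `pore_clip` with `perpendicular = TRUE`.
#' @export
to_perpendicular_view <- function(clip, en_face_angle) {
  stopifnot(inherits(clip, "pore_clip"))
  if (clip$perpendicular)
    stop("clip is already in perpendicular view: to_perpendicular_view applied twice")
  net <- en_face_angle - 90
  if (abs(net) < 1e-9) {
    clip$applied_rotations <- c(clip$applied_rotations,
                                list(list(axis = "x", degrees = 0)))
  } else {
    clip <- clip_apply_rotation(clip, "x", -net)
  }
  clip$perpendicular <- TRUE
  clip$en_face_angle <- en_face_angle %% 180
  clip
}

#' Measure rim diameters and pore diameter in the perpendicular view
#'
#' In the perpendicular view the membranes are two dark bands normal to the
#' clip's z axis. The measurement follows the protocol: (1) find the depth
#' (y slice) where the pore lumen is widest; (2) trace the two membrane
#' center-lines on that slice as intensity minima along each column
#' (quadratic sub-voxel refinement); (3) on each side i/ii of the pore,
#' follow the midline separation d(s) outward from the pore axis and take
#' the rim diameter as d at the first point where |dd/ds| stays below
#' `parallel_tol` over a `parallel_window_nm` run ("just become parallel");
#' (4) the pore diameter is the distance between the membrane-junction
#' points across the lumen; (5) kappa = 2/RD per side.
#'
#' @param clip a `pore_clip` in perpendicular view.
#' @param parallel_tol dimensionless slope threshold, default 0.05.
#' @param parallel_window_nm run length over which the slope must stay flat,
#'   default 15 nm.
#' @param pore_id identifier copied into the output row.
#' @return one-row data frame of class `pore_measurement`: `pore_id`,
#'   `en_face_angle_deg`, `rim_d_i_nm`, `rim_d_ii_nm`, `pore_d_nm`,
#'   `kappa_i_invnm`, `kappa_ii_invnm`, `qc_flags`.
#' @export
measure_rim_and_pore <- function(clip, parallel_tol = 0.05,
                                 parallel_window_nm = 15, pore_id = 1L) {
  stopifnot(inherits(clip, "pore_clip"))
  if (!clip$perpendicular)
    stop("clip must be in perpendicular view (run to_perpendicular_view)")
  g <- clip$grid
  d <- dim(g)
  vx <- g$voxel_size
  thr <- threshold_otsu(g$data)

  # (1) depth search: lumen width per y slice = widest central run of
  # columns with no dark voxel along z
  yc <- round(d[2] / 2)
  search <- max(2L, round(d[2] / 4))
  ys <- max(1, yc - search):min(d[2], yc + search)
  widths <- vapply(ys, function(iy) {
    sl <- g$data[, iy, ]                       # nz x nx
    lumen_run_length(colSums(sl < thr) == 0)
  }, 0)
  if (all(widths == 0)) stop("no pore: membranes are uninterrupted")
  y_star <- ys[which.max(widths)]

  # (2) membrane center-lines on the chosen slice (average 3 slices for
  # noise robustness)
  ysl <- intersect((y_star - 1):(y_star + 1), seq_len(d[2]))
  sl <- apply(g$data[, ysl, , drop = FALSE], c(1, 3), mean)  # nz x nx
  minima <- trace_membranes(sl, thr)
  has_mem <- !is.na(minima$z_lo)

  lum <- lumen_run(colSums(sl < thr) == 0)
  if (is.null(lum)) stop("no pore: membranes are uninterrupted")
  x0 <- mean(lum) * vx[3]                      # pore axis (nm, 1-based idx)

  qc <- character(0)
  # contiguous membrane run walking outward from the lumen on each side;
  # columns beyond a break (e.g. outside the rotated cube's valid region)
  # are not trusted
  contiguous_out <- function(from, step) {
    j <- from
    # skip the junction zone where the two midlines have merged into one
    while (j >= 1 && j <= d[3] && !has_mem[j]) j <- j + step
    cols <- integer(0)
    while (j >= 1 && j <= d[3] && has_mem[j]) {
      cols <- c(cols, j)
      j <- j + step
    }
    cols
  }
  sides <- list(i = contiguous_out(lum[1] - 1L, -1L),
                ii = contiguous_out(lum[2] + 1L, 1L))
  rim <- c(i = NA_real_, ii = NA_real_)
  for (nm in names(sides)) {
    cols <- sides[[nm]]
    if (length(cols) < 3) { qc <- c(qc, paste0("no_membrane_", nm)); next }
    s <- abs(cols * vx[3] - x0)
    o <- order(s)
    s <- s[o]
    dsep <- (minima$z_hi[cols] - minima$z_lo[cols])[o] * vx[1]
    if (length(dsep) >= 3) dsep <- stats::runmed(dsep, 3)
    rim_v <- rim_from_profile(s, dsep, parallel_tol, parallel_window_nm)
    if (is.na(rim_v)) qc <- c(qc, paste0("no_plateau_", nm))
    rim[nm] <- rim_v
  }

  # (4) junction points: innermost membrane-bearing column on each side
  left <- max(which(has_mem & seq_len(d[3]) < lum[1]), -Inf)
  right <- min(which(has_mem & seq_len(d[3]) > lum[2]), Inf)
  pore_d <- if (is.finite(left) && is.finite(right))
    (right - left) * vx[3] else NA_real_

  res <- data.frame(
    pore_id = pore_id,
    en_face_angle_deg = if (is.null(clip$en_face_angle)) NA_real_
                        else clip$en_face_angle,
    rim_d_i_nm = rim[["i"]], rim_d_ii_nm = rim[["ii"]],
    pore_d_nm = pore_d,
    kappa_i_invnm = 2 / rim[["i"]], kappa_ii_invnm = 2 / rim[["ii"]],
    qc_flags = paste(qc, collapse = ";"))
  class(res) <- c("pore_measurement", "data.frame")
  res
}

# longest run of TRUE (no-membrane columns) not touching the vector ends
lumen_run <- function(open) {
  n <- length(open)
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & starts > 1 & ends < n)
  if (!length(cand)) return(NULL)
  k <- cand[which.max(r$lengths[cand])]
  c(starts[k], ends[k])
}

lumen_run_length <- function(open) {
  run <- lumen_run(open)
  if (is.null(run)) 0 else run[2] - run[1] + 1
}

# For each column of a (nz x nx) slice, locate the two membrane dark-band
# centers as sub-voxel intensity minima below thr, one on each side of the
# mid-plane estimated from the detected minima.
trace_membranes <- function(sl, thr) {
  nz <- nrow(sl); nx <- ncol(sl)
  z_lo <- rep(NA_real_, nx); z_hi <- rep(NA_real_, nx)
  all_min <- vector("list", nx)
  for (j in seq_len(nx)) {
    p <- sl[, j]
    im <- which(p[2:(nz - 1)] <= p[1:(nz - 2)] &
                p[2:(nz - 1)] <= p[3:nz] &
                p[2:(nz - 1)] < thr) + 1
    if (length(im) > 1) {
      # merge plateaus/adjacent minima: keep local minima separated by > 2 px
      keep <- c(TRUE, diff(im) > 2)
      im <- im[keep]
    }
    all_min[[j]] <- im
  }
  mids <- unlist(all_min)
  if (!length(mids)) return(list(z_lo = z_lo, z_hi = z_hi))
  z_mid <- (min(mids) + max(mids)) / 2
  for (j in seq_len(nx)) {
    im <- all_min[[j]]
    lo <- im[im < z_mid]; hi <- im[im >= z_mid]
    if (!length(lo) || !length(hi)) next
    p <- sl[, j]
    lo <- lo[which.min(p[lo])]; hi <- hi[which.min(p[hi])]
    z_lo[j] <- refine_min(p, lo)
    z_hi[j] <- refine_min(p, hi)
  }
  list(z_lo = z_lo, z_hi = z_hi)
}

# quadratic sub-voxel refinement of a discrete minimum
refine_min <- function(p, i) {
  if (i <= 1 || i >= length(p)) return(as.numeric(i))
  a <- p[i - 1]; b <- p[i]; c_ <- p[i + 1]
  den <- a - 2 * b + c_
  if (den <= 0) return(as.numeric(i))
  i + 0.5 * (a - c_) / den
}

# first s where the least-squares slope of d(s) over the following
# window_nm run stays below tol ("just become parallel"); the fitted slope
# averages out per-column trace noise that per-step differences would
# amplify
rim_from_profile <- function(s, dsep, tol, window_nm) {
  n <- length(s)
  if (n < 3) return(NA_real_)
  for (i in seq_len(n - 2)) {
    idx <- which(s >= s[i] & s <= s[i] + window_nm)
    if (length(idx) < 3) next
    if (max(s[idx]) - s[i] < 0.8 * window_nm) next
    sl <- stats::cov(s[idx], dsep[idx]) / stats::var(s[idx])
    if (abs(sl) < tol) return(dsep[i])
  }
  NA_real_
}

#' Check measurements for dependence on the en-face angle
#'
#' Pearson correlation (two-sided) of the en-face angle with the per-pore
#' mean rim diameter and with the pore diameter, used as a QC gate against
#' anisotropic section-shrinkage bias, not as a correction.
#'
#' @param measurements data frame of pore measurements (>= 3 rows with
#'   distinct angles).
#' @return named list: `r_rim`, `p_rim`, `r_pore`, `p_pore`;
#'   zero variance in a variable yields NA with a `degenerate` flag.
#' @export
angle_bias_check <- function(measurements) {
  m <- measurements
  if (nrow(m) < 3 || length(unique(m$en_face_angle_deg)) < 3)
    stop("need >= 3 measurements with distinct angles")
  rim <- rowMeans(cbind(m$rim_d_i_nm, m$rim_d_ii_nm), na.rm = TRUE)
  ang <- m$en_face_angle_deg
  one <- function(v) {
    if (sd(v, na.rm = TRUE) == 0 || sd(ang) == 0)
      return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
    ct <- cor.test(ang, v, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
  }
  a <- one(rim); b <- one(m$pore_d_nm)
  list(r_rim = a$r, p_rim = a$p, r_pore = b$r, p_pore = b$p,
       degenerate = a$degenerate || b$degenerate)
}

#' Run the full rim-curvature pipeline on one pore
#'
#' Chains [extract_clip()], [align_envelope_to_x()],
#' [find_en_face_angle()], [to_perpendicular_view()] and
#' [measure_rim_and_pore()]. Failures at any stage yield an NA row with the
#' stage recorded in `qc_flags` rather than an error, so batch runs
#' complete.
#'
#' @param volume a [voxel_grid()].
#' @param center_nm pore center (z, y, x) nm.
#' @param half_extent_nm clip half extent, default 120.
#' @param bin_factor see [extract_clip()]; default 1 (volume already at
#'   working resolution).
#' @param step_deg en-face grid step, default 10.
#' @param pore_id identifier for the output row.
#' @param ... passed to [measure_rim_and_pore()].
#' @return one-row `pore_measurement` data frame.
#' @export
run_pore_pipeline <- function(volume, center_nm, half_extent_nm = 120,
                              bin_factor = 1, step_deg = 10, pore_id = 1L,
                              ...) {
  fail <- function(stage) {
    res <- data.frame(pore_id = pore_id, en_face_angle_deg = NA_real_,
                      rim_d_i_nm = NA_real_, rim_d_ii_nm = NA_real_,
                      pore_d_nm = NA_real_, kappa_i_invnm = NA_real_,
                      kappa_ii_invnm = NA_real_,
                      qc_flags = paste0("failed_", stage))
    class(res) <- c("pore_measurement", "data.frame")
    res
  }
  clip <- tryCatch(extract_clip(volume, center_nm, half_extent_nm,
                                bin_factor = bin_factor),
                   error = function(e) NULL)
  if (is.null(clip)) return(fail("extract"))
  clip <- tryCatch(align_envelope_to_x(clip), error = function(e) NULL)
  if (is.null(clip)) return(fail("align"))
  ef <- tryCatch(find_en_face_angle(clip, step_deg = step_deg),
                 error = function(e) NULL)
  if (is.null(ef)) return(fail("en_face"))
  clip <- to_perpendicular_view(clip, ef$angle)
  tryCatch(measure_rim_and_pore(clip, pore_id = pore_id, ...),
           error = function(e) fail("measure"))
}

#' Phantom-based rim-curvature recovery study
#'
#' Generates `n` single-pore phantoms with the stated true rim and pore
#' diameters at random tilts, runs the full clip-rotate-measure pipeline on
#' each, and returns per-pore measurements next to the truth. Each pore
#' contributes two rim-diameter values (sides i and ii) downstream unless
#' per-pore averaging is chosen.
#'
#' @param n number of pores.
#' @param rim_diameter,pore_diameter true values, nm.
#' @param tilt_max tilts are drawn uniformly from \[0, tilt_max\] degrees.
#' @param seed integer; drives tilts and rendering noise.
#' @param voxel_size working voxel, default 3 nm isotropic.
#' @param noise_sd rendering noise, default 10.
#' @param step_deg en-face grid step, default 10.
#' @param per_pore_average when TRUE, `kappa` holds one value per pore (the
#'   mean of sides i and ii) instead of both sides as separate data points.
#' @return list: `measurements` (n rows), `kappa` (per-side curvature
#'   values, NA dropped), `truth` (tilts etc.).
#' @export
simulate_pore_study <- function(n, rim_diameter, pore_diameter = 80,
                                tilt_max = 40, seed = 1L, voxel_size = 3,
                                noise_sd = 10, step_deg = 10,
                                per_pore_average = FALSE) {
  with_scene_seed(seed, {
    tilts <- runif(n, 0, tilt_max)
    seeds <- sample.int(1e6, n)
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      spec <- scene_spec(volume_shape = c(120, 120, 120),
                         voxel_size = voxel_size,
                         pore_specs = list(list(rim_diameter = rim_diameter,
                                                pore_diameter = pore_diameter,
                                                tilt_deg = tilts[k])),
                         noise_sd = noise_sd, seed = seeds[k])
      ph <- make_pore_volume(spec)
      ctr <- as.numeric(ph$truth[1, c("z_nm", "y_nm", "x_nm")])
      rows[[k]] <- run_pore_pipeline(ph$volume, ctr, pore_id = k,
                                     step_deg = step_deg)
    }
    meas <- do.call(rbind, rows)
    meas$true_tilt_deg <- tilts
    kap <- if (per_pore_average) {
      rowMeans(cbind(meas$kappa_i_invnm, meas$kappa_ii_invnm), na.rm = TRUE)
    } else {
      c(meas$kappa_i_invnm, meas$kappa_ii_invnm)
    }
    list(measurements = meas, kappa = kap[!is.na(kap)],
         truth = data.frame(pore_id = seq_len(n), tilt_deg = tilts,
                            rim_diameter_nm = rim_diameter,
                            pore_diameter_nm = pore_diameter))
  })
}
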