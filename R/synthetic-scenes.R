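#' Specification of a synthetic EM phantom scene
#'
#' Collects the geometric and imaging parameters for the two phantom
#' families: telophase-like scenes (an NE double-membrane sheet with gaps and
#' perinuclear vesicles, SBF-SEM-like contrast) and nuclear-pore tomogram
#' clips (a toroidal-rim pore at known tilt). Membranes render dark on a
#' bright background; Gaussian blur and additive Gaussian noise emulate the
#' imaging chain.
#'
#' Defaults encode the rendered study conditions: 7 nm dark-band membranes,
#' 40 nm inner-outer midline spacing away from pores, vesicle diameters
#' Normal(57, 8) nm truncated below, and vesicle centers placed 100-1000 nm
#' from the NE sheet so vicinity statistics are exercised.
#'
#' @param volume_shape (nz, ny, nx) voxels.
#' @param voxel_size (z, y, x) nm, or one number for isotropic voxels.
#' @param membrane_thickness rendered dark-band width (FWHM), nm.
#' @param perinuclear_spacing inner-outer membrane midline separation away
#'   from pores, nm (telophase scenes).
#' @param vesicle_count number of vesicles to place.
#' @param vesicle_diameter_mean,vesicle_diameter_sd nm, truth distribution.
#' @param vesicle_diameter_min truncation bound for diameters, nm; must stay
#'   above twice the membrane thickness so shells are renderable.
#' @param vesicle_distance_range (min, max) nm distance of vesicle centers
#'   from the NE sheet midplane.
#' @param gap_specs list of `list(dx =, dz =, center = c(x, z))` in nm:
#'   rectangular NE discontinuities.
#' @param pore_specs list of `list(rim_diameter =, pore_diameter =,
#'   tilt_deg =, azimuth_deg =)`; rim and pore diameter are independent
#'   parameters.
#' @param tortuosity_amp,tortuosity_wavelength gentle sheet undulation, nm.
#' @param background,membrane_contrast intensity units: bright background
#'   level and depth of the membrane dark band.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param blur_sigma isotropic Gaussian blur, nm.
#' @param seed integer; a fixed seed gives byte-identical output.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(volume_shape = c(120, 300, 300),
                       voxel_size = c(50, 4.5, 4.5),
                       membrane_thickness = 7,
                       perinuclear_spacing = 40,
                       vesicle_count = 0,
                       vesicle_diameter_mean = 57,
                       vesicle_diameter_sd = 8,
                       vesicle_diameter_min = NULL,
                       vesicle_distance_range = c(100, 1000),
                       gap_specs = list(),
                       pore_specs = list(),
                       tortuosity_amp = 15,
                       tortuosity_wavelength = 900,
                       background = 200,
                       membrane_contrast = 140,
                       noise_sd = 10,
                       blur_sigma = 1.5,
                       seed = 1L) {
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (is.null(vesicle_diameter_min))
    vesicle_diameter_min <- 2 * membrane_thickness
  if (vesicle_diameter_min <= 2 * membrane_thickness - 1e-9)
    stop("vesicle diameters must exceed twice the membrane thickness")
  for (p in pore_specs) {
    if (is.null(p$rim_diameter) || p$rim_diameter <= 0)
      stop("pore rim_diameter must be > 0")
    if (is.null(p$pore_diameter) || p$pore_diameter <= 0)
      stop("pore pore_diameter must be > 0")
  }
  structure(list(
    volume_shape = as.integer(volume_shape), voxel_size = voxel_size,
    membrane_thickness = membrane_thickness,
    perinuclear_spacing = perinuclear_spacing,
    vesicle_count = as.integer(vesicle_count),
    vesicle_diameter_mean = vesicle_diameter_mean,
    vesicle_diameter_sd = vesicle_diameter_sd,
    vesicle_diameter_min = vesicle_diameter_min,
    vesicle_distance_range = vesicle_distance_range,
    gap_specs = gap_specs, pore_specs = pore_specs,
    tortuosity_amp = tortuosity_amp,
    tortuosity_wavelength = tortuosity_wavelength,
    background = background, membrane_contrast = membrane_contrast,
    noise_sd = noise_sd, blur_sigma = blur_sigma, seed = as.integer(seed)),
    class = "scene_spec")
}

#' Read a scene specification from YAML
#' @param path YAML file whose keys match the [scene_spec()] arguments.
#' @return a `scene_spec`.
#' @export
read_scene_config <- function(path) {
  do.call(scene_spec, yaml::read_yaml(path))
}

with_scene_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Draw vesicle diameters from a truncated normal distribution
#'
#' Rejection sampling from Normal(mean, sd) truncated below at `lower`;
#' reproducible for a fixed seed.
#'
#' @param n number of draws (>= 0).
#' @param mean,sd nm; `mean` must be positive, `sd` nonnegative.
#' @param lower truncation bound, nm (diameters must exceed it).
#' @param seed optional integer; when NULL the current RNG stream is used.
#' @return numeric vector of n diameters in nm.
#' @export
sample_diameters <- function(n, mean, sd, lower = 14, seed = NULL) {
  if (n < 0) stop("'n' must be >= 0")
  if (mean <= 0) stop("'mean' must be positive")
  if (sd < 0) stop("'sd' must be >= 0")
  draw <- function() {
    if (n == 0) return(numeric(0))
    if (sd == 0) {
      if (mean <= lower) stop("degenerate draw below truncation bound")
      return(rep(mean, n))
    }
    out <- numeric(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- rnorm(2L * (n - length(out)), mean, sd)
      out <- c(out, cand[cand > lower])
      tries <- tries + 1L
      if (tries > 1000L) stop("truncation bound rejects nearly all draws")
    }
    out[seq_len(n)]
  }
  if (is.null(seed)) draw() else with_scene_seed(seed, draw())
}

# Sheet midplane height y(x, z) in nm: gently undulating around the volume
# center.
sheet_midplane <- function(spec, x, z) {
  ymid <- (spec$volume_shape[2] - 1) / 2 * spec$voxel_size[2]
  if (spec$tortuosity_amp <= 0) return(ymid + 0 * x)
  ymid + spec$tortuosity_amp *
    sin(2 * pi * x / spec$tortuosity_wavelength) *
    cos(2 * pi * z / spec$tortuosity_wavelength)
}

#' Generate a telophase-like phantom scene
#'
#' Renders an NE double-membrane sheet (two dark bands `perinuclear_spacing`
#' apart) with rectangular discontinuities realizing each gap spec, plus
#' spherical vesicle shells at random positions within the configured
#' distance range of the sheet. Labels (NE = 1, vesicle = 2; membrane voxels
#' only) and intensity are mutually consistent, and the returned ground
#' truth has one record per rendered object.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `volume` ([voxel_grid()]), `labels`
#'   ([label_volume()]) and `truth` (list of data frames `vesicles`, `gaps`).
#' @export
make_telophase_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, render_telophase(spec))
}

render_telophase <- function(spec) {
  d <- spec$volume_shape
  vx <- spec$voxel_size
  half_th <- spec$membrane_thickness / 2
  labels <- array(0L, dim = d)
  dark <- array(0, dim = d)     # membrane darkening field, 0..1

  xs <- (seq_len(d[3]) - 1) * vx[3]
  ys <- (seq_len(d[2]) - 1) * vx[2]
  zs <- (seq_len(d[1]) - 1) * vx[1]

  # NE sheet: per z-slice, vectorized over the (y, x) plane.
  gap_mask_xz <- function(x, z) {
    drop_it <- rep(FALSE, length(x))
    for (g in spec$gap_specs) {
      drop_it <- drop_it |
        (abs(x - g$center[1]) < g$dx / 2 & abs(z - g$center[2]) < g$dz / 2)
    }
    drop_it
  }
  for (iz in seq_len(d[1])) {
    mid <- sheet_midplane(spec, xs, zs[iz])         # length nx
    open_col <- gap_mask_xz(xs, rep(zs[iz], d[3]))
    for (s in c(-1, 1)) {
      surf <- mid + s * spec$perinuclear_spacing / 2
      # distance of each (y, x) voxel center to this membrane midline
      dist <- abs(outer(ys, surf, `-`))             # ny x nx
      memb <- dist <= half_th
      memb[, open_col] <- FALSE
      labels[iz, , ][memb] <- 1L
      prof <- exp(-dist^2 / (2 * (half_th / 1.1775)^2))   # FWHM = thickness
      prof[, open_col] <- 0
      dark[iz, , ] <- pmax(dark[iz, , ], prof)
    }
  }

  # Vesicles: dart-throwing placement within the stated distance band of the
  # sheet, no overlap between vesicles, then shell rendering.
  nv <- spec$vesicle_count
  truth_ves <- data.frame(id = integer(0), z_nm = numeric(0),
                          y_nm = numeric(0), x_nm = numeric(0),
                          diameter_nm = numeric(0))
  if (nv > 0) {
    diam <- sample_diameters(nv, spec$vesicle_diameter_mean,
                             spec$vesicle_diameter_sd,
                             lower = spec$vesicle_diameter_min)
    ext <- (d - 1) * vx
    rng <- spec$vesicle_distance_range
    centers <- matrix(NA_real_, nv, 3)              # (z, y, x) nm
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * nv
    while (placed < nv) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("infeasible packing: could not place ", nv,
             " vesicles after ", max_attempts, " attempts")
      r <- diam[placed + 1L] / 2
      cz <- runif(1, r, ext[1] - r)
      cx <- runif(1, r, ext[3] - r)
      side <- sample(c(-1, 1), 1)
      offs <- runif(1, rng[1], rng[2])
      cy <- sheet_midplane(spec, cx, cz) + side * offs
      if (cy < r || cy > ext[2] - r) next
      if (offs - r < spec$perinuclear_spacing / 2 + half_th) next
      if (placed > 0) {
        dz <- abs(centers[seq_len(placed), 1] - cz)
        dy <- abs(centers[seq_len(placed), 2] - cy)
        dx <- abs(centers[seq_len(placed), 3] - cx)
        # rasterized shells cannot merge under 26-connectivity when the
        # voxel-dilated bounding boxes clear each other on some axis
        rsum <- (diam[seq_len(placed)] + diam[placed + 1L]) / 2
        clear <- dz >= rsum + 2 * vx[1] + 2 |
                 dy >= rsum + 2 * vx[2] + 2 |
                 dx >= rsum + 2 * vx[3] + 2
        if (!all(clear)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cz, cy, cx)
    }
    # shell rendering inlined: routing the full arrays through a helper
    # would copy them once per vesicle
    for (i in seq_len(nv)) {
      center <- centers[i, ]; radius <- diam[i] / 2
      lo <- pmax(1L, floor((center - radius - 2 * half_th) / vx) + 1L)
      hi <- pmin(d, ceiling((center + radius + 2 * half_th) / vx) + 1L)
      iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
      zz <- (iz - 1) * vx[1] - center[1]
      yy <- (iy - 1) * vx[2] - center[2]
      xx <- (ix - 1) * vx[3] - center[3]
      # the stated diameter is the outer diameter: the membrane band
      # occupies [radius - thickness, radius] so the bounding box matches
      sdist <- abs(sqrt(outer(outer(zz^2, yy^2, `+`), xx^2, `+`)) -
                     (radius - half_th))
      sub <- labels[iz, iy, ix, drop = FALSE]
      sub[sdist <= half_th] <- 2L
      labels[iz, iy, ix] <- sub
      dark[iz, iy, ix] <- pmax(dark[iz, iy, ix, drop = FALSE],
                               exp(-sdist^2 / (2 * (half_th / 1.1775)^2)))
    }
    truth_ves <- data.frame(id = seq_len(nv), z_nm = centers[, 1],
                            y_nm = centers[, 2], x_nm = centers[, 3],
                            diameter_nm = diam)
  }

  truth_gaps <- if (length(spec$gap_specs)) {
    do.call(rbind, lapply(seq_along(spec$gap_specs), function(i) {
      g <- spec$gap_specs[[i]]
      data.frame(id = i, x_nm = g$center[1], z_nm = g$center[2],
                 dx_nm = g$dx, dz_nm = g$dz, area_nm2 = g$dx * g$dz)
    }))
  } else {
    data.frame(id = integer(0), x_nm = numeric(0), z_nm = numeric(0),
               dx_nm = numeric(0), dz_nm = numeric(0), area_nm2 = numeric(0))
  }

  vol <- spec$background - spec$membrane_contrast * pmin(dark, 1)
  if (spec$blur_sigma > 0)
    vol <- gauss_blur3(vol, spec$blur_sigma / vx)
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim = d)

  list(volume = voxel_grid(vol, vx),
       labels = label_volume(labels, vx, legend = c(NE = 1L, vesicle = 2L)),
       truth = list(vesicles = truth_ves, gaps = truth_gaps))
}


#' Generate a nuclear-pore tomogram phantom
#'
#' Renders one nuclear pore: two flat membrane midplanes separated by the
#' rim diameter, joined through a half-toroidal rim around a circular
#' fenestration of the stated pore diameter, the whole envelope rotated by
#' `tilt_deg` about x and `azimuth_deg` about z before rasterization.
#' Membranes are dark on a bright background; Gaussian blur and additive
#' noise follow. The spec must contain exactly one pore.
#'
#' The ground-truth en-face angle equals the tilt (modulo 180): the en-face
#' rotation search recovers it directly.
#'
#' @param spec a [scene_spec()] with one entry in `pore_specs`. An isotropic
#'   ~3 nm voxel and a cubic volume are the intended regime.
#' @return list with `volume` ([voxel_grid()]) and `truth` (one-row data
#'   frame: center, rim/pore diameter, tilt, azimuth, en_face_angle_deg and a
#'   `subresolution` flag set when the rim diameter is below the voxel size).
#' @export
make_pore_volume <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (length(spec$pore_specs) == 0) stop("pore_specs must be nonempty")
  if (length(spec$pore_specs) > 1)
    stop("one pore per phantom volume; call once per pore spec")
  with_scene_seed(spec$seed, render_pore(spec))
}

render_pore <- function(spec) {
  p <- spec$pore_specs[[1]]
  d <- spec$volume_shape
  vx <- spec$voxel_size
  rd <- p$rim_diameter
  pd <- p$pore_diameter
  tilt <- if (is.null(p$tilt_deg)) 0 else p$tilt_deg
  az <- if (is.null(p$azimuth_deg)) 0 else p$azimuth_deg
  r_c <- (pd + rd) / 2                       # rim-tube center circle radius
  ext <- (d - 1) * vx
  if (2 * r_c + rd > min(ext)) stop("pore larger than volume")
  subres <- rd < max(vx)
  if (subres)
    warning("rim diameter below voxel size: pore is unresolvable")

  ctr <- ext / 2                             # (z, y, x) nm
  zz <- (seq_len(d[1]) - 1) * vx[1] - ctr[1]
  yy <- (seq_len(d[2]) - 1) * vx[2] - ctr[2]
  xx <- (seq_len(d[3]) - 1) * vx[3] - ctr[3]
  Z <- rep(zz, times = d[2] * d[3])
  Y <- rep(rep(yy, each = d[1]), times = d[3])
  X <- rep(xx, each = d[1] * d[2])
  # envelope frame coordinates: q = R^T p with R = Rz(az) %*% Rx(tilt)
  R <- rot3_z(az) %*% rot3_x(tilt)
  Rt <- t(R)
  qx <- Rt[1, 1] * X + Rt[1, 2] * Y + Rt[1, 3] * Z
  qy <- Rt[2, 1] * X + Rt[2, 2] * Y + Rt[2, 3] * Z
  qz <- Rt[3, 1] * X + Rt[3, 2] * Y + Rt[3, 3] * Z
  rho <- sqrt(qx^2 + qz^2)
  # distance to the membrane midline surface: flat planes at qy = +-rd/2 for
  # rho >= r_c, half-torus (tube radius rd/2) inside
  d_plane <- pmin(abs(qy - rd / 2), abs(qy + rd / 2))
  d_tube <- abs(sqrt((rho - r_c)^2 + qy^2) - rd / 2)
  dist <- ifelse(rho >= r_c, d_plane, d_tube)
  half_th <- spec$membrane_thickness / 2
  dark <- exp(-dist^2 / (2 * (half_th / 1.1775)^2))
  vol <- spec$background - spec$membrane_contrast * dark
  dim(vol) <- d
  if (spec$blur_sigma > 0) vol <- gauss_blur3(vol, spec$blur_sigma / vx)
  if (spec$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim = d)

  truth <- data.frame(
    id = 1L, z_nm = ctr[1], y_nm = ctr[2], x_nm = ctr[3],
    rim_diameter_nm = rd, pore_diameter_nm = pd,
    tilt_deg = tilt, azimuth_deg = az,
    en_face_angle_deg = tilt %% 180,
    subresolution = subres)
  list(volume = voxel_grid(vol, vx), truth = truth)
}
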