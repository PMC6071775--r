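# Internal geometry: rotations are expressed as 3x3 matrices acting on
# column vectors in (x, y, z) order, in nm, about the volume center.
# Array indexing stays (z, y, x); the conversion happens only here.

rot3_x <- function(deg) {
  a <- deg * pi / 180; c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}

rot3_y <- function(deg) {
  a <- deg * pi / 180; c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}

rot3_z <- function(deg) {
  a <- deg * pi / 180; c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

rot3_axis <- function(axis, deg) {
  switch(axis, x = rot3_x(deg), y = rot3_y(deg), z = rot3_z(deg),
         stop("unknown rotation axis: ", axis))
}

# Physical center of a grid (z, y, x) nm: midpoint of the voxel-center lattice.
grid_center <- function(grid) {
  grid$origin + (dim(grid)[1:3] - 1) / 2 * grid$voxel_size
}

# Trilinear interpolation of grid intensities at physical points.
# xs/ys/zs are absolute coordinates in nm; points outside the lattice get
# `fill`.
sample_trilinear <- function(grid, xs, ys, zs, fill = 0) {
  d <- dim(grid$data)
  fz <- (zs - grid$origin[1]) / grid$voxel_size[1] + 1
  fy <- (ys - grid$origin[2]) / grid$voxel_size[2] + 1
  fx <- (xs - grid$origin[3]) / grid$voxel_size[3] + 1
  i0 <- floor(fz); j0 <- floor(fy); k0 <- floor(fx)
  wz <- fz - i0; wy <- fy - j0; wx <- fx - k0
  ok <- i0 >= 1 & i0 < d[1] & j0 >= 1 & j0 < d[2] & k0 >= 1 & k0 < d[3]
  out <- rep(fill, length(fz))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  wz <- wz[ok]; wy <- wy[ok]; wx <- wx[ok]
  v <- as.vector(grid$data)
  base <- i0 + d[1] * (j0 - 1) + d[1] * d[2] * (k0 - 1)
  sz <- 1; sy <- d[1]; sx <- d[1] * d[2]
  c000 <- v[base];                 c100 <- v[base + sz]
  c010 <- v[base + sy];            c110 <- v[base + sy + sz]
  c001 <- v[base + sx];            c101 <- v[base + sx + sz]
  c011 <- v[base + sx + sy];       c111 <- v[base + sx + sy + sz]
  out[ok] <-
    (1 - wx) * ((1 - wy) * ((1 - wz) * c000 + wz * c100) +
                wy * ((1 - wz) * c010 + wz * c110)) +
    wx * ((1 - wy) * ((1 - wz) * c001 + wz * c101) +
          wy * ((1 - wz) * c011 + wz * c111))
  out
}

# Resample a grid under an object rotation R about the grid center:
# output(p) = input(R^T (p - c) + c). Linear interpolation, single resampling.
resample_rotated <- function(grid, R, fill = NULL) {
  d <- dim(grid$data)
  ctr <- grid_center(grid)                        # (z, y, x)
  if (is.null(fill)) fill <- median(border_values(grid$data))
  zc <- voxel_centers(grid, 1) - ctr[1]
  yc <- voxel_centers(grid, 2) - ctr[2]
  xc <- voxel_centers(grid, 3) - ctr[3]
  Z <- rep(zc, times = d[2] * d[3])
  Y <- rep(rep(yc, each = d[1]), times = d[3])
  X <- rep(xc, each = d[1] * d[2])
  Rt <- t(R)
  sx <- Rt[1, 1] * X + Rt[1, 2] * Y + Rt[1, 3] * Z + ctr[3]
  sy <- Rt[2, 1] * X + Rt[2, 2] * Y + Rt[2, 3] * Z + ctr[2]
  sz <- Rt[3, 1] * X + Rt[3, 2] * Y + Rt[3, 3] * Z + ctr[1]
  vals <- sample_trilinear(grid, sx, sy, sz, fill = fill)
  voxel_grid(array(vals, dim = d), grid$voxel_size, grid$origin)
}

# Projection along the y axis of a slab |y - center| <= slab_half, after
# object rotation R. Returns a matrix M[z, x] on the grid's z/x lattice.
# stat "mean" gives the average-density view; "min" keeps only paths that
# stay bright throughout the slab (the fully open aperture).
project_slab_y <- function(grid, R, slab_half, fill = NULL,
                           stat = c("mean", "min")) {
  stat <- match.arg(stat)
  d <- dim(grid$data)
  ctr <- grid_center(grid)
  if (is.null(fill)) fill <- median(border_values(grid$data))
  zc <- voxel_centers(grid, 1) - ctr[1]
  xc <- voxel_centers(grid, 3) - ctr[3]
  ys <- seq(-slab_half, slab_half, by = min(grid$voxel_size))
  npix <- d[1] * d[3]
  Z <- rep(rep(zc, times = d[3]), times = length(ys))
  X <- rep(rep(xc, each = d[1]), times = length(ys))
  Y <- rep(ys, each = npix)
  Rt <- t(R)
  sx <- Rt[1, 1] * X + Rt[1, 2] * Y + Rt[1, 3] * Z + ctr[3]
  sy <- Rt[2, 1] * X + Rt[2, 2] * Y + Rt[2, 3] * Z + ctr[2]
  sz <- Rt[3, 1] * X + Rt[3, 2] * Y + Rt[3, 3] * Z + ctr[1]
  vals <- sample_trilinear(grid, sx, sy, sz, fill = fill)
  dim(vals) <- c(npix, length(ys))
  out <- if (stat == "mean") {
    rowMeans(vals)
  } else {
    Reduce(pmin, lapply(seq_len(ncol(vals)), function(k) vals[, k]))
  }
  matrix(out, d[1], d[3])
}

border_values <- function(a) {
  d <- dim(a)
  c(a[1, , ], a[d[1], , ], a[, 1, ], a[, d[2], ], a[, , 1], a[, , d[3]])
}

# Separable Gaussian blur; sigma in voxels per axis (z, y, x). Truncated at
# 3 sigma with per-row renormalization so edges are not darkened.
gauss_blur3 <- function(a, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s > 1e-6) {
      n <- dim(a)[1]
      r <- max(1L, ceiling(3 * s))
      off <- -r:r
      w <- exp(-off^2 / (2 * s^2))
      K <- matrix(0, n, n)
      idx <- outer(seq_len(n), off, `+`)
      for (m in seq_along(off)) {
        valid <- idx[, m] >= 1 & idx[, m] <= n
        K[cbind(which(valid), idx[valid, m])] <-
          K[cbind(which(valid), idx[valid, m])] + w[m]
      }
      K <- K / rowSums(K)
      da <- dim(a)
      dim(a) <- c(da[1], length(a) / da[1])
      a <- K %*% a
      dim(a) <- da
    }
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

# Otsu threshold on a 256-bin histogram.
threshold_otsu <- function(x, nbins = 256L) {
  r <- range(x)
  if (r[2] <= r[1]) return(r[1])
  h <- tabulate(pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * nbins) + 1, 1),
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / nbins * (r[2] - r[1])
}

# Isoperimetric circularity 4*pi*A/P^2 of a 2D logical mask, clamped to
# [0, 1]. The perimeter is the 4-neighbour boundary face count scaled by
# pi/4 (Cauchy-Crofton), which is unbiased for discs.
circularity_of_mask <- function(mask) {
  A <- sum(mask)
  if (A == 0) return(NA_real_)
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  faces <- sum(pad[-1, ] != pad[-nrow(pad), ]) +
    sum(pad[, -1] != pad[, -ncol(pad)])
  P <- faces * pi / 4
  min(1, 4 * pi * A / P^2)
}

# Largest Otsu-bright connected component not touching the image border,
# or NULL when none exists.
enclosed_bright_mask <- function(img) {
  thr <- threshold_otsu(img)
  mask <- img > thr
  lab <- label_components_2d(mask)
  if (!any(lab > 0)) return(NULL)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  ids <- setdiff(unique(as.vector(lab)), c(0L, border))
  if (!length(ids)) return(NULL)
  sizes <- tabulate(lab, max(lab))[ids]
  lab == ids[which.max(sizes)]
}

# 2D connected components (8-connectivity) via the 3D labeler.
label_components_2d <- function(mask) {
  d <- dim(mask)
  lab <- label_components_3d(as.logical(mask), c(d[1], d[2], 1L))
  matrix(lab, d[1], d[2])
}
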