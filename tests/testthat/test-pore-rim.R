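test_that("extract_clip crops, bins and windows with enclosure checking", {
  ph <- make_pore_volume(pore_spec(noise = 5, seed = 2))
  ctr <- as.numeric(ph$truth[1, c("z_nm", "y_nm", "x_nm")])

  clip <- extract_clip(ph$volume, ctr, 120, bin_factor = 1)
  expect_s3_class(clip, "pore_clip")
  expect_equal(dim(clip$base), c(80, 80, 80))      # 2 * 120 nm / 3 nm
  expect_true(all(clip$base$data >= 0 & clip$base$data <= 255))

  # determinism: two clips from the same center are identical
  clip2 <- extract_clip(ph$volume, ctr, 120, bin_factor = 1)
  expect_identical(clip$base$data, clip2$base$data)

  # a pore at the volume edge is not completely enclosed
  expect_error(extract_clip(ph$volume, c(10, ctr[2], ctr[3]), 120,
                            bin_factor = 1), "not completely enclosed")

  # binning path: a 0.75 nm phantom binned by 4 lands on the 3 nm grid
  fine <- make_pore_volume(
    scene_spec(volume_shape = c(120, 120, 120), voxel_size = 0.75,
               pore_specs = list(list(rim_diameter = 20, pore_diameter = 30)),
               noise_sd = 0, seed = 1))
  cl4 <- extract_clip(fine$volume, (dim(fine$volume) - 1) / 2 * 0.75, 30,
                      bin_factor = 4)
  expect_equal(cl4$base$voxel_size, c(3, 3, 3))
})

test_that("align_envelope_to_x recovers in-plane rotation", {
  # membranes already along x: identity within a degree
  c0 <- extract_clip(make_pore_volume(pore_spec(noise = 5, seed = 3))$volume,
                     c(178.5, 178.5, 178.5), 120, bin_factor = 1)
  a0 <- align_envelope_to_x(c0)
  expect_lt(abs(a0$applied_rotations[[1]]$degrees), 1)

  # 17 degrees in-plane: recovered within 2 degrees of -17
  c17 <- extract_clip(make_pore_volume(
    pore_spec(azimuth = 17, noise = 5, seed = 4))$volume,
    c(178.5, 178.5, 178.5), 120, bin_factor = 1)
  a17 <- align_envelope_to_x(c17)
  expect_lt(abs(a17$applied_rotations[[1]]$degrees - (-17)), 2)

  # pure noise: planarity error
  set.seed(5)
  nv <- voxel_grid(array(rnorm(60^3, 128, 30), dim = c(60, 60, 60)), 3)
  cn <- extract_clip(nv, c(88.5, 88.5, 88.5), 80, bin_factor = 1)
  expect_error(align_envelope_to_x(cn), "planar")
})

test_that("the en-face search recovers known tilts within half a grid step", {
  for (tilt in c(0, 30)) {
    ph <- make_pore_volume(pore_spec(tilt = tilt, noise = 5,
                                     seed = 20 + tilt))
    ctr <- as.numeric(ph$truth[1, c("z_nm", "y_nm", "x_nm")])
    clip <- align_envelope_to_x(extract_clip(ph$volume, ctr, 120,
                                             bin_factor = 1))
    ef <- find_en_face_angle(clip)
    delta <- min(abs(ef$angle - tilt), 180 - abs(ef$angle - tilt))
    expect_lte(delta, 5)
    expect_equal(nrow(ef$profile), 18)
  }
})

test_that("circularity of a rasterized disc is close to the analytic 1", {
  r <- 20
  xy <- expand.grid(i = 1:51, j = 1:51)
  mask <- matrix((xy$i - 26)^2 + (xy$j - 26)^2 <= r^2, 51, 51)
  expect_gte(nemorph:::circularity_of_mask(mask), 0.9)
  # elongation reduces the score
  ell <- matrix((xy$i - 26)^2 / 4 + (xy$j - 26)^2 <= 12^2, 51, 51)
  expect_lt(nemorph:::circularity_of_mask(ell),
            nemorph:::circularity_of_mask(mask))
})

test_that("to_perpendicular_view rotates back by 90 and rejects reuse", {
  ph <- make_pore_volume(pore_spec(noise = 5, seed = 6))
  ctr <- as.numeric(ph$truth[1, c("z_nm", "y_nm", "x_nm")])
  clip <- align_envelope_to_x(extract_clip(ph$volume, ctr, 120,
                                           bin_factor = 1))
  # en-face angle 90 means the view is already perpendicular: net 0
  pv <- to_perpendicular_view(clip, 90)
  expect_equal(pv$applied_rotations[[length(pv$applied_rotations)]]$degrees, 0)
  expect_error(to_perpendicular_view(pv, 0), "twice")

  # after the op the membranes appear as two dark bands interrupted by the
  # pore in the central axial slice
  clip2 <- align_envelope_to_x(extract_clip(ph$volume, ctr, 120,
                                            bin_factor = 1))
  pv2 <- to_perpendicular_view(clip2, find_en_face_angle(clip2)$angle)
  d <- dim(pv2$grid)
  sl <- pv2$grid$data[, round(d[2] / 2), ]          # nz x nx
  thr <- nemorph:::threshold_otsu(pv2$grid$data)
  dark_cols <- colSums(sl < thr) > 0
  expect_true(any(dark_cols))                       # bands present
  expect_true(any(!dark_cols[10:(d[3] - 10)]))      # interrupted by the pore
})

test_that("rim and pore measurement recovers phantom truth", {
  m <- measure_phantom_pore(pore_spec(rim = 26, pore = 80, tilt = 25,
                                      noise = 10, seed = 7,
                                      shape = c(120, 120, 120)))
  expect_equal(m$qc_flags, "")
  expect_lt(abs(m$rim_d_i_nm - 26), 3)
  expect_lt(abs(m$rim_d_ii_nm - 26), 3)
  expect_lt(abs(m$pore_d_nm - 80), 9)               # junction columns, 3 px
  # kappa = 2/RD exactly for each emitted side
  expect_equal(m$kappa_i_invnm * m$rim_d_i_nm, 2)
  expect_equal(m$kappa_ii_invnm * m$rim_d_ii_nm, 2)
  # both sides of a symmetric phantom agree within one voxel pitch
  expect_lt(abs(m$rim_d_i_nm - m$rim_d_ii_nm), 3)

  # flat parallel membranes with no pore: "no pore" error
  # (a poreless envelope is just the telophase sheet at 3 nm voxels)
  sc <- make_telophase_scene(sheet_spec(shape = c(80, 80, 80), voxel = 3,
                                        seed = 8))
  clip <- nemorph:::new_pore_clip(
    to_uint8(sc$volume), (dim(sc$volume) - 1) / 2 * 3, "flat")
  clip$perpendicular <- TRUE
  expect_error(measure_rim_and_pore(clip), "no pore")
})

test_that("a pore study reports per-side or per-pore-averaged curvature", {
  st2 <- simulate_pore_study(2, rim_diameter = 26, seed = 55)
  sta <- simulate_pore_study(2, rim_diameter = 26, seed = 55,
                             per_pore_average = TRUE)
  expect_equal(length(st2$kappa), 2 * length(sta$kappa))
  expect_equal(sort(sta$kappa),
               sort(rowMeans(cbind(st2$measurements$kappa_i_invnm,
                                   st2$measurements$kappa_ii_invnm))))
})

test_that("measured rim diameter is tilt-equivariant", {
  rims <- vapply(c(0, 20, 40), function(tilt) {
    m <- measure_phantom_pore(pore_spec(tilt = tilt, noise = 0,
                                        seed = 30 + tilt,
                                        shape = c(120, 120, 120)))
    mean(c(m$rim_d_i_nm, m$rim_d_ii_nm))
  }, 0)
  expect_lt(max(rims) - min(rims), 3)               # one voxel pitch
})

test_that("kappa conversion and angle-bias QC behave as specified", {
  # kappa = 2/RD: RD = 2 nm gives kappa = 1
  df <- data.frame(pore_id = 1:5, en_face_angle_deg = c(0, 10, 20, 30, 40),
                   rim_d_i_nm = 2, rim_d_ii_nm = 2, pore_d_nm = 50)
  expect_equal(2 / df$rim_d_i_nm[1], 1)

  # rim diameter proportional to angle: r = 1
  dfp <- data.frame(pore_id = 1:6,
                    en_face_angle_deg = seq(10, 60, 10),
                    rim_d_i_nm = seq(10, 60, 10) * 0.3,
                    rim_d_ii_nm = seq(10, 60, 10) * 0.3,
                    pore_d_nm = rnorm(6, 80))
  chk <- angle_bias_check(dfp)
  expect_equal(chk$r_rim, 1)
  expect_lt(chk$p_rim, 0.01)

  # angle-independent measurements: |r| small, p typically > 0.05
  set.seed(10)
  dfn <- data.frame(pore_id = 1:40,
                    en_face_angle_deg = runif(40, 0, 180),
                    rim_d_i_nm = rnorm(40, 26, 1),
                    rim_d_ii_nm = rnorm(40, 26, 1),
                    pore_d_nm = rnorm(40, 80, 3))
  chk2 <- angle_bias_check(dfn)
  expect_lt(abs(chk2$r_rim), 0.4)
  expect_gt(chk2$p_rim, 0.05)

  # degenerate: zero variance flagged, two points rejected
  dfz <- dfn; dfz$pore_d_nm <- 80
  expect_true(angle_bias_check(dfz)$degenerate)
  expect_error(angle_bias_check(dfn[1:2, ]), ">= 3")
})
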