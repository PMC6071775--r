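test_that("telophase scenes honor empty, gap and determinism contracts", {
  # no vesicles, no gaps: intact double membrane, empty vesicle table
  sc <- make_telophase_scene(sheet_spec())
  expect_equal(nrow(sc$truth$vesicles), 0)
  expect_equal(nrow(sc$truth$gaps), 0)
  expect_true(any(sc$labels$labels == 1L))
  expect_false(any(sc$labels$labels == 2L))
  # each z slice shows the two membrane traces of an intact sheet
  occ <- colSums(sc$labels$labels[4, , ]) > 0
  expect_true(all(occ))

  # gap ground truth: area is dx * dz exactly
  g <- sheet_spec(gaps = list(list(dx = 100, dz = 140, center = c(450, 245))))
  sc2 <- make_telophase_scene(g)
  expect_equal(sc2$truth$gaps$area_nm2, 14000)

  # determinism: same spec + seed twice gives identical volumes
  s <- sheet_spec(nves = 12, seed = 17)
  a <- make_telophase_scene(s)
  b <- make_telophase_scene(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$truth$vesicles, b$truth$vesicles)
})

test_that("labels and intensity are mutually consistent in noise-free scenes", {
  s <- sheet_spec(nves = 15, shape = c(8, 160, 160), seed = 5)
  sc <- make_telophase_scene(s)
  bg_median <- median(sc$volume$data[sc$labels$labels == 0L])
  labeled <- sc$volume$data[sc$labels$labels != 0L]
  expect_true(all(labeled < bg_median))
})

test_that("vesicle ground truth closes over connected components", {
  # isotropic voxels well below the shell diameter: rasterized shells stay
  # singly connected (coarse section pitches can split a thin shell into
  # cap and equator pieces, or miss a sub-section sphere entirely)
  s <- sheet_spec(nves = 25, shape = c(80, 160, 220),
                  voxel = c(4.5, 4.5, 4.5), seed = 8)
  sc <- make_telophase_scene(s)
  rec <- extract_candidates(sc$labels)
  expect_equal(nrow(rec), 25)
  expect_equal(nrow(sc$truth$vesicles), 25)
})

test_that("infeasible vesicle packing errors after bounded retries", {
  s <- sheet_spec(nves = 400, shape = c(4, 60, 60), seed = 1)
  expect_error(make_telophase_scene(s), "infeasible packing")
})

test_that("sample_diameters draws a reproducible truncated normal", {
  expect_equal(sample_diameters(0, 57, 8, seed = 1), numeric(0))
  expect_equal(sample_diameters(5, 57, 0, seed = 1), rep(57, 5))
  expect_error(sample_diameters(3, -5, 1), "positive")
  d <- sample_diameters(1e4, 57, 8, lower = 20, seed = 42)
  expect_true(all(d > 20))
  # CLT bound: sample mean within 3 * sd / sqrt(n) of the target
  # (truncation at 4.6 sd shifts the mean negligibly)
  expect_lt(abs(mean(d) - 57), 3 * 8 / sqrt(1e4))
  expect_identical(d, sample_diameters(1e4, 57, 8, lower = 20, seed = 42))
})

test_that("pore phantoms render the stated rim geometry", {
  # tilt 0, no noise: the central slice through the pore axis shows two
  # parallel dark bands whose center separation is the rim diameter
  ph <- make_pore_volume(pore_spec(rim = 26, pore = 80, tilt = 0))
  d <- dim(ph$volume)
  sl <- ph$volume$data[round(d[1] / 2), , ]          # ny x nx
  p <- sl[, 5]                                       # far from the pore
  loc <- which(p[2:(length(p) - 1)] <= p[1:(length(p) - 2)] &
               p[2:(length(p) - 1)] <= p[3:length(p)] &
               p[2:(length(p) - 1)] < 150) + 1
  expect_length(loc, 2)
  expect_equal(diff(loc) * 3, 26, tolerance = 3)
  # away from the pore, the same two bands run parallel across columns
  p2 <- sl[, 10]
  loc2 <- which(p2[2:(length(p2) - 1)] <= p2[1:(length(p2) - 2)] &
                p2[2:(length(p2) - 1)] <= p2[3:length(p2)] &
                p2[2:(length(p2) - 1)] < 150) + 1
  expect_equal(loc, loc2)
})

test_that("tilted pore phantoms are the stated rotation of the untilted one", {
  p0 <- make_pore_volume(pore_spec(tilt = 0))
  p30 <- make_pore_volume(pore_spec(tilt = 30))
  rot <- nemorph:::resample_rotated(p0$volume, nemorph:::rot3_x(30),
                                    fill = 200)
  core <- 30:70                       # away from resampling borders
  err <- abs(rot$data[core, core, core] - p30$volume$data[core, core, core])
  rng <- diff(range(p0$volume$data))
  expect_lt(mean(err) / rng, 0.02)    # interpolation error only
})

test_that("pore phantom edge cases are flagged", {
  expect_warning(ph <- make_pore_volume(
    pore_spec(rim = 2, pore = 40, shape = c(60, 60, 60))), "unresolvable")
  expect_true(ph$truth$subresolution)
  expect_error(make_pore_volume(
    pore_spec(pore = 200, shape = c(40, 40, 40))), "larger than volume")
  expect_error(make_pore_volume(sheet_spec()), "nonempty")
  sp2 <- pore_spec()
  sp2$pore_specs <- c(sp2$pore_specs, sp2$pore_specs)
  expect_error(make_pore_volume(sp2), "one pore per phantom")
  ph2 <- make_pore_volume(pore_spec(seed = 9, noise = 10))
  ph3 <- make_pore_volume(pore_spec(seed = 9, noise = 10))
  expect_identical(ph2$volume$data, ph3$volume$data)
})
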