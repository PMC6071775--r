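test_that("find_gaps recovers a known gap and honors the merge rules", {
  # one 100 x 140 nm gap on 70 nm sections: dz is exactly two sections
  sc <- make_telophase_scene(
    sheet_spec(gaps = list(list(dx = 100, dz = 140, center = c(450, 245)))))
  g <- find_gaps(sc$labels)
  expect_equal(nrow(g), 1)
  expect_equal(g$dz_nm, 140)
  expect_lt(abs(g$dx_nm - 100), 4.5)            # within one voxel pitch
  expect_equal(g$area_nm2, g$dx_nm * g$dz_nm)   # exact product, no rounding
  expect_equal(as.character(g$size_class), "medium")

  # intact envelope: no gaps
  expect_equal(nrow(find_gaps(make_telophase_scene(sheet_spec())$labels)), 0)

  # two disjoint gaps are not merged
  sc2 <- make_telophase_scene(sheet_spec(
    gaps = list(list(dx = 90, dz = 140, center = c(300, 245)),
                list(dx = 120, dz = 140, center = c(900, 245))),
    shape = c(8, 120, 300)))
  g2 <- find_gaps(sc2$labels)
  expect_equal(nrow(g2), 2)
  expect_equal(sort(g2$dz_nm), c(140, 140))

  # a span wider than the edge-separation cap is not a converging gap
  sc3 <- make_telophase_scene(sheet_spec(
    gaps = list(list(dx = 300, dz = 140, center = c(450, 245)))))
  expect_equal(nrow(find_gaps(sc3$labels)), 0)
  expect_gt(nrow(find_gaps(sc3$labels, max_edge_separation = 400)), 0)

  expect_error(find_gaps(label_volume(array(0L, dim = c(3, 10, 10)),
                                      c(70, 4.5, 4.5))), "no NE")
})

test_that("gap size classes honor the printed ranges", {
  # values inside each published range
  expect_equal(as.character(classify_gap(8000)), "small")
  expect_equal(as.character(classify_gap(50000)), "medium")
  expect_equal(as.character(classify_gap(200000)), "large")
  # midpoint thresholds close the dead zones
  expect_equal(as.character(classify_gap(c(10449, 10450, 90999, 91000))),
               c("small", "medium", "medium", "large"))
  # strict mode returns unclassified inside the dead zones
  expect_equal(as.character(classify_gap(10200, mode = "strict")),
               "unclassified")
  expect_equal(as.character(classify_gap(8000, mode = "strict")), "small")
  expect_error(classify_gap(0), "positive")

  # monotone, piecewise-constant classification
  set.seed(5)
  areas <- sort(runif(200, 1000, 400000))
  cls <- classify_gap(areas)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("vicinity fields partition vesicles into close and far annuli", {
  ves <- data.frame(z_nm = 0, y_nm = c(300, 400, 800), x_nm = 450)
  f <- sample_vicinity(c(0, 0, 450), ves)
  expect_equal(f$close_count, 2)
  expect_equal(f$far_count, 1)
  expect_equal(f$close_density_um2, 2 / (pi * 0.5^2))
  expect_equal(f$far_density_um2, 1 / (pi * (1 - 0.25)))

  # no vesicles: zero densities
  f0 <- sample_vicinity(c(0, 0, 0), ves[0, ])
  expect_equal(f0$close_density_um2, 0)
  expect_equal(f0$far_density_um2, 0)

  # rejected vesicles are excluded
  ves$accepted <- c(TRUE, FALSE, TRUE)
  expect_equal(sample_vicinity(c(0, 0, 450), ves)$close_count, 1)
  expect_error(sample_vicinity(c(0, 0, 0), ves, radius = 400,
                               close_radius = 500), "radius")
})

test_that("vicinity counts are rotation-invariant about the field center", {
  set.seed(6)
  n <- 50
  pts <- matrix(rnorm(3 * n, sd = 400), ncol = 3)
  ves <- data.frame(z_nm = pts[, 1], y_nm = pts[, 2], x_nm = pts[, 3])
  f1 <- sample_vicinity(c(0, 0, 0), ves)
  th <- 0.7
  rot <- cbind(c(1, 0, 0), c(0, cos(th), sin(th)), c(0, -sin(th), cos(th)))
  prot <- pts %*% rot
  ves2 <- data.frame(z_nm = prot[, 1], y_nm = prot[, 2], x_nm = prot[, 3])
  f2 <- sample_vicinity(c(0, 0, 0), ves2)
  expect_equal(f1$close_count, f2$close_count)
  expect_equal(f1$far_count, f2$far_count)
})

test_that("uniform vesicle fields give equal close and far densities", {
  # projected-2D counting on a dense uniform plane of points
  set.seed(7)
  n <- 40000
  ves <- data.frame(z_nm = 0, y_nm = runif(n, -1500, 1500),
                    x_nm = runif(n, -1500, 1500))
  f <- sample_vicinity(c(0, 0, 0), ves, projected_2d = TRUE)
  expect_equal(f$close_density_um2 / f$far_density_um2, 1, tolerance = 0.1)
})

test_that("random control points respect separation and reproducibility", {
  sc <- make_telophase_scene(sheet_spec())
  p1 <- random_control_points(sc$labels, 5, seed = 7, min_separation = 100)
  p2 <- random_control_points(sc$labels, 5, seed = 7, min_separation = 100)
  expect_identical(p1, p2)
  dd <- as.matrix(dist(p1))
  expect_true(all(dd[upper.tri(dd)] >= 100))

  p3 <- random_control_points(sc$labels, 1, seed = 1)
  idx <- round(p3 / sc$labels$voxel_size) + 1
  expect_equal(sc$labels$labels[idx[1], idx[2], idx[3]], 1L)

  # infeasible separation in a small cell errors out
  expect_error(random_control_points(sc$labels, 10, seed = 1,
                                     min_separation = 2000),
               "infeasible separation")

  # controls can be forced away from gap endpoints
  g <- find_gaps(make_telophase_scene(
    sheet_spec(gaps = list(list(dx = 100, dz = 140,
                                center = c(450, 245)))))$labels)
  p4 <- random_control_points(sc$labels, 3, seed = 2, min_separation = 100,
                              gap_endpoints = g, min_gap_distance = 300)
  for (i in seq_len(nrow(p4))) {
    d_a <- sqrt(sum((p4[i, ] - c(g$a_z_nm, g$a_y_nm, g$a_x_nm))^2))
    expect_gte(d_a, 300)
  }
})

test_that("density comparison recovers a constructed enrichment", {
  # groups identical: no significant pairs
  fields <- data.frame(group = rep(c("a", "b"), each = 5),
                       close_density_um2 = rep(c(1, 2, 3, 2, 1), 2))
  cmp <- density_comparison(fields)
  expect_gt(min(cmp$posthoc), 0.99)

  # two groups: ANOVA p equals the pooled-variance t-test p (F = t^2)
  set.seed(8)
  f2 <- data.frame(group = rep(c("a", "b"), each = 12),
                   close_density_um2 = c(rnorm(12, 5), rnorm(12, 6)))
  cmp2 <- density_comparison(f2)
  tt <- t.test(close_density_um2 ~ group, data = f2, var.equal = TRUE)
  expect_equal(cmp2$omnibus_p, tt$p.value)

  # five-fold enrichment near large gaps stands out against controls
  set.seed(9)
  f3 <- data.frame(
    group = rep(c("large_close", "control_close"), each = 8),
    close_density_um2 = c(rpois(8, 25), rpois(8, 5)) / (pi * 0.25))
  cmp3 <- density_comparison(f3)
  expect_lt(cmp3$posthoc["large_close", "control_close"], 0.001)
  expect_equal(unname(cmp3$stars["large_close", "control_close"]) %in%
                 c("***", "****"), TRUE)
})
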