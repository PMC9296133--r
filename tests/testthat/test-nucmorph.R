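test_that("shoelace area matches closed forms and is orientation-independent", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_identical(polygon_area(sq), 1)
  expect_identical(polygon_area(sq[4:1, ]), 1)
  # inscribed regular 256-gon of circumradius 4
  theta <- 2 * pi * (0:255) / 256
  gon <- cbind(4 * cos(theta), 4 * sin(theta))
  expect_equal(polygon_area(gon), inscribed_ngon_area(256, 4), tolerance = 1e-9)
  # bowtie rejected
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(polygon_area(bow), class = "nedyn_geometry_error")
  expect_error(polygon_area(sq[1:2, ]), class = "nedyn_geometry_error")
})

test_that("diameter measurement recovers a rasterized disk", {
  img <- matrix(50, 64, 64)
  img[disk_mask(64, 31.5, 31.5, 20)] <- 200
  geo <- measure_diameter(img, pixel_size_um = 0.1)
  # equivalent diameter within half a pixel of the generating disk
  expect_lt(abs(geo$diameter_um - 4.0), 0.05)
  expect_equal(geo$volume_um3, 4 / 3 * pi * geo$radius_um^3)
  expect_equal(geo$surface_um2, 4 * pi * geo$radius_um^2)
})

test_that("sphere geometry fields satisfy their exact identities", {
  g <- nucleus_geometry(8)
  expect_equal(g$volume_um3, 268.0826, tolerance = 1e-4)  # (4/3) pi 4^3
  expect_identical(g$volume_um3, 4 / 3 * pi * 4^3)
  expect_identical(g$surface_um2, 4 * pi * 16)
  expect_identical(nucleus_geometry(0)$volume_um3, 0)
})

test_that("contour volume integrates slice polygons times the spacing", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  one <- contour_stack(list(sq), spacing_um = 0.1625)
  expect_equal(contour_volume(one), 0.1625)
  # sphere stack within 1% of the analytic volume
  cs <- gen_sphere_contours(4, 0.1625, 256, jitter_um = 0)
  v_true <- 4 / 3 * pi * 64
  expect_lt(abs(contour_volume(cs) - v_true) / v_true, 0.01)
  # and agrees with the exact-circle Riemann oracle up to the polygon deficit
  v_riemann <- riemann_sphere_volume(4, 0.1625)
  deficit <- inscribed_ngon_area(256, 1) / pi
  expect_equal(contour_volume(cs), v_riemann * deficit, tolerance = 1e-9)
  expect_error(contour_stack(list()), class = "nedyn_geometry_error")
  bad <- contour_stack(list(sq, cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))))
  expect_error(contour_volume(bad), "slice 2", class = "nedyn_geometry_error")
})

test_that("theoretical volume uses the equivalent radius of the widest slice", {
  sq_pi <- cbind(c(0, 1, 1, 0) * sqrt(pi), c(0, 0, 1, 1) * sqrt(pi))
  one <- contour_stack(list(sq_pi))
  expect_equal(theoretical_volume(one), 4 * pi / 3, tolerance = 1e-12)
  two <- contour_stack(list(sq_pi, sq_pi * 2))  # areas pi and 4 pi
  expect_equal(theoretical_volume(two), 32 * pi / 3, tolerance = 1e-12)
  cs <- gen_sphere_contours(4, 0.1625, 256, jitter_um = 0)
  v_true <- 4 / 3 * pi * 64
  expect_lt(abs(theoretical_volume(cs) - v_true) / v_true, 0.01)
})

test_that("sphericity holds for spheres and fails for 2:1 ellipsoids", {
  cs <- gen_sphere_contours(4, 0.1625, 256, jitter_um = 0)
  res <- sphericity_check(cs)
  expect_lt(res$deviation, 0.02)
  expect_true(res$within_10pct)
  # prolate ellipsoid, semi-axes (4, 4, 8): integrated ~ 2x the widest-slice sphere
  d <- 0.1625
  ks <- (-ceiling(8 / d)):(ceiling(8 / d))
  ks <- ks[abs(ks * d) < 8]
  theta <- 2 * pi * (0:255) / 256
  slices <- lapply(ks, function(k) {
    rho <- 4 * sqrt(1 - (k * d)^2 / 64)
    cbind(rho * cos(theta), rho * sin(theta))
  })
  ell <- contour_stack(slices, z_index = ks, spacing_um = d)
  res_e <- sphericity_check(ell)
  v_ell <- 4 / 3 * pi * 4 * 4 * 8
  expect_equal(res_e$v_integrated_um3, v_ell, tolerance = 0.01)
  expect_equal(res_e$deviation, 1.0, tolerance = 0.03)
  expect_false(res_e$within_10pct)
  # identical volumes give deviation 0
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  flatstack <- contour_stack(list(sq))
  r0 <- sphericity_check(flatstack)
  expect_equal(r0$deviation,
               abs(r0$v_integrated_um3 - r0$v_theoretical_um3) / r0$v_theoretical_um3)
})

test_that("integrated volume converges under refinement and scales as s^3", {
  v_true <- 4 / 3 * pi * 64
  errs <- vapply(list(c(32, 0.65), c(64, 0.325), c(256, 0.1625)), function(p) {
    cs <- gen_sphere_contours(4, p[2], p[1], jitter_um = 0)
    abs(contour_volume(cs) - v_true) / v_true
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # monotone refinement
  # exact s^3 scaling of the integrator
  cs <- gen_sphere_contours(2, 0.5, 64, jitter_um = 0)
  scaled <- contour_stack(lapply(cs$slices, function(m) m * 3),
                          z_index = cs$z_index, spacing_um = cs$spacing_um * 3)
  expect_equal(contour_volume(scaled), 27 * contour_volume(cs),
               tolerance = 1e-12)
})

test_that("expansion rate is the OLS slope of volume against time", {
  expect_equal(growth_rate(c(0, 10, 20), c(10, 20, 30))$rate_um3_per_s, 1)
  expect_equal(growth_rate(c(0, 10, 20, 30), rep(5, 4))$rate_um3_per_s, 0)
  expect_error(growth_rate(c(0, 10), c(1, 2)), class = "nedyn_input_error")
  # noisy linear truth: slope within a few analytic OLS standard errors
  set.seed(31)
  t <- seq(0, 190, 10); truth_slope <- 0.8
  v <- 5 + truth_slope * t + rnorm(20, 0, 1)
  se <- 1 / sqrt(sum((t - mean(t))^2))  # sd(slope) for noise sd 1
  expect_lt(abs(growth_rate(t, v)$rate_um3_per_s - truth_slope), 4 * se)
})
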