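test_that("counts in air are conserved and view-independent", {
  # compact source in air with a clean detector (no penetration, no tails):
  # the expected photopeak counts equal sensitivity x activity x duration
  g <- voxel_grid(33, 4.92)
  src <- voxelize_fraction(g, function(x, y, z) x^2 + y^2 + z^2 <= 15^2)
  am <- activity_map(g, 2 * src)
  mm <- mu_map(g, array(0, dim = g$shape))
  geom <- acquisition_geometry(12, 30, 150, 900)
  det <- detector_model(pen_fraction = 0, scatter_alpha = 0)
  proj <- forward_project(am, mm, geom, det, acq_start = 0)
  expected <- det$sensitivity * total_activity(am) * geom$duration
  expect_rel_equal(sum(proj$photopeak), expected, 0.01)
  pv <- apply(proj$photopeak, 3, sum)
  expect_lt((max(pv) - min(pv)) / mean(pv), 0.01)
  # psf widths do not change the totals (blur is normalized)
  det2 <- detector_model(pen_fraction = 0, scatter_alpha = 0,
                         psf_offset = 6, psf_slope = 0.06)
  proj2 <- forward_project(am, mm, geom, det2, acq_start = 0)
  expect_rel_equal(sum(proj2$photopeak), sum(proj$photopeak), 0.005)
})

test_that("uniformly increasing attenuation never increases any bin", {
  g <- voxel_grid(24, 4.92)
  ph <- make_cylinder_phantom(70, 70, 3, g)
  geom <- acquisition_geometry(8, 45, 150, 900)
  det <- detector_model()
  base <- forward_project(ph$activity, ph$mu, geom, det, acq_start = 0)
  denser <- mu_map(g, ph$mu$values * 1.5)
  more <- forward_project(ph$activity, denser, geom, det, acq_start = 0)
  expect_true(all(more$photopeak <= base$photopeak + 1e-9))
})

test_that("septal penetration moves counts outside the body shadow", {
  g <- voxel_grid(48, 4.92)
  ph <- make_cylinder_phantom(80, 80, 5, g)
  geom <- acquisition_geometry(8, 45, 150, 900)
  p0 <- forward_project(ph$activity, ph$mu, geom,
                        detector_model(pen_fraction = 0), acq_start = 0)
  p8 <- forward_project(ph$activity, ph$mu, geom,
                        detector_model(pen_fraction = 0.08), acq_start = 0)
  # shadow: bins that receive geometric counts
  shadow <- p0$photopeak[, , 1] > 1e-6 * max(p0$photopeak[, , 1])
  frac0 <- sum(p0$photopeak[, , 1][!shadow]) / sum(p0$photopeak[, , 1])
  frac8 <- sum(p8$photopeak[, , 1][!shadow]) / sum(p8$photopeak[, , 1])
  expect_gt(frac8, frac0)
})

test_that("scatter-window totals are the stated multiple of geometric totals", {
  # generous margin so the 60 mm scatter blur stays on the detector
  g <- voxel_grid(48, 4.92)
  ph <- make_cylinder_phantom(60, 60, 2, g)
  geom <- acquisition_geometry(6, 60, 150, 900)
  det <- detector_model(pen_fraction = 0, scatter_alpha = 0.15)
  mm0 <- mu_map(g, array(0, dim = g$shape))
  proj <- forward_project(ph$activity, mm0, geom, det, acq_start = 0)
  geom_total <- det$sensitivity * total_activity(ph$activity) * geom$duration
  expect_rel_equal(sum(proj$scatter), 0.15 * geom_total, 0.01)
})

test_that("empty activity projects to all-zero data", {
  g <- voxel_grid(16, 4.92)
  am <- activity_map(g, array(0, dim = g$shape))
  mm <- mu_map(g, array(0, dim = g$shape))
  proj <- forward_project(am, mm, acquisition_geometry(4, 90, 150, 900),
                          detector_model(), acq_start = 0)
  expect_true(all(proj$photopeak == 0) && all(proj$scatter == 0))
})

test_that("Poisson noise has the right law, determinism and zero handling", {
  g <- voxel_grid(c(1000, 1, 1), 1)
  geom <- acquisition_geometry(1, 360, 150, 900)
  proj <- structure(list(
    photopeak = array(1e4, dim = c(1000, 1, 1)),
    scatter = array(0, dim = c(1000, 1, 1)),
    geometry = geom, windows = energy_windows(),
    detector = detector_model(), grid = g, acq_start = 0,
    noiseless = TRUE, noiseless_mean = NULL, seed = NULL),
    class = "projection_set")
  n1 <- add_poisson_noise(proj, 42)
  n2 <- add_poisson_noise(proj, 42)
  expect_identical(n1$photopeak, n2$photopeak)
  expect_true(all(n1$scatter == 0))
  expect_rel_equal(mean(n1$photopeak), 1e4, 0.1)
  expect_rel_equal(var(as.numeric(n1$photopeak)), 1e4, 0.1)
  expect_identical(n1$noiseless_mean$photopeak, proj$photopeak)
  expect_error(add_poisson_noise(n1, 1), "noiseless")
})

test_that("decay follows the closed form", {
  expect_equal(decay_activity(10, lu177_half_life()), 5)
  expect_equal(decay_activity(7, 0), 7)
  expect_equal(decay_activity(541, 6.6475 * 86400, 6.6475 * 86400), 270.5)
  expect_equal(decay_activity(5, -lu177_half_life()), 10)
  expect_error(decay_activity(1, 1, 0), "positive")
})
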