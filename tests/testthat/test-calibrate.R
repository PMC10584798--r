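test_that("cylindrical VOIs of printed dimensions have the printed volumes", {
  g <- voxel_grid(129, 2.46)
  vin <- make_cylindrical_voi(g, diameter = 140, height = 126)
  expect_equal(round(attr(vin, "volume_l"), 1), 1.9)
  expect_rel_equal(attr(vin, "volume_ml"), pi * 70^2 * 126 / 1000, 0.01)
  vout <- make_cylindrical_voi(g, diameter = 220, height = 200)
  # analytic 7.60 L; the voxelized mask stays close to it
  expect_rel_equal(attr(vout, "volume_l"), 7.60, 0.01)
  expect_error(make_cylindrical_voi(g, 140, 0), "empty")
  expect_error(make_cylindrical_voi(g, 1000, 100), "exceeds")
})

test_that("calibration factor follows its defining equation", {
  g <- voxel_grid(c(4, 4, 4), 10)
  vals <- array(0, dim = c(4, 4, 4))
  vals[2, 2, 2] <- 100
  rv <- luquant:::recon_volume(g, vals, recon_params("OSEM", 1), t_acq = 1)
  voi <- array(TRUE, dim = c(4, 4, 4))
  r0 <- compute_icf(rv, voi, calibration_inputs(1, dt = 0))
  expect_equal(r0$icf, 100)
  r1 <- compute_icf(rv, voi, calibration_inputs(1, dt = lu177_half_life()))
  expect_equal(r1$icf, 200)
  rv0 <- rv; rv0$values[] <- 0
  expect_error(compute_icf(rv0, voi, calibration_inputs(1)), "zero counts")
})

test_that("calibration uncertainty propagates counting and activity terms", {
  # counting term negligible at calibration count levels: 2.0 percent
  C <- 94.6 * 900 * 541
  expect_equal(round(100 * compute_icf_uncertainty(C, 0.02), 1), 2.0)
  expect_equal(compute_icf_uncertainty(100, 0), 0.1)
  expect_equal(compute_icf_uncertainty(1e18, 0.02), 0.02, tolerance = 1e-6)
  expect_error(compute_icf_uncertainty(0), "positive")
})

test_that("quantification error is the exact relative difference", {
  g <- voxel_grid(c(4, 4, 4), 10)
  p <- recon_params("OSEM", 1)
  rv <- luquant:::recon_volume(g, array(98.7, dim = c(4, 4, 4)), p, t_acq = 1)
  voi <- array(TRUE, dim = c(4, 4, 4))
  icf <- structure(list(icf = 64, u_icf_rel = 0.02,
                        counts = 1, voi_volume_ml = 1, t_acq = 1, params = p),
                   class = "icf_result")
  q <- quantify(rv, voi, icf, truth = 100)
  expect_equal(q$a_meas, 98.7)
  expect_equal(100 * q$error, -1.3)
  q0 <- quantify(rv, voi, icf, truth = q$a_meas)
  expect_equal(q0$error, 0)
})

test_that("protocol provenance is enforced between ICF and quantification", {
  ts <- toy_setup(n = 16, seed = 13)
  voi <- array(TRUE, dim = ts$grid$shape)
  r1 <- reconstruct(ts$proj, ts$phantom$mu, recon_params("OSEM", 4))
  r2 <- reconstruct(ts$proj, ts$phantom$mu, recon_params("OSEM", 6))
  icf1 <- compute_icf(r1, voi, calibration_inputs(5))
  expect_error(quantify(r2, voi, icf1, 5), "does not match")
  expect_warning(quantify(r2, voi, icf1, 5, override = TRUE), "different")
})

test_that("self-calibration on the same acquisition closes exactly", {
  # calibrating and quantifying the SAME reconstruction with the same VOI
  # returns the decayed truth by construction, whatever the image quality
  ts <- toy_setup(n = 16, seed = 17, noise = FALSE)
  voi <- make_cylindrical_voi(ts$grid, 0.7 * 16 * 4.92, 0.7 * 16 * 4.92)
  r <- reconstruct(ts$proj, ts$phantom$mu, recon_params("OSEM", 8))
  icf <- compute_icf(r, voi, calibration_inputs(5, dt = 0))
  q <- quantify(r, voi, icf, truth = 5)
  expect_lt(abs(q$error), 1e-12)
})

test_that("the calibration factor is invariant under acquisition rescaling", {
  # doubling T_acq with counts doubled leaves the ICF unchanged
  g <- voxel_grid(c(4, 4, 4), 10)
  p <- recon_params("OSEM", 1)
  voi <- array(TRUE, dim = c(4, 4, 4))
  r1 <- luquant:::recon_volume(g, array(10, dim = c(4, 4, 4)), p, t_acq = 900)
  r2 <- luquant:::recon_volume(g, array(20, dim = c(4, 4, 4)), p, t_acq = 1800)
  i1 <- compute_icf(r1, voi, calibration_inputs(3))
  i2 <- compute_icf(r2, voi, calibration_inputs(3))
  expect_equal(i1$icf, i2$icf)
})
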