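test_that("CT-grid resampling preserves constants and total counts", {
  g <- voxel_grid(32, 4.92)
  p <- recon_params("OSEM", 1)
  rv <- luquant:::recon_volume(g, array(5, dim = g$shape), p, 900)
  ct <- voxel_grid(c(120, 120, 48), c(1, 1, 2.5))
  rs <- resample_to_ct(rv, ct)
  # density convention: a constant field stays constant, up to the
  # voxel-volume rescale that conserves counts
  interior <- rs$values[10:110, 10:110, 5:43]
  expect_lt(diff(range(interior)) / mean(interior), 1e-9)
  # identity grid passes through untouched
  expect_identical(resample_to_ct(rv, g), rv)
  expect_error(resample_to_ct(rv, voxel_grid(10, 1, origin = c(1e4, 0, 0))),
               "overlap")
})

test_that("resampling a reconstruction conserves counts within 1%", {
  nb <- nema_bundle()
  ct <- voxel_grid(c(240, 240, 40), c(1, 1, 2.5))
  rs <- resample_to_ct(nb$recon_cold, ct)
  # compare totals over the common support (the CT grid covers the spheres
  # and body interior); integrate the source over the same world box
  src <- nb$recon_cold
  ext <- ct$shape * ct$spacing / 2
  co <- luquant:::grid_coord_arrays(src$grid)
  inbox <- abs(co$x) <= ext[1] & abs(co$y) <= ext[2] & abs(co$z) <= ext[3]
  expect_rel_equal(sum(rs$values), sum(src$values[inbox]), 0.01)
})

test_that("sphere VOIs match their analytic volumes at CT resolution", {
  ct <- voxel_grid(c(60, 60, 24), c(1, 1, 2.5))
  for (d in c(10, 13, 17, 22, 28, 37)) {
    v <- sphere_voi(ct, c(0, 0, 0), d)
    expect_rel_equal(v$volume_ml, pi / 6 * d^3 / 1000, 0.05)
  }
})

test_that("self-calibrated uniform activity recovers RC of 100%", {
  # a whole-body VOI on the calibration phantom itself must close at 100%
  ts <- toy_setup(n = 16, seed = 19, noise = FALSE)
  r <- reconstruct(ts$proj, ts$phantom$mu, recon_params("OSEM", 20))
  body_ml <- ts$phantom$volume_ml
  conc <- 5 / body_ml
  voi <- array(TRUE, dim = ts$grid$shape)
  icf <- compute_icf(r, voi, calibration_inputs(5, dt = 0))
  whole <- structure(list(mask = voi,
                          volume_ml = prod(ts$grid$shape) *
                            voxel_volume(ts$grid, "mL") ,
                          center = c(0, 0, 0), diameter = NA,
                          grid = ts$grid), class = "sphere_voi")
  conc_whole <- 5 / whole$volume_ml
  rc <- compute_rc(r, whole, icf, conc_whole, dt = 0)
  expect_equal(rc, 100, tolerance = 1e-9)
})

test_that("recovery degrades with sphere size and hot background", {
  nb <- nema_bundle()
  ct <- voxel_grid(c(240, 240, 40), c(1, 1, 2.5))
  spheres <- lapply(1:6, function(i)
    sphere_voi(ct, nb$cold$sphere_centers[i, ], nb$cold$sphere_diameters[i]))
  tb_cold <- rc_table(list(nb$recon_cold), spheres, list(nb$icf), 1.6, ct,
                      "cold", nb$cfg$dt)
  tb_hot <- rc_table(list(nb$recon_hot), spheres, list(nb$icf), 1.6, ct,
                     "hot", nb$cfg$dt)
  # partial volume: small spheres recover less (2-point noise tolerance)
  expect_true(all(diff(tb_cold$rc) > -2))
  expect_lt(tb_cold$rc[1], tb_cold$rc[6])
  # background activity degrades the smallest sphere's recovery
  expect_lte(tb_hot$rc[1], tb_cold$rc[1])
  # an empty reconstruction list yields an empty table
  expect_equal(nrow(rc_table(list(), spheres, list(), 1.6, ct)), 0)
})
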