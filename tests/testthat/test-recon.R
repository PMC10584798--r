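test_that("BSREM with beta 0 and unit unrelaxed steps equals OSEM voxelwise", {
  ts <- toy_setup(n = 16, seed = 3)
  po <- recon_params("OSEM", 6)
  pb <- recon_params("BSREM", 6, beta = 0, alpha0 = 1, eta = 0)
  ro <- reconstruct(ts$proj, ts$phantom$mu, po)
  rb <- reconstruct(ts$proj, ts$phantom$mu, pb)
  expect_lt(max(abs(rb$values - ro$values) / (abs(ro$values) + 1e-9)), 1e-6)
})

test_that("MLEM conserves counts without attenuation", {
  g <- voxel_grid(33, 4.92)
  src <- voxelize_fraction(g, function(x, y, z) x^2 + y^2 + z^2 <= 12^2)
  am <- activity_map(g, src)
  mm0 <- mu_map(g, array(0, dim = g$shape))
  geom <- acquisition_geometry(12, 30, 150, 900)
  det <- detector_model(pen_fraction = 0, scatter_alpha = 0)
  proj <- forward_project(am, mm0, geom, det, acq_start = 0)  # noiseless
  r <- reconstruct(proj, mm0, recon_params("OSEM", 200, psf_mode = "matched",
                                           scatter_correction = FALSE))
  expect_rel_equal(sum(r$values), sum(proj$photopeak), 0.005)
  expect_true(all(r$values >= 0))
})

test_that("Poisson log-likelihood is non-decreasing over full MLEM passes", {
  ts <- toy_setup(n = 16, seed = 5)
  p <- recon_params("OSEM", 12)
  snaps <- reconstruct(ts$proj, ts$phantom$mu, p,
                       snapshot_updates = c(1, 2, 4, 8, 12))
  ll <- vapply(snaps, function(v)
    recon_objective(v, ts$proj, ts$phantom$mu, p)$loglik, numeric(1))
  expect_true(all(diff(ll) > -1e-6 * abs(ll[1])))
})

test_that("BSREM penalized objective is non-decreasing with default relaxation", {
  ts <- toy_setup(n = 16, seed = 7)
  p <- recon_params("BSREM", 12, beta = 0.01)
  snaps <- reconstruct(ts$proj, ts$phantom$mu, p,
                       snapshot_updates = c(1, 2, 4, 8, 12))
  obj <- vapply(snaps, function(v)
    recon_objective(v, ts$proj, ts$phantom$mu, p)$objective, numeric(1))
  expect_true(all(diff(obj) > -1e-6 * abs(obj[1])))
})

test_that("regularization strength monotonically reduces noise", {
  ts <- cached("toy32_noisy", toy_setup(n = 32, n_views = 20, seed = 9,
                                        activity = 40))
  voi <- make_cylindrical_voi(ts$grid, 0.4 * 32 * 4.92, 0.4 * 32 * 4.92)
  cvs <- vapply(c(0, 0.005, 0.05), function(b) {
    r <- reconstruct(ts$proj, ts$phantom$mu,
                     recon_params("BSREM", 48, beta = b))
    compute_cv(r, voi)$cv
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
})

test_that("degenerate reconstruction inputs are rejected", {
  ts <- toy_setup(n = 16)
  expect_error(recon_params("OSEM", 0), "positive")
  expect_error(recon_params("OSEM", 4, beta = 0.1), "BSREM")
  expect_error(recon_params("BSREM", 4, beta = -1), "nonnegative")
  # subsets must divide the views (12 views here)
  expect_error(reconstruct(ts$proj, ts$phantom$mu,
                           recon_params("OSEM", 2, subsets = 5)), "divide")
  zero <- ts$proj
  zero$photopeak[] <- 0
  zero$scatter[] <- 0
  expect_warning(r0 <- reconstruct(zero, ts$phantom$mu,
                                   recon_params("OSEM", 2)), "all-zero")
  expect_true(all(r0$values == 0))
})

test_that("relative difference prior matches hand-computed values", {
  two <- array(c(2, 0), dim = c(2, 1, 1))
  expect_equal(rdp_penalty(two, gamma = 0, eps = 0)$value, 2)
  const <- array(5, dim = c(4, 4, 4))
  r <- rdp_penalty(const)
  expect_equal(r$value, 0)
  expect_true(all(r$gradient == 0))
  # large gamma kills the penalty
  x <- array(runif(64), dim = c(4, 4, 4))
  expect_lt(rdp_penalty(x, gamma = 1e9)$value,
            1e-6 * rdp_penalty(x, gamma = 1)$value)
})

test_that("relative difference prior gradient matches finite differences", {
  set.seed(21)
  x <- array(runif(27, 0.5, 2), dim = c(3, 3, 3))
  g <- rdp_penalty(x, gamma = 1, eps = 1e-6)$gradient
  h <- 1e-6
  for (i in c(1, 14, 27)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fd <- (rdp_penalty(xp, gamma = 1, eps = 1e-6)$value -
             rdp_penalty(xm, gamma = 1, eps = 1e-6)$value) / (2 * h)
    expect_rel_equal(g[i], fd, 1e-4)
  }
})

test_that("dual-energy-window estimate uses the window width ratio", {
  w <- energy_windows()
  expect_equal(w$width_ratio, 24.96 / 18.5, tolerance = 1e-6)
  ts <- toy_setup(n = 16, noise = FALSE)
  est <- dew_scatter_estimate(ts$proj, k = 1)
  expect_true(all(est <= ts$proj$photopeak + 1e-12))
  zs <- ts$proj
  zs$scatter[] <- 0
  expect_true(all(dew_scatter_estimate(zs) == 0))
  ns <- ts$proj
  ns$scatter <- NULL
  expect_error(dew_scatter_estimate(ns), "scatter")
})

test_that("scatter correction is inert on clean data", {
  g <- voxel_grid(16, 4.92)
  ph <- make_cylinder_phantom(40, 40, 2, g)
  det <- detector_model(pen_fraction = 0, scatter_alpha = 0)
  geom <- acquisition_geometry(8, 45, 150, 900)
  proj <- forward_project(ph$activity, ph$mu, geom, det, acq_start = 0)
  r_on <- reconstruct(proj, ph$mu, recon_params("OSEM", 10))
  r_off <- reconstruct(proj, ph$mu,
                       recon_params("OSEM", 10, scatter_correction = FALSE))
  expect_lt(max(abs(r_on$values - r_off$values)) / max(r_off$values), 1e-3)
})

test_that("sensitivity weighting of beta reflects attenuation depth", {
  g <- voxel_grid(24, 4.92)
  geom <- acquisition_geometry(8, 45, 150, 900)
  mm0 <- mu_map(g, array(0, dim = g$shape))
  b0 <- sensitivity_weight_beta(mm0, 0.08, geom, psf_mode = "none")
  ctr <- b0[10:15, 10:15, 10:15]
  # view-interpolation ripple only: essentially the scalar beta
  expect_lt(sd(ctr) / mean(ctr), 0.05)
  ph <- make_cylinder_phantom(100, 100, 1, g)
  b1 <- sensitivity_weight_beta(ph$mu, 0.08, geom)
  expect_lt(b1[12, 12, 12], b1[4, 12, 12])
})

test_that("OSEM metrics are subset-invariant at fixed updates", {
  ts <- cached("toy32_noisy", toy_setup(n = 32, n_views = 20, seed = 9,
                                        activity = 40))
  voi <- make_cylindrical_voi(ts$grid, 0.4 * 32 * 4.92, 0.4 * 32 * 4.92)
  r1 <- reconstruct(ts$proj, ts$phantom$mu, recon_params("OSEM", 40))
  r4 <- reconstruct(ts$proj, ts$phantom$mu,
                    recon_params("OSEM", 10, subsets = 4))
  cv1 <- compute_cv(r1, voi)$cv
  cv4 <- compute_cv(r4, voi)$cv
  expect_lt(abs(cv4 - cv1) / cv1, 0.05)
  m1 <- mean(r1$values[voi])
  m4 <- mean(r4$values[voi])
  expect_lt(abs(m4 - m1) / m1, 0.05)
})
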