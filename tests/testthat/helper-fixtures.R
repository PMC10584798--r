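# Shared fixtures.  The heavy simulation/reconstruction bundles are computed
# once per test session and cached; every bundle is deterministic under its
# stated seed.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small toy acquisition of a uniform cylinder; fast enough for unit tests
toy_setup <- function(n = 16, spacing = 4.92, n_views = 12, seed = 3,
                      activity = 5, det = detector_model(), noise = TRUE) {
  g <- voxel_grid(n, spacing)
  ext <- n * spacing
  ph <- make_cylinder_phantom(0.6 * ext, 0.6 * ext, activity, g)
  geom <- acquisition_geometry(n_views, 360 / n_views, 150, 900)
  proj <- forward_project(ph$activity, ph$mu, geom, det, acq_start = 0)
  if (noise) proj <- add_poisson_noise(proj, seed)
  list(grid = g, phantom = ph, geom = geom, proj = proj)
}

# the full desk-profile calibration + quantification study (the same
# conditions the acceptance script reproduces)
desk_quant_bundle <- function() {
  cached("desk_quant", {
    run_characterization(desk_profile(1), stages = "quantification")
  })
}

# desk-profile penetration-free variant, converged protocols only: used to
# isolate the septal-penetration contribution to the inner-VOI bias
desk_penfree_bundle <- function() {
  cached("desk_penfree", {
    cfg <- desk_profile(1)
    cfg$det <- detector_model(pen_fraction = 0)
    cfg$update_grid <- c(96, 192)
    cfg$include_factory <- FALSE
    run_characterization(cfg, stages = "quantification")
  })
}

# NEMA cold/hot simulations with one converged protocol for recovery tests
nema_bundle <- function() {
  cached("nema", {
    cfg <- desk_profile(1)
    g <- cfg$grid
    # the regularized protocol: the relative difference prior is what makes
    # recovery sensitive to background activity (hot denominators weaken its
    # edge preservation), mirroring the reported cold/hot contrast
    params <- recon_params("BSREM", 96, beta = 0.005,
                           psf_mode = cfg$psf_mode)
    cold <- make_nema_phantom(1.6, 0, g)
    hot <- make_nema_phantom(1.6, 0.16, g)
    jas <- make_cylinder_phantom(209, 186, 541, g)
    sim <- function(ph, seed) add_poisson_noise(
      forward_project(ph$activity, ph$mu, cfg$geom, cfg$det, cfg$windows,
                      acq_start = cfg$dt), seed)
    jr <- reconstruct(sim(jas, 101), jas$mu, params)
    icf <- compute_icf(jr, make_cylindrical_voi(g, 230, 220),
                       calibration_inputs(541, cfg$dt))
    list(cfg = cfg, cold = cold, hot = hot, icf = icf,
         recon_cold = reconstruct(sim(cold, 102), cold$mu, params),
         recon_hot = reconstruct(sim(hot, 103), hot$mu, params))
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
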