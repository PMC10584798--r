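test_that("noise matching selects the closest protocol with tie rules", {
  cands <- list(list(params = recon_params("OSEM", 48), cv = 0.12),
                list(params = recon_params("OSEM", 72), cv = 0.149),
                list(params = recon_params("OSEM", 96), cv = 0.19))
  best <- match_noise(cands, 0.15)
  expect_equal(best$params$iterations, 72L)
  # permutation invariance
  best2 <- match_noise(rev(cands), 0.15)
  expect_equal(best2$params$iterations, 72L)
  # exact tie: fewer updates wins
  tie <- list(list(params = recon_params("OSEM", 96), cv = 0.16),
              list(params = recon_params("OSEM", 48), cv = 0.14))
  expect_equal(match_noise(tie, 0.15)$params$iterations, 48L)
  expect_warning(single <- match_noise(cands[2], 0.5), "single")
  expect_equal(single$params$iterations, 72L)
  expect_error(match_noise(list(), 0.15), "empty")
})

test_that("peak 1-mL statistic finds hot lesions", {
  # the 1-mL sphere radius is (3 * 1000 / 4 pi)^(1/3) = 6.20 mm
  expect_equal((3 * 1000 / (4 * pi))^(1 / 3), 6.2035, tolerance = 1e-4)
  g <- voxel_grid(32, 2.46)
  p <- recon_params("OSEM", 1)
  u <- luquant:::recon_volume(g, array(7, dim = g$shape), p, 900)
  all_mask <- array(TRUE, dim = g$shape)
  pk <- peak_1ml_mean(u, all_mask)
  expect_equal(pk$peak_mean, 7, tolerance = 1e-9)
  # hot Gaussian blob in flat background peaks at its centroid
  co <- luquant:::grid_coord_arrays(g)
  blob <- 1 + 50 * exp(-((co$x - 5)^2 + (co$y + 2.5)^2 + co$z^2) / 100)
  v <- luquant:::recon_volume(g, blob, p, 900)
  pk2 <- peak_1ml_mean(v, all_mask)
  expect_lt(max(abs(pk2$center - c(5, -2.5, 0))), 2.47)
  expect_error(peak_1ml_mean(u, array(FALSE, dim = g$shape)), "empty")
})

test_that("isocontour segmentation respects threshold and connectivity", {
  g <- voxel_grid(32, 2.46)
  p <- recon_params("OSEM", 1)
  co <- luquant:::grid_coord_arrays(g)
  sph1 <- (co$x + 15)^2 + co$y^2 + co$z^2 <= 10^2
  sph2 <- (co$x - 15)^2 + co$y^2 + co$z^2 <= 10^2
  vals <- 0.1 + 10 * (sph1 | sph2)
  v <- luquant:::recon_volume(g, vals, p, 900)
  m <- isocontour_segment(v, c(-15, 0, 0), peak_mean = 10.1, fraction = 0.3)
  expect_true(all(m[sph1]))
  expect_false(any(m[sph2]))  # only the seeded component
  vol_ml <- sum(m) * voxel_volume(g, "mL")
  expect_rel_equal(vol_ml, 4 / 3 * pi * 10^3 / 1000, 0.15)
  # fraction 1 keeps only voxels at or above the peak mean
  m1 <- isocontour_segment(v, c(-15, 0, 0), peak_mean = 10.1, fraction = 1)
  expect_true(all(v$values[m1] >= 10.1))
  expect_error(isocontour_segment(v, c(0, 30, 0), 10.1), "below")
})

test_that("lesion concentration scales inversely with the ICF", {
  g <- voxel_grid(16, 2.46)
  p <- recon_params("OSEM", 1)
  v <- luquant:::recon_volume(g, array(50, dim = g$shape), p, t_acq = 900)
  mask <- array(FALSE, dim = g$shape)
  mask[6:10, 6:10, 6:10] <- TRUE
  mk_icf <- function(icf) structure(
    list(icf = icf, u_icf_rel = 0.02, counts = 1, voi_volume_ml = 1,
         t_acq = 900, params = p), class = "icf_result")
  c1 <- lesion_concentration(v, mask, mk_icf(100))
  c2 <- lesion_concentration(v, mask, mk_icf(200))
  expect_equal(c1, 2 * c2)
  expect_error(lesion_concentration(v, array(FALSE, dim = g$shape),
                                    mk_icf(100)), "empty")
})

test_that("a noiseless uniform lesion quantifies close to truth", {
  # closure through the full chain: simulate, reconstruct, self-calibrate,
  # segment nothing (whole-lesion truth mask), quantify
  g <- voxel_grid(32, 4.92)
  ph <- make_cylinder_phantom(120, 120, 8, g)
  geom <- acquisition_geometry(12, 30, 150, 900)
  proj <- forward_project(ph$activity, ph$mu, geom, detector_model(),
                          acq_start = 0)
  r <- reconstruct(proj, ph$mu, recon_params("OSEM", 30))
  icf <- compute_icf(r, array(TRUE, dim = g$shape), calibration_inputs(8))
  mask <- ph$activity$values > 0.99 * max(ph$activity$values)
  conc <- lesion_concentration(r, mask, icf)
  truth_kbq <- 1000 * 8 / ph$volume_ml
  expect_rel_equal(conc, truth_kbq, 0.10)
})

test_that("exact Wilcoxon p equals brute-force sign enumeration", {
  brute <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    tot <- sum(r)
    vs <- vapply(0:(2^n - 1), function(m) {
      signs <- as.integer(intToBits(m))[1:n]
      sum(r[signs == 1])
    }, numeric(1))
    mean(abs(vs - tot / 2) >= abs(V - tot / 2) - 1e-9)
  }
  expect_equal(wilcoxon_signed_rank(c(3, 4, 5, 6, 7),
                                    c(1, 2, 3, 4, 5))$p_value, 2 / 32)
  set.seed(41)
  for (n in c(4, 7, 9, 12)) {
    a <- rnorm(n)
    b <- rnorm(n)
    # include ties in |differences| occasionally
    if (n == 9) b[2] <- a[2] - (a[1] - b[1])
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, brute(a - b), tolerance = 1e-12)
    # swapping the pair order leaves p unchanged
    expect_equal(wilcoxon_signed_rank(b, a)$p_value, got$p_value)
  }
  # agreement with the reference implementation on tie-free data
  set.seed(43)
  a <- rnorm(15); b <- rnorm(15)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, ref$p.value,
               tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "nonzero")
})

test_that("Wilcoxon test holds its nominal type-I error at n = 27", {
  set.seed(47)
  rej <- mean(replicate(1000, {
    a <- rnorm(27); b <- rnorm(27)
    wilcoxon_signed_rank(a, b)$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("five-number summaries use linear quartile interpolation", {
  s <- summary_stats(c(-19, -5, -2, 1, 3))
  expect_equal(unname(s["median"]), -2)
  expect_equal(unname(summary_stats(rep(4, 6))), rep(4, 5))
  set.seed(53)
  u <- summary_stats(runif(1e4, -10, 10))
  expect_lt(abs(u["median"]), 0.5)
  expect_error(summary_stats(numeric(0)), "empty")
})

test_that("the cohort workflow freezes masks across protocols", {
  # patient-like volume -> two reconstructions -> segmentation on the
  # reference protocol only; the identical voxel set quantifies both
  g <- voxel_grid(48, 4.92)
  pat <- make_patient_phantom(3, lesion_conc_range = c(2000, 5000),
                              grid = g, seed = 31)
  geom <- acquisition_geometry(12, 30, 150, 900)
  proj <- add_poisson_noise(
    forward_project(pat$activity, pat$mu, geom, detector_model(),
                    acq_start = 0), 32)
  recons <- list(
    ref = reconstruct(proj, pat$mu, recon_params("OSEM", 24)),
    alt = reconstruct(proj, pat$mu,
                      recon_params("BSREM", 24, beta = 0.005)))
  all_voi <- array(TRUE, dim = g$shape)
  a_total <- total_activity(pat$activity)
  icfs <- lapply(recons, compute_icf, voi = all_voi,
                 inputs = calibration_inputs(a_total))
  rel <- numeric(0)
  for (i in seq_len(nrow(pat$lesions))) {
    ctr <- as.numeric(pat$lesions[i, c("x", "y", "z")])
    search <- array(FALSE, dim = g$shape)
    idx <- round(world_to_index(g, ctr))
    lo <- pmax(idx - 5L, 1L); hi <- pmin(idx + 5L, g$shape)
    search[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    pk <- peak_1ml_mean(recons$ref, search)
    mask <- isocontour_segment(recons$ref, pk$center, pk$peak_mean)
    # the frozen mask (one voxel set) quantifies every protocol
    c_ref <- lesion_concentration(recons$ref, mask, icfs$ref)
    c_alt <- lesion_concentration(recons$alt, mask, icfs$alt)
    expect_gt(c_ref, 0)
    expect_gt(sum(mask) * voxel_volume(g, "mL"), 1)
    rel <- c(rel, 100 * (c_alt - c_ref) / c_ref)
  }
  s <- summary_stats(rel)
  expect_true(s["min"] <= s["median"] && s["median"] <= s["max"])
  # the regularized reconstruction reads lower lesion concentrations
  expect_lt(s[["median"]], 0)
})
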