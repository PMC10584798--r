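# Synthetic acquisition: forward-project activity maps into noisy
# dual-window projection data with attenuation, distance-dependent
# collimator response, septal-penetration tails and emulated scatter.

#' Acquisition geometry
#'
#' Parallel-beam emulation of a 360-degree step-and-sweep acquisition: the
#' volume is rotated view by view and projected onto a detector grid with the
#' voxel pitch of the reconstruction grid.  `detector_radius` is the fixed
#' source-to-collimator distance entering the distance-dependent response.
#'
#' @param n_views Number of views; together with `angular_step` it must cover
#'   360 degrees.
#' @param angular_step Angular step between views, degrees.
#' @param detector_radius Collimator face to rotation axis distance, mm.
#' @param duration Total acquisition duration, s (dwell per view is
#'   `duration / n_views`).
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(n_views = 180, angular_step = 2,
                                 detector_radius = 150, duration = 900) {
  if (abs(n_views * angular_step - 360) > 1e-6)
    stop("n_views x angular_step must cover 360 degrees")
  if (duration <= 0) stop("duration must be positive")
  structure(list(n_views = as.integer(n_views),
                 angular_step = angular_step,
                 detector_radius = detector_radius,
                 duration = duration),
            class = "acquisition_geometry")
}

#' Energy windows
#'
#' Photopeak and scatter windows given as centre plus/minus a fractional
#' half-width; the defaults are 208 keV (+/- 6 percent) and 185 keV (+/- 5
#' percent).  The ratio of window widths enters the dual-energy-window
#' scatter estimate.
#'
#' @param photopeak_center,photopeak_halfwidth_frac Photopeak centre (keV)
#'   and fractional half-width.
#' @param scatter_center,scatter_halfwidth_frac Scatter window centre (keV)
#'   and fractional half-width.
#' @return An object of class `energy_windows` with window bounds (keV) and
#'   `width_ratio` (photopeak width / scatter width).
#' @export
energy_windows <- function(photopeak_center = 208,
                           photopeak_halfwidth_frac = 0.06,
                           scatter_center = 185,
                           scatter_halfwidth_frac = 0.05) {
  pp <- photopeak_center * c(1 - photopeak_halfwidth_frac,
                             1 + photopeak_halfwidth_frac)
  sc <- scatter_center * c(1 - scatter_halfwidth_frac,
                           1 + scatter_halfwidth_frac)
  if (sc[2] > pp[1]) stop("windows must be disjoint")
  structure(list(photopeak = pp, scatter = sc,
                 width_ratio = diff(pp) / diff(sc)),
            class = "energy_windows")
}

#' Detector and collimator model
#'
#' Gaussian distance-dependent collimator-detector response with total FWHM
#' `sqrt(psf_intrinsic_fwhm^2 + (psf_offset + psf_slope * d)^2)` at distance
#' `d` from the collimator face, a very broad Gaussian septal-penetration
#' tail carrying `pen_fraction` of the geometric counts, and an emulated
#' downscatter/tail component: the scatter window records `scatter_alpha`
#' times the geometric projection blurred with `scatter_fwhm`, and the
#' photopeak is contaminated by the same component scaled by the window
#' width ratio.  The default dual-energy-window correction (see
#' [dew_scatter_estimate()]) is calibrated to remove the total photopeak
#' contamination but carries the scatter window's narrower spatial shape —
#' the shape mismatch with the much broader penetration tail is what
#' produces the halo artefact and interior underestimation this detector
#' model is designed to exhibit.
#'
#' @param sensitivity System sensitivity in air, cps/MBq.
#' @param psf_intrinsic_fwhm Intrinsic detector FWHM, mm.
#' @param psf_offset,psf_slope Collimator FWHM at the face (mm) and growth
#'   per mm distance.
#' @param pen_fraction Fraction of geometric counts diverted into the
#'   penetration tail, in `[0, 1)`.
#' @param pen_fwhm FWHM (mm) of the penetration tail, broad relative to
#'   the imaged bodies (long-range septal-penetration streaks).
#' @param scatter_alpha Scatter-window amplitude relative to the geometric
#'   projection.
#' @param scatter_fwhm FWHM of the scatter blur, mm.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(sensitivity = 136, psf_intrinsic_fwhm = 2.46,
                           psf_offset = 2, psf_slope = 0.03,
                           pen_fraction = 0.2, pen_fwhm = 250,
                           scatter_alpha = 0.15, scatter_fwhm = 60) {
  if (sensitivity <= 0) stop("sensitivity must be positive")
  if (psf_intrinsic_fwhm <= 0 || pen_fwhm <= 0 || scatter_fwhm <= 0)
    stop("all FWHMs must be positive")
  if (pen_fraction < 0 || pen_fraction >= 1)
    stop("pen_fraction must be in [0, 1)")
  if (scatter_alpha < 0) stop("scatter_alpha must be nonnegative")
  structure(list(sensitivity = sensitivity,
                 psf_intrinsic_fwhm = psf_intrinsic_fwhm,
                 psf_offset = psf_offset, psf_slope = psf_slope,
                 pen_fraction = pen_fraction, pen_fwhm = pen_fwhm,
                 scatter_alpha = scatter_alpha, scatter_fwhm = scatter_fwhm),
            class = "detector_model")
}

view_angles_rad <- function(geom) {
  (seq_len(geom$n_views) - 1) * geom$angular_step * pi / 180
}

#' Forward-project an activity map into dual-window projection data
#'
#' Simulates the expected (noiseless) projection counts for every view:
#' the volume is rotated into the detector frame, attenuated along the
#' projection direction, blurred plane by plane with the distance-dependent
#' collimator response, and summed along rays.  Septal penetration and the
#' scatter/tail component are added as broad Gaussian redistributions of the
#' geometric counts (see [detector_model()]).  Counts are scaled so a point
#' source of activity `A` in air yields `sensitivity * A * duration`
#' expected geometric counts over the full acquisition.  Physical decay is
#' applied from the activity map's reference time to `acq_start`.
#'
#' @param activity An [activity_map()] (MBq/mL).
#' @param mu A [mu_map()] on the same grid.
#' @param geom An [acquisition_geometry()].
#' @param det A [detector_model()].
#' @param windows An [energy_windows()].
#' @param acq_start Acquisition start time (s, same clock as the activity
#'   map's `ref_time`).
#' @param half_life Physical half-life (s) used for the decay to
#'   `acq_start`.
#' @return An object of class `projection_set` holding noiseless mean count
#'   arrays `photopeak` and `scatter` of dimension (nu, nv, n_views).
#' @export
forward_project <- function(activity, mu, geom = acquisition_geometry(),
                            det = detector_model(),
                            windows = energy_windows(),
                            acq_start = activity$ref_time,
                            half_life = lu177_half_life()) {
  stopifnot(inherits(activity, "activity_map"), inherits(mu, "mu_map"))
  if (!grids_equal(activity$grid, mu$grid))
    stop("activity and mu must share a grid")
  g <- activity$grid
  if (g$shape[1] != g$shape[2])
    stop("in-plane grid must be square for rotation-based projection")
  decay <- exp(-log(2) * (acq_start - activity$ref_time) / half_life)
  dwell <- geom$duration / geom$n_views
  scale <- det$sensitivity * dwell * voxel_volume(g, "mL") * decay
  sim <- cpp_simulate(activity$values, mu$values, g$spacing,
                      view_angles_rad(geom), geom$detector_radius,
                      det$psf_intrinsic_fwhm, det$psf_offset, det$psf_slope,
                      det$pen_fraction, det$pen_fwhm,
                      det$scatter_alpha, det$scatter_fwhm,
                      windows$width_ratio, scale)
  structure(list(photopeak = sim$photopeak, scatter = sim$scatter,
                 geometry = geom, windows = windows, detector = det,
                 grid = g, acq_start = acq_start, noiseless = TRUE,
                 noiseless_mean = NULL, seed = NULL),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf(
    "<projection_set> %d views, %d x %d bins, %.4g photopeak counts (%s)\n",
    x$geometry$n_views, dim(x$photopeak)[1], dim(x$photopeak)[2],
    sum(x$photopeak), if (x$noiseless) "noiseless means" else "Poisson"))
  invisible(x)
}

#' Apply Poisson counting noise to a projection set
#'
#' Independent Poisson draw per bin and window; the noiseless means are
#' retained in `noiseless_mean`.  Reproducible under `seed`; the caller's
#' RNG state is restored.
#'
#' @param proj A noiseless [forward_project()] result.
#' @param seed Integer seed.
#' @return The projection set with integer-valued count arrays.
#' @export
add_poisson_noise <- function(proj, seed) {
  stopifnot(inherits(proj, "projection_set"))
  if (!proj$noiseless) stop("projection set does not hold noiseless means")
  if (any(proj$photopeak < 0) || any(proj$scatter < 0))
    stop("negative means")
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  out <- proj
  out$noiseless_mean <- list(photopeak = proj$photopeak,
                             scatter = proj$scatter)
  out$photopeak <- array(rpois(length(proj$photopeak), proj$photopeak),
                         dim = dim(proj$photopeak))
  out$scatter <- array(rpois(length(proj$scatter), proj$scatter),
                       dim = dim(proj$scatter))
  out$noiseless <- FALSE
  out$seed <- seed
  out
}

#' Radioactive decay of an activity
#'
#' @param A Activity (MBq).
#' @param dt Elapsed time (s); may be negative to back-decay.
#' @param half_life Physical half-life (s).
#' @return `A * exp(-log(2) * dt / half_life)`.
#' @export
#' @examples
#' decay_activity(541, lu177_half_life(), lu177_half_life())
decay_activity <- function(A, dt, half_life = lu177_half_life()) {
  if (half_life <= 0) stop("half_life must be positive")
  A * exp(-log(2) * dt / half_life)
}
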