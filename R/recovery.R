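# Recovery coefficients on the NEMA spheres, with CT-grid resampling.

#' Resample a reconstruction to another (CT) grid
#'
#' Trilinear interpolation of the counts-per-voxel values onto the target
#' grid, with values rescaled by the voxel-volume ratio so that total counts
#' are preserved (voxel values are treated as densities during the
#' interpolation).  Identical grids pass through unchanged.
#'
#' @param recon A `recon_volume`.
#' @param ct_grid Target [voxel_grid()] (CT resolution, typically
#'   1.0 x 1.0 x 2.5 mm).
#' @return A `recon_volume` on `ct_grid`.
#' @export
resample_to_ct <- function(recon, ct_grid) {
  stopifnot(inherits(recon, "recon_volume"), inherits(ct_grid, "voxel_grid"))
  if (grids_equal(recon$grid, ct_grid)) return(recon)
  src <- recon$grid
  lo_s <- src$origin; hi_s <- src$origin + (src$shape - 1) * src$spacing
  lo_d <- ct_grid$origin
  hi_d <- ct_grid$origin + (ct_grid$shape - 1) * ct_grid$spacing
  if (any(hi_d < lo_s) || any(lo_d > hi_s)) stop("grids do not overlap")
  vals <- cpp_resample_trilinear(recon$values, src$spacing, src$origin,
                                 ct_grid$shape, ct_grid$spacing,
                                 ct_grid$origin)
  vals <- vals * voxel_volume(ct_grid) / voxel_volume(src)
  recon_volume(ct_grid, vals, recon$params, recon$t_acq, recon$acq_start)
}

#' Spherical VOI on a (CT) grid
#'
#' Geometric sphere mask rendered from a known centre and diameter, with
#' 3x3x3 partial-volume subsampling (voxels at least half inside belong to
#' the mask).  The synthetic equivalent of a manual CT delineation.
#'
#' @param grid A [voxel_grid()].
#' @param center Sphere centre, world mm.
#' @param diameter Sphere diameter, mm.
#' @return An object of class `sphere_voi` with `mask`, `volume_ml`,
#'   `center` and `diameter`.
#' @export
sphere_voi <- function(grid, center, diameter) {
  if (diameter <= 0) stop("diameter must be positive")
  r <- diameter / 2
  frac <- voxelize_fraction(grid, function(x, y, z) {
    (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= r^2
  })
  mask <- frac >= 0.5
  structure(list(mask = mask,
                 volume_ml = sum(mask) * voxel_volume(grid, "mL"),
                 center = center, diameter = diameter, grid = grid),
            class = "sphere_voi")
}

#' Recovery coefficient of a spherical insert
#'
#' Measured-to-true activity concentration ratio in percent:
#' `RC = C / (T_acq * ICF * V) / (c_prep * exp(-log(2) * dt / half_life))
#' * 100`, with `C` the counts inside the spherical VOI on the resampled
#' image, `V` the VOI volume (mL) and `c_prep` the prepared concentration
#' (MBq/mL).
#'
#' @param resampled A `recon_volume` on the VOI grid (see
#'   [resample_to_ct()]).
#' @param voi A [sphere_voi()].
#' @param icf An [icf_result][compute_icf()] from the same protocol.
#' @param c_prep Prepared sphere concentration, MBq/mL.
#' @param dt Preparation-to-acquisition delay, s.
#' @param half_life Physical half-life, s.
#' @param override Allow a protocol mismatch.
#' @return Recovery coefficient in percent.
#' @export
compute_rc <- function(resampled, voi, icf, c_prep, dt = 0,
                       half_life = lu177_half_life(), override = FALSE) {
  stopifnot(inherits(resampled, "recon_volume"), inherits(voi, "sphere_voi"),
            inherits(icf, "icf_result"))
  if (!same_protocol(resampled$params, icf$params) && !override)
    stop("ICF protocol does not match the reconstruction protocol")
  if (voi$volume_ml <= 0) stop("VOI volume is zero")
  if (!all(dim(voi$mask) == resampled$grid$shape))
    stop("VOI grid does not match the resampled volume")
  C <- sum(resampled$values[voi$mask])
  conc_meas <- C / (resampled$t_acq * icf$icf * voi$volume_ml)
  conc_true <- c_prep * exp(-log(2) * dt / half_life)
  100 * conc_meas / conc_true
}

#' Recovery-coefficient table for a set of reconstructions
#'
#' @param recons Named list of `recon_volume`s (native SPECT grid).
#' @param spheres List of [sphere_voi()]s on the CT grid.
#' @param icfs List of [icf_result][compute_icf()]s parallel to `recons`.
#' @param c_prep Prepared sphere concentration, MBq/mL.
#' @param ct_grid CT-resolution [voxel_grid()] the images are resampled to.
#' @param background `"cold"` or `"hot"` label carried into the table.
#' @param dt,half_life Decay bookkeeping as in [compute_rc()].
#' @return Data frame keyed by (protocol, algorithm, iterations, subsets,
#'   sphere diameter, background) with an `rc` column in percent.
#' @export
rc_table <- function(recons, spheres, icfs, c_prep, ct_grid,
                     background = "cold", dt = 0,
                     half_life = lu177_half_life()) {
  if (length(recons) == 0L)
    return(data.frame(protocol = character(), algorithm = character(),
                      iterations = integer(), subsets = integer(),
                      diameter_mm = numeric(), background = character(),
                      rc = numeric()))
  rows <- list()
  for (i in seq_along(recons)) {
    rs <- resample_to_ct(recons[[i]], ct_grid)
    p <- recons[[i]]$params
    for (sph in spheres) {
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = protocol_label(p), algorithm = p$algorithm,
        iterations = p$iterations, subsets = p$subsets,
        diameter_mm = sph$diameter, background = background,
        rc = compute_rc(rs, sph, icfs[[i]], c_prep, dt, half_life))
    }
  }
  do.call(rbind, rows)
}
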