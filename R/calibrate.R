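# Image calibration factor (ICF) and activity quantification accuracy.

#' Cylindrical volume of interest
#'
#' Boolean voxel mask of a cylinder (axis along z).  A voxel belongs to the
#' VOI when its centre lies inside; the reported volume is the voxel count
#' times the voxel volume.
#'
#' @param grid A [voxel_grid()].
#' @param diameter,height Cylinder dimensions, mm.
#' @param center Cylinder centre, world mm (default: grid centre axis).
#' @return Logical array with attributes `volume_ml` and `volume_l`.
#' @export
#' @examples
#' g <- voxel_grid(c(96, 96, 96), spacing = 2.46)
#' v <- make_cylindrical_voi(g, diameter = 140, height = 126)
#' attr(v, "volume_l")  # about 1.9 L
make_cylindrical_voi <- function(grid, diameter, height, center = c(0, 0, 0)) {
  if (diameter <= 0 || height <= 0)
    stop("VOI dimensions must be positive: empty mask")
  check_fits(abs(center) * 2 + c(diameter, diameter, height), grid, "VOI")
  co <- grid_coord_arrays(grid)
  mask <- ((co$x - center[1])^2 + (co$y - center[2])^2 <= (diameter / 2)^2) &
    (abs(co$z - center[3]) <= height / 2)
  vol_ml <- sum(mask) * voxel_volume(grid, "mL")
  attr(mask, "volume_ml") <- vol_ml
  attr(mask, "volume_l") <- vol_ml / 1000
  mask
}

#' Calibration inputs
#'
#' Bundles the quantities entering the calibration-factor equation: the
#' prepared activity, its relative uncertainty, the prep-to-acquisition
#' delay and the half-life.
#'
#' @param a_prep Activity at phantom preparation, MBq.
#' @param dt Time from preparation to acquisition start, s.
#' @param half_life Physical half-life, s.
#' @param u_a_rel Relative standard uncertainty of `a_prep` (default 2
#'   percent, the typical radionuclide-calibrator uncertainty).
#' @return An object of class `calibration_inputs`.
#' @export
calibration_inputs <- function(a_prep, dt = 0,
                               half_life = lu177_half_life(),
                               u_a_rel = 0.02) {
  if (a_prep <= 0) stop("a_prep must be positive")
  if (half_life <= 0) stop("half_life must be positive")
  structure(list(a_prep = a_prep, dt = dt, half_life = half_life,
                 u_a_rel = u_a_rel),
            class = "calibration_inputs")
}

#' Image calibration factor
#'
#' `ICF = C / (T_acq * A_prep * exp(-log(2) * dt / half_life))` in cps/MBq,
#' with `C` the total reconstructed counts inside the calibration VOI and
#' the decayed denominator the activity present at acquisition start.  The
#' relative uncertainty combines the counting term `sqrt(C)/C` with the
#' activity uncertainty (see [compute_icf_uncertainty()]).
#'
#' @param recon A `recon_volume`.
#' @param voi Logical mask on the reconstruction grid.
#' @param inputs A [calibration_inputs()].
#' @return An object of class `icf_result` with fields `icf`, `u_icf_rel`,
#'   `counts`, `voi_volume_ml` and the reconstruction `params`.
#' @export
compute_icf <- function(recon, voi, inputs) {
  stopifnot(inherits(recon, "recon_volume"),
            inherits(inputs, "calibration_inputs"))
  if (!all(dim(voi) == recon$grid$shape))
    stop("VOI does not match the reconstruction grid")
  C <- sum(recon$values[voi])
  if (C <= 0) stop("zero counts in the calibration VOI")
  a_acq <- decay_activity(inputs$a_prep, inputs$dt, inputs$half_life)
  icf <- C / (recon$t_acq * a_acq)
  structure(list(icf = icf,
                 u_icf_rel = compute_icf_uncertainty(C, inputs$u_a_rel),
                 counts = C,
                 voi_volume_ml = sum(voi) * voxel_volume(recon$grid, "mL"),
                 t_acq = recon$t_acq,
                 params = recon$params),
            class = "icf_result")
}

#' @export
print.icf_result <- function(x, ...) {
  cat(sprintf("<icf_result> %.4g cps/MBq (u = %.2g%%), %s\n",
              x$icf, 100 * x$u_icf_rel, protocol_label(x$params)))
  invisible(x)
}

#' Relative uncertainty of the calibration factor
#'
#' Propagation of the counting uncertainty `u(C) = sqrt(C)` and the
#' relative activity uncertainty:
#' `u(ICF)/ICF = sqrt((sqrt(C)/C)^2 + u_a_rel^2)`.  The square-root counting
#' model is applied to the reconstructed counts as such, a deliberate
#' convention even though reconstructed voxels are not independent Poisson
#' variables.
#'
#' @param C Total reconstructed counts in the calibration VOI (> 0).
#' @param u_a_rel Relative uncertainty of the prepared activity.
#' @return Relative uncertainty (fraction).
#' @export
#' @examples
#' compute_icf_uncertainty(4.6e7, 0.02)  # ~0.020
compute_icf_uncertainty <- function(C, u_a_rel = 0.02) {
  if (C <= 0) stop("C must be positive")
  sqrt(1 / C + u_a_rel^2)
}

#' Quantify activity (or activity concentration) in a VOI
#'
#' `A_meas = sum(counts in VOI) / (T_acq * ICF)` in MBq; the concentration
#' variant divides by the VOI volume.  The quantification error is
#' `(A_meas - truth) / truth`.  The ICF must come from the same
#' reconstruction protocol as the volume being quantified; pass
#' `override = TRUE` to bypass the check (a warning is emitted).
#'
#' @param recon A `recon_volume`.
#' @param voi Logical mask on the reconstruction grid.
#' @param icf An [icf_result][compute_icf()].
#' @param truth True decayed activity (MBq) or concentration (MBq/mL),
#'   matching `mode`.
#' @param mode `"activity"` or `"concentration"`.
#' @param override Allow a protocol mismatch between `icf` and `recon`.
#' @return An object of class `quant_result` with `a_meas`, `truth` and
#'   `error` (fraction).
#' @export
quantify <- function(recon, voi, icf, truth,
                     mode = c("activity", "concentration"),
                     override = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(recon, "recon_volume"), inherits(icf, "icf_result"))
  if (!same_protocol(recon$params, icf$params)) {
    if (!override)
      stop("ICF protocol does not match the reconstruction protocol")
    warning("quantifying with an ICF from a different protocol")
  }
  if (!all(dim(voi) == recon$grid$shape))
    stop("VOI does not match the reconstruction grid")
  C <- sum(recon$values[voi])
  a_meas <- C / (recon$t_acq * icf$icf)
  if (mode == "concentration")
    a_meas <- a_meas / (sum(voi) * voxel_volume(recon$grid, "mL"))
  structure(list(a_meas = a_meas, truth = truth,
                 error = (a_meas - truth) / truth,
                 mode = mode, params = recon$params),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s %.4g vs truth %.4g: error %+.2f%%\n",
              x$mode, x$a_meas, x$truth, 100 * x$error))
  invisible(x)
}
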