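# Digital phantoms: voxelized activity (MBq/mL) and attenuation (1/mm at
# 208 keV) maps.  Compartment boundaries are anti-aliased by 3x3x3
# subsampling of each voxel, which keeps voxelized volumes close to the
# analytic ones and makes activity fills mass-conserving.

#' Construct an activity map
#'
#' @param grid A [voxel_grid()].
#' @param values Array of activity concentration (MBq/mL), one value per
#'   voxel; must be nonnegative.
#' @param ref_time Reference time (s) at which the concentrations hold.
#' @return An object of class `activity_map`.
#' @export
activity_map <- function(grid, values, ref_time = 0) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (!all(dim(values) == grid$shape)) stop("values do not match grid shape")
  if (any(values < 0)) stop("activity concentrations must be nonnegative")
  structure(list(grid = grid, values = values, ref_time = ref_time),
            class = "activity_map")
}

#' Construct an attenuation map
#'
#' @param grid A [voxel_grid()].
#' @param values Array of linear attenuation coefficients (1/mm at 208 keV).
#' @return An object of class `mu_map`.
#' @export
mu_map <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (!all(dim(values) == grid$shape)) stop("values do not match grid shape")
  if (any(values < 0)) stop("attenuation coefficients must be nonnegative")
  structure(list(grid = grid, values = values), class = "mu_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> total %.4g MBq on ", total_activity(x)))
  print(x$grid)
  invisible(x)
}

#' @export
print.mu_map <- function(x, ...) {
  cat(sprintf("<mu_map> support %d voxels on ", sum(x$values > 0)))
  print(x$grid)
  invisible(x)
}

#' Total activity of an activity map
#'
#' @param map An [activity_map()].
#' @return Total activity in MBq (sum of concentration times voxel volume).
#' @export
total_activity <- function(map) {
  sum(map$values) * voxel_volume(map$grid, "mL")
}

# fraction of each voxel inside the region described by `inside_fn(x, y, z)`
# (world mm coordinates, vectorized), by 3x subsampling per axis.  Voxels
# away from the boundary keep their centre value; only voxels where the
# centre classification changes within one voxel are subsampled.
voxelize_fraction <- function(grid, inside_fn) {
  co <- grid_coord_arrays(grid)
  ctr <- inside_fn(co$x, co$y, co$z)
  frac <- array(as.numeric(ctr), dim = grid$shape)
  # boundary voxels: centre classification differs from any face neighbour
  sh <- function(a, ax, by) {
    out <- a
    n <- dim(a)[ax]
    src <- seq_len(n) - by
    src <- pmin(pmax(src, 1L), n)
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[ax]] <- src
    do.call(`[`, c(list(a), idx))
  }
  bnd <- array(FALSE, dim = grid$shape)
  for (ax in 1:3) for (by in c(-1L, 1L)) bnd <- bnd | (ctr != sh(ctr, ax, by))
  idx <- which(bnd)
  if (length(idx)) {
    x0 <- co$x[idx]; y0 <- co$y[idx]; z0 <- co$z[idx]
    acc <- numeric(length(idx))
    sub <- c(-1, 0, 1) / 3
    for (ox in sub) for (oy in sub) for (oz in sub)
      acc <- acc + inside_fn(x0 + ox * grid$spacing[1],
                             y0 + oy * grid$spacing[2],
                             z0 + oz * grid$spacing[3])
    frac[idx] <- acc / 27
  }
  frac
}

check_fits <- function(extent_needed, grid, what) {
  if (any(extent_needed > grid_extent(grid) + 1e-9))
    stop(sprintf("%s (%.0f x %.0f x %.0f mm) exceeds the grid extent", what,
                 extent_needed[1], extent_needed[2], extent_needed[3]))
}

#' Uniform cylinder phantom
#'
#' Builds a uniformly filled, water-attenuating cylinder (axis along z,
#' centred in the grid by default).  The fill is mass-conserving: the voxel
#' concentrations are scaled so that the total activity of the map equals
#' `activity` exactly.
#'
#' @param diameter,height Cylinder dimensions in mm.
#' @param activity Total activity in MBq.
#' @param grid A [voxel_grid()].
#' @param center Cylinder centre in world mm.
#' @param mu_water Linear attenuation inside the body (1/mm at 208 keV).
#' @param ref_time Preparation time (s) of the stated activity.
#' @return List with `activity` ([activity_map()]), `mu` ([mu_map()]) and
#'   `volume_ml` (voxelized body volume).
#' @export
#' @examples
#' g <- voxel_grid(c(48, 48, 48), spacing = 4.92)
#' ph <- make_cylinder_phantom(200, 180, 700, g)
#' total_activity(ph$activity)
make_cylinder_phantom <- function(diameter, height, activity, grid,
                                  center = c(0, 0, 0),
                                  mu_water = MU_WATER_208, ref_time = 0) {
  if (diameter <= 0 || height <= 0) stop("dimensions must be positive")
  if (activity < 0) stop("activity must be nonnegative")
  check_fits(abs(center) * 2 + c(diameter, diameter, height), grid, "cylinder")
  r <- diameter / 2
  frac <- voxelize_fraction(grid, function(x, y, z) {
    ((x - center[1])^2 + (y - center[2])^2 <= r^2) &
      (abs(z - center[3]) <= height / 2)
  })
  vol_ml <- sum(frac) * voxel_volume(grid, "mL")
  conc <- if (activity > 0) activity / vol_ml else 0
  list(activity = activity_map(grid, conc * frac, ref_time = ref_time),
       mu = mu_map(grid, mu_water * frac),
       volume_ml = vol_ml)
}

#' NEMA IEC sphere phantom
#'
#' Six spheres (diameters 10, 13, 17, 22, 28 and 37 mm) placed on a
#' 57.2 mm-radius ring in one transaxial plane, inside an elliptic-cylinder
#' body.  `background_conc = 0` gives the cold-background configuration.
#'
#' @param sphere_conc Activity concentration in the spheres (MBq/mL).
#' @param background_conc Activity concentration in the body (MBq/mL).
#' @param grid A [voxel_grid()].
#' @param body_semiaxes Transaxial semi-axes of the body (mm).
#' @param body_height Body height (mm).
#' @param mu_water Linear attenuation inside the body (1/mm).
#' @param ref_time Preparation time (s) of the stated concentrations.
#' @return List with `activity`, `mu`, `sphere_centers` (6 x 3 matrix, mm),
#'   `sphere_diameters`, per-sphere fraction masks `sphere_frac` and
#'   voxelized sphere volumes `sphere_volumes_ml`.
#' @export
make_nema_phantom <- function(sphere_conc, background_conc = 0, grid,
                              body_semiaxes = c(150, 110), body_height = 180,
                              mu_water = MU_WATER_208, ref_time = 0) {
  if (sphere_conc < 0 || background_conc < 0)
    stop("concentrations must be nonnegative")
  check_fits(c(2 * body_semiaxes, body_height), grid, "NEMA body")
  ang <- (0:5) * pi / 3
  centers <- cbind(NEMA_RING_RADIUS * cos(ang), NEMA_RING_RADIUS * sin(ang), 0)
  d <- NEMA_SPHERE_DIAMETERS
  # adjacent centres sit one ring radius apart; radii sums must stay smaller
  for (i in 1:5)
    if ((d[i] + d[i + 1]) / 2 >= NEMA_RING_RADIUS)
      stop("spheres overlap after placement")
  body <- voxelize_fraction(grid, function(x, y, z) {
    ((x / body_semiaxes[1])^2 + (y / body_semiaxes[2])^2 <= 1) &
      (abs(z) <= body_height / 2)
  })
  sphere_frac <- vector("list", 6L)
  vols <- numeric(6L)
  stot <- array(0, dim = grid$shape)
  for (i in 1:6) {
    ci <- centers[i, ]
    ri <- d[i] / 2
    f <- voxelize_fraction(grid, function(x, y, z) {
      (x - ci[1])^2 + (y - ci[2])^2 + (z - ci[3])^2 <= ri^2
    })
    sphere_frac[[i]] <- f
    vols[i] <- sum(f) * voxel_volume(grid, "mL")
    stot <- stot + f
  }
  act <- sphere_conc * stot + background_conc * pmax(body - stot, 0)
  list(activity = activity_map(grid, act, ref_time = ref_time),
       mu = mu_map(grid, mu_water * body),
       sphere_centers = centers,
       sphere_diameters = d,
       sphere_frac = sphere_frac,
       sphere_volumes_ml = vols)
}

#' Patient-like lesion phantom
#'
#' An ellipsoidal torso with low uniform background uptake and randomly
#' placed ellipsoidal lesions, mimicking post-therapy Lu-177 distributions.
#' Lesion volumes and activity concentrations are drawn uniformly from the
#' supplied ranges; placement is rejection-sampled so lesions stay inside the
#' torso and do not overlap.  Fully reproducible under `seed`.
#'
#' @param n_lesions Number of lesions (>= 1).
#' @param lesion_volume_range Range of lesion volumes, mL.
#' @param lesion_conc_range Range of lesion concentrations, kBq/mL.
#' @param grid A [voxel_grid()].
#' @param seed Integer seed.
#' @param background_kbq_ml Torso background concentration, kBq/mL.
#' @param torso_semiaxes Torso ellipsoid semi-axes, mm.
#' @param mu_water Linear attenuation inside the torso (1/mm).
#' @param max_tries Placement retries per lesion before failing.
#' @return List with `activity`, `mu`, `lesion_masks` (list of logical
#'   arrays) and a `lesions` data frame (centre, equivalent diameter, true
#'   volume and concentration).
#' @export
make_patient_phantom <- function(n_lesions,
                                 lesion_volume_range = c(5.3, 29.5),
                                 lesion_conc_range = c(204, 5648),
                                 grid, seed = 1,
                                 background_kbq_ml = 50,
                                 torso_semiaxes = c(150, 100, 200),
                                 mu_water = MU_WATER_208,
                                 max_tries = 200L) {
  if (n_lesions < 1) stop("n_lesions must be >= 1")
  if (any(lesion_volume_range <= 0) || any(lesion_conc_range <= 0))
    stop("ranges must be positive")
  sa <- pmin(torso_semiaxes, grid_extent(grid) / 2)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  vols <- runif(n_lesions, lesion_volume_range[1], lesion_volume_range[2])
  concs <- runif(n_lesions, lesion_conc_range[1], lesion_conc_range[2])
  # ellipsoid with mild random anisotropy, volume-preserving
  radii <- matrix(0, n_lesions, 3)
  centers <- matrix(0, n_lesions, 3)
  for (i in seq_len(n_lesions)) {
    r_eq <- (3 * vols[i] * 1000 / (4 * pi))^(1 / 3)
    ar <- runif(2, 0.8, 1.25)
    radii[i, ] <- r_eq * c(ar[1], ar[2], 1 / (ar[1] * ar[2]))
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- runif(3, -1, 1) * (sa - radii[i, ] - grid$spacing)
      # inside torso: centre plus radius margin within the ellipsoid
      if (sum(((abs(cand) + radii[i, ]) / sa)^2) > 1) next
      ok <- TRUE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          gap <- sqrt(sum((cand - centers[j, ])^2))
          if (gap < max(radii[i, ]) + max(radii[j, ]) + grid$spacing[1]) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place lesion ", i, " without overlap")
  }

  torso <- voxelize_fraction(grid, function(x, y, z) {
    (x / sa[1])^2 + (y / sa[2])^2 + (z / sa[3])^2 <= 1
  })
  act <- background_kbq_ml / 1000 * torso
  masks <- vector("list", n_lesions)
  for (i in seq_len(n_lesions)) {
    ci <- centers[i, ]; ri <- radii[i, ]
    f <- voxelize_fraction(grid, function(x, y, z) {
      ((x - ci[1]) / ri[1])^2 + ((y - ci[2]) / ri[2])^2 +
        ((z - ci[3]) / ri[3])^2 <= 1
    })
    act <- act + (concs[i] / 1000 - background_kbq_ml / 1000) * f
    masks[[i]] <- f >= 0.5
  }
  lesions <- data.frame(
    lesion = seq_len(n_lesions),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    volume_ml = vols, conc_kbq_ml = concs
  )
  list(activity = activity_map(grid, pmax(act, 0)),
       mu = mu_map(grid, mu_water * torso),
       lesion_masks = masks, lesions = lesions)
}

# seed the RNG restorably: returns a restore function for on.exit
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
}
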