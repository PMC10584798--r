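# Protocol optimization by noise matching, lesion segmentation and
# quantification, and paired nonparametric statistics.

#' Select the protocol whose noise matches a target
#'
#' Picks the candidate minimizing `|cv - target_cv|`; exact ties are broken
#' in favour of fewer updates.  This mirrors the selection of the
#' iteration-subset combination whose noise equals that of the factory
#' protocol.
#'
#' @param candidates List of candidates, each a list with elements `params`
#'   (a [recon_params()]) and `cv` (measured noise).
#' @param target_cv Target coefficient of variation.
#' @return The winning candidate, augmented with `delta_cv`.
#' @export
#' @examples
#' cands <- list(
#'   list(params = recon_params("OSEM", 48), cv = 0.12),
#'   list(params = recon_params("OSEM", 72), cv = 0.149),
#'   list(params = recon_params("OSEM", 96), cv = 0.19))
#' protocol_label(match_noise(cands, 0.15)$params)
match_noise <- function(candidates, target_cv) {
  if (length(candidates) == 0L) stop("empty candidate list")
  delta <- vapply(candidates, function(c) abs(c$cv - target_cv), numeric(1))
  updates <- vapply(candidates, function(c) c$params$updates, numeric(1))
  ord <- order(delta, updates)
  if (length(candidates) == 1L)
    warning("single candidate: returned regardless of its noise distance")
  best <- candidates[[ord[1]]]
  best$delta_cv <- delta[ord[1]]
  best
}

# fractional-fill spherical kernel of a given volume (mL), normalized
sphere_kernel <- function(grid, volume_ml = 1) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  nr <- ceiling(r / grid$spacing) + 1L
  kg <- voxel_grid(2L * nr + 1L, spacing = grid$spacing)
  k <- voxelize_fraction(kg, function(x, y, z) x^2 + y^2 + z^2 <= r^2)
  k / sum(k)
}

#' Peak 1-mL mean of a volume
#'
#' Convolves the volume with a normalized spherical 1-mL kernel (radius
#' 6.2 mm) and returns the location and value of the largest mean inside
#' the search mask — the peak-VOI statistic used to anchor isocontour
#' segmentation.
#'
#' @param volume A `recon_volume`.
#' @param search_mask Logical mask restricting the peak search.
#' @param volume_ml Kernel volume, mL.
#' @return List with `center` (world mm), `center_index` and `peak_mean`.
#' @export
peak_1ml_mean <- function(volume, search_mask, volume_ml = 1) {
  stopifnot(inherits(volume, "recon_volume"))
  g <- volume$grid
  if (!all(dim(search_mask) == g$shape))
    stop("search mask does not match the volume")
  if (!any(search_mask)) stop("search mask is empty")
  kern <- sphere_kernel(g, volume_ml)
  if (sum(search_mask) * voxel_volume(g, "mL") < volume_ml)
    stop("search mask smaller than the kernel volume")
  sm <- cpp_conv3(volume$values, kern)
  sm[!search_mask] <- -Inf
  i <- arrayInd(which.max(sm), g$shape)
  list(center = as.numeric(index_to_world(g, as.numeric(i))),
       center_index = as.integer(i),
       peak_mean = max(sm))
}

#' Isocontour lesion segmentation
#'
#' Thresholds the volume at `fraction` of a previously determined peak mean
#' and keeps the 26-connected component containing the seed.  The resulting
#' mask is meant to be frozen and applied unchanged to every other
#' reconstruction of the same anatomy.
#'
#' @param volume A `recon_volume`.
#' @param seed_center World point (mm) inside the lesion.
#' @param peak_mean Reference peak value (see [peak_1ml_mean()]).
#' @param fraction Isocontour fraction of `peak_mean` (default 0.30).
#' @return Logical lesion mask.
#' @export
isocontour_segment <- function(volume, seed_center, peak_mean,
                               fraction = 0.30) {
  stopifnot(inherits(volume, "recon_volume"))
  if (peak_mean <= 0) stop("peak_mean must be positive")
  g <- volume$grid
  thr <- fraction * peak_mean
  idx <- round(world_to_index(g, seed_center))
  if (any(idx < 1) || any(idx > g$shape)) stop("seed outside the volume")
  if (volume$values[idx[1], idx[2], idx[3]] < thr)
    stop("seed voxel below the isocontour threshold")
  supra <- array(as.integer(volume$values >= thr), dim = g$shape)
  comp <- cpp_connected_component(supra, idx[1] - 1L, idx[2] - 1L,
                                  idx[3] - 1L)
  array(comp > 0, dim = g$shape)
}

#' Lesion activity concentration
#'
#' Mean activity concentration in a lesion mask via the calibration factor:
#' `sum(counts) / (T_acq * ICF * V)`, reported in kBq/mL.
#'
#' @param volume A `recon_volume`.
#' @param mask Logical lesion mask on the same grid.
#' @param icf An [icf_result][compute_icf()] from the same protocol.
#' @param override Allow a protocol mismatch.
#' @return Concentration in kBq/mL.
#' @export
lesion_concentration <- function(volume, mask, icf, override = FALSE) {
  stopifnot(inherits(volume, "recon_volume"), inherits(icf, "icf_result"))
  if (!same_protocol(volume$params, icf$params) && !override)
    stop("ICF protocol does not match the reconstruction protocol")
  if (!any(mask)) stop("empty lesion mask")
  v_ml <- sum(mask) * voxel_volume(volume$grid, "mL")
  1000 * sum(volume$values[mask]) / (volume$t_acq * icf$icf * v_ml)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired observations.  Zero differences are
#' dropped; ties receive mid-ranks.  For `n <= exact_max` pairs the p value
#' is exact, from the full null distribution of the positive-rank sum over
#' all `2^n` sign assignments (computed by convolution, equivalent to
#' enumeration); beyond that a normal approximation with tie correction is
#' used.
#'
#' @param a,b Paired measurement vectors (or `b` omitted and `a` a
#'   two-column matrix).
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `statistic` (positive-rank sum `V`), `p_value`, `n`
#'   (pairs after dropping zeros) and `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(3, 4, 5, 6, 7), c(1, 2, 3, 4, 5))$p_value # 0.0625
wilcoxon_signed_rank <- function(a, b = NULL, exact_max = 25L) {
  if (is.null(b)) {
    if (!is.matrix(a) || ncol(a) != 2L)
      stop("provide two vectors or a two-column matrix")
    b <- a[, 2]; a <- a[, 1]
  }
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) stop("fewer than two nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of the positive-rank sum over all sign assignments;
    # ranks doubled so mid-ranks become integers
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L)  # f[s + 1] = number of assignments with sum s
    f[1] <- 1
    for (ri in r2) {
      g <- numeric(tot + 1L)
      g[(ri + 1L):(tot + 1L)] <- f[1:(tot + 1L - ri)]
      f <- f + g
    }
    probs <- f / 2^n
    s <- 0:tot
    # symmetric null: two-sided p sums outcomes at least as extreme
    dev <- abs(s - tot / 2)
    p <- sum(probs[dev >= abs(2 * V - tot / 2) - 1e-9])
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = min(p, 1), n = n, method = method)
}

#' Five-number summary of relative differences
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by linear interpolation between order statistics (type 7).
#'
#' @param rel_diffs Numeric vector (nonempty).
#' @return Named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
summary_stats <- function(rel_diffs) {
  if (length(rel_diffs) == 0L) stop("empty input")
  q <- quantile(rel_diffs, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
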