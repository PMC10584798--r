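# Physical constants used throughout the package.  All lengths are mm,
# activities MBq, times s unless a function documents otherwise.

#' Physical half-life of Lu-177
#'
#' Evaluated physical half-life of Lu-177, 6.6475 days.
#'
#' @param unit `"s"` (default) or `"d"`.
#' @return Half-life in the requested unit.
#' @export
#' @examples
#' lu177_half_life("d")
lu177_half_life <- function(unit = c("s", "d")) {
  unit <- match.arg(unit)
  days <- 6.6475
  if (unit == "d") days else days * 86400
}

# linear attenuation coefficient of water at 208 keV [1/mm] (NIST)
MU_WATER_208 <- 0.0136

# NEMA IEC sphere insert diameters [mm] and canonical ring radius [mm]
NEMA_SPHERE_DIAMETERS <- c(10, 13, 17, 22, 28, 37)
NEMA_RING_RADIUS <- 57.2

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))
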