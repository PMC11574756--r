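# Canonical conformer lattice of the six-membered-ring puckering sphere.
#
# With the ring atoms ordered O5, C1, C2, C3, C4, C5 (the glycoscience
# convention used throughout this package) the 4C1 chair sits at the north
# pole (theta = 0) and 1C4 at the south pole. Boats and twist-boats (skews)
# alternate every 30 degrees of phi on the equator; envelopes and half-chairs
# alternate every 30 degrees on the theta = 54.74 / 125.26 degree bands
# (54.7356 = atan(sqrt(2)), the latitude of a pure single-atom displacement).
#
# The lattice is constructed, not tabulated: each canonical name corresponds
# to a pure m = 2 and/or m = 3 displacement pattern whose (theta, phi) follow
# from the puckering sums in closed form. Names use the flat IUPAC encoding
# with ring-position superscripts before and subscripts after the family
# letter ("4C1", "1,4B", "4E", "OS2", ...).

.theta_env <- 54.7356103172453  # atan(sqrt(2)) in degrees

.conformer_lattice <- local({
  equator <- c("3,OB", "3S1", "B1,4", "5S1", "2,5B", "2SO",
               "B3,O", "1S3", "1,4B", "1S5", "B2,5", "OS2")
  north <- c("OE", "OH1", "E1", "2H1", "2E", "2H3",
             "E3", "4H3", "4E", "4H5", "E5", "OH5")
  south <- c("3E", "3H4", "E4", "5H4", "5E", "5HO",
             "EO", "1HO", "1E", "1H2", "E2", "3H2")
  phi12 <- seq(0, 330, by = 30)
  fam_eq <- rep(c("boat", "twist-boat"), 6)
  fam_band <- rep(c("envelope", "half-chair"), 6)
  tibble::tibble(
    name = c("4C1", "1C4", equator, north, south),
    family = c("chair", "chair", fam_eq, fam_band, fam_band),
    canonical_theta = c(0, 180, rep(90, 12),
                        rep(.theta_env, 12), rep(180 - .theta_env, 12)),
    canonical_phi = c(0, 0, phi12, phi12, phi12)
  )
})

#' Canonical conformers of a six-membered ring
#'
#' The 38 canonical puckered conformers of a pyranose-type ring and their
#' positions on the Cremer--Pople sphere: 2 chairs at the poles, 6 boats and
#' 6 twist-boats alternating every 30 degrees on the equator, and 12
#' envelopes plus 12 half-chairs alternating every 30 degrees on the
#' `theta = 54.74` and `125.26` degree bands. Ring atoms are ordered
#' O5, C1, ..., C5, which places `4C1` at the north pole.
#'
#' @return A tibble with columns `name`, `family`, `canonical_theta`,
#'   `canonical_phi` (degrees).
#' @export
#' @examples
#' conformer_table()
conformer_table <- function() .conformer_lattice

# Canonical (theta, phi) of a named conformer; errors on unknown names.
conformer_angles <- function(name) {
  i <- match(name, .conformer_lattice$name)
  if (anyNA(i)) {
    abort(paste0("unknown conformer name(s): ",
                 paste(name[is.na(i)], collapse = ", ")))
  }
  list(theta = .conformer_lattice$canonical_theta[i],
       phi = .conformer_lattice$canonical_phi[i])
}
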