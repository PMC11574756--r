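# Cremer-Pople puckering coordinates for six-membered rings.
#
# Atom ordering is fixed and matters: position 1 = O5 (ring oxygen), then
# C1..C5. Conformer names flip hemispheres under re-ordering (a B1,4 ring
# relabelled becomes 1,4B), so every function in this file assumes -- and the
# readers enforce -- this order. Angles are degrees at the API boundary.

.ring_atoms <- c("O5", "C1", "C2", "C3", "C4", "C5")

ring_positions <- function(ring, atoms = .ring_atoms) {
  stopifnot(is.data.frame(ring))
  need <- c("atom", "x", "y", "z")
  if (!all(need %in% names(ring))) {
    abort("ring must have columns atom, x, y, z")
  }
  i <- match(atoms, ring$atom)
  if (anyNA(i)) {
    abort(paste0("ring atoms missing: ", paste(atoms[is.na(i)], collapse = ", ")))
  }
  pos <- as.matrix(ring[i, c("x", "y", "z")])
  storage.mode(pos) <- "double"
  if (nrow(pos) != 6) abort("a puckering ring needs exactly six atoms")
  d <- as.matrix(stats::dist(pos))
  if (min(d[upper.tri(d)]) < 1e-6) {
    abort("invalid ring geometry: coincident atoms")
  }
  pos
}

# Core Cremer-Pople machinery on a 6 x 3 coordinate matrix.
cp_from_positions <- function(pos) {
  pos <- sweep(pos, 2, colMeans(pos))
  j <- 0:5
  w_sin <- sin(2 * pi * j / 6)
  w_cos <- cos(2 * pi * j / 6)
  rp <- colSums(pos * w_sin)
  rpp <- colSums(pos * w_cos)
  n <- c(rp[2] * rpp[3] - rp[3] * rpp[2],
         rp[3] * rpp[1] - rp[1] * rpp[3],
         rp[1] * rpp[2] - rp[2] * rpp[1])
  nn <- vec_norm(n)
  if (nn < 1e-12) abort("invalid ring geometry: degenerate mean plane")
  z <- as.numeric(pos %*% (n / nn))
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  phi2 <- atan2(q2s, q2c) %% (2 * pi)
  q3 <- sqrt(1 / 6) * sum((-1)^j * z)
  list(q2 = q2, phi2 = phi2, q3 = q3, z = z)
}

#' Cremer--Pople puckering coordinates of a six-membered ring
#'
#' Computes the total puckering amplitude `Q` (angstrom), the polar angles
#' `theta` in `[0, 180]` and `phi` in `[0, 360)` (degrees), the Cartesian
#' puckering coordinates `qx, qy, qz`, and the normalized puckering
#' collective variables `cv1 = qx/Q`, `cv2 = qy/Q`, `cv3 = qz/Q`.
#'
#' The construction follows the standard prescription: translate the ring to
#' its geometric centre, take the mean plane normal from the cross product of
#' the two trigonometrically weighted lattice sums, project out-of-plane
#' displacements, and assemble `(q2, phi2)` from the m = 2 Fourier component
#' and `q3` from the alternating sum. Ring atoms must be ordered
#' O5, C1, ..., C5 (see [conformer_table()]).
#'
#' @param ring Data frame with columns `atom`, `x`, `y`, `z` (angstrom)
#'   containing at least the six ring atoms.
#' @param atoms Character vector of the six ring atom names, in order.
#'
#' @return A one-row tibble with columns `Q`, `theta`, `phi`, `qx`, `qy`,
#'   `qz`, `cv1`, `cv2`, `cv3`, `q2`, `phi2`, `q3`, `phi_defined`. For a
#'   planar ring (`Q < 1e-6`) the angular and cv fields are `NA` and
#'   `phi_defined` is `FALSE`; at the poles (`sin(theta) < 1e-8`) `phi` is
#'   reported as 0 with `phi_defined = FALSE`.
#' @export
#' @examples
#' cremer_pople(ideal_ring(0.57, 90, 240))
cremer_pople <- function(ring, atoms = .ring_atoms) {
  pos <- ring_positions(ring, atoms)
  cp <- cp_from_positions(pos)
  Q <- sqrt(cp$q2^2 + cp$q3^2)
  if (Q < 1e-6) {
    return(tibble(
      Q = Q, theta = NA_real_, phi = NA_real_,
      qx = 0, qy = 0, qz = 0,
      cv1 = NA_real_, cv2 = NA_real_, cv3 = NA_real_,
      q2 = cp$q2, phi2 = rad2deg(cp$phi2), q3 = cp$q3,
      phi_defined = FALSE
    ))
  }
  theta <- atan2(cp$q2, cp$q3)  # q2 >= 0 so theta in [0, pi]
  phi_defined <- sin(theta) >= 1e-8
  phi <- if (phi_defined) cp$phi2 else 0
  qx <- Q * sin(theta) * cos(phi)
  qy <- Q * sin(theta) * sin(phi)
  qz <- Q * cos(theta)
  tibble(
    Q = Q, theta = rad2deg(theta), phi = rad2deg(phi) %% 360,
    qx = qx, qy = qy, qz = qz,
    cv1 = qx / Q, cv2 = qy / Q, cv3 = qz / Q,
    q2 = cp$q2, phi2 = rad2deg(cp$phi2), q3 = cp$q3,
    phi_defined = phi_defined
  )
}

#' Puckering coordinates for every frame of a ring trajectory
#'
#' @param traj Data frame with columns `frame`, `atom`, `x`, `y`, `z` (and
#'   optionally `time`); rows beyond the six ring atoms are ignored.
#' @param atoms Six ring atom names, in order (default `O5, C1, ..., C5`).
#' @param classify If `TRUE` (default) append the nearest canonical
#'   conformer via [classify_conformer()].
#'
#' @return A tibble with one row per frame: `frame` (and `time` if present),
#'   the [cremer_pople()] columns, and `conformer`/`family` when
#'   `classify = TRUE`.
#' @export
pucker_trajectory <- function(traj, atoms = .ring_atoms, classify = TRUE) {
  stopifnot(is.data.frame(traj), "frame" %in% names(traj))
  frames <- split(traj, traj$frame)
  out <- purrr::map(frames, function(fr) {
    st <- cremer_pople(fr, atoms)
    st$frame <- fr$frame[1]
    if ("time" %in% names(fr)) st$time <- fr$time[1]
    st
  })
  out <- dplyr::bind_rows(out) |> dplyr::arrange(.data$frame)
  out <- dplyr::relocate(out, "frame")
  if (classify) {
    ok <- !is.na(out$theta)
    out$conformer <- NA_character_
    out$family <- NA_character_
    if (any(ok)) {
      cls <- classify_conformer(out[ok, ])
      out$conformer[ok] <- cls$conformer
      out$family[ok] <- cls$family
    }
  }
  out
}

#' Build an ideal ring at prescribed puckering coordinates
#'
#' Inverse of [cremer_pople()]: the in-plane projection is a regular hexagon
#' of circumradius `bond_length` (so the planar bond length equals
#' `bond_length`), traversed clockwise when viewed from +z so that the mean
#' plane normal points along +z, and the out-of-plane displacements are the
#' Cremer--Pople inverse formula
#' `z_j = sqrt(1/3) q2 cos(phi + 120 (j-1)) + sqrt(1/6) q3 (-1)^(j-1)`
#' with `q2 = Q sin(theta)`, `q3 = Q cos(theta)`. Only the z-displacements
#' carry pucker; `cremer_pople(ideal_ring(Q, theta, phi))` recovers
#' `(Q, theta, phi)` to floating-point accuracy.
#'
#' @param Q Puckering amplitude, angstrom (>= 0).
#' @param theta,phi Polar and azimuthal puckering angles, degrees.
#' @param bond_length Planar hexagon bond length, angstrom (default 1.54).
#'
#' @return A six-row tibble with columns `atom`, `x`, `y`, `z`.
#' @export
#' @examples
#' ideal_ring(0.5, 0, 0)   # a 4C1-like chair
ideal_ring <- function(Q, theta, phi, bond_length = 1.54) {
  stopifnot(Q >= 0)
  j <- 0:5
  alpha <- -2 * pi * j / 6
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  q2 <- Q * sin(th)
  q3 <- Q * cos(th)
  z <- sqrt(1 / 3) * q2 * cos(ph + 4 * pi * j / 6) + sqrt(1 / 6) * q3 * (-1)^j
  tibble(
    atom = .ring_atoms,
    x = bond_length * cos(alpha),
    y = bond_length * sin(alpha),
    z = z
  )
}

#' Classify puckering states onto the canonical conformer lattice
#'
#' Assigns each `(theta, phi)` state to the canonical conformer minimizing
#' great-circle distance on the puckering sphere. Exact ties are broken by
#' lexicographic conformer name and flagged in the `tie` column.
#'
#' @param states Data frame with columns `theta`, `phi` (degrees), e.g. from
#'   [cremer_pople()] or [pucker_trajectory()].
#'
#' @return A tibble with columns `conformer`, `family`, `canonical_theta`,
#'   `canonical_phi`, `distance` (degrees), `tie`.
#' @export
#' @examples
#' classify_conformer(cremer_pople(ideal_ring(0.55, 90, 240)))
classify_conformer <- function(states) {
  stopifnot(is.data.frame(states), all(c("theta", "phi") %in% names(states)))
  if (anyNA(states$theta)) {
    abort("planar ring: puckering angles undefined, cannot classify")
  }
  lat <- .conformer_lattice[order(.conformer_lattice$name), ]
  res <- purrr::map(seq_len(nrow(states)), function(i) {
    d <- sphere_distance(states$theta[i], states$phi[i] %||% 0,
                         lat$canonical_theta, lat$canonical_phi)
    k <- which.min(d)  # first in lexicographic order on ties
    tibble(
      conformer = lat$name[k], family = lat$family[k],
      canonical_theta = lat$canonical_theta[k],
      canonical_phi = lat$canonical_phi[k],
      distance = d[k],
      tie = sum(abs(d - d[k]) < 1e-9) > 1
    )
  })
  dplyr::bind_rows(res)
}

#' Project puckering states onto a hemisphere disc
#'
#' Polar azimuthal equidistant projection of the requested hemisphere: the
#' pole maps to the origin and the equator to the unit rim circle, with
#' `x = r cos(phi)`, `y = r sin(phi)` and `r = theta / 90` (north) or
#' `(180 - theta) / 90` (south). States with `theta` strictly beyond the
#' equator are excluded and counted. This is the disc view commonly used for
#' northern-hemisphere conformational free-energy landscapes of pyranoses.
#'
#' @param states Data frame with columns `theta`, `phi` (degrees).
#' @param hemisphere `"north"` (default) or `"south"`. The equator
#'   (`theta = 90`) belongs to both.
#'
#' @return A tibble of the included states with added columns `x`, `y`;
#'   attribute `n_excluded` holds the number of excluded states. Warns when
#'   all states fall in the opposite hemisphere.
#' @export
hemisphere_projection <- function(states, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(is.data.frame(states), nrow(states) > 0,
            all(c("theta", "phi") %in% names(states)))
  keep <- if (hemisphere == "north") states$theta <= 90 else states$theta >= 90
  keep[is.na(keep)] <- FALSE
  out <- states[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn(paste0("no states in the ", hemisphere, " hemisphere"))
    out <- states[0, , drop = FALSE]
  }
  r <- if (hemisphere == "north") out$theta / 90 else (180 - out$theta) / 90
  out$x <- r * cos(deg2rad(out$phi))
  out$y <- r * sin(deg2rad(out$phi))
  out <- as_tibble(out)
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "hemisphere") <- hemisphere
  out
}
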