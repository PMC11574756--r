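# Small shared helpers. Angles cross the API in degrees and are converted to
# radians at the point of use; times reported to users are rounded half-up
# (so 113.625 -> 113.63, matching the convention of the simulation logs this
# package mirrors), never with round()'s round-half-even.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Great-circle distance (degrees) between (theta, phi) points on a sphere,
# theta = polar angle from +z, phi = azimuth. Vectorised over the first pair.
sphere_distance <- function(theta1, phi1, theta2, phi2) {
  t1 <- deg2rad(theta1); t2 <- deg2rad(theta2)
  dphi <- deg2rad(phi1 - phi2)
  c_ang <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dphi)
  rad2deg(acos(pmin(1, pmax(-1, c_ang))))
}

# Spherical linear interpolation between two (theta, phi) directions,
# f in [0, 1]; returns list(theta, phi) in degrees. Used for scripted
# pucker itineraries that travel along the geodesic between conformers.
sphere_slerp <- function(theta1, phi1, theta2, phi2, f) {
  to_vec <- function(th, ph) {
    th <- deg2rad(th); ph <- deg2rad(ph)
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  a <- to_vec(theta1, phi1)
  b <- to_vec(theta2, phi2)
  omega <- acos(pmin(1, pmax(-1, sum(a * b))))
  v <- if (omega < 1e-12) {
    matrix(rep(a, length(f)), ncol = 3, byrow = TRUE)
  } else {
    wa <- sin((1 - f) * omega) / sin(omega)
    wb <- sin(f * omega) / sin(omega)
    cbind(wa * a[1] + wb * b[1], wa * a[2] + wb * b[2], wa * a[3] + wb * b[3])
  }
  theta <- rad2deg(acos(pmin(1, pmax(-1, v[, 3]))))
  phi <- rad2deg(atan2(v[, 2], v[, 1])) %% 360
  list(theta = theta, phi = phi)
}

vec_norm <- function(v) sqrt(sum(v^2))

# Signed torsion angle (degrees, IUPAC convention, range (-180, 180])
# for points a-b-c-d given as length-3 numeric vectors.
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vec_norm(b2)
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Standard internal-coordinate (z-matrix style) atom placement: returns the
# position of atom D given positions of A, B, C, the C-D bond length, the
# B-C-D angle (deg) and the A-B-C-D torsion (deg).
place_by_internal <- function(a, b, c, bond, angle, torsion) {
  angle <- deg2rad(angle)
  torsion <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / vec_norm(bc)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vec_norm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          -bond * sin(angle) * sin(torsion))  # sign matches torsion_angle()
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
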