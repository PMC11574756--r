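# Seeded generators for every input the analysis consumes: fluctuating and
# Markov-switching ring trajectories, scripted reaction trajectories with
# recrossings, dyad-distance ensembles, and hill histories. Each generator
# is a pure function of its arguments plus the seed (bit-identical reruns).
#
# Reaction trajectories use abstract distance-carrier atoms, not chemically
# valid sugar geometry: the analysis layer consumes only distances, puckers
# and dihedrals, so each frame embeds the prescribed distances exactly
# (atoms placed sequentially along an axis by a fixed deterministic
# construction) and noise is applied to the prescribed *distances* before
# embedding. This is a documented limitation, not an approximation of the
# analysis itself.

#' Generate a fluctuating, conformer-switching ring trajectory
#'
#' Frames are built from [ideal_ring()] at each conformer's canonical
#' puckering angles plus isotropic Gaussian positional noise. The occupied
#' conformer follows a Markov chain: at each frame, with probability
#' `switch_rate`, the conformer is redrawn from the occupancy distribution
#' (which is therefore also the stationary distribution).
#'
#' @param conformers Named numeric vector of occupancies summing to 1, e.g.
#'   `c("1,4B" = 0.7, "4C1" = 0.3)`; names must be canonical conformers.
#' @param n_frames Number of frames.
#' @param q Puckering amplitude, angstrom (default 0.55, a typical pyranose
#'   value).
#' @param noise_sd Isotropic positional noise SD per coordinate, angstrom.
#' @param switch_rate Per-frame probability of redrawing the conformer.
#' @param dt Frame spacing, ps (default 0.01).
#' @param seed Mandatory integer seed.
#' @return Trajectory tibble (`frame`, `time`, `residue = "RNG1"`, `atom`,
#'   `x`, `y`, `z`) with the per-frame generating conformer in the
#'   `conformer_path` attribute.
#' @export
#' @examples
#' traj <- gen_ring_trajectory(c("1,4B" = 1), n_frames = 5, seed = 1)
#' pucker_trajectory(traj)$conformer
gen_ring_trajectory <- function(conformers, n_frames, q = 0.55,
                                noise_sd = 0.02, switch_rate = 0.05,
                                dt = 0.01, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_frames >= 1, noise_sd >= 0)
  if (abs(sum(conformers) - 1) > 1e-8) abort("occupancies must sum to 1")
  ang <- conformer_angles(names(conformers))
  set.seed(seed)
  state <- sample.int(length(conformers), 1, prob = conformers)
  path <- integer(n_frames)
  for (i in seq_len(n_frames)) {
    if (i > 1 && stats::runif(1) < switch_rate) {
      state <- sample.int(length(conformers), 1, prob = conformers)
    }
    path[i] <- state
  }
  out <- purrr::map(seq_len(n_frames), function(i) {
    ring <- ideal_ring(q, ang$theta[path[i]], ang$phi[path[i]])
    tibble(
      frame = i, time = (i - 1) * dt, residue = "RNG1", atom = ring$atom,
      x = ring$x + stats::rnorm(6, 0, noise_sd),
      y = ring$y + stats::rnorm(6, 0, noise_sd),
      z = ring$z + stats::rnorm(6, 0, noise_sd)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "conformer_path") <- names(conformers)[path]
  attr(out, "spec") <- list(conformers = as.list(conformers), n_frames = n_frames,
                            q = q, noise_sd = noise_sd,
                            switch_rate = switch_rate, dt = dt, seed = seed)
  out
}

#' Default keyframes of the scripted glycosylation reaction path
#'
#' Named distances (angstrom), the flattening dihedral (degrees) and the
#' ring pucker at the Michaelis complex (`xi = 0`), transition state
#' (`xi = 0.5`) and product (`xi = 1`). The anchoring values mirror the
#' mechanism this package models: glycosidic C1-O' 1.5 -> 2.6 angstrom from
#' MC to TS while Ow-C1 closes 3.5 -> 2.6; the dyad proton Nd-H 1.32
#' (shared) -> 1.06 (on His); anomeric C1-O5 1.41 -> 1.29 with ring
#' flattening to 11 degrees at the TS; and a 1,4B -> 4E -> 1,4B pucker path.
#' Remaining entries are standard bond-length choices completing the path.
#'
#' @return Tibble with columns `xi`, the six reaction-CV distances
#'   (`d_nd_h`, `d_h_o1`, `d_c1_o1`, `d_ow_c1`, `d_ow_hw`, `d_hw_od90`),
#'   `d_nd_od320`, `d_c1_o5`, `dihedral`, `theta`, `phi`.
#' @export
reaction_keyframes <- function() {
  tibble(
    xi        = c(0, 0.5, 1),
    d_nd_h    = c(1.32, 1.06, 1.04),
    d_h_o1    = c(1.80, 1.20, 1.00),
    d_c1_o1   = c(1.50, 2.60, 3.20),
    d_ow_c1   = c(3.50, 2.60, 1.45),
    d_ow_hw   = c(0.98, 1.05, 1.60),
    d_hw_od90 = c(1.80, 1.50, 1.00),
    d_nd_od320 = c(2.54, 2.76, 2.80),
    d_c1_o5   = c(1.41, 1.29, 1.41),
    dihedral  = c(35, 11, 30),
    theta     = c(90, .theta_env, 90),
    phi       = c(240, 240, 240)
  )
}

# atoms carrying the six reaction-CV distances, placed collinearly;
# cumulative signs give each atom's x offset from the previous one
.chain_atoms <- tibble(
  residue = c("HIS302", "HIS302", "GAL1", "LIG1", "WAT1", "WAT1", "ASP90"),
  atom = c("ND1", "HD1", "O1", "C1", "OW", "HW1", "OD1"),
  dist_name = c(NA, "d_nd_h", "d_h_o1", "d_c1_o1", "d_ow_c1", "d_ow_hw",
                "d_hw_od90")
)

#' Generate a scripted reaction trajectory with recrossings
#'
#' Builds a trajectory in which every keyframed quantity follows
#' piecewise-linear interpolation in the normalized reaction coordinate
#' `xi` through `xi = 0 (MC), 0.5 (TS), 1 (P)`, with `n_recrossings` full
#' forward/backward passes (R -> P -> R ...) and `hold_frames` of dwell at
#' each R/P endpoint so basin visits register. Gaussian noise of SD
#' `noise_sd` is added to each prescribed distance and to the dihedral
#' (scaled by 10 deg/angstrom) before embedding; the embedded coordinates
#' then realise the noisy distances exactly. The ring pucker travels along
#' the sphere geodesic between keyframe puckers (noise-free).
#'
#' @param keyframes Keyframe tibble (default [reaction_keyframes()]).
#' @param n_recrossings Number of complete R -> P -> R cycles (>= 1).
#' @param frames_per_leg Frames per forward or backward leg (default 60).
#' @param hold_frames Frames of dwell at each endpoint (default
#'   `frames_per_leg %/% 3`).
#' @param noise_sd Distance noise SD, angstrom (default 0.03).
#' @param q Ring puckering amplitude, angstrom.
#' @param dt Frame spacing, ps (default 0.01).
#' @param seed Mandatory integer seed.
#' @return Trajectory tibble (`frame`, `time`, `residue`, `atom`, `x`, `y`,
#'   `z`) containing the distance-carrier atoms (residues HIS302, GAL1,
#'   LIG1, WAT1, ASP90, ASP320, dihedral carriers in LIG1) and the ring
#'   (residue RNG1). The `prescribed` attribute holds the per-frame noisy
#'   prescription (`frame`, `time`, `xi`, every keyframed column); the
#'   `spec` attribute records the generating parameters. Aborts naming the
#'   offending distance if noise drives a prescribed distance
#'   non-positive (the collinear embedding realises any positive set).
#' @export
gen_reaction_trajectory <- function(keyframes = reaction_keyframes(),
                                    n_recrossings = 2, frames_per_leg = 60,
                                    hold_frames = NULL, noise_sd = 0.03,
                                    q = 0.55, dt = 0.01, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_recrossings >= 1, frames_per_leg >= 2)
  dist_cols <- c("d_nd_h", "d_h_o1", "d_c1_o1", "d_ow_c1", "d_ow_hw",
                 "d_hw_od90", "d_nd_od320", "d_c1_o5")
  need <- c("xi", dist_cols, "dihedral", "theta", "phi")
  if (!all(need %in% names(keyframes))) {
    abort(paste0("keyframes missing columns: ",
                 paste(setdiff(need, names(keyframes)), collapse = ", ")))
  }
  if (is.null(hold_frames)) hold_frames <- frames_per_leg %/% 3

  # xi path: hold(R), up, hold(P), down, ..., hold(R)
  leg_up <- seq(0, 1, length.out = frames_per_leg + 1)[-1]
  leg_dn <- rev(seq(0, 1, length.out = frames_per_leg + 1))[-1]
  xi <- rep(0, hold_frames)
  for (k in seq_len(n_recrossings)) {
    xi <- c(xi, leg_up, rep(1, hold_frames), leg_dn, rep(0, hold_frames))
  }
  n <- length(xi)
  set.seed(seed)

  presc <- tibble(frame = seq_len(n), time = (seq_len(n) - 1) * dt, xi = xi)
  for (col in c(dist_cols, "dihedral")) {
    v <- stats::approx(keyframes$xi, keyframes[[col]], xout = xi)$y
    nsd <- if (col == "dihedral") 10 * noise_sd else noise_sd
    presc[[col]] <- v + stats::rnorm(n, 0, nsd)
  }
  bad <- which(vapply(dist_cols, function(c) any(presc[[c]] <= 0), TRUE))
  if (length(bad) > 0) {
    abort(paste0("unrealizable geometry: non-positive prescribed distance ",
                 paste(dist_cols[bad], collapse = ", ")))
  }
  pk <- sphere_slerp(keyframes$theta[1], keyframes$phi[1],
                     keyframes$theta[2], keyframes$phi[2], pmin(xi, 0.5) * 2)
  pk2 <- sphere_slerp(keyframes$theta[2], keyframes$phi[2],
                      keyframes$theta[3], keyframes$phi[3],
                      pmax(xi - 0.5, 0) * 2)
  theta_path <- ifelse(xi <= 0.5, pk$theta, pk2$theta)
  phi_path <- ifelse(xi <= 0.5, pk$phi, pk2$phi)

  frames <- purrr::map(seq_len(n), function(i) {
    d <- presc[i, ]
    # collinear chain realising the six CV distances exactly
    steps <- c(0, d$d_nd_h, d$d_h_o1, d$d_c1_o1, d$d_ow_c1, d$d_ow_hw,
               d$d_hw_od90)
    xs <- cumsum(steps)
    chain <- tibble(residue = .chain_atoms$residue, atom = .chain_atoms$atom,
                    x = xs, y = 0, z = 0)
    # dyad acceptor opposite the chain
    asp320 <- tibble(residue = "ASP320", atom = "OD1",
                     x = -d$d_nd_od320, y = 0, z = 0)
    # anomeric fragment for C1-O5 and the C5-O5-C1-C2 dihedral
    c1 <- c(xs[4], 0, 0)
    o5 <- c1 + c(0, 0, d$d_c1_o5)
    c2 <- c1 + c(0, 1.52, 0)
    c5 <- place_by_internal(c2, c1, o5, bond = 1.43, angle = 112,
                            torsion = d$dihedral)
    frag <- tibble(residue = "LIG1",
                   atom = c("O5", "C2", "C5"),
                   x = c(o5[1], c2[1], c5[1]),
                   y = c(o5[2], c2[2], c5[2]),
                   z = c(o5[3], c2[3], c5[3]))
    ring <- ideal_ring(q, theta_path[i], phi_path[i])
    ring_t <- tibble(residue = "RNG1", atom = ring$atom,
                     x = ring$x + 30, y = ring$y + 30, z = ring$z)
    fr <- dplyr::bind_rows(chain, asp320, frag, ring_t)
    fr$frame <- i
    fr$time <- (i - 1) * dt
    fr
  })
  out <- dplyr::bind_rows(frames) |>
    dplyr::relocate("frame", "time")
  attr(out, "prescribed") <- presc
  attr(out, "spec") <- list(n_recrossings = n_recrossings,
                            frames_per_leg = frames_per_leg,
                            hold_frames = hold_frames, noise_sd = noise_sd,
                            q = q, dt = dt, seed = seed)
  out
}

#' Generate a donor-H / donor-acceptor dyad ensemble
#'
#' Frames carrying a His-like dyad with donor-H and donor-acceptor distances
#' drawn from independent Gaussians -- the synthetic stand-in for a
#' Michaelis-complex trajectory in which the proton is shared between donor
#' and acceptor.
#'
#' @param mean_dh,sd_dh Donor-H distance mean and SD, angstrom.
#' @param mean_da,sd_da Donor-acceptor distance mean and SD, angstrom.
#' @param n Number of frames (>= 10).
#' @param seed Mandatory integer seed.
#' @param dt Frame spacing, ps.
#' @return Trajectory tibble with residues HIS302 (`ND1`, `HD1`) and ASP320
#'   (`OD1`), atoms collinear so the two generated distances are exact.
#' @export
#' @examples
#' traj <- gen_dyad_ensemble(1.32, 0.21, 2.54, 0.09, n = 100, seed = 7)
gen_dyad_ensemble <- function(mean_dh, sd_dh, mean_da, sd_da, n, seed,
                              dt = 0.01) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(sd_dh >= 0, sd_da >= 0, n >= 10)
  set.seed(seed)
  dh <- stats::rnorm(n, mean_dh, sd_dh)
  da <- stats::rnorm(n, mean_da, sd_da)
  purrr::map_dfr(seq_len(n), function(i) {
    tibble(
      frame = i, time = (i - 1) * dt,
      residue = c("HIS302", "HIS302", "ASP320"),
      atom = c("ND1", "HD1", "OD1"),
      x = c(0, dh[i], da[i]), y = 0, z = 0
    )
  })
}

#' Measure the standard dyad distances of a generated ensemble
#'
#' Convenience wrapper around [measure_frames()] with the His302/Asp320
#' selector pair used by [gen_dyad_ensemble()] and
#' [gen_reaction_trajectory()].
#'
#' @param traj Trajectory tibble containing HIS302 `ND1`/`HD1` and ASP320
#'   `OD1`.
#' @return Tibble with `frame`, `d_dh`, `d_da`.
#' @export
measure_dyad <- function(traj) {
  measure_frames(traj, distances = list(
    d_dh = list(c("HIS302", "ND1"), c("HIS302", "HD1")),
    d_da = list(c("HIS302", "ND1"), c("ASP320", "OD1"))
  ))
}

#' Generate a hill history with the two-level height schedule
#'
#' Hills are deposited at `time = index * stride * timestep` (fs, reported
#' in ps) with height `initial_height` for hills `1..switch_after` and
#' `reduced_height` afterwards -- the exact bookkeeping of the manual
#' height-reduction protocol. Centers follow a reflected Gaussian random
#' walk inside `bounds` (or a caller-supplied path).
#'
#' @param n_hills Number of hills.
#' @param stride MD steps between depositions (default 250).
#' @param timestep MD timestep, fs (default 0.5).
#' @param initial_height,reduced_height Heights, kcal/mol (defaults 1.0 and
#'   0.5).
#' @param switch_after Hill count after which the reduced height applies
#'   (default 599); `Inf` disables the switch.
#' @param widths Named per-CV Gaussian sigma (CV units); the names define
#'   the CV names (default `c(cv1 = 0.030, cv2 = 0.040, cv3 = 0.015)`, the
#'   puckering-CV protocol widths).
#' @param centers Optional matrix/data frame of hill centers (`n_hills` rows,
#'   one column per CV); when `NULL`, a reflected random walk with per-step
#'   SD equal to each CV's width, started at the bounds' midpoint.
#' @param bounds Reflection bounds for the random walk (default `c(-1, 1)`,
#'   the normalized-puckering range).
#' @param seed Mandatory integer seed (unused when `centers` is supplied but
#'   still required, to keep generator calls uniformly reproducible).
#' @return A hills tibble ([new_hills()]).
#' @export
#' @examples
#' h <- gen_hills(10, seed = 1)
#' h$height
gen_hills <- function(n_hills, stride = 250, timestep = 0.5,
                      initial_height = 1.0, reduced_height = 0.5,
                      switch_after = 599,
                      widths = c(cv1 = 0.030, cv2 = 0.040, cv3 = 0.015),
                      centers = NULL, bounds = c(-1, 1), seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_hills >= 1, stride > 0, timestep > 0)
  if (reduced_height > initial_height) {
    abort("reduced_height must not exceed initial_height")
  }
  cvn <- names(widths)
  if (is.null(cvn)) cvn <- paste0("cv", seq_along(widths))
  set.seed(seed)
  if (is.null(centers)) {
    reflect <- function(x, lo, hi) {
      span <- hi - lo
      y <- (x - lo) %% (2 * span)
      lo + ifelse(y > span, 2 * span - y, y)
    }
    centers <- vapply(seq_along(widths), function(i) {
      reflect(mean(bounds) + cumsum(stats::rnorm(n_hills, 0, widths[i])),
              bounds[1], bounds[2])
    }, numeric(n_hills))
    centers <- matrix(centers, nrow = n_hills)
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == n_hills, ncol(centers) == length(widths))
  }
  idx <- seq_len(n_hills)
  h <- tibble(time = idx * stride * timestep / 1000)
  for (i in seq_along(cvn)) h[[cvn[i]]] <- centers[, i]
  for (i in seq_along(cvn)) h[[paste0("sigma_", cvn[i])]] <- unname(widths[i])
  h$height <- ifelse(idx <= switch_after, initial_height, reduced_height)
  new_hills(h, cvn)
}

#' Write a generator's spec sidecar
#'
#' Records the generating parameters (including the seed) of a synthetic
#' trajectory next to its data file, as JSON.
#'
#' @param traj A generated trajectory carrying a `spec` attribute.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_spec_sidecar <- function(traj, path) {
  spec <- attr(traj, "spec")
  if (is.null(spec)) abort("trajectory has no spec attribute")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
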