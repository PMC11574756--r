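# Standard (fixed-height-schedule) metadynamics: Gaussian bias hills, bias
# evaluation, free-energy-landscape reconstruction as the negated bias, and
# hill-count/time bookkeeping. Heights follow a two-level schedule (an
# initial height reduced once after a set number of depositions), matching
# the manual height reduction used in the QM/MM protocols this package
# mirrors; well-tempered metadynamics is deliberately out of scope.

#' Construct a hills tibble
#'
#' A hills tibble holds time-ordered Gaussian bias hills: columns `index`
#' (deposition ordinal, 1-based), `time` (ps), one center column per CV,
#' `sigma_<cv>` width columns (CV units) and `height` (kcal/mol).
#'
#' @param x Data frame with columns `time`, the CV centers, `sigma_<cv>` and
#'   `height`.
#' @param cv_names Character vector naming the CV center columns.
#' @return The validated hills tibble, classed `glycofel_hills`, with the CV
#'   names in the `cv_names` attribute.
#' @export
new_hills <- function(x, cv_names) {
  x <- as_tibble(x)
  need <- c("time", cv_names, paste0("sigma_", cv_names), "height")
  if (!all(need %in% names(x))) {
    abort(paste0("hills tibble missing columns: ",
                 paste(setdiff(need, names(x)), collapse = ", ")))
  }
  if (!"index" %in% names(x)) x$index <- seq_len(nrow(x))
  if (nrow(x) > 0) {
    if (any(x$height <= 0)) abort("hill heights must be positive")
    if (any(as.matrix(x[, paste0("sigma_", cv_names)]) <= 0)) {
      abort("hill widths must be positive")
    }
    if (is.unsorted(x$time, strictly = TRUE)) {
      abort("hill times must be strictly increasing")
    }
  }
  x <- dplyr::relocate(x, "index", "time")
  attr(x, "cv_names") <- cv_names
  class(x) <- unique(c("glycofel_hills", class(x)))
  x
}

#' CV names of a hills tibble
#' @param hills A hills tibble.
#' @return Character vector of CV names.
#' @export
cv_names <- function(hills) {
  cv <- attr(hills, "cv_names")
  if (is.null(cv)) abort("not a hills tibble: missing cv_names attribute")
  cv
}

as_points_matrix <- function(points, cv) {
  if (is.data.frame(points)) {
    if (!all(cv %in% names(points))) {
      abort(paste0("points must have the CV columns: ", paste(cv, collapse = ", ")))
    }
    points <- as.matrix(points[, cv, drop = FALSE])
  } else if (is.matrix(points)) {
    if (ncol(points) != length(cv)) abort("points dimension does not match CV count")
  } else {
    points <- matrix(points, ncol = length(cv),
                     byrow = length(points) > length(cv))
    if (ncol(points) != length(cv)) abort("points dimension does not match CV count")
  }
  storage.mode(points) <- "double"
  points
}

#' Accumulated metadynamics bias at CV points
#'
#' Sums, over all hills deposited up to `upto_time`, the Gaussian
#' `height * exp(-sum_i (x_i - c_i)^2 / (2 sigma_i^2))`.
#'
#' @param hills A hills tibble.
#' @param points Evaluation points: a numeric vector (one or more points of
#'   the CV dimension), a matrix with one column per CV, or a data frame
#'   with the CV columns.
#' @param upto_time Only hills with `time <= upto_time` contribute
#'   (default all).
#' @return Numeric vector of bias energies, kcal/mol (non-negative).
#' @export
bias_energy <- function(hills, points, upto_time = Inf) {
  cv <- cv_names(hills)
  P <- as_points_matrix(points, cv)
  h <- hills[hills$time <= upto_time, , drop = FALSE]
  if (nrow(h) == 0) return(rep(0, nrow(P)))
  C <- as.matrix(h[, cv, drop = FALSE])
  S <- as.matrix(h[, paste0("sigma_", cv), drop = FALSE])
  H <- h$height
  out <- numeric(nrow(P))
  # chunk points to bound the n_points x n_hills working matrix
  chunk <- max(1L, as.integer(5e6 / nrow(h)))
  starts <- seq(1L, nrow(P), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(P))
    E <- matrix(0, length(idx), nrow(h))
    for (i in seq_along(cv)) {
      E <- E + outer(P[idx, i], C[, i], "-")^2 /
        matrix(2 * S[, i]^2, length(idx), nrow(h), byrow = TRUE)
    }
    out[idx] <- as.numeric(exp(-E) %*% H)
  }
  out
}

#' Reconstruct the free-energy landscape from deposited hills
#'
#' The landscape estimate is the negated accumulated bias of the full hill
#' history, `F(x) = -V_bias(x)`, shifted so that its minimum is exactly 0
#' (the final-bias convention; the convergence trace below exposes how the
#' estimate evolved with deposition).
#'
#' @param hills A hills tibble.
#' @param grid Named list of grid vectors, one per CV (names must match the
#'   hills CV names), e.g. `list(x = seq(-2, 2, length.out = 201))`.
#' @param basins Optional two disjoint CV intervals for the convergence
#'   diagnostic, as a list of two `c(lo, hi)` ranges on the *first* CV
#'   (e.g. `list(reactant = c(-1.5, -0.5), product = c(0.5, 1.5))`). When
#'   given, the free-energy difference between the two basin minima is
#'   traced against hill count and stored in the `convergence` attribute.
#' @param trace_every Hill-count spacing of the convergence trace
#'   (default 10).
#' @return A tibble with the CV grid columns, `bias` and `fel` (kcal/mol,
#'   `min(fel) == 0`), classed `glycofel_fel`; attributes `cv_names` and,
#'   when `basins` is given, `convergence` (tibble `n_hills`, `delta_f` =
#'   F(basin 2 minimum) - F(basin 1 minimum)).
#' @export
reconstruct_fel <- function(hills, grid, basins = NULL, trace_every = 10) {
  cv <- cv_names(hills)
  if (nrow(hills) == 0) abort("empty hill history: nothing to reconstruct")
  if (!all(cv %in% names(grid))) {
    abort("grid must be a named list with one vector per CV")
  }
  pts <- tidyr::expand_grid(!!!rlang::set_names(grid[cv], cv))
  b <- bias_energy(hills, pts)
  out <- pts
  out$bias <- b
  out$fel <- -b - min(-b)
  out <- as_tibble(out)
  attr(out, "cv_names") <- cv
  if (!is.null(basins)) {
    attr(out, "convergence") <- fel_convergence(hills, grid, basins, trace_every)
  }
  class(out) <- unique(c("glycofel_fel", class(out)))
  out
}

#' Basin free-energy-difference convergence trace
#'
#' For growing prefixes of the hill history, computes the free-energy
#' difference between the minima of two basins -- the stopping diagnostic
#' used to decide when a conformational landscape is converged (deposition
#' continues until the difference between local minima stays constant).
#'
#' @inheritParams reconstruct_fel
#' @return Tibble with columns `n_hills`, `delta_f` (kcal/mol; basin 2 minus
#'   basin 1).
#' @export
fel_convergence <- function(hills, grid, basins, trace_every = 10) {
  cv <- cv_names(hills)
  stopifnot(length(basins) == 2)
  pts_all <- tidyr::expand_grid(!!!rlang::set_names(grid[cv], cv))
  sel <- lapply(basins, function(rng) {
    pts_all[pts_all[[cv[1]]] >= rng[1] & pts_all[[cv[1]]] <= rng[2], , drop = FALSE]
  })
  if (any(vapply(sel, nrow, 0L) == 0)) abort("basin range contains no grid points")
  C <- as.matrix(hills[, cv, drop = FALSE])
  S <- as.matrix(hills[, paste0("sigma_", cv), drop = FALSE])
  H <- hills$height
  per_basin_max <- lapply(sel, function(p) {
    P <- as.matrix(p[, cv, drop = FALSE])
    E <- matrix(0, nrow(P), nrow(C))
    for (i in seq_along(cv)) {
      E <- E + outer(P[, i], C[, i], "-")^2 /
        matrix(2 * S[, i]^2, nrow(P), nrow(C), byrow = TRUE)
    }
    G <- sweep(exp(-E), 2, H, "*")            # per-hill contributions
    Gc <- t(apply(G, 1, cumsum))              # cumulative bias per point
    if (nrow(P) == 1) Gc <- matrix(Gc, nrow = 1)
    apply(Gc, 2, max)                         # max bias in basin vs n_hills
  })
  n <- unique(c(seq(trace_every, nrow(hills), by = trace_every), nrow(hills)))
  tibble(
    n_hills = n,
    # F_basin_min = -max(bias in basin); delta_f = F2 - F1
    delta_f = per_basin_max[[1]][n] - per_basin_max[[2]][n]
  )
}

#' Convert a hill count to deposited simulation time
#'
#' `n_hills * stride * timestep`, converted fs to ps. The rounded column
#' uses half-up rounding to 2 decimals, the convention under which 909
#' hills at one hill per 250 steps of 0.5 fs reads 113.63 ps.
#'
#' @param n_hills Number of deposited hills (vectorised).
#' @param stride MD steps between depositions.
#' @param timestep MD timestep, fs.
#' @return Tibble with columns `n_hills`, `time_ps` (unrounded) and
#'   `time_ps_rounded`.
#' @export
#' @examples
#' hill_count_to_time(c(909, 885), stride = 250, timestep = 0.5)
hill_count_to_time <- function(n_hills, stride, timestep) {
  if (any(n_hills <= 0) || stride <= 0 || timestep <= 0) {
    abort("n_hills, stride and timestep must all be positive")
  }
  t_ps <- n_hills * stride * timestep / 1000
  tibble(n_hills = n_hills, time_ps = t_ps,
         time_ps_rounded = round_half_up(t_ps, 2))
}

# ---- analytic toy potentials -------------------------------------------

#' Analytic toy potentials for desk-scale metadynamics validation
#'
#' Available forms:
#' \describe{
#'   \item{`double_well` (1D)}{`V(x) = barrier * ((x/a)^2 - 1)^2`; minima at
#'     `x = -a, +a` with `V = 0`, barrier top at `x = 0` with `V = barrier`.}
#'   \item{`harmonic` (1D)}{`V(x) = k/2 x^2`; its stationary CV variance
#'     `kB T / k` makes the Langevin sampler directly testable.}
#'   \item{`triwell` (2D)}{three Gaussian wells of depth `barrier` at
#'     radius 1 (azimuths 90, 210, 330 degrees) on a quartic confinement.}
#' }
#'
#' @param id Potential id.
#' @param barrier Barrier height (double_well) or well depth (triwell),
#'   kcal/mol.
#' @param a Minima positions `+/- a` for the double well (CV units).
#' @param k Force constant for `harmonic`, kcal/mol per CV unit^2.
#' @param width Gaussian well width for `triwell` (CV units).
#' @param temperature Simulation temperature, K.
#' @return A `toy_potential` object: fields `id`, `dim`, `params`,
#'   `temperature`, value function `f`, gradient `grad`, suggested CV grid
#'   `bound`, and `minima`.
#' @export
#' @examples
#' pot <- toy_potential("double_well", barrier = 5)
#' pot$f(0)     # the barrier top
toy_potential <- function(id = c("double_well", "harmonic", "triwell"),
                          barrier = 5, a = 1, k = 10, width = 0.5,
                          temperature = 300) {
  id <- match.arg(id)
  if (barrier <= 0 || a <= 0 || k <= 0 || width <= 0 || temperature <= 0) {
    abort("toy potential parameters must be positive")
  }
  pot <- switch(id,
    double_well = list(
      dim = 1L, params = c(barrier = barrier, a = a),
      f = function(x) barrier * ((x / a)^2 - 1)^2,
      grad = function(x) barrier * 4 * x * ((x / a)^2 - 1) / a^2,
      bound = 2 * a, minima = c(-a, a)
    ),
    harmonic = list(
      dim = 1L, params = c(k = k),
      f = function(x) 0.5 * k * x^2,
      grad = function(x) k * x,
      bound = 3 * sqrt(.kB * temperature / k), minima = 0
    ),
    triwell = list(
      dim = 2L,
      params = c(barrier = barrier, width = width),
      f = function(x) {
        x <- matrix(x, ncol = 2)
        ang <- deg2rad(c(90, 210, 330))
        v <- 0.5 * (x[, 1]^2 + x[, 2]^2)^2
        for (aa in ang) {
          v <- v - barrier * exp(-((x[, 1] - cos(aa))^2 + (x[, 2] - sin(aa))^2) /
                                   (2 * width^2))
        }
        v
      },
      grad = function(x) {
        x <- matrix(x, ncol = 2)
        ang <- deg2rad(c(90, 210, 330))
        r2 <- x[, 1]^2 + x[, 2]^2
        g <- cbind(2 * r2 * x[, 1], 2 * r2 * x[, 2])
        for (aa in ang) {
          e <- exp(-((x[, 1] - cos(aa))^2 + (x[, 2] - sin(aa))^2) / (2 * width^2))
          g <- g + barrier * e / width^2 * cbind(x[, 1] - cos(aa), x[, 2] - sin(aa))
        }
        g
      },
      bound = 2, minima = cbind(cos(deg2rad(c(90, 210, 330))),
                                sin(deg2rad(c(90, 210, 330))))
    )
  )
  pot$id <- id
  pot$temperature <- temperature
  class(pot) <- "toy_potential"
  pot
}

#' Run overdamped-Langevin metadynamics on a toy potential
#'
#' Euler--Maruyama integration of the overdamped Langevin equation
#' `dx = -grad(V + V_bias)/gamma dt + sqrt(2 kB T dt / gamma) xi`, with a
#' Gaussian bias hill deposited at the current CV position every `stride`
#' steps. Hill heights follow the two-level schedule: `initial_height` for
#' hills `1..switch_after`, `reduced_height` afterwards. The compiled loop
#' evaluates the exact sum over all deposited hills at every step.
#'
#' @param potential A [toy_potential()].
#' @param x0 Starting CV position (defaults to the potential's first
#'   minimum).
#' @param n_hills Maximum number of hills to deposit.
#' @param stride MD steps between depositions (default 250).
#' @param timestep Timestep, fs (default 0.5).
#' @param friction Langevin friction `gamma`, kcal mol^-1 ps per CV unit^2
#'   (default 1).
#' @param width Gaussian hill width(s), CV units; one value per CV.
#' @param initial_height,reduced_height,switch_after Height schedule,
#'   kcal/mol; defaults 1.0 reduced to 0.5 after 599 hills.
#' @param seed Mandatory integer RNG seed.
#' @param record_every Record the CV every this many steps (default 10).
#' @param stop_recross If positive, stop once the trajectory has completed
#'   this many reactant-product-reactant recrossings between `basin_r` and
#'   `basin_p` (first-CV intervals); 0 disables.
#' @param tail_steps Extra integration steps after the recrossing target is
#'   met, so the closing reactant visit registers as a dwell rather than a
#'   touch (default `5 * stride`).
#' @param stop_min_dwell Minimum continuous residence (ps) in a basin for the
#'   stop counter to register the visit, mirroring the dwell filter of
#'   [detect_recrossings()] (default 0.05).
#' @param basin_r,basin_p Reactant / product intervals on the first CV used
#'   by `stop_recross` (default the double-well minima neighbourhoods).
#' @return A list of class `glycofel_metad_run` with elements `colvar`
#'   (tibble `time`, CV columns, `bias`), `hills` (hills tibble),
#'   `potential`, and the run parameters. Aborts with a diagnostic if the
#'   trajectory leaves `10 *` the potential's grid bound.
#' @export
run_toy_metadynamics <- function(potential, x0 = NULL, n_hills = 1500,
                                 stride = 250, timestep = 0.5, friction = 1,
                                 width = 0.1,
                                 initial_height = 1.0, reduced_height = 0.5,
                                 switch_after = 599,
                                 seed, record_every = 10,
                                 stop_recross = 0,
                                 basin_r = NULL, basin_p = NULL,
                                 tail_steps = 5 * stride,
                                 stop_min_dwell = 0.05) {
  stopifnot(inherits(potential, "toy_potential"))
  if (missing(seed)) abort("seed is mandatory for toy metadynamics runs")
  if (timestep <= 0 || friction <= 0 || potential$temperature <= 0) {
    abort("timestep, friction and temperature must be positive")
  }
  if (reduced_height > initial_height) {
    abort("reduced_height must not exceed initial_height")
  }
  d <- potential$dim
  if (is.null(x0)) {
    x0 <- if (d == 1) potential$minima[1] else potential$minima[1, ]
  }
  width <- rep_len(width, d)
  if (is.null(basin_r)) basin_r <- c(-1.3, -0.7)
  if (is.null(basin_p)) basin_p <- c(0.7, 1.3)
  pot_code <- match(potential$id, c("double_well", "harmonic", "triwell"))
  set.seed(seed)
  res <- metad_langevin_cpp(
    pot_code, as.numeric(potential$params), as.numeric(x0),
    n_hills, as.integer(stride), timestep / 1000,
    .kB * potential$temperature, friction, width,
    initial_height, reduced_height, as.integer(switch_after),
    as.integer(record_every), 10 * potential$bound,
    as.integer(stop_recross), basin_r, basin_p, as.integer(tail_steps),
    max(1L, as.integer(round(stop_min_dwell / (timestep / 1000))))
  )
  if (res$diverged) {
    abort(sprintf(
      "toy metadynamics trajectory diverged at t = %.4f ps (CV beyond 10x grid bound %.2f)",
      res$diverge_time, potential$bound))
  }
  cvn <- if (d == 1) "x" else c("x", "y")
  colvar <- as_tibble(as.data.frame(res$traj))
  names(colvar) <- c("time", cvn, "bias")
  hl <- as_tibble(as.data.frame(res$hills))
  names(hl) <- c("time", cvn, paste0("sigma_", cvn), "height")
  out <- list(
    colvar = colvar,
    hills = new_hills(hl, cvn),
    potential = potential,
    params = list(stride = stride, timestep = timestep, friction = friction,
                  width = width, initial_height = initial_height,
                  reduced_height = reduced_height, switch_after = switch_after,
                  seed = seed, record_every = record_every),
    n_recross = res$n_recross
  )
  class(out) <- "glycofel_metad_run"
  out
}

#' @export
print.glycofel_metad_run <- function(x, ...) {
  cat("Toy metadynamics run (", x$potential$id, ")\n", sep = "")
  cat("  hills deposited: ", nrow(x$hills),
      ", simulated time: ", sprintf("%.2f ps", max(x$colvar$time)), "\n", sep = "")
  if (x$n_recross > 0) cat("  recrossings at stop: ", x$n_recross, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.glycofel_metad_run <- function(x, ...) {
  tibble(
    potential = x$potential$id,
    n_hills = nrow(x$hills),
    time_ps = max(x$colvar$time),
    temperature = x$potential$temperature,
    initial_height = x$params$initial_height,
    reduced_height = x$params$reduced_height,
    switch_after = x$params$switch_after,
    n_recross = x$n_recross,
    seed = x$params$seed
  )
}
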