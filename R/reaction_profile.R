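# Recrossing-cycle segmentation of biased reaction trajectories and
# per-cycle free-energy profiles combined by Boltzmann (exponential)
# averaging with SD/SE bands.
#
# Conventions, since several are possible: per-cycle profiles use the
# cumulative hill history up to the end of the cycle (profiles from later
# cycles therefore include all earlier bias); the exponential average is
# -kBT ln mean(exp(-F/kBT)) at the simulation temperature; SD and SE are
# computed pointwise on the *unshifted* per-cycle profiles so the shared
# reactant minimum is not forced to zero variance.

#' Detect reactant-product-reactant recrossing cycles
#'
#' Segments a CV time series into maximal non-overlapping R -> P -> R cycles.
#' A basin visit only counts when the trajectory dwells inside the basin
#' interval for at least `min_dwell` (contiguous samples); this filters
#' grazing excursions. When a hills tibble is supplied, the deposition index
#' reached at each recrossing completion is reported, mirroring how biased
#' simulations log "the n-th recrossing took place once m hills were
#' deposited".
#'
#' @param colvar Tibble with columns `time` (ps) and the CV (first non-time
#'   column, or named via `cv`).
#' @param reactant_range,product_range Disjoint CV intervals `c(lo, hi)`.
#' @param min_dwell Minimum continuous residence time in a basin for the
#'   visit to count, ps (default 0.5).
#' @param hills Optional hills tibble for hill-index bookkeeping.
#' @param cv Name of the CV column (default: first column other than
#'   `time`/`bias`).
#' @return Tibble with one row per complete cycle: `cycle`, `start_time`,
#'   `end_time` (ps) and, with `hills`, `recross_hill_index`. When no
#'   complete cycle exists the result has zero rows and a `diagnostic`
#'   attribute describing the deepest product-ward excursion.
#' @export
detect_recrossings <- function(colvar, reactant_range, product_range,
                               min_dwell = 0.5, hills = NULL, cv = NULL) {
  stopifnot("time" %in% names(colvar))
  if (is.null(cv)) cv <- setdiff(names(colvar), c("time", "bias"))[1]
  x <- colvar[[cv]]
  t <- colvar$time
  if (min_dwell <= 0) abort("min_dwell must be positive")
  if (max(reactant_range) >= min(product_range) &&
      max(product_range) >= min(reactant_range)) {
    abort("reactant and product ranges must be disjoint")
  }
  in_r <- x >= reactant_range[1] & x <= reactant_range[2]
  in_p <- x >= product_range[1] & x <= product_range[2]

  # collapse to dwell-filtered basin visit episodes
  code <- ifelse(in_r, 1L, ifelse(in_p, 2L, 0L))
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- t[ends] - t[starts]
  visit <- r$values != 0L & dur >= min_dwell
  ep <- tibble(
    basin = r$values[visit],
    t_enter = t[starts[visit]],
    t_leave = t[ends[visit]]
  )

  cycles <- list()
  phase <- 0L  # 0: before first R; 1: R seen; 2: P seen after R
  start_t <- NA_real_
  for (i in seq_len(nrow(ep))) {
    b <- ep$basin[i]
    if (b == 1L) {
      if (phase == 0L) {
        start_t <- ep$t_enter[i]
        phase <- 1L
      } else if (phase == 2L) {
        cycles[[length(cycles) + 1L]] <-
          tibble(start_time = start_t, end_time = ep$t_enter[i])
        start_t <- ep$t_enter[i]  # the closing R visit opens the next cycle
        phase <- 1L
      }
      # phase 1: repeated reactant visits keep the original cycle start
    } else if (b == 2L && phase == 1L) {
      phase <- 2L
    }
  }
  if (length(cycles) == 0) {
    out <- tibble(cycle = integer(0), start_time = numeric(0),
                  end_time = numeric(0))
    toward_p <- if (mean(product_range) >= mean(reactant_range)) max(x) else min(x)
    attr(out, "diagnostic") <- sprintf(
      "no complete R->P->R cycle; deepest product-ward excursion reached CV = %.4f (product basin [%.3f, %.3f])",
      toward_p, product_range[1], product_range[2])
    return(out)
  }
  out <- dplyr::bind_rows(cycles)
  out$cycle <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "cycle")
  if (!is.null(hills)) {
    out$recross_hill_index <- vapply(
      out$end_time, function(te) sum(hills$time <= te), 0L)
  }
  out
}

#' Free-energy profile for one recrossing cycle
#'
#' `F(s) = -` (bias accumulated from the start of the run to the end of the
#' cycle) evaluated on the grid, shifted so the minimum over the reactant
#' range is 0 (cumulative-hills convention; set `cumulative = FALSE` to use
#' only the hills deposited within the cycle).
#'
#' @param hills Hills tibble.
#' @param cycle One row of [detect_recrossings()] output (or any list with
#'   `start_time`, `end_time`).
#' @param grid Numeric grid over the CV.
#' @param reactant_range CV interval whose minimum is shifted to zero; when
#'   `NULL`, the global minimum is used.
#' @param cumulative Use all hills from time 0 (default) or only the
#'   cycle's own span.
#' @return Tibble with columns `s` and `f` (kcal/mol). Grid points outside
#'   the hills' sampled CV range are kept but flagged with a warning.
#' @export
profile_per_cycle <- function(hills, cycle, grid, reactant_range = NULL,
                              cumulative = TRUE) {
  cv <- cv_names(hills)
  if (length(cv) != 1) abort("reaction profiles are defined for 1D hill histories")
  t0 <- if (cumulative) -Inf else cycle$start_time
  h <- hills[hills$time >= t0 & hills$time <= cycle$end_time, , drop = FALSE]
  if (nrow(h) == 0) abort("cycle hill span contains no hills")
  sampled <- range(h[[cv]])
  if (min(grid) < sampled[1] - 3 * max(h[[paste0("sigma_", cv)]]) ||
      max(grid) > sampled[2] + 3 * max(h[[paste0("sigma_", cv)]])) {
    warn("profile grid extends beyond the sampled CV range; tails are unreliable")
  }
  f <- -bias_energy(new_hills(h, cv), matrix(grid, ncol = 1))
  ref <- if (is.null(reactant_range)) {
    min(f)
  } else {
    sel <- grid >= reactant_range[1] & grid <= reactant_range[2]
    if (!any(sel)) abort("reactant range contains no grid points")
    min(f[sel])
  }
  tibble(s = grid, f = f - ref)
}

#' Boltzmann (exponential) average of free-energy profiles
#'
#' Combines per-cycle profiles as
#' `f_avg(s) = -kB T ln[ (1/n) sum_i exp(-F_i(s) / kB T) ]`, the standard
#' convention for averaging metadynamics profiles over recrossing cycles,
#' then shifts the average so its minimum is 0. `sd` and `se = sd/sqrt(n)`
#' are computed pointwise across the profiles as given (unshifted).
#'
#' @param profiles A list of profile tibbles from [profile_per_cycle()]
#'   (common grid required), or one tibble with columns `s`, `f`, `cycle`.
#' @param temperature Temperature, K (default 300).
#' @return Tibble of class `glycofel_avg_profile` with columns `s`, `f_avg`,
#'   `sd`, `se`; attributes `n_cycles` and `temperature`.
#' @export
exponential_average <- function(profiles, temperature = 300) {
  if (is.data.frame(profiles)) {
    stopifnot(all(c("s", "f", "cycle") %in% names(profiles)))
    profiles <- lapply(split(profiles, profiles$cycle), function(d) d[, c("s", "f")])
  }
  stopifnot(length(profiles) >= 1)
  s <- profiles[[1]]$s
  for (p in profiles) {
    if (!isTRUE(all.equal(p$s, s))) abort("profiles must share a common grid")
  }
  Fm <- vapply(profiles, function(p) p$f, numeric(length(s)))
  Fm <- matrix(Fm, nrow = length(s))
  kT <- .kB * temperature
  n <- ncol(Fm)
  # log-sum-exp, stabilised by the pointwise minimum
  fmin <- apply(Fm, 1, min)
  f_avg <- fmin - kT * log(rowMeans(exp(-(Fm - fmin) / kT)))
  sd_p <- if (n > 1) apply(Fm, 1, stats::sd) else rep(0, length(s))
  out <- tibble(
    s = s,
    f_avg = f_avg - min(f_avg),
    sd = sd_p,
    se = sd_p / sqrt(n)
  )
  attr(out, "n_cycles") <- n
  attr(out, "temperature") <- temperature
  class(out) <- unique(c("glycofel_avg_profile", class(out)))
  out
}

#' Barrier and reaction free energy from an averaged profile
#'
#' `delta_g_dagger` is the profile maximum on the segment between the two
#' basins minus the reactant minimum; `delta_g_rxn` is the product minimum
#' minus the reactant minimum; `ts_position` is the argmax. The uncertainty
#' at the TS is the pointwise SE (and SD) there. If several local maxima on
#' the inter-basin segment lie within one SD of the highest, a multi-TS
#' warning lists them.
#'
#' @param profile Averaged profile from [exponential_average()], or any
#'   tibble with `s`, `f_avg` (optionally `sd`, `se`).
#' @param reactant_range,product_range CV intervals of the two basins.
#' @return A `glycofel_barrier` object (list) with fields `delta_g_dagger`,
#'   `delta_g_rxn`, `ts_position`, `ts_se`, `ts_sd`, `exergonic`,
#'   `reactant_min`, `product_min`, `candidates`. Supports [tidy()] and
#'   [glance()].
#' @export
extract_barrier <- function(profile, reactant_range, product_range) {
  stopifnot(all(c("s", "f_avg") %in% names(profile)))
  s <- profile$s
  f <- profile$f_avg
  sel_r <- s >= reactant_range[1] & s <= reactant_range[2]
  sel_p <- s >= product_range[1] & s <= product_range[2]
  if (!any(sel_r) || !any(sel_p)) {
    abort("profile grid does not cover both basin ranges")
  }
  i_r <- which(sel_r)[which.min(f[sel_r])]
  i_p <- which(sel_p)[which.min(f[sel_p])]
  seg <- if (s[i_r] <= s[i_p]) which(s >= s[i_r] & s <= s[i_p]) else
    which(s >= s[i_p] & s <= s[i_r])
  i_ts <- seg[which.max(f[seg])]
  sd_v <- if ("sd" %in% names(profile)) profile$sd else rep(0, length(s))
  se_v <- if ("se" %in% names(profile)) profile$se else rep(0, length(s))

  # local maxima on the inter-basin segment within one SD of the top
  fs <- f[seg]
  n <- length(fs)
  loc <- if (n >= 3) {
    which(fs[2:(n - 1)] > fs[1:(n - 2)] & fs[2:(n - 1)] >= fs[3:n]) + 1L
  } else integer(0)
  cand <- seg[loc]
  cand <- cand[f[cand] >= f[i_ts] - max(sd_v[i_ts], 1e-12)]
  if (length(cand) > 1) {
    warn(paste0("multiple transition-state candidates within one SD: s = ",
                paste(sprintf("%.3f", s[cand]), collapse = ", ")))
  }
  out <- list(
    delta_g_dagger = f[i_ts] - f[i_r],
    delta_g_rxn = f[i_p] - f[i_r],
    ts_position = s[i_ts],
    ts_se = se_v[i_ts],
    ts_sd = sd_v[i_ts],
    exergonic = (f[i_p] - f[i_r]) < 0,
    reactant_min = s[i_r],
    product_min = s[i_p],
    candidates = s[cand]
  )
  class(out) <- "glycofel_barrier"
  out
}

#' @export
print.glycofel_barrier <- function(x, ...) {
  cat(sprintf("Free-energy barrier: %.2f +/- %.2f kcal/mol (SE at TS) at s = %.3f\n",
              x$delta_g_dagger, x$ts_se, x$ts_position))
  cat(sprintf("Reaction free energy: %.2f kcal/mol (%s)\n",
              x$delta_g_rxn, if (x$exergonic) "exergonic" else "endergonic"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.glycofel_barrier <- function(x, ...) {
  tibble(
    term = c("delta_g_dagger", "delta_g_rxn", "ts_position"),
    estimate = c(x$delta_g_dagger, x$delta_g_rxn, x$ts_position),
    std.error = c(x$ts_se, NA_real_, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.glycofel_barrier <- function(x, ...) {
  tibble(
    delta_g_dagger = x$delta_g_dagger,
    delta_g_rxn = x$delta_g_rxn,
    ts_position = x$ts_position,
    ts_se = x$ts_se,
    ts_sd = x$ts_sd,
    exergonic = x$exergonic,
    n_ts_candidates = length(x$candidates)
  )
}

#' Bin observables along a normalized reaction coordinate
#'
#' Maps the reaction CV on the forward (R -> P) half of a cycle onto
#' `xi in [0, 1]` between the reactant-minimum and product-minimum CV
#' positions, then bins per-frame observables by `xi` with mean and SD per
#' bin. If the CV is not monotone in time beyond `tolerance` (fraction of
#' backward steps), the mapping falls back to time ordering with a warning.
#'
#' @param data Tibble with columns `time`, `s` (the CV) and observable
#'   columns.
#' @param s_reactant,s_product CV values of the reactant and product minima.
#' @param n_bins Number of xi bins (default 20).
#' @param observables Character vector of observable columns (default: all
#'   numeric columns except `time`, `s`).
#' @param tolerance Tolerated fraction of CV steps moving backward before
#'   the time-ordering fallback engages (default 0.2).
#' @return Tibble with `xi` (bin centre) and `<obs>_mean`, `<obs>_sd`,
#'   `n` per bin; empty bins are reported with `NA` means, never
#'   interpolated.
#' @export
normalized_reaction_coordinate <- function(data, s_reactant, s_product,
                                           n_bins = 20, observables = NULL,
                                           tolerance = 0.2) {
  stopifnot(all(c("time", "s") %in% names(data)))
  if (is.null(observables)) {
    observables <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                           c("time", "s", "frame"))
  }
  data <- dplyr::arrange(data, .data$time)
  xi <- (data$s - s_reactant) / (s_product - s_reactant)
  step_sign <- sign(diff(xi))
  frac_back <- if (length(step_sign) > 0) mean(step_sign < 0) else 0
  if (frac_back > tolerance) {
    warn(sprintf(
      "CV not monotone along the cycle (%.0f%% backward steps); using time ordering for xi",
      100 * frac_back))
    xi <- (seq_len(nrow(data)) - 1) / max(1, nrow(data) - 1)
  }
  xi <- pmin(1, pmax(0, xi))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  bin <- cut(xi, breaks, include.lowest = TRUE, labels = FALSE)
  out <- tibble(xi = centers)
  for (ob in observables) {
    v <- data[[ob]]
    out[[paste0(ob, "_mean")]] <- vapply(seq_len(n_bins), function(b) {
      vv <- v[which(bin == b)]
      if (length(vv) == 0) NA_real_ else mean(vv)
    }, 0)
    out[[paste0(ob, "_sd")]] <- vapply(seq_len(n_bins), function(b) {
      vv <- v[which(bin == b)]
      if (length(vv) < 2) NA_real_ else stats::sd(vv)
    }, 0)
  }
  out$n <- vapply(seq_len(n_bins), function(b) sum(bin == b, na.rm = TRUE), 0L)
  out
}
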