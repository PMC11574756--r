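# Collective variables: the signed multi-distance reaction coordinate for
# glycoside hydrolysis, normalized puckering CVs, and the calibration
# protocols that derive Gaussian widths and deposition strides from an
# unbiased equilibration run.

#' Default six-distance glycosylation reaction coordinate
#'
#' The reaction CV is a signed linear combination of the six covalent-bond
#' distances expected to break (+) or form (-) in the inverting,
#' single-displacement mechanism:
#' `d(Nd-H)His302 - d(H-O') + d(C1-O') - d(Ow-C1) + d(Ow-Hw) - d(Hw-OAsp90)`,
#' where O' is the glycosidic oxygen of the leaving-group galactose, Ow/Hw
#' the catalytic water, and C1 the anomeric carbon of the -1 sugar.
#' Selectors are residue + atom name pairs, matching the residue/atom naming
#' used by the synthetic generators ([gen_reaction_trajectory()]).
#'
#' @return A reaction-CV tibble with columns `residue_a`, `atom_a`,
#'   `residue_b`, `atom_b`, `sign`, `label`.
#' @export
#' @examples
#' gh117_reaction_cv()
gh117_reaction_cv <- function() {
  tibble(
    residue_a = c("HIS302", "HIS302", "LIG1", "WAT1", "WAT1", "WAT1"),
    atom_a    = c("ND1", "HD1", "C1", "OW", "OW", "HW1"),
    residue_b = c("HIS302", "GAL1", "GAL1", "LIG1", "WAT1", "ASP90"),
    atom_b    = c("HD1", "O1", "O1", "C1", "HW1", "OD1"),
    sign      = c(1, -1, 1, -1, 1, -1),
    label     = c("Nd-H", "H-O'", "C1-O'", "Ow-C1", "Ow-Hw", "Hw-OAsp90")
  )
}

validate_reaction_cv <- function(cv) {
  need <- c("residue_a", "atom_a", "residue_b", "atom_b", "sign")
  if (!is.data.frame(cv) || !all(need %in% names(cv))) {
    abort("reaction CV must be a data frame with columns residue_a, atom_a, residue_b, atom_b, sign")
  }
  if (nrow(cv) < 1) abort("reaction CV needs at least one distance term")
  if (!all(cv$sign %in% c(-1, 1))) abort("reaction CV signs must be +1 or -1")
  same <- cv$residue_a == cv$residue_b & cv$atom_a == cv$atom_b
  if (any(same)) abort("reaction CV terms must involve two distinct atoms")
  invisible(cv)
}

# Resolve (residue, atom) selector pairs in one frame; returns n x 3 matrix.
frame_lookup <- function(frame, residue, atom) {
  key <- paste(frame$residue, frame$atom)
  i <- match(paste(residue, atom), key)
  if (anyNA(i)) {
    missing <- paste0(residue[is.na(i)], "/", atom[is.na(i)])
    abort(paste0("atom selector(s) not found in frame: ",
                 paste(unique(missing), collapse = ", ")))
  }
  cbind(frame$x[i], frame$y[i], frame$z[i])
}

#' Evaluate the reaction CV over a trajectory
#'
#' For every frame, computes `sum(sign * ||a - b||)` over the CV's distance
#' terms. The CV is exactly linear in each distance, so along a reaction
#' path where breaking bonds lengthen and forming bonds shorten it increases
#' monotonically.
#'
#' @param traj Trajectory tibble (`frame`, `residue`, `atom`, `x`, `y`, `z`,
#'   optional `time`).
#' @param cv Reaction-CV term table (default [gh117_reaction_cv()]).
#' @return Tibble with columns `frame` (and `time` when present) and `s`
#'   (the CV value, angstrom).
#' @export
evaluate_reaction_cv <- function(traj, cv = gh117_reaction_cv()) {
  validate_reaction_cv(cv)
  frames <- split(traj, traj$frame)
  out <- purrr::map(frames, function(fr) {
    a <- frame_lookup(fr, cv$residue_a, cv$atom_a)
    b <- frame_lookup(fr, cv$residue_b, cv$atom_b)
    d <- sqrt(rowSums((a - b)^2))
    res <- tibble(frame = fr$frame[1], s = sum(cv$sign * d))
    if ("time" %in% names(fr)) res$time <- fr$time[1]
    res
  })
  out <- dplyr::bind_rows(out) |> dplyr::arrange(.data$frame)
  dplyr::relocate(out, "frame")
}

#' Pairwise distances named by CV term labels
#'
#' Convenience companion to [evaluate_reaction_cv()]: the individual signed
#' terms, one column per labelled distance.
#'
#' @inheritParams evaluate_reaction_cv
#' @return Tibble with `frame` and one distance column per term label.
#' @export
reaction_cv_terms <- function(traj, cv = gh117_reaction_cv()) {
  validate_reaction_cv(cv)
  lab <- cv$label %||% paste0("d", seq_len(nrow(cv)))
  frames <- split(traj, traj$frame)
  out <- purrr::map(frames, function(fr) {
    a <- frame_lookup(fr, cv$residue_a, cv$atom_a)
    b <- frame_lookup(fr, cv$residue_b, cv$atom_b)
    d <- sqrt(rowSums((a - b)^2))
    res <- tibble(frame = fr$frame[1])
    res[lab] <- as.list(d)
    res
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$frame)
}

#' Gaussian hill width from an unbiased CV series
#'
#' The deposition width for a CV is taken as half the sample standard
#' deviation (n - 1 denominator) of that CV in an unbiased equilibration
#' run.
#'
#' @param series Numeric vector of CV samples, or a data frame with a
#'   `value` column.
#' @return The suggested hill width sigma, in CV units.
#' @export
#' @examples
#' estimate_gaussian_width(c(-1, 1))  # 0.5 * sqrt(2)
estimate_gaussian_width <- function(series) {
  x <- if (is.data.frame(series)) series$value else series
  if (length(x) < 2) abort("need at least 2 samples to estimate a width")
  s <- stats::sd(x)
  if (s == 0) abort("constant series: width would be zero")
  0.5 * s
}

#' Deposition time from CV oscillations in an unbiased run
#'
#' Identifies local maxima of the CV series (strict three-point comparison
#' after smoothing with a centred moving average, default window 5 samples)
#' and returns the mean interval between the first five consecutive peaks --
#' the protocol for choosing how often to deposit bias. Because "peak" is
#' only approximately defined for a real trajectory, the mean over all
#' detected peaks and the unsmoothed peak count are reported alongside.
#'
#' @param times Sample times, ps (strictly increasing).
#' @param values CV values, same length.
#' @param smooth_window Centred moving-average window, samples (odd;
#'   default 5). `1` disables smoothing.
#' @return Tibble with one row: `deposition_time` (ps; mean of the four gaps
#'   between the first five peaks), `n_peaks`, `all_peaks_mean` (ps),
#'   `n_peaks_unsmoothed`.
#' @export
estimate_deposition_time <- function(times, values, smooth_window = 5) {
  stopifnot(length(times) == length(values), smooth_window %% 2 == 1)
  if (is.unsorted(times, strictly = TRUE)) abort("times must be strictly increasing")
  # strict three-point maxima; NA comparisons (incomplete smoothing windows
  # at the edges) never qualify because which() drops NA
  local_maxima <- function(v) {
    n <- length(v)
    if (n < 3) return(integer(0))
    i <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]
    which(!is.na(i) & i) + 1L
  }
  smoothed <- if (smooth_window > 1) {
    as.numeric(stats::filter(values, rep(1 / smooth_window, smooth_window),
                             sides = 2))
  } else {
    values
  }
  pk <- local_maxima(smoothed)
  if (length(pk) < 5) {
    abort(sprintf(
      "insufficient oscillation: found %d peaks, need at least 5", length(pk)))
  }
  t_pk <- times[pk]
  tibble(
    deposition_time = mean(diff(t_pk[1:5])),
    n_peaks = length(pk),
    all_peaks_mean = mean(diff(t_pk)),
    n_peaks_unsmoothed = length(local_maxima(values))
  )
}

#' Normalized puckering collective variables
#'
#' The unit-sphere CVs `cv1 = qx/Q`, `cv2 = qy/Q`, `cv3 = qz/Q` of one or
#' more puckering states; delegates to [cremer_pople()] output columns.
#'
#' @param state A puckering state tibble from [cremer_pople()] or
#'   [pucker_trajectory()].
#' @return Tibble with columns `cv1`, `cv2`, `cv3` (unit norm per row).
#' @export
puckering_cvs <- function(state) {
  stopifnot(all(c("cv1", "cv2", "cv3") %in% names(state)))
  if (any(state$Q <= 1e-6) || anyNA(state$cv1)) {
    abort("planar ring: normalized puckering CVs undefined")
  }
  as_tibble(state[, c("cv1", "cv2", "cv3")])
}
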