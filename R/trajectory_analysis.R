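# Per-frame catalytic-geometry analysis: named distances and the ring
# flattening dihedral, shared-proton (low-barrier hydrogen bond) detection
# for the His/Asp general-acid dyad, conformer itinerary strings, and the
# oxocarbenium-character descriptor pair (anomeric C1-O5 bond length and
# the C5-O5-C1-C2 dihedral).

#' Measure catalytic geometry for every frame
#'
#' @param traj Trajectory tibble (`frame`, `residue`, `atom`, `x`, `y`, `z`,
#'   optional `time`).
#' @param distances Named list of distance selectors, each
#'   `list(c(residue_a, atom_a), c(residue_b, atom_b))`; the names become
#'   output columns.
#' @param dihedral Optional list of four `c(residue, atom)` selectors for a
#'   signed torsion (IUPAC convention), reported as `dihedral` in degrees
#'   in `(-180, 180]`.
#' @param ring_residue Optional residue name holding the six ring atoms
#'   O5, C1..C5; when given, puckering coordinates and the conformer label
#'   are appended via [cremer_pople()] / [classify_conformer()].
#'
#' @return Tibble with one row per frame: `frame` (and `time`), one column
#'   per named distance (angstrom), `dihedral` (degrees) when requested, and
#'   `Q`, `theta`, `phi`, `conformer`, `family` when `ring_residue` is given.
#' @export
#' @examples
#' traj <- gen_dyad_ensemble(1.32, 0.21, 2.54, 0.09, n = 20, seed = 1)
#' head(measure_frames(traj, distances = list(
#'   d_dh = list(c("HIS302", "ND1"), c("HIS302", "HD1")),
#'   d_da = list(c("HIS302", "ND1"), c("ASP320", "OD1")))))
measure_frames <- function(traj, distances = list(), dihedral = NULL,
                           ring_residue = NULL) {
  frames <- split(traj, traj$frame)
  rows <- purrr::map(frames, function(fr) {
    res <- tibble(frame = fr$frame[1])
    if ("time" %in% names(fr)) res$time <- fr$time[1]
    for (nm in names(distances)) {
      sel <- distances[[nm]]
      a <- frame_lookup(fr, sel[[1]][1], sel[[1]][2])
      b <- frame_lookup(fr, sel[[2]][1], sel[[2]][2])
      res[[nm]] <- sqrt(sum((a - b)^2))
    }
    if (!is.null(dihedral)) {
      p <- lapply(dihedral, function(s) as.numeric(frame_lookup(fr, s[1], s[2])))
      res$dihedral <- torsion_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    }
    res
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$frame)
  if (!is.null(ring_residue)) {
    ring_traj <- traj[traj$residue == ring_residue, , drop = FALSE]
    if (nrow(ring_traj) == 0) {
      abort(paste0("ring residue not found in trajectory: ", ring_residue))
    }
    pk <- pucker_trajectory(ring_traj, classify = TRUE)
    out <- dplyr::left_join(
      out, pk[, c("frame", "Q", "theta", "phi", "conformer", "family")],
      by = "frame")
  }
  out
}

#' Shared-proton (low-barrier hydrogen bond) analysis of an acid dyad
#'
#' For a donor-H...acceptor triple measured over a trajectory, reports mean
#' and SD of the donor-H and donor-acceptor distances, the fraction of
#' frames in which the proton is "shared" (donor-H at least `shared_dh_min`
#' *and* donor-acceptor at most `lbhb_da_max`), and an LBHB flag raised when
#' `fraction_shared >= 0.25` and the mean donor-acceptor distance is within
#' `lbhb_da_max`. The default thresholds (1.2 and 2.6 angstrom) are
#' heuristics consistent with reported shared-proton dyad geometry
#' (donor-H around 1.3, donor-acceptor around 2.5 angstrom); they are
#' configurable and make `fraction_shared` monotone non-decreasing as
#' `shared_dh_min` decreases.
#'
#' @param frames Tibble with columns `d_dh` (donor-H, angstrom) and `d_da`
#'   (donor-acceptor, angstrom), e.g. from [measure_frames()]; at least 10
#'   rows.
#' @param shared_dh_min Donor-H distance above which the proton counts as
#'   displaced toward the acceptor (default 1.2).
#' @param lbhb_da_max Donor-acceptor distance below which the hydrogen bond
#'   is short enough to be low-barrier (default 2.6).
#' @return A `glycofel_dyad` object (list) with fields `mean_dh`, `sd_dh`,
#'   `mean_da`, `sd_da`, `fraction_shared`, `lbhb_flag`, `n_frames`,
#'   `thresholds`. Supports [tidy()] and [glance()].
#' @export
dyad_analysis <- function(frames, shared_dh_min = 1.2, lbhb_da_max = 2.6) {
  stopifnot(all(c("d_dh", "d_da") %in% names(frames)))
  if (nrow(frames) < 10) abort("dyad analysis needs at least 10 frames")
  shared <- frames$d_dh >= shared_dh_min & frames$d_da <= lbhb_da_max
  out <- list(
    mean_dh = mean(frames$d_dh), sd_dh = stats::sd(frames$d_dh),
    mean_da = mean(frames$d_da), sd_da = stats::sd(frames$d_da),
    fraction_shared = mean(shared),
    lbhb_flag = mean(shared) >= 0.25 && mean(frames$d_da) <= lbhb_da_max,
    n_frames = nrow(frames),
    thresholds = c(shared_dh_min = shared_dh_min, lbhb_da_max = lbhb_da_max)
  )
  class(out) <- "glycofel_dyad"
  out
}

#' @export
print.glycofel_dyad <- function(x, ...) {
  cat(sprintf("Dyad geometry over %d frames:\n", x$n_frames))
  cat(sprintf("  donor-H        %.2f +/- %.2f A\n", x$mean_dh, x$sd_dh))
  cat(sprintf("  donor-acceptor %.2f +/- %.2f A\n", x$mean_da, x$sd_da))
  cat(sprintf("  proton shared in %.0f%% of frames; low-barrier H-bond: %s\n",
              100 * x$fraction_shared, if (x$lbhb_flag) "yes" else "no"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.glycofel_dyad <- function(x, ...) {
  tibble(
    term = c("donor_h", "donor_acceptor"),
    estimate = c(x$mean_dh, x$mean_da),
    std.dev = c(x$sd_dh, x$sd_da)
  )
}

#' @exportS3Method generics::glance
glance.glycofel_dyad <- function(x, ...) {
  tibble(
    mean_dh = x$mean_dh, sd_dh = x$sd_dh,
    mean_da = x$mean_da, sd_da = x$sd_da,
    fraction_shared = x$fraction_shared,
    lbhb_flag = x$lbhb_flag, n_frames = x$n_frames
  )
}

#' Conformational itinerary of a ring trajectory
#'
#' Run-length compresses per-frame conformer labels into the itinerary a
#' sugar traverses (e.g. `"1,4B -> 4E -> 1,4B"`). Runs shorter than
#' `min_dwell_fraction` of the trajectory are treated as flicker and merged
#' into their longer neighbour, so the string is idempotent under
#' re-compression.
#'
#' @param frames Tibble with a `conformer` column (e.g. from
#'   [pucker_trajectory()] or [measure_frames()]); conformers must be
#'   defined (non-`NA`) in at least 90 percent of frames.
#' @param min_dwell_fraction Minimum dwell (fraction of frames) for a
#'   conformer run to appear in the itinerary (default 0.02).
#' @param sep Separator used in the rendered string.
#' @return A `glycofel_itinerary` object: fields `steps` (tibble
#'   `conformer`, `dwell_fraction`), `string`, `n_frames`. `format()` and
#'   `print()` render the string.
#' @export
itinerary <- function(frames, min_dwell_fraction = 0.02, sep = " -> ") {
  stopifnot("conformer" %in% names(frames))
  lab <- frames$conformer
  if (mean(is.na(lab)) > 0.10) {
    abort("pucker undefined in more than 10% of frames (mostly planar trajectory)")
  }
  lab <- lab[!is.na(lab)]
  n <- length(lab)
  r <- rle(lab)
  # merge sub-threshold runs into their largest neighbour, shortest first
  while (length(r$lengths) > 1 && min(r$lengths) < min_dwell_fraction * n) {
    i <- which.min(r$lengths)
    j <- if (i == 1) 2L
    else if (i == length(r$lengths)) i - 1L
    else if (r$lengths[i - 1] >= r$lengths[i + 1]) i - 1L else i + 1L
    r$lengths[j] <- r$lengths[j] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    # re-collapse equal neighbours created by the merge
    r <- rle(inverse.rle(r))
  }
  steps <- tibble(conformer = r$values, dwell_fraction = r$lengths / n)
  out <- list(
    steps = steps,
    string = paste(steps$conformer, collapse = sep),
    n_frames = n
  )
  class(out) <- "glycofel_itinerary"
  out
}

#' @export
format.glycofel_itinerary <- function(x, ...) x$string

#' @export
print.glycofel_itinerary <- function(x, ...) {
  cat("Conformational itinerary: ", x$string, "\n", sep = "")
  print(x$steps)
  invisible(x)
}

#' Oxocarbenium-character descriptors along a trajectory
#'
#' The paired series that signals an oxocarbenium ion-like species at the
#' transition state: shortening of the anomeric C1-O5 bond and flattening
#' of the ring (C5-O5-C1-C2 dihedral approaching 0). Suitable for binning
#' with [normalized_reaction_coordinate()].
#'
#' @param frames Tibble with columns `d_c1_o5` (angstrom) and `dihedral`
#'   (degrees), e.g. from [measure_frames()].
#' @return Tibble with `frame` (and `time`), `d_c1_o5`, `dihedral`;
#'   attributes `min_d_c1_o5` / `max_flattening` report where the bond is
#'   shortest and the ring flattest (frame indices).
#' @export
oxocarbenium_descriptors <- function(frames) {
  stopifnot(all(c("d_c1_o5", "dihedral") %in% names(frames)))
  keep <- intersect(c("frame", "time", "d_c1_o5", "dihedral"), names(frames))
  out <- as_tibble(frames[, keep])
  attr(out, "min_d_c1_o5") <- out$frame[which.min(out$d_c1_o5)]
  attr(out, "max_flattening") <- out$frame[which.min(abs(out$dihedral))]
  out
}
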