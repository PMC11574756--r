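# Readers and writers for the plain-text formats the package consumes:
# multi-model PDB and multi-frame chemical XYZ trajectories, and the
# PLUMED-style HILLS / COLVAR whitespace dialects.
#
# The in-memory trajectory container is a plain tibble with columns
# frame, residue, atom, x, y, z (+ optional time, ps). "residue" is the
# residue name and number pasted together ("HIS302"), which keeps atom
# selectors format-agnostic across PDB and XYZ.

#' Read a (multi-model) PDB file as a trajectory tibble
#'
#' Uses \pkg{bio3d} to parse ATOM/HETATM records; each MODEL becomes one
#' frame.
#'
#' @param path PDB file path.
#' @return Tibble with columns `frame`, `residue`, `atom`, `x`, `y`, `z`.
#' @export
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  residue <- paste0(at$resid, at$resno)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- nrow(at)
  purrr::map_dfr(seq_len(n_frames), function(f) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    tibble(frame = f, residue = residue, atom = at$elety,
           x = m[, 1], y = m[, 2], z = m[, 3])
  })
}

#' Write a trajectory tibble as a multi-model PDB file
#'
#' Emits fixed-width ATOM records wrapped in MODEL/ENDMDL blocks, one model
#' per frame. The residue column is split back into a 3-letter residue name
#' and number when it matches `NAME123`; otherwise the residue is written as
#' `UNK` with a sequential number.
#'
#' @param traj Tibble with columns `frame`, `residue`, `atom`, `x`, `y`, `z`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(traj, path) {
  stopifnot(all(c("frame", "residue", "atom", "x", "y", "z") %in% names(traj)))
  resname <- toupper(substr(gsub("[0-9]+$", "", traj$residue), 1, 3))
  resno <- suppressWarnings(as.integer(stringr::str_extract(traj$residue, "[0-9]+$")))
  bad <- resname == "" | is.na(resno)
  if (any(bad)) {
    resname[bad] <- "UNK"
    resno[bad] <- as.integer(factor(traj$residue[bad]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  frames <- split(seq_len(nrow(traj)), traj$frame)
  for (fi in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", fi), con)
    idx <- frames[[fi]]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_along(idx),
      substr(traj$atom[idx], 1, 4),
      resname[idx], resno[idx],
      traj$x[idx], traj$y[idx], traj$z[idx]
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-frame chemical XYZ trajectory
#'
#' Standard XYZ layout: atom count line, comment line, then one
#' `name x y z` line per atom, repeated per frame. Atom names of the form
#' `RESIDUE:ATOM` are split into the trajectory's `residue` and `atom`
#' columns (the writer emits this form); bare names get residue `MOL1`.
#'
#' @param path XYZ file path.
#' @return Tibble with columns `frame`, `residue`, `atom`, `x`, `y`, `z`.
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1
  f <- 0
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort(paste0("malformed XYZ atom-count line at line ", i))
    f <- f + 1
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    name <- vapply(parts, `[[`, "", 1)
    has_res <- grepl(":", name, fixed = TRUE)
    residue <- ifelse(has_res, sub(":.*$", "", name), "MOL1")
    atom <- ifelse(has_res, sub("^[^:]*:", "", name), name)
    out[[f]] <- tibble(
      frame = f, residue = residue, atom = atom,
      x = as.numeric(vapply(parts, `[[`, "", 2)),
      y = as.numeric(vapply(parts, `[[`, "", 3)),
      z = as.numeric(vapply(parts, `[[`, "", 4))
    )
    i <- i + 2 + n
  }
  dplyr::bind_rows(out)
}

#' Write a trajectory tibble as multi-frame XYZ
#'
#' Atom names are written as `RESIDUE:ATOM` so the residue survives the
#' round trip; the comment line carries the frame index (and time when a
#' `time` column is present).
#'
#' @inheritParams write_pdb_frames
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(traj, path) {
  stopifnot(all(c("frame", "residue", "atom", "x", "y", "z") %in% names(traj)))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in split(traj, traj$frame)) {
    writeLines(as.character(nrow(fr)), con)
    cmt <- sprintf("frame %s", fr$frame[1])
    if ("time" %in% names(fr)) cmt <- sprintf("%s time %.6f ps", cmt, fr$time[1])
    writeLines(cmt, con)
    writeLines(sprintf("%s:%s %18.10f %18.10f %18.10f",
                       fr$residue, fr$atom, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

# ---- HILLS / COLVAR dialects -------------------------------------------

#' Read a PLUMED-style HILLS file
#'
#' Layout: a `#! FIELDS time <cv...> <sigma_cv...> height` comment header,
#' then whitespace-separated numeric columns
#' `time center_1..center_n sigma_1..sigma_n height`.
#'
#' @param path HILLS file path.
#' @return A hills tibble (see [new_hills()]) with columns `index`, `time`
#'   (ps), one center column per CV, `sigma_<cv>` columns, and `height`
#'   (kcal/mol); CV names from the header are kept in the `cv_names`
#'   attribute.
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#!")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  cv_names <- NULL
  if (length(hdr) > 0) {
    f <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1])), "[[:space:]]+")[[1]]
    f <- f[nzchar(f)]
    cv_names <- f[!(f %in% c("time", "height")) & !startsWith(f, "sigma_")]
  }
  vals <- strsplit(trimws(body), "[[:space:]]+")
  m <- do.call(rbind, lapply(vals, as.numeric))
  n_cv <- (ncol(m) - 2) / 2
  if (n_cv != round(n_cv)) abort("malformed HILLS file: bad column count")
  if (is.null(cv_names) || length(cv_names) != n_cv) {
    cv_names <- paste0("cv", seq_len(n_cv))
  }
  out <- as_tibble(as.data.frame(m))
  names(out) <- c("time", cv_names, paste0("sigma_", cv_names), "height")
  new_hills(out, cv_names)
}

#' Write a hills tibble as a PLUMED-style HILLS file
#'
#' @param hills Hills tibble from [new_hills()], [read_hills()],
#'   [gen_hills()] or [run_toy_metadynamics()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  cv <- cv_names(hills)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS time", paste(cv, collapse = " "),
                   paste(paste0("sigma_", cv), collapse = " "), "height"), con)
  cols <- c("time", cv, paste0("sigma_", cv), "height")
  m <- as.matrix(hills[, cols])
  writeLines(apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  invisible(path)
}

#' Read a PLUMED-style COLVAR file
#'
#' Layout: optional `#! FIELDS time <cv...> [bias]` header, then
#' whitespace-separated numeric columns `time cv_1..cv_n [bias]`.
#'
#' @param path COLVAR file path.
#' @return Tibble with `time` (ps), one column per CV, and `bias` when
#'   present.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#!")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  vals <- strsplit(trimws(body), "[[:space:]]+")
  m <- do.call(rbind, lapply(vals, as.numeric))
  nms <- NULL
  if (length(hdr) > 0) {
    f <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1])), "[[:space:]]+")[[1]]
    nms <- f[nzchar(f)]
  }
  if (is.null(nms) || length(nms) != ncol(m)) {
    nms <- c("time", paste0("cv", seq_len(ncol(m) - 1)))
  }
  out <- as_tibble(as.data.frame(m))
  names(out) <- nms
  out
}

#' Write a COLVAR tibble as a PLUMED-style file
#'
#' @param colvar Tibble whose first column is `time`; remaining columns are
#'   CV values and, optionally, `bias`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(colvar, path) {
  stopifnot(names(colvar)[1] == "time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(colvar), collapse = " ")), con)
  m <- as.matrix(colvar)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  invisible(path)
}
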