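#' Construct a molecular trajectory object
#'
#' Coordinates are stored in nanometres internally; PDB input (Angstrom) is
#' converted on read. Frames are 0-based in all reporting.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (nm).
#' @param atoms data frame with one row per atom: columns `name`, `resid`,
#'   `resname`, `element` (all optional except `name`).
#' @param frame_interval_ps time between frames in picoseconds.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, atoms, frame_interval_ps = 10) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            frame_interval_ps > 0)
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$name)) stop("atom table must have a 'name' column")
  if (nrow(atoms) != dim(coords)[1])
    stop("atom table and coordinate array disagree on atom count")
  if (is.null(atoms$resid)) atoms$resid <- 1L
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[0-9']", "", atoms$name), 1, 1)
  structure(list(coords = coords, atoms = atoms,
                 frame_interval_ps = frame_interval_ps),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d atoms, %d frames, %.3g ps/frame (%.4g ns span)\n",
              d[1], d[3], x$frame_interval_ps,
              d[3] * x$frame_interval_ps / 1000))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Resolve an atom selection to row indices
#'
#' Selections may be integer indices, a logical mask, or character labels of
#' the form `"resid:name"` (e.g. `"148:OG"`) or bare atom names.
#'
#' @param traj an `md_trajectory`.
#' @param sel selection (integer, logical or character).
#' @return integer atom indices.
#' @export
atom_select <- function(traj, sel) {
  at <- traj$atoms
  if (is.logical(sel)) return(which(sel))
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    if (any(sel < 1 | sel > nrow(at))) stop("atom index out of range")
    return(sel)
  }
  idx <- integer(0)
  for (s in sel) {
    if (grepl(":", s, fixed = TRUE)) {
      parts <- strsplit(s, ":", fixed = TRUE)[[1]]
      hit <- which(at$resid == as.integer(parts[1]) & at$name == parts[2])
    } else {
      hit <- which(at$name == s)
    }
    if (length(hit) == 0) stop(sprintf("no atom matches selection '%s'", s))
    idx <- c(idx, hit)
  }
  idx
}

#' Read a multi-model PDB file as a trajectory
#'
#' Uses bio3d for parsing; MODEL/ENDMDL records become frames. Coordinates
#' are converted from Angstrom to nm.
#'
#' @param path PDB file path.
#' @param frame_interval_ps frame spacing in picoseconds.
#' @return An `md_trajectory`.
#' @export
read_trajectory_pdb <- function(path, frame_interval_ps = 10) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                       # n_frames x 3*n_atoms, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(0, dim = c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  atoms <- data.frame(name = pdb$atom$elety,
                      resid = pdb$atom$resno,
                      resname = pdb$atom$resid,
                      element = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                                       substr(pdb$atom$elety, 1, 1),
                                       pdb$atom$elesy))
  md_trajectory(coords, atoms, frame_interval_ps)
}

#' Write a trajectory as multi-model PDB (Angstrom)
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  xyz <- matrix(0, nrow = nf, ncol = 3 * na)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(traj$coords[, , f])) * 10  # nm -> A
  con <- file(path, "w")
  on.exit(close(con))
  at <- traj$atoms
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (a in seq_len(na)) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        a, substr(at$name[a], 1, 4), substr(at$resname[a], 1, 3),
        at$resid[a], xyz[f, 3 * a - 2], xyz[f, 3 * a - 1], xyz[f, 3 * a],
        at$element[a]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a whitespace XYZ-per-frame trajectory
#'
#' Plain-text format: each frame is a block of `n_atoms` lines
#' `name x y z` (nm), frames separated by blank lines.
#'
#' @param path file path.
#' @param frame_interval_ps frame spacing (ps).
#' @return An `md_trajectory`.
#' @export
read_trajectory_xyz <- function(path, frame_interval_ps = 10) {
  lines <- readLines(path)
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0]
  parse_block <- function(b) {
    f <- do.call(rbind, strsplit(trimws(b), "\\s+"))
    list(names = f[, 1],
         xyz = matrix(as.numeric(f[, 2:4]), ncol = 3))
  }
  parsed <- lapply(blocks, parse_block)
  na <- length(parsed[[1]]$names)
  if (!all(vapply(parsed, function(p) length(p$names), 1L) == na))
    stop("inconsistent atom count across frames")
  coords <- array(0, dim = c(na, 3, length(parsed)))
  for (f in seq_along(parsed)) coords[, , f] <- parsed[[f]]$xyz
  md_trajectory(coords, data.frame(name = parsed[[1]]$names),
                frame_interval_ps)
}
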