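# Trajectory observables: H-bond occupancy, pair distances, rigid-body
# superposition, RMSF/RMSD, buried-water residency. Internal units: nm, ps.

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow the widely used trajectory-analysis convention: a bond is
#' counted when the donor--acceptor distance is at most 0.35 nm and the
#' hydrogen--donor--acceptor angle is at most 30 degrees (both comparisons
#' inclusive).
#'
#' @param max_donor_acceptor_nm distance cutoff (nm).
#' @param max_angle_deg hydrogen--donor--acceptor angle cutoff (degrees).
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_donor_acceptor_nm = 0.35, max_angle_deg = 30) {
  stopifnot(max_donor_acceptor_nm > 0, max_angle_deg > 0)
  structure(list(max_donor_acceptor_nm = max_donor_acceptor_nm,
                 max_angle_deg = max_angle_deg),
            class = "hbond_criteria")
}

.atom1 <- function(traj, sel, what) {
  idx <- atom_select(traj, sel)
  if (length(idx) != 1)
    stop(sprintf("selection for %s must resolve to exactly one atom", what))
  idx
}

#' Per-frame hydrogen-bond series for one donor--H--acceptor triad
#'
#' Frame `i` is bonded iff the donor--acceptor distance is `<=` the distance
#' cutoff and the hydrogen--donor--acceptor angle (at the donor) is `<=` the
#' angle cutoff.
#'
#' @param traj an [md_trajectory()].
#' @param donor,hydrogen,acceptor single-atom selections (see
#'   [atom_select()]).
#' @param criteria an [hbond_criteria()].
#' @return Logical vector, one element per frame.
#' @export
hbond_series <- function(traj, donor, hydrogen, acceptor,
                         criteria = hbond_criteria()) {
  d_i <- .atom1(traj, donor, "donor")
  h_i <- .atom1(traj, hydrogen, "hydrogen")
  a_i <- .atom1(traj, acceptor, "acceptor")
  if (length(unique(c(d_i, h_i, a_i))) != 3)
    stop("donor, hydrogen and acceptor must be distinct atoms")
  D <- traj$coords[d_i, , , drop = FALSE]
  H <- traj$coords[h_i, , , drop = FALSE]
  A <- traj$coords[a_i, , , drop = FALSE]
  dim(D) <- dim(H) <- dim(A) <- c(3, n_frames(traj))
  da <- sqrt(colSums((A - D)^2))
  v1 <- H - D; v2 <- A - D
  cosang <- colSums(v1 * v2) / (sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  # inclusive boundaries, with a guard so exactly-on-threshold geometry is
  # not lost to floating-point round-off
  (da <= criteria$max_donor_acceptor_nm + 1e-12) &
    (ang <= criteria$max_angle_deg + 1e-9)
}

#' Occupancy statistics over one or more H-bond series
#'
#' @param series logical vector or list of equal-length logical vectors (one
#'   per triad).
#' @return List with `pct_any_bond`, `pct_two_bonds` (two or more triads
#'   bonded simultaneously), `pct_no_bond`, and `per_triad_share` (each
#'   triad's bonded frames as a percentage of frames with at least one bond).
#' @export
occupancy_stats <- function(series) {
  if (is.logical(series)) series <- list(series)
  nfr <- unique(vapply(series, length, 1L))
  if (length(nfr) != 1) stop("series must all have equal length")
  m <- do.call(cbind, series)
  nbonds <- rowSums(m)
  any_b <- nbonds >= 1
  share <- if (sum(any_b) > 0) 100 * colSums(m & any_b) / sum(any_b)
           else rep(NA_real_, ncol(m))
  names(share) <- names(series)
  list(pct_any_bond = 100 * mean(any_b),
       pct_two_bonds = 100 * mean(nbonds >= 2),
       pct_no_bond = 100 * mean(!any_b),
       per_triad_share = share)
}

#' Pair distance series and histogram
#'
#' @param traj an [md_trajectory()].
#' @param atom_a,atom_b single-atom selections.
#' @param bin_nm histogram bin width in nm (default 0.02); bins are
#'   left-closed `[lo, hi)`.
#' @return List with `series` (nm per frame) and `histogram` (data frame
#'   `lo`, `hi`, `mid`, `density`; density integrates to 1).
#' @export
pair_distance <- function(traj, atom_a, atom_b, bin_nm = 0.02) {
  a_i <- .atom1(traj, atom_a, "atom_a")
  b_i <- .atom1(traj, atom_b, "atom_b")
  A <- traj$coords[a_i, , ]; B <- traj$coords[b_i, , ]
  dim(A) <- dim(B) <- c(3, n_frames(traj))
  d <- sqrt(colSums((A - B)^2))
  lo0 <- floor(min(d) / bin_nm) * bin_nm
  breaks <- seq(lo0, max(d) + bin_nm, by = bin_nm)
  counts <- vapply(seq_len(length(breaks) - 1), function(k)
    sum(d >= breaks[k] & d < breaks[k + 1]), 0)
  density <- counts / (sum(counts) * bin_nm)
  list(series = d,
       histogram = data.frame(lo = head(breaks, -1), hi = tail(breaks, -1),
                              mid = head(breaks, -1) + bin_nm / 2,
                              density = density))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' between two coordinate sets over a selection.
#'
#' @param coords `n x 3` matrix to move (nm).
#' @param reference `n x 3` target matrix.
#' @param selection atom indices used for the fit (default all).
#' @return List with `rotation` (3x3), `translation` (length 3; the fitted
#'   map is `x %*% R + t`), `rmsd` (nm over the selection after fitting) and
#'   `coords` (all atoms transformed).
#' @export
superpose <- function(coords, reference, selection = NULL) {
  stopifnot(ncol(coords) == 3, ncol(reference) == 3,
            nrow(coords) == nrow(reference))
  sel <- if (is.null(selection)) seq_len(nrow(coords)) else selection
  if (length(sel) < 3) stop("superposition needs at least 3 atoms")
  X <- coords[sel, , drop = FALSE]
  Y <- reference[sel, , drop = FALSE]
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  # degenerate (collinear) selections have rank-deficient covariance
  if (qr(Xc)$rank < 2 || qr(Yc)$rank < 2)
    stop("degenerate (collinear) selection; superposition is ill-defined")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Dm <- diag(c(1, 1, d))
  R <- s$u %*% Dm %*% t(s$v)      # x %*% R maps moving onto reference frame
  t_vec <- yc - as.vector(xc %*% R)
  moved <- sweep(coords %*% R, 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((moved[sel, , drop = FALSE] - Y)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, coords = moved)
}

# superpose every frame of a trajectory onto a reference coordinate set
.fit_frames <- function(traj, reference, fit_sel) {
  nf <- n_frames(traj)
  out <- traj
  for (f in seq_len(nf)) {
    sp <- superpose(traj$coords[, , f], reference, fit_sel)
    out$coords[, , f] <- sp$coords
  }
  out
}

#' Per-atom root mean square fluctuation
#'
#' Each frame is superposed onto the time-average structure using
#' `fit_selection` (two-pass: average after aligning to frame 1, then align
#' to that average); the RMSF of atom `a` is the root mean square of its
#' displacement from its time-averaged position. Set `fit_selection = NA`
#' to skip fitting (coordinates used as-is).
#'
#' @param traj an [md_trajectory()] with at least 10 frames.
#' @param selection atoms to report (default all).
#' @param fit_selection atoms used for superposition (default: the report
#'   selection); `NA` disables fitting.
#' @return Named numeric vector of per-atom RMSF (nm).
#' @export
rmsf <- function(traj, selection = NULL, fit_selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 10) stop("RMSF needs at least 10 frames")
  sel <- if (is.null(selection)) seq_len(n_atoms(traj)) else
    atom_select(traj, selection)
  do_fit <- !(length(fit_selection) == 1 && is.na(fit_selection))
  if (do_fit) {
    fit_sel <- if (is.null(fit_selection)) sel else
      atom_select(traj, fit_selection)
    traj <- .fit_frames(traj, traj$coords[, , 1], fit_sel)
    avg <- apply(traj$coords, c(1, 2), mean)
    traj <- .fit_frames(traj, avg, fit_sel)
  }
  avg <- apply(traj$coords, c(1, 2), mean)
  out <- vapply(sel, function(a) {
    disp <- traj$coords[a, , ] - avg[a, ]
    sqrt(mean(colSums(matrix(disp, nrow = 3)^2)))
  }, 0)
  names(out) <- paste0(traj$atoms$resid[sel], ":", traj$atoms$name[sel])
  out
}

#' Difference between two RMSF profiles
#'
#' Convention: `reference - variant`, so positive values mean the reference
#' protein is more flexible at that position.
#'
#' @param rmsf_ref,rmsf_variant equal-length RMSF vectors from [rmsf()].
#' @return Numeric difference vector.
#' @export
rmsf_difference <- function(rmsf_ref, rmsf_variant) {
  stopifnot(length(rmsf_ref) == length(rmsf_variant))
  rmsf_ref - rmsf_variant
}

#' Per-frame RMSD of a residue after a global fit
#'
#' Frames are superposed onto frame 0 using `fit_selection` (default: all
#' C-alpha atoms, falling back to all atoms when none are present), then the
#' RMSD of the residue's heavy atoms relative to frame 0 is computed per
#' frame.
#'
#' @param traj an [md_trajectory()].
#' @param residue_selection atoms of the residue of interest.
#' @param fit_selection atoms for the global fit; `NA` disables fitting.
#' @return Numeric vector of per-frame RMSD (nm); element 1 (frame 0) is 0.
#' @export
residue_rmsd_series <- function(traj, residue_selection, fit_selection = NULL) {
  res_sel <- atom_select(traj, residue_selection)
  res_sel <- res_sel[traj$atoms$element[res_sel] != "H"]  # heavy atoms
  if (length(res_sel) == 0) stop("residue selection has no heavy atoms")
  do_fit <- !(length(fit_selection) == 1 && is.na(fit_selection))
  if (do_fit) {
    fit_sel <- if (is.null(fit_selection)) {
      ca <- which(traj$atoms$name == "CA")
      if (length(ca) >= 3) ca else seq_len(n_atoms(traj))
    } else atom_select(traj, fit_selection)
    traj <- .fit_frames(traj, traj$coords[, , 1], fit_sel)
  }
  ref <- traj$coords[res_sel, , 1, drop = FALSE]
  dim(ref) <- c(length(res_sel), 3)
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- traj$coords[res_sel, , f, drop = FALSE]
    dim(fr) <- c(length(res_sel), 3)
    sqrt(mean(rowSums((fr - ref)^2)))
  }, 0)
}

#' Residency time of a buried water molecule
#'
#' The residency is the time from frame 0 until the water oxygen's distance
#' to the reference atom first exceeds `cutoff_nm` continuously for longer
#' than `grace_ps` (brief flickers outside the cutoff are ignored). If the
#' water never leaves for that long, the residency equals the trajectory
#' span and is flagged as retained.
#'
#' @param traj an [md_trajectory()].
#' @param water_O,reference_atom single-atom selections.
#' @param cutoff_nm distance cutoff (default 0.35 nm).
#' @param grace_ps excursions shorter than this are ignored (default 10 ps).
#' @return List with `residency_ps`, `retained` (logical) and the distance
#'   `series` (nm).
#' @export
water_residency <- function(traj, water_O, reference_atom,
                            cutoff_nm = 0.35, grace_ps = 10) {
  o_i <- .atom1(traj, water_O, "water O")
  r_i <- .atom1(traj, reference_atom, "reference atom")
  O <- traj$coords[o_i, , ]; R <- traj$coords[r_i, , ]
  dim(O) <- dim(R) <- c(3, n_frames(traj))
  d <- sqrt(colSums((O - R)^2))
  dt <- traj$frame_interval_ps
  span <- n_frames(traj) * dt
  outside <- d > cutoff_nm
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths           # 0-based start frame of each run
  long_exit <- which(r$values & r$lengths * dt > grace_ps)
  if (length(long_exit) == 0)
    return(list(residency_ps = span, retained = TRUE, series = d))
  list(residency_ps = starts[long_exit[1]] * dt, retained = FALSE, series = d)
}

#' Fraction of time an acceptor has no hydrogen bond to any water
#'
#' Each water contributes one donor triad per hydrogen (water O as donor).
#' Returns the percentage of frames in which no water satisfies the H-bond
#' criterion towards the acceptor.
#'
#' @param traj an [md_trajectory()].
#' @param acceptor_atom single-atom selection.
#' @param water_list list of waters, each `list(O =, H = c(...))` with
#'   single-atom selections.
#' @param criteria an [hbond_criteria()].
#' @return Percentage of unsolvated frames in `[0, 100]`.
#' @export
unsolvated_fraction <- function(traj, acceptor_atom, water_list,
                                criteria = hbond_criteria()) {
  nf <- n_frames(traj)
  if (length(water_list) == 0) return(100)
  bonded_any <- rep(FALSE, nf)
  for (w in water_list) {
    for (h in w$H) {
      bonded_any <- bonded_any |
        hbond_series(traj, donor = w$O, hydrogen = h,
                     acceptor = acceptor_atom, criteria = criteria)
    }
  }
  100 * mean(!bonded_any)
}
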