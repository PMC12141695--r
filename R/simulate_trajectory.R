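#' Script for a synthetic hydrogen-bond trajectory
#'
#' Declares, frame by frame, whether each donor--hydrogen--acceptor triad
#' satisfies the geometric H-bond criterion and whether each water oxygen sits
#' within the residency cutoff of the acceptor. The generator then places
#' coordinates deterministically so the criteria evaluate exactly as scripted.
#'
#' @param n_frames number of frames; all scripted vectors must have this
#'   length.
#' @param frame_interval_ps frame spacing in picoseconds.
#' @param triads list of triad scripts, each `list(label =, bonded = logical)`.
#' @param waters list of water scripts, each
#'   `list(label =, inside = logical, bonded = logical)`; `bonded` defaults to
#'   `inside`.
#' @param jitter_nm amplitude of uniform sub-tolerance coordinate jitter
#'   (default 0; keep below 0.005 nm to preserve the scripted outcomes).
#' @param seed seed for the jitter.
#' @return A list of class `hbond_script`.
#' @export
hbond_script <- function(n_frames, frame_interval_ps = 10,
                         triads = list(), waters = list(),
                         jitter_nm = 0, seed = 1L) {
  stopifnot(n_frames >= 1, frame_interval_ps > 0, jitter_nm >= 0)
  chk <- function(v, what) {
    if (length(v) != n_frames)
      stop(sprintf("scripted %s vector must cover all %d frames contiguously",
                   what, n_frames))
    as.logical(v)
  }
  triads <- lapply(seq_along(triads), function(i) {
    tr <- triads[[i]]
    list(label = if (is.null(tr$label)) paste0("triad", i) else tr$label,
         bonded = chk(tr$bonded, "triad bonded"))
  })
  waters <- lapply(seq_along(waters), function(i) {
    w <- waters[[i]]
    inside <- chk(w$inside, "water inside")
    bonded <- if (is.null(w$bonded)) inside else chk(w$bonded, "water bonded")
    if (any(bonded & !inside))
      stop("a water cannot be H-bonded while outside the cutoff")
    list(label = if (is.null(w$label)) paste0("W", i) else w$label,
         inside = inside, bonded = bonded)
  })
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval_ps = frame_interval_ps,
                 triads = triads, waters = waters,
                 jitter_nm = jitter_nm, seed = as.integer(seed)),
            class = "hbond_script")
}

# unit vector and an arbitrary perpendicular
.perp <- function(u) {
  v <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p <- v - sum(v * u) * u
  p / sqrt(sum(p^2))
}

#' Generate a trajectory with scripted H-bond occupancy and water residency
#'
#' The acceptor (a chromophore-phenolate-like oxygen) sits at the origin.
#' For each triad, bonded frames place the donor 0.30 nm from the acceptor
#' with a hydrogen--donor--acceptor angle of 10 degrees (criterion satisfied:
#' d <= 0.35 nm, theta <= 30 deg); violated frames move the donor to 0.50 nm.
#' Waters carry an O--H1--H2 topology; "inside" frames place the O 0.30 nm
#' from the acceptor (0.50 nm outside), and "bonded" frames point H1 straight
#' at the acceptor while non-bonded inside frames rotate it to 60 degrees.
#'
#' @param script an [hbond_script()].
#' @return A list of class `hbond_sim` with elements `traj`
#'   (an [md_trajectory()]), `topology` (triad/water atom labels as used by
#'   the trajectory observables) and `script`.
#' @export
simulate_hbond_trajectory <- function(script) {
  stopifnot(inherits(script, "hbond_script"))
  nf <- script$n_frames
  ntr <- length(script$triads); nw <- length(script$waters)

  # atom table: acceptor, then (donor, hydrogen) per triad, then O/H1/H2 per water
  atoms <- data.frame(name = "OH", resid = 66L, resname = "CRO", element = "O")
  triad_names <- c("OG", "N", "ND1", "OD1", "OE1", "NE2")
  for (i in seq_len(ntr)) {
    dn <- if (i <= length(triad_names)) triad_names[i] else paste0("D", i)
    atoms <- rbind(atoms,
                   data.frame(name = dn, resid = 148L, resname = "SER",
                              element = substr(dn, 1, 1)),
                   data.frame(name = paste0("H", dn), resid = 148L,
                              resname = "SER", element = "H"))
  }
  for (i in seq_len(nw)) {
    rid <- 300L + i
    atoms <- rbind(atoms,
                   data.frame(name = "OW", resid = rid, resname = "HOH", element = "O"),
                   data.frame(name = "HW1", resid = rid, resname = "HOH", element = "H"),
                   data.frame(name = "HW2", resid = rid, resname = "HOH", element = "H"))
  }

  coords <- array(0, dim = c(nrow(atoms), 3, nf))
  theta_ok <- 10 * pi / 180; theta_bad <- 60 * pi / 180

  # triad directions fan out in the xy-plane; waters in the -z hemisphere
  for (i in seq_len(ntr)) {
    ang <- 2 * pi * (i - 1) / max(ntr, 1)
    u <- c(cos(ang), sin(ang), 0)
    p <- .perp(u)
    d_idx <- 2 * i; h_idx <- 2 * i + 1
    bonded <- script$triads[[i]]$bonded
    for (f in seq_len(nf)) {
      d <- if (bonded[f]) 0.30 else 0.50
      D <- d * u
      # H at 0.10 nm from the donor, tilted theta from the donor->acceptor axis
      H <- D + 0.10 * (cos(theta_ok) * (-u) + sin(theta_ok) * p)
      coords[d_idx, , f] <- D
      coords[h_idx, , f] <- H
    }
  }
  base <- 1 + 2 * ntr
  for (i in seq_len(nw)) {
    ang <- 2 * pi * (i - 1) / max(nw, 1)
    u <- c(cos(ang) * 0.4, sin(ang) * 0.4, -0.9)
    u <- u / sqrt(sum(u^2))
    p <- .perp(u)
    o_idx <- base + 3 * (i - 1) + 1
    w <- script$waters[[i]]
    for (f in seq_len(nf)) {
      d <- if (w$inside[f]) 0.30 else 0.50
      O <- d * u
      th <- if (w$bonded[f]) 0 else theta_bad
      H1 <- O + 0.10 * (cos(th) * (-u) + sin(th) * p)
      H2 <- O + 0.10 * (cos(2.0) * (-u) + sin(2.0) * (-p))  # always away
      coords[o_idx, , f] <- O
      coords[o_idx + 1, , f] <- H1
      coords[o_idx + 2, , f] <- H2
    }
  }

  if (script$jitter_nm > 0) {
    set.seed(script$seed)
    coords <- coords + array(runif(length(coords), -script$jitter_nm,
                                   script$jitter_nm), dim = dim(coords))
  }

  traj <- md_trajectory(coords, atoms, script$frame_interval_ps)
  topology <- list(
    acceptor = "66:OH",
    triads = lapply(seq_len(ntr), function(i) {
      dn <- atoms$name[2 * i]
      list(label = script$triads[[i]]$label,
           donor = paste0("148:", dn),
           hydrogen = paste0("148:H", dn),
           acceptor = "66:OH")
    }),
    waters = lapply(seq_len(nw), function(i) {
      rid <- 300L + i
      list(label = script$waters[[i]]$label,
           O = paste0(rid, ":OW"),
           H = c(paste0(rid, ":HW1"), paste0(rid, ":HW2")))
    })
  )
  structure(list(traj = traj, topology = topology, script = script),
            class = "hbond_sim")
}

#' Write the topology of a scripted trajectory as JSON
#' @param sim an `hbond_sim`.
#' @param path output path.
#' @export
write_topology_json <- function(sim, path) {
  jsonlite::write_json(sim$topology, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
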