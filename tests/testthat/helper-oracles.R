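# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Horn's quaternion method for optimal rigid superposition RMSD.
quaternion_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- crossprod(Xc, Yc)  # S[i,j] = sum x_i y_j
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# Exhaustive-search segmentation oracle: minimises the same objective
# (sum SSE/sigma^2 + beta per breakpoint) over all breakpoint subsets of
# size <= max_bp. Returns the optimal objective and breakpoints.
exhaustive_segmentation <- function(x, sigma, beta, max_bp = 3) {
  n <- length(x)
  sse <- function(lo, hi) {  # frames lo..hi inclusive, 1-based
    v <- x[lo:hi]
    sum((v - mean(v))^2)
  }
  obj_for <- function(bp) {  # bp: 0-based breakpoints, sorted
    starts <- c(1, bp + 1)
    ends <- c(bp, n)
    sum(vapply(seq_along(starts), function(k) sse(starts[k], ends[k]), 0)) /
      sigma^2 + beta * length(bp)
  }
  best <- list(objective = obj_for(integer(0)), breakpoints = integer(0))
  for (k in seq_len(max_bp)) {
    for (bp in asplit(utils::combn(n - 1, k), 2)) {
      o <- obj_for(as.integer(bp))
      if (o < best$objective)
        best <- list(objective = o, breakpoints = as.integer(bp))
    }
  }
  best
}

# objective of a given segmentation under the package's parametrisation
segmentation_objective <- function(x, breakpoints, sigma, beta) {
  n <- length(x)
  starts <- c(1, breakpoints + 1)
  ends <- c(breakpoints, n)
  sum(vapply(seq_along(starts), function(k) {
    v <- x[starts[k]:ends[k]]
    sum((v - mean(v))^2)
  }, 0)) / sigma^2 + beta * length(breakpoints)
}

# Apply the event-calling grouping rules to ground-truth on intervals:
# merge gaps shorter than `window` frames, then drop events shorter than
# `window`. Mirrors the rule so truth and calls are comparable.
truth_events <- function(intervals, window = 15L) {
  if (nrow(intervals) == 0) return(intervals)
  merged <- intervals[1, , drop = FALSE]
  if (nrow(intervals) > 1) {
    for (r in 2:nrow(intervals)) {
      gap <- intervals[r, "start"] - merged[nrow(merged), "end"]
      if (gap < window) merged[nrow(merged), "end"] <- intervals[r, "end"]
      else merged <- rbind(merged, intervals[r, , drop = FALSE])
    }
  }
  merged[merged[, "end"] - merged[, "start"] >= window, , drop = FALSE]
}

# A minimal hand-built trajectory: coordinates list of n_atoms x 3 matrices.
make_traj <- function(frame_list, names = NULL, dt_ps = 10) {
  na <- nrow(frame_list[[1]])
  if (is.null(names)) names <- paste0("A", seq_len(na))
  coords <- array(0, dim = c(na, 3, length(frame_list)))
  for (f in seq_along(frame_list)) coords[, , f] <- frame_list[[f]]
  md_trajectory(coords, data.frame(name = names), dt_ps)
}

# random rigid motion
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}
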