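# hand-built triad geometry: donor at distance d along x, hydrogen tilted
# theta degrees off the donor->acceptor axis, acceptor at origin
triad_frame <- function(d, theta_deg) {
  th <- theta_deg * pi / 180
  D <- c(d, 0, 0)
  H <- D + 0.1 * c(-cos(th), sin(th), 0)
  rbind(A = c(0, 0, 0), D = D, H = H)
}

test_that("H-bond criterion boundaries are inclusive", {
  frames <- list(triad_frame(0.34, 29), triad_frame(0.36, 29),
                 triad_frame(0.35, 30), triad_frame(0.34, 31))
  traj <- make_traj(frames, names = c("ACC", "DON", "HYD"))
  s <- hbond_series(traj, "DON", "HYD", "ACC")
  expect_identical(s, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("hbond series is invariant under global rigid motion", {
  set.seed(33)
  bonded <- rep(c(TRUE, FALSE), c(7, 5))
  sim <- simulate_hbond_trajectory(
    hbond_script(12, triads = list(list(bonded = bonded))))
  tri <- sim$topology$triads[[1]]
  moved <- sim$traj
  for (f in seq_len(12)) {
    R <- random_rotation()
    moved$coords[, , f] <- sim$traj$coords[, , f] %*% R +
      matrix(rnorm(3), n_atoms(sim$traj), 3, byrow = TRUE)
  }
  expect_identical(hbond_series(moved, tri$donor, tri$hydrogen, tri$acceptor),
                   bonded)
})

test_that("occupancy statistics summarise multi-triad scenarios", {
  # any-bond 60%, both bonded 5.5% of 1000 frames
  b1 <- rep(FALSE, 1000); b1[1:550] <- TRUE        # side chain
  b2 <- rep(FALSE, 1000); b2[496:600] <- TRUE      # backbone; overlap 55
  st <- occupancy_stats(list(side = b1, backbone = b2))
  expect_equal(st$pct_any_bond, 60.0)
  expect_equal(st$pct_two_bonds, 5.5)
  expect_equal(st$pct_no_bond, 40.0)
  expect_equal(unname(st$per_triad_share["backbone"]), 100 * 105 / 600)
  # degenerate cases
  st0 <- occupancy_stats(rep(FALSE, 10))
  expect_equal(st0$pct_any_bond, 0)
  expect_equal(st0$pct_no_bond, 100)
  st1 <- occupancy_stats(list(a = rep(c(TRUE, FALSE), 5),
                              b = rep(c(TRUE, FALSE), 5)))
  expect_equal(unname(st1$per_triad_share), c(100, 100))
  expect_lte(st1$pct_two_bonds, st1$pct_any_bond)
})

test_that("pair distances and histograms behave on constructed cases", {
  # two static atoms 0.27 nm apart: one left-closed bin [0.26, 0.28)
  frames <- rep(list(rbind(c(0, 0, 0), c(0.27, 0, 0))), 5)
  traj <- make_traj(frames, names = c("P", "Q"))
  pd <- pair_distance(traj, "P", "Q", bin_nm = 0.02)
  expect_equal(pd$series, rep(0.27, 5))
  occupied <- pd$histogram[pd$histogram$density > 0, ]
  expect_equal(nrow(occupied), 1)
  expect_equal(occupied$lo, 0.26)
  # coincident atoms
  frames0 <- rep(list(rbind(c(1, 1, 1), c(1, 1, 1))), 3)
  expect_equal(pair_distance(make_traj(frames0, c("P", "Q")), "P", "Q")$series,
               rep(0, 3))
  # alternating two-state distance: bimodal 50/50 and unit mass
  fr <- lapply(1:10, function(f)
    rbind(c(0, 0, 0), c(ifelse(f %% 2 == 0, 0.30, 0.50), 0, 0)))
  pd2 <- pair_distance(make_traj(fr, c("P", "Q")), "P", "Q", bin_nm = 0.02)
  dens <- pd2$histogram$density[pd2$histogram$density > 0]
  expect_equal(length(dens), 2)
  expect_equal(dens[1], dens[2])
  expect_equal(sum(pd2$histogram$density) * 0.02, 1, tolerance = 1e-12)
})

test_that("Kabsch superposition handles identity and pure rotations", {
  set.seed(44)
  X <- matrix(rnorm(30), 10, 3)
  sp <- superpose(X, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  sp2 <- superpose(X %*% Rz, X)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-12)
})

test_that("superposition RMSD matches the quaternion oracle", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    Y <- matrix(rnorm(3 * n), n, 3)
    expect_equal(superpose(X, Y)$rmsd, quaternion_rmsd(X, Y),
                 tolerance = 1e-10)
  }
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
})

test_that("RMSF closed forms hold for scripted motions", {
  # one atom oscillating +/- d along x, others fixed; no fitting
  d <- 0.05
  frames <- lapply(1:20, function(f) {
    m <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0.5))
    m[4, 1] <- 0.5 + ifelse(f %% 2 == 0, d, -d)
    m
  })
  traj <- make_traj(frames, names = c("A", "B", "C", "M"))
  r <- rmsf(traj, fit_selection = NA)
  expect_equal(unname(r), c(0, 0, 0, d), tolerance = 1e-12)
  # isotropic Gaussian jitter: RMSF ~ sigma * sqrt(3)
  set.seed(66)
  sg <- 0.02
  frames2 <- lapply(1:400, function(f)
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) + matrix(rnorm(9, 0, sg), 3, 3))
  r2 <- rmsf(make_traj(frames2, c("A", "B", "C")), fit_selection = NA)
  se <- sg * sqrt(3) / sqrt(2 * 400)     # rough SE of an RMS over 400 frames
  expect_true(all(abs(r2 - sg * sqrt(3)) < 6 * se))
})

test_that("RMSF difference profiles follow the reference-minus-variant rule", {
  a <- c(r1 = 0.10, r2 = 0.20)
  b <- c(r1 = 0.05, r2 = 0.25)
  expect_equal(unname(rmsf_difference(a, b)), c(0.05, -0.05))
})

test_that("residue RMSD series is zero at frame 0 and tracks displacement", {
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.4, 0.4, 0))
  frames <- lapply(1:12, function(f) {
    m <- base
    if (f > 6) m[4, ] <- m[4, ] + c(0.1, 0, 0)  # rigid 0.1 nm displacement
    m
  })
  traj <- make_traj(frames, names = c("CA", "CA2", "CA3", "RES"))
  s <- residue_rmsd_series(traj, "RES", fit_selection = c("CA", "CA2", "CA3"))
  expect_equal(s[1], 0, tolerance = 1e-12)
  expect_equal(s[1:6], rep(0, 6), tolerance = 1e-10)
  expect_equal(s[7:12], rep(0.1, 6), tolerance = 1e-10)
})

test_that("water residency obeys the grace rule and the retained flag", {
  dt <- 10
  mk <- function(inside) {
    sim <- simulate_hbond_trajectory(hbond_script(
      length(inside), frame_interval_ps = dt,
      waters = list(list(inside = inside))))
    list(traj = sim$traj, w = sim$topology$waters[[1]],
         acc = sim$topology$acceptor)
  }
  # never leaves: residency = span, retained
  m <- mk(rep(TRUE, 50))
  r <- water_residency(m$traj, m$w$O, m$acc)
  expect_true(r$retained)
  expect_equal(r$residency_ps, 500)
  # a single-frame excursion (10 ps, not > grace) is ignored
  inside <- rep(TRUE, 50); inside[20] <- FALSE; inside[40:50] <- FALSE
  m2 <- mk(inside)
  r2 <- water_residency(m2$traj, m2$w$O, m2$acc, grace_ps = 10)
  expect_false(r2$retained)
  expect_equal(r2$residency_ps, 390)     # exit at frame 39 (0-based)
  # with a tiny grace the blip terminates residency at frame 19
  r3 <- water_residency(m2$traj, m2$w$O, m2$acc, grace_ps = 5)
  expect_equal(r3$residency_ps, 190)
})

test_that("unsolvated fraction counts frames with no water H-bond", {
  expect_equal(unsolvated_fraction(
    simulate_hbond_trajectory(hbond_script(
      10, waters = list(list(inside = rep(TRUE, 10)))))$traj,
    "66:OH", list()), 100)
  sim <- simulate_hbond_trajectory(hbond_script(
    20, waters = list(list(inside = rep(TRUE, 20)))))
  w <- sim$topology$waters[[1]]
  expect_equal(unsolvated_fraction(sim$traj, sim$topology$acceptor,
                                   list(list(O = w$O, H = w$H))), 0)
  # scripted 5.7%-unbonded scenario
  bonded <- rep(TRUE, 1000); bonded[1:57] <- FALSE
  sim2 <- simulate_hbond_trajectory(hbond_script(
    1000, waters = list(list(inside = rep(TRUE, 1000), bonded = bonded))))
  w2 <- sim2$topology$waters[[1]]
  expect_equal(unsolvated_fraction(sim2$traj, sim2$topology$acceptor,
                                   list(list(O = w2$O, H = w2$H))), 5.7)
})

test_that("missing atoms are reported by name", {
  traj <- make_traj(list(matrix(0, 3, 3) + diag(3)), names = c("A", "B", "C"))
  expect_error(hbond_series(traj, "A", "B", "Z"), "Z")
  expect_error(atom_select(traj, "99:XX"), "99:XX")
})
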