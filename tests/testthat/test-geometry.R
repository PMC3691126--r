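test_that("superposition recovers rigid transforms and rejects degenerate sets", {
  set.seed(3)
  pts <- matrix(rnorm(30), ncol = 3)
  k <- kabsch_superpose(pts, pts)
  expect_equal(k$rmsd, 0)
  expect_equal(k$rotation, diag(3))
  rot <- rotation_matrix(c(1, 2, 3), 0.8)
  moved <- pts %*% t(rot) + matrix(c(4, -2, 7), 10, 3, byrow = TRUE)
  k2 <- kabsch_superpose(pts, moved)
  expect_lt(k2$rmsd, 1e-8)
  expect_equal(det(k2$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition matches the bio3d least-squares fit", {
  set.seed(9)
  a <- matrix(rnorm(24), ncol = 3)
  b <- a %*% t(rotation_matrix(c(0, 1, 1), 1.2)) + 2 + matrix(rnorm(24, sd = 0.3), ncol = 3)
  k <- kabsch_superpose(a, b)
  fitted_bio3d <- matrix(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b)),
                                        fixed.inds = 1:24,
                                        mobile.inds = 1:24),
                         ncol = 3, byrow = TRUE)
  expect_equal(k$fitted, fitted_bio3d, tolerance = 1e-6)
})

test_that("RMSD series is zero for static or rigidly moved frames", {
  cx <- make_two_chain_complex(4, 4)
  n <- nrow(cx$coords)
  coords <- array(NA_real_, c(3, n, 3))
  coords[1, , ] <- cx$coords
  coords[2, , ] <- cx$coords + 2          # rigid translation
  coords[3, , ] <- cx$coords %*% t(rotation_matrix(c(1, 0, 2), 0.5))
  traj <- trajectory(coords)
  ser <- rmsd_series(traj, cx$topology, "receptor")
  expect_equal(ser$values, c(0, 0, 0), tolerance = 1e-8)
})

test_that("one displaced atom gives RMSD d/sqrt(N) over the measured group", {
  cx <- make_two_chain_complex(4, 4)
  fit <- cx$topology$partitions$receptor
  mea <- cx$topology$partitions$gprotein
  n <- nrow(cx$coords)
  coords <- array(rep(cx$coords, each = 2), c(2, n, 3))
  d <- 1.7
  coords[2, mea[1], 1] <- coords[2, mea[1], 1] + d
  traj <- trajectory(coords)
  ser <- rmsd_series(traj, cx$topology, fit, mea)
  expect_equal(ser$values[2], d / sqrt(length(mea)), tolerance = 1e-10)
})

test_that("RMSF matches its closed form and a direct recomputation", {
  cx <- make_two_chain_complex(4, 4)
  fit <- cx$topology$partitions$receptor
  n <- nrow(cx$coords)
  # one gprotein atom alternates +/- d along x around its mean
  d <- 0.9
  coords <- array(rep(cx$coords, each = 4), c(4, n, 3))
  tgt <- cx$topology$partitions$gprotein[2]
  coords[, tgt, 1] <- coords[, tgt, 1] + c(d, -d, d, -d)
  traj <- trajectory(coords)
  out <- rmsf(traj, cx$topology, fit, cx$topology$partitions$gprotein)
  expect_equal(out$rmsf[2], d, tolerance = 1e-10)
  expect_equal(out$rmsf[-2], rep(0, nrow(out) - 1), tolerance = 1e-10)

  # random trajectory against a direct implementation of the definition
  set.seed(21)
  coords2 <- array(rnorm(5 * n * 3, sd = 0.1), c(5, n, 3)) +
    array(rep(cx$coords, each = 5), c(5, n, 3))
  traj2 <- trajectory(coords2)
  mine <- rmsf(traj2, cx$topology, fit, fit)$rmsf
  # direct: superpose each frame on frame 1 over fit atoms, then RMS about
  # the time mean (independent loop-based recomputation)
  fitted <- lapply(1:5, function(f) {
    k <- kabsch_superpose(coords2[1, fit, ], coords2[f, fit, ])
    sweep(coords2[f, fit, ] %*% t(k$rotation), 2, k$translation, "+")
  })
  direct <- sapply(seq_along(fit), function(i) {
    pos <- t(sapply(fitted, function(m) m[i, ]))
    mu <- colMeans(pos)
    sqrt(mean(rowSums(sweep(pos, 2, mu)^2)))
  })
  expect_equal(mine, direct, tolerance = 1e-10)
  expect_error(rmsf(make_static_trajectory(cx, 1), cx$topology, fit),
               "2 frames")
})

test_that("dihedral angles follow the standard torsion convention", {
  # planar cis -> 0, planar trans -> 180
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, 1, 0)), 0)
  expect_equal(dihedral_angle(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, -1, 0)), 180)
  for (phi in c(-150, -60, 30, 60, 100, 179)) {
    q <- ternint:::.torsion_quadruple(phi)
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), phi,
                 tolerance = 1e-6)
    # cross-check against the bio3d torsion implementation
    expect_equal(bio3d::torsion.xyz(as.vector(t(q)), atm.inc = 4), phi,
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), "coincident")
})

test_that("dihedral sign flips under mirror reflection", {
  q <- ternint:::.torsion_quadruple(72)
  m <- q; m[, 3] <- -m[, 3]
  expect_equal(dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ]), -72,
               tolerance = 1e-6)
})

test_that("rotamer classification recovers designed state fractions exactly", {
  sim <- make_dihedral_trajectory(state_fractions = c(0.5, 0.3, 0.2),
                                  n_frames = 1000, seed = 4)
  ser <- dihedral_series(sim$trajectory, sim$quadruple)
  states <- classify_rotamer_states(ser)
  expect_equal(unname(states$state_occupancies), c(0.5, 0.3, 0.2))
  expect_equal(sum(states$state_occupancies), 1)
  expect_false(any(is.na(states$states)))
  # every frame matches the designed schedule
  expect_equal(states$states, paste0("state", sim$states))
})

test_that("every angle lands in exactly one default bin", {
  ser <- ternint:::.series(0:359, seq(-179.5, 180, by = 1), "sweep")
  states <- classify_rotamer_states(ser)
  expect_false(any(is.na(states$states)))
  expect_equal(sum(states$state_occupancies), 1)
  expect_error(classify_rotamer_states(ser, c(-10, -10, 50)), "overlap")
})

test_that("centre-of-mass and atom distances agree with hand values", {
  atoms <- data.frame(serial = 1:2, name = c("X1", "X2"), element = "C",
                      res_name = c("AAA", "BBB"), res_id = 1:2,
                      chain_id = c("A", "B"))
  top <- topology(atoms, partitions = list(a = 1L, b = 2L))
  coords <- array(0, c(2, 2, 3))
  coords[, 2, 1] <- 3; coords[, 2, 2] <- 4
  traj <- trajectory(coords)
  com <- com_distance_series(traj, top, 1L, 2L, mass_weighted = FALSE)
  expect_equal(com$values, c(5, 5))
  ad <- atom_distance_series(traj, 1L, 2L)
  expect_equal(ad$values, com$values)
  expect_equal(com_distance_series(traj, top, 1L, 1L)$values, c(0, 0))
  expect_error(atom_distance_series(traj, 2L, 2L), "differ")
})

test_that("stable-window selection finds the flat stretch with earliest ties", {
  flat <- ternint:::.series(0:99, rep(1.5, 100), "flat")
  w <- select_stable_window(flat, 0.1)
  expect_equal(c(w$start, w$end), c(1, 100))
  # drift for 40 frames then flat 41..100
  v <- c(seq(5, 2, length.out = 40), rep(1, 60))
  ser <- ternint:::.series(0:99, v, "drift")
  w2 <- select_stable_window(ser, 0.05, min_length = 10)
  expect_equal(c(w2$start, w2$end), c(41, 100))
  # two equal flat windows: earliest wins
  v3 <- c(rep(0, 10), 5, rep(1, 10), 5, rep(2, 10))
  w3 <- select_stable_window(ternint:::.series(seq_along(v3) - 1, v3, "x"),
                             0.01, min_length = 5)
  expect_equal(c(w3$start, w3$end), c(1, 10))
  # nothing qualifies
  w4 <- select_stable_window(ternint:::.series(0:3, c(0, 5, 10, 15), "x"),
                             0.1, min_length = 3)
  expect_false(w4$found)
})
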