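test_that("molecular-mechanics terms match closed forms", {
  atoms <- data.frame(serial = 1:2, name = c("Q1", "Q2"), element = "C",
                      res_name = "TST", res_id = 1:2, chain_id = "A",
                      charge = c(1, -1), gb_radius = 1.7,
                      lj_rmin_half = c(1.5, 1.5), lj_epsilon = c(0, 0),
                      mass = 12)
  top <- topology(atoms)
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))
  e <- compute_mm_energy(xyz, top)
  expect_equal(e$e_coulomb, -332.0636 / 3, tolerance = 1e-12)
  expect_equal(e$e_vdw, 0)
  expect_equal(e$total, e$e_coulomb)

  # neutral pair with epsilon = 0 has zero energy
  top0 <- top; top0$atoms$charge <- 0
  expect_equal(compute_mm_energy(xyz, top0)$total, 0)

  # LJ minimum: E = -eps at r = rmin_i + rmin_j
  topl <- top; topl$atoms$charge <- 0
  topl$atoms$lj_epsilon <- c(0.2, 0.2)
  e2 <- compute_mm_energy(rbind(c(0, 0, 0), c(3.0, 0, 0)), topl)
  expect_equal(e2$e_vdw, -0.2, tolerance = 1e-12)
})

test_that("1-2/1-3 exclusions and 1-4 scaling shape the nonbonded sum", {
  atoms <- data.frame(serial = 1:4, name = paste0("C", 1:4), element = "C",
                      res_name = "TST", res_id = 1L, chain_id = "A",
                      charge = c(0.5, 0, 0, -0.5), gb_radius = 1.7,
                      lj_rmin_half = 0, lj_epsilon = 0, mass = 12)
  bonds <- data.frame(i = 1:3, j = 2:4, k = 0, r0 = 1.5)
  top <- topology(atoms, bonds)
  xyz <- cbind(c(0, 1.5, 3, 4.5), 0, 0)
  e <- compute_mm_energy(xyz, top)
  # only the 1-4 pair (1,4) survives, scaled by 1/1.2
  expect_equal(e$e_coulomb, 332.0636 * 0.5 * (-0.5) / 4.5 / 1.2,
               tolerance = 1e-12)
  expect_equal(e$e_bond, 0)  # r0 matches geometry and k = 0
})

test_that("effective Born radii match the isolated limit and a quadrature oracle", {
  # isolated atom: intrinsic radius minus the 0.09 A offset
  expect_equal(effective_born_radii(matrix(0, 1, 3), 1.5), 1.41)

  # two-atom descreening against direct numerical integration
  oracle_integral <- function(d, rho, s) {
    f <- function(u) {
      ct <- (d^2 + u^2 - s^2) / (2 * d * u)
      frac <- ifelse(ct <= -1, 1, ifelse(ct >= 1, 0, (1 - ct) / 2))
      frac / u^2
    }
    lo <- max(rho, d - s)
    stats::integrate(f, lo, d + s, rel.tol = 1e-10)$value
  }
  for (case in list(c(3.0, 1.41, 1.2), c(2.0, 1.5, 1.7),
                    c(1.2, 1.0, 1.5), c(5.0, 1.61, 0.8))) {
    expect_equal(ternint:::.hct_integral(case[1], case[2], case[3]),
                 oracle_integral(case[1], case[2], case[3]),
                 tolerance = 1e-7)
  }

  # burial by a neighbour shell strictly increases the effective radius
  shell <- sphere_lattice(30) * 4
  iso <- effective_born_radii(matrix(0, 1, 3), 1.5)
  buried <- effective_born_radii(rbind(c(0, 0, 0), shell), rep(1.5, 31))
  expect_gt(buried[1], iso)
  expect_error(effective_born_radii(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    c(1.5, 1.5)), "overlapping")
})

test_that("GB reduces to the Born equation for a single sphere", {
  for (q in c(-2, -1, 0.5, 1)) {
    for (a in c(1, 1.5, 2, 3)) {
      target <- -(332.0636 / 2) * (1 - 1 / 78.5) * q^2 / a
      got <- gb_polar_energy(matrix(0, 1, 3), q, a)
      expect_equal(got, target, tolerance = 1e-9)
    }
  }
  expect_equal(gb_polar_energy(matrix(0, 1, 3), 0, 2), 0)
  expect_error(gb_polar_energy(matrix(0, 1, 3), 1, 2, eps_in = 80,
                               eps_out = 78.5), "eps_out")
})

test_that("charged sphere fixtures hit the Born closed form", {
  s <- make_charged_sphere_system(1, 2.0)
  reff <- effective_born_radii(s$coords, s$topology$atoms$gb_radius)
  expect_equal(reff, 2.0)
  g <- gb_polar_energy(s$coords, 1, reff)
  expect_equal(g, -(332.0636 / 2) * (1 - 1 / 78.5) / 2, tolerance = 1e-9)
  # charge-sign symmetry
  g_neg <- gb_polar_energy(s$coords, -1, reff)
  expect_equal(g, g_neg)
})

test_that("Coulomb plus GB tends to the screened-Coulomb limit at 50 A", {
  xy <- rbind(c(0, 0, 0), c(50, 0, 0))
  reff <- effective_born_radii(xy, c(2.09, 2.09))
  cross <- gb_polar_energy(xy, c(1, -1), reff) -
    gb_polar_energy(matrix(0, 1, 3), 1, reff[1]) -
    gb_polar_energy(matrix(0, 1, 3), -1, reff[2])
  total <- -332.0636 / 50 + cross
  target <- -332.0636 / (78.5 * 50)
  expect_lt(abs(total - target) / abs(target), 0.01)
})

test_that("SASA matches analytic spheres, caps, and containment limits", {
  # isolated sphere
  expect_equal(shrake_rupley_sasa(matrix(0, 1, 3), 1.6, 1.4, 960),
               4 * pi * 3^2, tolerance = 1e-3)
  # two equal overlapping spheres: lost area is a spherical cap each
  d <- 1.5; r <- 1.6 + 1.4
  sas <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.6, 1.6),
                            1.4, 960)
  analytic <- 4 * pi * r^2 - 2 * pi * r * (r - d / 2)
  expect_lt(abs(sas[1] - analytic) / analytic, 0.01)
  expect_lt(abs(sas[2] - analytic) / analytic, 0.01)
  # an atom caged inside a tight shell has zero accessible surface
  cage <- sphere_lattice(60) * 2.2
  sas2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), cage),
                             rep(1.2, 61), 1.4, 240)
  expect_equal(sas2[1], 0)
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), -1), "negative")
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), 1.5, n_points = 50),
               ">= 92")
})

test_that("complex surface never exceeds the sum of its parts", {
  fx <- fixture_saltbridge(1)
  top <- fx$cx$topology
  xyz <- fx$cx$coords
  ga <- top$partitions$receptor; gb <- top$partitions$gprotein
  r <- top$atoms$gb_radius
  all_ <- sum(shrake_rupley_sasa(xyz, r, 1.4, 240))
  parts <- sum(shrake_rupley_sasa(xyz[ga, ], r[ga], 1.4, 240)) +
    sum(shrake_rupley_sasa(xyz[gb, ], r[gb], 1.4, 240))
  expect_lte(all_, parts)
})

test_that("bonded components of the binding energy are exact zeros", {
  fx <- fixture_saltbridge(3)
  dg <- binding_free_energy(fx$traj, fx$cx$topology)
  expect_identical(dg$components$d_bond, rep(0, 3))
  expect_identical(dg$components$d_angle, rep(0, 3))
  expect_identical(dg$components$d_dihedral, rep(0, 3))
})

test_that("far-separated neutral groups bind with ~zero energy", {
  cx <- make_two_chain_complex(3, 3, apart = 80)
  traj <- make_static_trajectory(cx, 2)
  dg <- binding_free_energy(traj, cx$topology)
  expect_lt(abs(dg$mean), 0.01)
})

test_that("single-frame Delta G equals an independent direct summation", {
  cx <- make_two_chain_complex(
    3, 3, interface_spec = data.frame(res_a = 2, res_b = 2, distance = 3.2),
    res_types_a = c("ALA", "LYS", "ALA"),
    res_types_b = c("ALA", "GLU", "ALA"))
  cfg <- analysis_config(sasa_points = 240)
  traj <- make_static_trajectory(cx, 1)
  dg <- binding_free_energy(traj, cx$topology, cfg)
  direct <- oracle_frame_dg(cx$coords, cx$topology, cfg)
  expect_equal(dg$dg[1], direct, tolerance = 1e-9)
})

test_that("the designed bound complex has a negative mean Delta G", {
  fx <- fixture_saltbridge(3)
  dg <- binding_free_energy(fx$traj, fx$cx$topology)
  expect_lt(dg$mean, 0)
})

test_that("binding energies are invariant under a global rigid transform", {
  fx <- fixture_saltbridge(1)
  cfg <- analysis_config(sasa_points = 240)
  dg1 <- binding_free_energy(fx$traj, fx$cx$topology, cfg,
                             window = c(1, 1))
  rot <- rotation_matrix(c(2, -1, 1), 1.1)
  moved <- fx$cx$coords %*% t(rot) + matrix(c(5, 6, -7),
                                            nrow(fx$cx$coords), 3,
                                            byrow = TRUE)
  traj2 <- make_static_trajectory(list(topology = fx$cx$topology,
                                       coords = moved), 1)
  dg2 <- binding_free_energy(traj2, fx$cx$topology, cfg, window = c(1, 1))
  # MM and GB terms are exactly invariant; the deterministic SASA lattice
  # is orientation-dependent at the sub-0.1 kcal/mol level
  for (cn in c("d_vdw", "d_coulomb", "d_gb"))
    expect_equal(dg1$components[[cn]], dg2$components[[cn]],
                 tolerance = 1e-8)
  expect_equal(dg1$components$d_sa, dg2$components$d_sa, tolerance = 0.05)
  expect_equal(dg1$mean, dg2$mean, tolerance = 0.05)
})

test_that("trend fitting is exact on constructed series and antisymmetric", {
  expect_equal(fit_energy_trend(c(0, 500, 1000), rep(2, 3))$slope, 0)
  t_ps <- seq(0, 5000, by = 500)
  v <- 3 + 0.02 * t_ps / 1000
  f <- fit_energy_trend(t_ps, v)
  expect_equal(f$slope, 0.02, tolerance = 1e-9)
  expect_equal(f$intercept, 3, tolerance = 1e-9)
  r <- fit_energy_trend(rev(t_ps), v)
  expect_equal(r$slope, -0.02, tolerance = 1e-9)
  expect_error(fit_energy_trend(c(1, 1), c(0, 1)), "constant time")
})

test_that("snapshot striding matches the requested picosecond spacing", {
  cx <- make_two_chain_complex(2, 2)
  traj <- make_static_trajectory(cx, 20, dt = 100)
  expect_equal(snapshot_frames(traj, NULL, 500), seq(1, 20, by = 5))
  expect_message(snapshot_frames(traj, NULL, 250), "using")
  expect_error(snapshot_frames(traj, NULL, -1), "stride")
})
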