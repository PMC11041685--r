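test_that("centre of mass is the mass-weighted mean and equivariant", {
  expect_equal(center_of_mass(bead_model(rbind(c(0, 0, 0), c(2, 0, 0)))),
               c(1, 0, 0))
  expect_equal(center_of_mass(bead_model(rbind(c(0, 0, 0), c(4, 0, 0)),
                                         masses = c(1, 3))),
               c(3, 0, 0))
  pts <- matrix(rnorm(30), 10, 3)
  t0 <- c(1.5, -2, 0.3)
  expect_equal(center_of_mass(bead_model(sweep(pts, 2, -t0))),
               center_of_mass(bead_model(pts)) + t0)
})

test_that("radius of gyration has its closed forms", {
  expect_equal(radius_of_gyration(bead_model(matrix(c(1, 2, 3), 1, 3))), 0)
  s <- 2.5
  tri <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  expect_equal(radius_of_gyration(bead_model(tri)), s / sqrt(3))
  rg <- vapply(1:2, function(k) {
    radius_of_gyration(bead_model(monomer_coords(build_sierpinski(k))))
  }, numeric(1))
  expect_equal(rg[2] / rg[1], 2, tolerance = 0.05)
})

# a small assembly with hand-placed dimer geometry for torsion checks:
# dimer 0 of hexamer 0 and dimer 3 of hexamer 1 are rebuilt as parallel
# two-bead dimers 3 nm apart; dimer B may be rotated rigidly by `angle`
# degrees about the com(A)-com(B) (x) axis from the cis arrangement.
dihedral_fixture <- function(angle = 0) {
  a <- build_sierpinski(1)
  set_mono <- function(a, id, pos, part) {
    i <- match(id, a$monomers$id)
    a$monomers$x[i] <- pos[1]; a$monomers$y[i] <- pos[2]
    a$monomers$z[i] <- pos[3]; a$monomers$participates[i] <- part
    a
  }
  th <- angle * pi / 180
  a <- set_mono(a, 0L, c(0, 1, 0), TRUE)
  a <- set_mono(a, 1L, c(0, -1, 0), FALSE)
  a <- set_mono(a, 6L, c(3, cos(th), sin(th)), TRUE)   # dimer 3, hexamer 1
  a <- set_mono(a, 7L, c(3, -cos(th), -sin(th)), FALSE)
  a
}

test_that("the dimer-dimer dihedral is a standard four-point torsion", {
  expect_equal(dihedral_between_dimers(0L, 3L, dihedral_fixture()), 0)

  # rotate dimer B by 60 degrees about the com-com (x) axis
  a60 <- dihedral_fixture(60)
  expect_equal(dihedral_between_dimers(0L, 3L, a60), 60, tolerance = 1e-9)
  expect_equal(abs(dihedral_between_dimers(0L, 3L, a60, absolute = FALSE)), 60,
               tolerance = 1e-9)

  # invariance under a global rigid rotation of all beads
  R <- hexfract:::rotation_matrix(c(1, 2, 0.5), 33)
  rot <- a60
  xyz <- cbind(rot$monomers$x, rot$monomers$y, rot$monomers$z) %*% t(R)
  rot$monomers$x <- xyz[, 1]; rot$monomers$y <- xyz[, 2]; rot$monomers$z <- xyz[, 3]
  expect_equal(dihedral_between_dimers(0L, 3L, rot), 60, tolerance = 1e-9)

  expect_error(dihedral_between_dimers(0L, 99L, dihedral_fixture()), "unknown")
})

test_that("rotation decomposition recovers constructed dimer rotations", {
  ref <- bead_model(monomer_coords(build_sierpinski(1)))
  expect_equal(
    rotation_between_conformations(ref, ref, 1:6, 7:12)$angle_deg, 0)

  axis <- c(0.3, -0.5, 0.81)
  axis <- axis / sqrt(sum(axis^2))
  make_target <- function(angle) {
    tgt <- ref
    R <- hexfract:::rotation_matrix(axis, angle)
    centre <- colMeans(ref$positions[7:12, ])
    tgt$positions[7:12, ] <-
      sweep(sweep(ref$positions[7:12, ], 2, centre) %*% t(R), 2, centre, "+")
    tgt
  }
  out <- rotation_between_conformations(ref, make_target(4), 1:6, 7:12)
  expect_equal(out$angle_deg, 4, tolerance = 1e-6)
  expect_equal(abs(sum(out$axis * axis)), 1, tolerance = 1e-6)

  # composing 3 then 2 degrees about the same axis gives 5
  tgt5 <- make_target(3)
  R2 <- hexfract:::rotation_matrix(axis, 2)
  centre <- colMeans(ref$positions[7:12, ])
  tgt5$positions[7:12, ] <-
    sweep(sweep(tgt5$positions[7:12, ], 2, centre) %*% t(R2), 2, centre, "+")
  expect_equal(rotation_between_conformations(ref, tgt5, 1:6, 7:12)$angle_deg,
               5, tolerance = 1e-6)

  line <- bead_model(cbind(1:6, 0, 0))
  expect_error(rotation_between_conformations(line, line, 1:6, 1:6),
               "collinear")
})

test_that("the hinged triangle only closes as the fold angle vanishes", {
  g60 <- closure_gap(60)
  expect_gt(g60, 5)            # order 10 nm at the level-1 angle
  expect_lt(g60, 30)
  thetas <- seq(60, 2, by = -2)
  gaps <- vapply(thetas, closure_gap, numeric(1))
  expect_true(all(diff(gaps) < 0))  # shrinks as the angle relaxes
  root <- closure_root()
  expect_lt(root, 60)
  expect_lt(closure_gap(root), 0.1)
  expect_error(closure_gap(0), "0, 180")
  expect_error(closure_gap(181), "0, 180")
})

test_that("the Debye profile has its closed forms and Guinier limit", {
  one <- debye_profile(bead_model(matrix(0, 1, 3)), c(0.1, 1, 5))
  expect_equal(one$intensity, c(1, 1, 1))

  d <- 3.7
  q <- seq(0.05, 2, by = 0.05)
  two <- debye_profile(bead_model(rbind(c(0, 0, 0), c(d, 0, 0))), q)
  expect_equal(two$intensity, 2 + 2 * sin(q * d) / (q * d), tolerance = 1e-12)

  bm <- bead_model(monomer_coords(build_sierpinski(1)))
  rg <- radius_of_gyration(bm)
  n <- nrow(bm$positions)
  qlow <- seq(0.005, 0.5 / rg, length.out = 20)
  I <- debye_profile(bm, qlow)$intensity
  expect_equal(I, n^2 * exp(-qlow^2 * rg^2 / 3), tolerance = 0.01)
})

test_that("Guinier fits recover Rg on exact, Debye and noisy profiles", {
  q <- seq(0.01, 0.4, by = 0.01)
  exact <- scattering_profile(q, 5 * exp(-q^2 * 16 / 3))
  gf <- guinier_fit(exact)
  expect_equal(gf$Rg, 4, tolerance = 1e-9)
  expect_equal(gf$I0, 5, tolerance = 1e-9)
  expect_named(glance(gf), c("Rg", "I0", "n_points", "q_max", "qRg_max"))

  for (a in c(lapply(0:2, build_sierpinski), list(build_compact_triangle(3)))) {
    bm <- bead_model(monomer_coords(a))
    pr <- debye_profile(bm, seq(0.005, 1, by = 0.005))
    expect_equal(guinier_fit(pr)$Rg, radius_of_gyration(bm), tolerance = 0.03)
  }

  bm <- bead_model(monomer_coords(build_sierpinski(1)))
  noisy <- simulate_saxs(bm, seq(0.005, 1, by = 0.005), noise_frac = 0.02,
                         seed = 5)
  expect_equal(guinier_fit(noisy)$Rg, radius_of_gyration(bm), tolerance = 0.1)

  rising <- scattering_profile(q, exp(q^2))
  expect_error(guinier_fit(rising), "no Guinier decay")
})

test_that("mixture Rg is the z-average and rises with concentration", {
  rgs <- vapply(0:2, function(k) {
    radius_of_gyration(bead_model(monomer_coords(build_sierpinski(k))))
  }, numeric(1))
  srg <- c("1" = 0.5, "2" = 1.1, "6" = rgs[1], "18" = rgs[2], "54" = rgs[3])

  single <- tibble::tibble(n = 18, conc = 1e-9)
  expect_equal(mixture_rg(single, srg), unname(srg["18"]))

  mix <- tibble::tibble(n = c(6, 54), conc = c(1e-9, 1e-9))
  hand <- sqrt((6^2 * rgs[1]^2 + 54^2 * rgs[3]^2) / (6^2 + 54^2))
  expect_equal(mixture_rg(mix, srg), hand)

  apps <- vapply(c(1e-8, 5e-8, 2e-7, 1e-6, 5e-6, 2e-5), function(C) {
    mixture_rg(solve_equilibrium(species_ladder(), eq_conditions(C)), srg)
  }, numeric(1))
  expect_true(all(diff(apps) > 0))

  expect_error(mixture_rg(tibble::tibble(n = 7, conc = 1), srg), "missing")
})
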