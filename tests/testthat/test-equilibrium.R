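test_that("species constants follow the interface products and couplings", {
  ld <- species_ladder(K_dim = 10, K_hex = 20, K_f1 = 30, K_f2 = 5)

  # far below the pKa with no ligand, couplings vanish
  low <- eq_conditions(1e-9, pH = 2, pKa = 8.2)
  expect_equal(species_constant(ld, 6, low), 10^3 * 20^3, tolerance = 1e-6)
  expect_equal(species_constant(ld, 18, low, log10 = TRUE),
               9 * log10(10) + 9 * log10(20) + 3 * log10(30),
               tolerance = 1e-6)
  expect_equal(species_constant(ld, 1, low), 1)

  # at the pKa with two protonatable groups each fractal interface is / 4
  at <- eq_conditions(1e-9, pH = 8.2, pKa = 8.2, n_protonatable = 2)
  expect_equal(species_constant(ld, 18, at) / species_constant(ld, 18, low),
               (1 / 4)^3, tolerance = 1e-4)
  # hexamer has no fractal interfaces: unaffected
  expect_equal(species_constant(ld, 6, at), species_constant(ld, 6, low))

  # effective beta_18 strictly decreasing in pH and in ligand
  b_ph <- vapply(seq(6, 10, by = 0.5), function(ph) {
    species_constant(ld, 18, eq_conditions(1e-9, pH = ph), log10 = TRUE)
  }, numeric(1))
  expect_true(all(diff(b_ph) < 0))
  b_l <- vapply(10^seq(-7, -2), function(L) {
    species_constant(ld, 18, eq_conditions(1e-9, ligand_conc = L),
                     log10 = TRUE)
  }, numeric(1))
  expect_true(all(diff(b_l) < 0))

  expect_error(species_constant(ld, 7, low), "unknown species")
  expect_error(species_ladder(K_f1 = 10, K_f2 = 20), "K_f2")
})

test_that("the solver conserves subunits and handles degenerate ladders", {
  # no association at all: everything is monomer
  ld0 <- species_ladder(0, 0, 0, 0)
  d0 <- solve_equilibrium(ld0, eq_conditions(1e-6))
  expect_equal(d0$subunit_fraction[d0$n == 1], 1)
  expect_equal(d0$conc[d0$n == 1], 1e-6, tolerance = 1e-9)

  # conservation at random parameter draws
  set.seed(99)
  for (i in 1:1000) {
    ld <- species_ladder(10^runif(1, 8, 15), 10^runif(1, 8, 15),
                         10^runif(1, 4, 7), 10^runif(1, 2, 4))
    cn <- eq_conditions(10^runif(1, -9, -4), pH = runif(1, 6, 10),
                        ligand_conc = 10^runif(1, -8, -2))
    d <- solve_equilibrium(ld, cn)
    expect_lt(abs(sum(d$n * d$conc) - cn$total_subunit_conc) /
                cn$total_subunit_conc, 1e-9)
    expect_equal(sum(d$subunit_fraction), 1, tolerance = 1e-9)
  }
})

test_that("stepwise equilibria agree with the overall constants", {
  # three-species ladder (monomer, dimer, hexamer): the solved
  # concentrations must satisfy each stepwise mass-action law
  ld <- species_ladder(K_dim = 1e6, K_hex = 1e5, K_f1 = 0, K_f2 = 0)
  d <- solve_equilibrium(ld, eq_conditions(1e-5))
  m <- d$conc[d$n == 1]; c2 <- d$conc[d$n == 2]; c6 <- d$conc[d$n == 6]
  expect_equal(c2 / m^2, 1e6, tolerance = 1e-6)
  # hexamer from three dimers: stepwise constant beta_6 / beta_2^3 = K_hex^3
  expect_equal(c6 / c2^3, 1e5^3, tolerance = 1e-4)
})

test_that("default calibration puts >= 80% of subunits in 18mers at 50 nM", {
  d <- solve_equilibrium(species_ladder(), eq_conditions(50e-9, pH = 7.5))
  expect_gte(d$subunit_fraction[d$n == 18], 0.8)
  # monomer and dimer negligible at MP concentrations
  expect_lt(sum(d$subunit_fraction[d$n <= 2]), 1e-4)
  # 54mers essentially absent at 50 nM but present above a micromolar
  expect_lt(d$subunit_fraction[d$n == 54], 0.01)
  d2u <- solve_equilibrium(species_ladder(), eq_conditions(2e-6, pH = 7.5))
  expect_gt(d2u$subunit_fraction[d2u$n == 54], 0.05)
})

test_that("the pH titration disassembles 18mers with a single inflection", {
  grid <- seq(7, 9.5, by = 0.1)
  tc <- titration_curve(species_ladder(), eq_conditions(50e-9), "pH", grid)
  f18 <- tc$subunit_fraction[tc$n == 18]
  expect_gt(f18[1], 0.8)
  expect_lt(f18[length(f18)], 0.05)
  expect_true(all(diff(f18) < 0))          # monotone non-increasing
  # single inflection: the decrement has one interior minimum
  slopes <- diff(f18)
  expect_equal(sum(diff(sign(diff(slopes))) != 0), 1)
})

test_that("the pH midpoint shifts one-to-one with the pKa", {
  midpoint <- function(pka) {
    grid <- seq(5, 12, by = 0.01)
    tc <- titration_curve(species_ladder(),
                          eq_conditions(50e-9, pKa = pka), "pH", grid)
    f18 <- tc$subunit_fraction[tc$n == 18]
    stats::approx(f18, grid, xout = max(f18) / 2)$y
  }
  expect_equal(midpoint(8.7) - midpoint(7.7), 1, tolerance = 0.02)
})

test_that("ligand saturation returns the population to hexamers", {
  grid <- c(0, 10^seq(-6, -1))
  tc <- titration_curve(species_ladder(), eq_conditions(50e-9), "ligand",
                        grid)
  f18 <- tc$subunit_fraction[tc$n == 18]
  f6 <- tc$subunit_fraction[tc$n == 6]
  expect_true(all(diff(f18) <= 1e-12))
  expect_gt(f6[length(f6)], 0.99)
  expect_error(titration_curve(species_ladder(), eq_conditions(1e-9),
                               "pH", numeric(0)), "non-empty")
})

test_that("larger species grow monotonically with total concentration", {
  grid <- 10^seq(-9, -4.5, by = 0.25)
  tc <- titration_curve(species_ladder(), eq_conditions(50e-9),
                        "total_conc", grid)
  f54 <- tc$subunit_fraction[tc$n == 54]
  expect_true(all(diff(f54) >= -1e-12))
})

test_that("removing the level-1 interface leaves only hexamers", {
  ld <- species_ladder(K_f1 = 0, K_f2 = 0)
  d <- solve_equilibrium(ld, eq_conditions(50e-9))
  expect_equal(d$subunit_fraction[d$n == 18], 0)
  expect_equal(d$subunit_fraction[d$n == 54], 0)
  expect_gt(d$subunit_fraction[d$n == 6], 0.999)
})

test_that("the activity index averages activity over subunit fractions", {
  hexonly <- solve_equilibrium(species_ladder(K_f1 = 0, K_f2 = 0),
                               eq_conditions(50e-9))
  expect_equal(activity_index(hexonly), 1, tolerance = 1e-4)

  all18 <- tibble::tibble(n = c(6, 18), species = c("hexamer", "18mer"),
                          conc = c(0, 1e-9),
                          subunit_fraction = c(0, 1))
  expect_equal(activity_index(all18, c("6" = 1, "18" = 0)), 0)

  # closed form f * alpha + (1 - f) against brute-force sum
  d <- solve_equilibrium(species_ladder(), eq_conditions(50e-9))
  f <- sum(d$subunit_fraction[d$n >= 18])
  alpha <- 0.5
  expect_equal(activity_index(d), f * alpha + (1 - f), tolerance = 1e-9)

  expect_error(activity_index(all18, c("6" = 1)), "missing species")
  expect_error(activity_index(all18, c("6" = 2, "18" = 0)), "0, 1")
})
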