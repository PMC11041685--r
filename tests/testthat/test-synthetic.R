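test_that("mass-event simulation is seeded and faithful to its metadata", {
  ev <- simulate_mp(c("18" = 1), n_events = 2000, seed = 9)
  expect_true(all(abs(ev$masses - 18 * 44.3) < 6 * 16))  # sd = 2% of 797.4
  expect_identical(ev$masses,
                   simulate_mp(c("18" = 1), n_events = 2000, seed = 9)$masses)
  expect_false(identical(ev$masses,
                         simulate_mp(c("18" = 1), n_events = 2000,
                                     seed = 10)$masses))

  # zero noise: quantification recovers the realized sample exactly
  ev0 <- simulate_mp(c("6" = 0.4, "18" = 0.6), n_events = 1000, seed = 1,
                     error_model = list(sd_floor_kda = 0, sd_frac = 0))
  q <- suppressWarnings(quantify_mp(ev0))
  n6 <- sum(ev0$masses == 6 * 44.3)
  n18 <- sum(ev0$masses == 18 * 44.3)
  expect_equal(q$count[match(c(6, 18), q$n)], c(n6, n18), tolerance = 1e-4)
  expect_equal(q$subunit_fraction[q$n == 6],
               6 * n6 / (6 * n6 + 18 * n18), tolerance = 1e-4)

  expect_error(simulate_mp(c("6" = 0.7, "18" = 0.7), n_events = 10, seed = 1),
               "sum to 1")
  # a solved distribution is accepted directly
  d <- solve_equilibrium(species_ladder(), eq_conditions(50e-9))
  ev2 <- simulate_mp(d, n_events = 100, seed = 1)
  expect_equal(length(ev2$masses), 100)
})

test_that("scattering simulation reduces noise by frame averaging", {
  bm <- bead_model(monomer_coords(build_sierpinski(1)))
  q <- seq(0.05, 1, by = 0.05)
  clean <- simulate_saxs(bm, q, noise_frac = 0, seed = 1)
  expect_equal(clean$intensity, debye_profile(bm, q)$intensity)

  dev1 <- vapply(1:40, function(s) {
    p <- simulate_saxs(bm, q, noise_frac = 0.02, seed = s, n_frames = 1)
    (p$intensity[1] - clean$intensity[1]) / clean$intensity[1]
  }, numeric(1))
  dev10 <- vapply(1:40, function(s) {
    p <- simulate_saxs(bm, q, noise_frac = 0.02, seed = 1000 + s,
                       n_frames = 10)
    (p$intensity[1] - clean$intensity[1]) / clean$intensity[1]
  }, numeric(1))
  expect_equal(stats::sd(dev1) / stats::sd(dev10), sqrt(10), tolerance = 0.5)

  expect_error(simulate_saxs(bm, q, noise_frac = -1), ">= 0")
  expect_error(simulate_saxs(list(distribution = tibble::tibble(n = 6, conc = 0),
                                  models = list()), q), "empty model set")
})

test_that("equilibrium -> scattering -> Guinier composes monotonically", {
  models <- c(
    list("1" = bead_model(matrix(0, 1, 3)),
         "2" = bead_model(rbind(c(-1.1, 0, 0), c(1.1, 0, 0)))),
    stats::setNames(lapply(0:2, function(k) {
      bead_model(monomer_coords(build_sierpinski(k)))
    }), c("6", "18", "54"))
  )
  rg <- vapply(c(1e-8, 1e-7, 1e-6, 1e-5), function(C) {
    d <- solve_equilibrium(species_ladder(), eq_conditions(C))
    pr <- simulate_saxs(list(distribution = d, models = models),
                        seq(0.01, 1, 0.01), noise_frac = 0.01, seed = 8,
                        n_frames = 10)
    guinier_fit(pr)$Rg
  }, numeric(1))
  expect_true(all(diff(rg) > 0))
})

test_that("image degradation is seeded, bounded and gentle on D", {
  img <- rasterize(build_sierpinski(1), 350)
  expect_identical(unclass(degrade_image(img, 0, 0, seed = 1)),
                   unclass(img))
  d1 <- degrade_image(img, blur_px = 2, speckle_prob = 0.003, seed = 6)
  expect_identical(unclass(d1),
                   unclass(degrade_image(img, 2, 0.003, seed = 6)))
  clean <- fit_dimension(box_count(img))$D
  dirty <- fit_dimension(box_count(d1))$D
  expect_equal(dirty, clean, tolerance = 0.08)
  # heavier speckle scatters dimension-2 dust across the frame and biases
  # the estimate upward
  heavy <- degrade_image(img, blur_px = 2, speckle_prob = 0.01, seed = 6)
  expect_gt(fit_dimension(box_count(heavy))$D, dirty)
  expect_error(degrade_image(img, 0, 0.05, seed = 1), "0.05")
})

test_that("every format round-trips losslessly", {
  dir <- withr::local_tempdir()

  a <- build_sierpinski(1)
  write_assembly_json(a, file.path(dir, "a.json"))
  b <- read_assembly_json(file.path(dir, "a.json"))
  expect_equal(b$monomers, a$monomers, tolerance = 1e-12)
  expect_equal(b$fractal_bonds, a$fractal_bonds)
  expect_equal(unclass(b$params), unclass(a$params))
  expect_equal(b$level, a$level)

  write_assembly_pdb(a, file.path(dir, "a.pdb"))
  bm <- read_bead_pdb(file.path(dir, "a.pdb"))
  expect_equal(bm$positions, unname(monomer_coords(a)), tolerance = 1e-3,
               ignore_attr = TRUE)

  ev <- simulate_mp(c("6" = 1), n_events = 100, seed = 1)
  write_events_csv(ev, file.path(dir, "ev.csv"))
  ev2 <- read_events_csv(file.path(dir, "ev.csv"))
  expect_equal(ev2$masses, ev$masses, tolerance = 1e-12)
  expect_equal(ev2$metadata$seed, 1)

  pr <- debye_profile(bead_model(monomer_coords(a)), seq(0.1, 1, 0.1))
  write_profile_csv(pr, file.path(dir, "p.csv"))
  pr2 <- read_profile_csv(file.path(dir, "p.csv"))
  expect_equal(pr2$intensity, pr$intensity, tolerance = 1e-12)

  img <- rasterize(a, 128)
  write_image_png(img, file.path(dir, "i.png"))
  img2 <- read_image_png(file.path(dir, "i.png"))
  expect_identical(matrix(as.logical(img2), nrow(img2)),
                   matrix(as.logical(img), nrow(img)))
})
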