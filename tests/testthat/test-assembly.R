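test_that("a hexamer is a D3-symmetric ring of three dimers", {
  hx <- build_hexamer()
  expect_equal(nrow(hx$monomers), 6)
  expect_equal(nrow(hx$dimers), 3)
  expect_equal(nrow(hx$hexamers), 1)
  expect_equal(nrow(hx$fractal_bonds), 0)
  expect_true(validate_assembly(hx))

  # all monomer centres equidistant from the centroid: Rg == ring_radius
  bm <- bead_model(monomer_coords(hx))
  expect_equal(radius_of_gyration(bm), hx$params$ring_radius, tolerance = 1e-12)

  # 120-degree rotation maps the monomer set onto itself
  rot <- transform_assembly(hx, deg = 120)
  d <- as.matrix(dist(rbind(monomer_coords(hx)[, 1:2],
                            monomer_coords(rot)[, 1:2])))[1:6, 7:12]
  expect_lt(max(apply(d, 1, min)), 1e-9)

  # corner directions of the three dimers separated by 120 degrees
  ang <- sort(atan2(hx$dimers$corner_dy, hx$dimers$corner_dx) * 180 / pi)
  expect_equal(diff(ang), c(120, 120), tolerance = 1e-9)

  expect_error(geometry_params(hexamer_width = -1), "must be > 0")
  expect_error(geometry_params(dihedral_level1 = 200), "0, 180")
})

test_that("Sierpinski levels have the 6 * 3^k stoichiometry and bond count", {
  for (k in 0:3) {
    a <- build_sierpinski(k)
    expect_equal(nrow(a$monomers), subunit_count(k))
    expect_equal(nrow(a$hexamers), 3^k)
    expect_equal(nrow(a$fractal_bonds), (3^k - 1) * 3 / 2)
    expect_true(validate_assembly(a))
  }
  expect_equal(nrow(build_sierpinski(1)$dimers), 9)
  expect_equal(subunit_count(0), 6)
  expect_equal(c(subunit_count(1), subunit_count(2), subunit_count(3)),
               c(18, 54, 162))
  expect_error(build_sierpinski(-1), ">= 0")
  expect_error(subunit_count(-2), ">= 0")
})

test_that("level 0 equals the bare hexamer and the edge doubles per level", {
  expect_equal(build_sierpinski(0)$monomers, build_hexamer()$monomers)
  w <- geometry_params()$hexamer_width
  for (k in 1:3) {
    a <- build_sierpinski(k)
    edge <- diff(range(a$hexamers$x)) + w
    expect_equal(edge, 2^k * w, tolerance = 1e-9)
  }
})

test_that("each level is three translated copies of the previous level", {
  for (k in 1:3) {
    a <- build_sierpinski(k)
    prev <- build_sierpinski(k - 1)
    n_prev <- 3^(k - 1)
    prev_xy <- cbind(prev$hexamers$x, prev$hexamers$y)
    for (copy in 0:2) {
      idx <- copy * n_prev + seq_len(n_prev)
      sub <- cbind(a$hexamers$x[idx], a$hexamers$y[idx])
      shift <- colMeans(sub) - colMeans(prev_xy)
      expect_lt(max(abs(sweep(sub, 2, shift) - prev_xy)), 1e-9)
    }
  }
})

test_that("levels >= 2 have a central void wider than a hexamer", {
  for (k in 2:3) {
    a <- build_sierpinski(k)
    centroid <- colMeans(monomer_coords(a))
    d <- sqrt(rowSums(sweep(monomer_coords(a), 2, centroid)^2))
    expect_gt(min(d), a$params$hexamer_width / 2)
  }
})

test_that("compact triangles close-pack rows of hexamers", {
  tri <- build_compact_triangle(3)
  expect_equal(nrow(tri$hexamers), 6)
  expect_equal(nrow(tri$monomers), 36)
  expect_equal(nrow(tri$fractal_bonds), 0)
  expect_equal(diff(range(tri$hexamers$x)) + 10, 30)  # 30 nm edge
  expect_equal(nrow(build_compact_triangle(1)$monomers), 6)
  expect_error(build_compact_triangle(0), ">= 1")

  # rows = 2 has the same hexamer centres as level 1, up to translation
  c2 <- build_compact_triangle(2)$hexamers
  l1 <- build_sierpinski(1)$hexamers
  a <- cbind(c2$x - mean(c2$x), c2$y - mean(c2$y))
  b <- cbind(l1$x - mean(l1$x), l1$y - mean(l1$y))
  d <- as.matrix(dist(rbind(a, b)))[1:3, 4:6]
  expect_lt(max(apply(d, 1, min)), 1e-9)
})

test_that("mass-radius scaling matches log 3 / log 2", {
  expect_equal(mass_radius_dimension(lapply(0:4, build_sierpinski)),
               log(3) / log(2), tolerance = 0.02)
  expect_equal(mass_radius_dimension(lapply(0:2, build_sierpinski)),
               log(3) / log(2), tolerance = 0.05)
  a <- build_hexamer()
  expect_error(mass_radius_dimension(list(a, a, a)), "degenerate")
  expect_error(mass_radius_dimension(list(a, a)), "at least 3")
})

test_that("the chaos game is seeded, bounded and Sierpinski-dimensional", {
  v <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  p1 <- chaos_game(5000, seed = 11, vertices = v)
  p2 <- chaos_game(5000, seed = 11, vertices = v)
  expect_identical(p1, p2)
  expect_false(identical(p1, chaos_game(5000, seed = 12, vertices = v)))

  # every point inside the convex hull (barycentric coordinates >= 0)
  M <- cbind(v[2, ] - v[1, ], v[3, ] - v[1, ])
  bary <- t(solve(M) %*% t(cbind(p1$x - v[1, 1], p1$y - v[1, 2])))
  expect_true(all(bary >= -1e-12 & rowSums(bary) <= 1 + 1e-12))

  expect_error(chaos_game(10, seed = 1, vertices = rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")

  pts <- chaos_game(200000, seed = 1)
  D <- fit_dimension(box_count(rasterize_points(pts, 1024),
                               analytic_box_sizes(1024)),
                     aggregate = "min_cover")$D
  expect_equal(D, log(3) / log(2), tolerance = 0.03)
})

test_that("Pascal parity matches the additive oracle and 3^k totals", {
  expect_identical(pascal_parity(64), pascal_parity_oracle(64))
  expect_equal(sum(pascal_parity(4)), 9)
  expect_true(all(pascal_parity(4)[4, 1:4]))  # 1 3 3 1 all odd
  for (k in 1:8) {
    expect_equal(sum(pascal_parity(2^k)), 3^k)
  }
  expect_error(pascal_parity(0), ">= 1")
})

test_that("subdivision produces 3^depth triangles that tile the corners", {
  tr <- sierpinski_subdivision(4)
  expect_equal(nrow(tr), 81)
  expect_equal(max(tr$x2), 1)  # outer corners preserved
  expect_equal(min(tr$x1), 0)
  expect_error(sierpinski_subdivision(-1), ">= 0")
})
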