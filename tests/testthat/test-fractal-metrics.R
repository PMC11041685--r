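test_that("rasterization is deterministic and respects the render style", {
  a0 <- build_hexamer()
  img <- rasterize(a0, 128, style = "ring")
  expect_identical(unclass(img), unclass(rasterize(a0, 128, style = "ring")))
  # annulus: centre pixel background, ring radius foreground
  mid <- ncol(img) %/% 2
  expect_false(img[mid, mid])
  expect_true(any(img))
  expect_lt(mean(img), 1)

  # level-1 bounding box is 2x smaller than level-2 at equal px/nm
  im1 <- rasterize(build_sierpinski(1), 350, style = "ring")
  im2 <- rasterize(build_sierpinski(2), style = "ring",
                   px_per_nm = attr(im1, "px_per_nm"))
  span <- function(im) diff(range(which(im, arr.ind = TRUE)[, 2]))
  expect_equal(span(im2) / span(im1), 2, tolerance = 0.05)

  expect_error(rasterize(a0, 32), ">= 64")
  empty <- a0
  empty$monomers <- empty$monomers[0, ]
  expect_error(rasterize(empty), "no monomers")
})

test_that("box counting tiles exactly and is monotone under refinement", {
  full <- hexfract:::new_raster_image(matrix(TRUE, 255, 255))
  bc <- box_count(full, 85, offsets = list(c(0, 0)))
  expect_equal(bc$counts$count, 9)

  one <- matrix(FALSE, 100, 100)
  one[40, 60] <- TRUE
  bc1 <- box_count(hexfract:::new_raster_image(one), c(17, 43, 85))
  expect_true(all(bc1$counts$count == 1))

  img <- rasterize(build_sierpinski(1), 350)
  ct <- box_count(img)$counts
  for (off in unique(ct$offset)) {
    sub <- ct[ct$offset == off, ]
    expect_true(all(diff(sub$count[order(sub$box_size)]) <= 0))
    expect_true(all(sub$count > 0))
  }
  expect_error(box_count(img, 400), "exceeds")
  expect_error(box_count(img, 1), ">= 2")
})

test_that("dimension fitting recovers exact power laws and degenerate cases", {
  sizes <- c(64, 32, 16, 8, 4)
  fake <- structure(list(
    counts = tibble::tibble(box_size = sizes, offset = 1L,
                            count = 1e4 * (1 / sizes)^1.5),
    dim = c(256, 256), n_foreground = 100
  ), class = "box_count_result")
  f <- suppressWarnings(fit_dimension(fake))  # lm warns on a perfect fit
  expect_equal(f$D, 1.5, tolerance = 1e-9)
  expect_equal(f$R2, 1, tolerance = 1e-9)

  const <- fake
  const$counts$count <- 7L
  expect_warning(fc <- fit_dimension(const), "degenerate")
  expect_equal(fc$D, 0)

  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  gl <- glance(f)
  expect_named(gl, c("D", "D_sd", "R2", "n_points"))
})

test_that("limit shapes bracket the estimator: plane ~ 2, line ~ 1", {
  # box sizes well below the shape size, so the scaling regime dominates
  sizes <- c(32, 24, 16, 12, 8, 6, 4)
  solid <- matrix(FALSE, 1024, 1024)
  for (r in 1:1024) solid[r, 1:r] <- TRUE  # filled right triangle
  Dsolid <- fit_dimension(box_count(hexfract:::new_raster_image(solid),
                                    sizes))$D
  expect_equal(Dsolid, 2, tolerance = 0.05)

  line <- matrix(FALSE, 1024, 1024)
  line[512, ] <- TRUE
  Dline <- fit_dimension(box_count(hexfract:::new_raster_image(line),
                                   sizes))$D
  expect_equal(Dline, 1, tolerance = 0.05)
})

test_that("deep subdivision rasters reproduce the analytic dimension", {
  img <- rasterize_triangles(sierpinski_subdivision(8), 1024, margin_frac = 0)
  D <- fit_dimension(box_count(img, analytic_box_sizes(1024)),
                     aggregate = "min_cover")$D
  expect_equal(D, log(3) / log(2), tolerance = 0.03)
})

test_that("subdivision, chaos-game and Pascal rasters agree on D", {
  width <- 1024
  sizes <- analytic_box_sizes(width)
  Ds <- fit_dimension(box_count(
    rasterize_triangles(sierpinski_subdivision(8), width, margin_frac = 0),
    sizes), aggregate = "min_cover")$D
  Dc <- fit_dimension(box_count(
    rasterize_points(chaos_game(200000, seed = 1), width), sizes),
    aggregate = "min_cover")$D
  Dp <- fit_dimension(box_count(rasterize_parity(pascal_parity(width)),
                                sizes), aggregate = "min_cover")$D
  expect_lt(max(c(Ds, Dc, Dp)) - min(c(Ds, Dc, Dp)), 0.05)
})

test_that("dimension estimates are invariant under translation and rotation", {
  a <- build_sierpinski(1)
  base <- fit_dimension(box_count(rasterize(a, 350)))$D

  rot <- transform_assembly(a, deg = 120)
  Drot <- fit_dimension(box_count(rasterize(rot, 350)))$D
  expect_equal(Drot, base, tolerance = 0.02)

  # translation by whole boxes: pad the image by one box on each side
  img <- rasterize(a, 350)
  pad <- matrix(FALSE, nrow(img) + 170, ncol(img) + 170)
  pad[85 + seq_len(nrow(img)), 85 + seq_len(ncol(img))] <- img
  Dpad <- fit_dimension(box_count(hexfract:::new_raster_image(pad)))$D
  expect_equal(Dpad, base, tolerance = 0.02)
})

test_that("silhouette dimensions fall between the limit shapes", {
  D1 <- fit_dimension(box_count(rasterize(build_sierpinski(1), 350)))$D
  expect_gt(D1, 1)
  expect_lt(D1, 2)
})
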