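# Rasterization of assemblies and reference fractal sets into binary
# silhouette images (class-average-like), plus PNG/TIFF round-trip I/O.

new_raster_image <- function(mat, px_per_nm = NA_real_, style = NA_character_) {
  structure(mat, px_per_nm = px_per_nm, render_style = style,
            class = c("raster_image", "matrix", "array"))
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, %.1f%% foreground, %s px/nm, style %s\n",
              nrow(x), ncol(x), 100 * mean(x),
              format(attr(x, "px_per_nm"), digits = 4),
              attr(x, "render_style")))
  invisible(x)
}

#' Rasterize an assembly into a binary silhouette
#'
#' Renders an assembly into a square binary image emulating a negative-stain
#' class average: either every monomer as a filled disc (`style = "disc"`)
#' or every hexamer as an annulus with an open centre (`style = "ring"`,
#' matching the ring-shaped hexamer densities). The content is scaled to
#' span the image width minus the margin, and the rendering is
#' deterministic.
#'
#' @param assembly An `assembly` with at least one monomer.
#' @param target_width_px Image width/height in pixels (>= 64).
#' @param style `"ring"` or `"disc"`.
#' @param blob_radius_nm Disc radius (disc style; defaults to the monomer
#'   radius) or annulus half-thickness (ring style; defaults to half the
#'   monomer radius -- the annulus stands in for the thresholded contour of
#'   the monomer-ring density, and the exact threshold applied to the real
#'   class averages is unpublished, so this is the calibrated emulation
#'   parameter).
#' @param margin_frac Fraction of the image width left as margin on each
#'   side (default 0.05).
#' @param px_per_nm Optional fixed scale; when given, the image is sized to
#'   fit the content at that scale (plus margins) and `target_width_px` is
#'   ignored.
#' @return A `raster_image` (logical matrix, row-major, origin top-left)
#'   with attributes `px_per_nm` and `render_style`.
#' @examples
#' img <- rasterize(build_sierpinski(1), 350, style = "ring")
#' @export
rasterize <- function(assembly, target_width_px = 350,
                      style = c("ring", "disc"),
                      blob_radius_nm = NULL, margin_frac = 0.05,
                      px_per_nm = NULL) {
  stopifnot(inherits(assembly, "assembly"))
  style <- match.arg(style)
  if (nrow(assembly$monomers) == 0) stop_param("assembly has no monomers")
  check_scalar_number(target_width_px, "target_width_px", integerish = TRUE)
  if (is.null(px_per_nm) && target_width_px < 64) {
    stop_param("target_width_px must be >= 64")
  }
  if (is.null(blob_radius_nm)) {
    blob_radius_nm <- assembly$params$monomer_radius / ifelse(style == "ring", 2, 1)
  }
  check_scalar_number(blob_radius_nm, "blob_radius_nm", positive = TRUE)

  if (style == "disc") {
    cx <- assembly$monomers$x; cy <- assembly$monomers$y
    rin <- rep(0, length(cx)); rout <- rep(blob_radius_nm, length(cx))
  } else {
    cx <- assembly$hexamers$x; cy <- assembly$hexamers$y
    rr <- assembly$params$ring_radius
    rin <- rep(max(rr - blob_radius_nm, 0), length(cx))
    rout <- rep(rr + blob_radius_nm, length(cx))
  }

  xmin <- min(cx - rout); xmax <- max(cx + rout)
  ymin <- min(cy - rout); ymax <- max(cy + rout)
  extent <- max(xmax - xmin, ymax - ymin)
  if (is.null(px_per_nm)) {
    width <- as.integer(target_width_px)
    px_per_nm <- width * (1 - 2 * margin_frac) / extent
  } else {
    check_scalar_number(px_per_nm, "px_per_nm", positive = TRUE)
    width <- as.integer(ceiling(extent * px_per_nm / (1 - 2 * margin_frac)))
  }

  # pixel-centre coordinates; (row 1, col 1) is top-left
  x0 <- (xmin + xmax) / 2 - width / 2 / px_per_nm
  y0 <- (ymin + ymax) / 2 + width / 2 / px_per_nm
  px_x <- x0 + (seq_len(width) - 0.5) / px_per_nm
  px_y <- y0 - (seq_len(width) - 0.5) / px_per_nm

  mat <- matrix(FALSE, width, width)
  for (i in seq_along(cx)) {
    cols <- which(abs(px_x - cx[i]) <= rout[i])
    rows <- which(abs(px_y - cy[i]) <= rout[i])
    if (!length(cols) || !length(rows)) next
    d2 <- outer((px_y[rows] - cy[i])^2, (px_x[cols] - cx[i])^2, "+")
    hit <- d2 <= rout[i]^2 & d2 >= rin[i]^2
    mat[rows, cols] <- mat[rows, cols] | hit
  }
  new_raster_image(mat, px_per_nm, style)
}

#' Rasterize a 2D point set
#'
#' Marks the pixel containing each point; used for chaos-game sets.
#'
#' @param points A data frame or matrix with columns/first two columns x, y.
#' @param width_px Image width (square image).
#' @param margin_frac Margin fraction per side.
#' @return A `raster_image`.
#' @export
rasterize_points <- function(points, width_px = 1024, margin_frac = 0.02) {
  pts <- as.matrix(points[, 1:2])
  if (nrow(pts) < 1) stop_param("no points to rasterize")
  check_scalar_number(width_px, "width_px", integerish = TRUE, positive = TRUE)
  width <- as.integer(width_px)
  ext <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  scale <- width * (1 - 2 * margin_frac) / ext
  cx <- (min(pts[, 1]) + max(pts[, 1])) / 2
  cy <- (min(pts[, 2]) + max(pts[, 2])) / 2
  col <- pmin(pmax(floor((pts[, 1] - cx) * scale + width / 2), 0), width - 1L)
  row <- pmin(pmax(floor((cy - pts[, 2]) * scale + width / 2), 0), width - 1L)
  mat <- matrix(FALSE, width, width)
  mat[unique(as.integer(row) + width * as.integer(col)) + 1L] <- TRUE
  new_raster_image(mat, NA_real_, "points")
}

#' Rasterize filled triangles
#'
#' Fills every triangle of a [sierpinski_subdivision()] table into a square
#' binary image (half-plane test per triangle over its pixel bounding box).
#'
#' @param triangles Tibble with columns `x1, y1, x2, y2, x3, y3`.
#' @param width_px Image width.
#' @param margin_frac Margin fraction per side.
#' @return A `raster_image`.
#' @export
rasterize_triangles <- function(triangles, width_px = 2048,
                                margin_frac = 0.02) {
  tr <- as.matrix(triangles)
  if (nrow(tr) < 1) stop_param("no triangles to rasterize")
  width <- as.integer(width_px)
  xs <- tr[, c(1, 3, 5)]; ys <- tr[, c(2, 4, 6)]
  ext <- max(max(xs) - min(xs), max(ys) - min(ys))
  scale <- width * (1 - 2 * margin_frac) / ext
  cx <- (min(xs) + max(xs)) / 2
  cy <- (min(ys) + max(ys)) / 2
  px <- function(x) (x - cx) * scale + width / 2       # 0-based continuous col
  py <- function(y) (cy - y) * scale + width / 2       # 0-based continuous row
  mat <- matrix(FALSE, width, width)
  colx <- px(xs); rowy <- py(ys)
  for (i in seq_len(nrow(tr))) {
    c1 <- colx[i, 1]; c2 <- colx[i, 2]; c3 <- colx[i, 3]
    r1 <- rowy[i, 1]; r2 <- rowy[i, 2]; r3 <- rowy[i, 3]
    cols <- seq(max(floor(min(c1, c2, c3)), 0), min(ceiling(max(c1, c2, c3)), width - 1))
    rows <- seq(max(floor(min(r1, r2, r3)), 0), min(ceiling(max(r1, r2, r3)), width - 1))
    if (!length(cols) || !length(rows)) next
    pcx <- cols + 0.5; pcy <- rows + 0.5
    # barycentric sign tests on the pixel-centre grid
    det <- (c2 - c1) * (r3 - r1) - (c3 - c1) * (r2 - r1)
    if (abs(det) < 1e-12) next
    wx <- outer(pcy - r1, pcx - c1, function(dy, dx) ((r3 - r1) * dx - (c3 - c1) * dy) / det)
    wy <- outer(pcy - r1, pcx - c1, function(dy, dx) (-(r2 - r1) * dx + (c2 - c1) * dy) / det)
    hit <- wx >= -1e-9 & wy >= -1e-9 & (wx + wy) <= 1 + 1e-9
    mat[rows + 1L, cols + 1L] <- mat[rows + 1L, cols + 1L] | hit
  }
  new_raster_image(mat, NA_real_, "triangles")
}

#' Raster image from a Pascal-parity mask
#'
#' Interprets the lower-triangular parity mask as a binary image (one pixel
#' per cell). The cell lattice is an affine image of the triangular lattice,
#' and box-counting dimension is invariant under such maps, so this raster
#' is directly comparable to the geometric constructions.
#'
#' @param mask Logical matrix from [pascal_parity()].
#' @return A `raster_image`.
#' @export
rasterize_parity <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop_param("mask must be a logical matrix")
  }
  new_raster_image(unclass(mask), NA_real_, "parity")
}

#' Write / read a binary image as 8-bit PNG
#'
#' Foreground pixels are stored as 255, background as 0; reading thresholds
#' at 0.5. The round trip is lossless.
#'
#' @param image A `raster_image`.
#' @param path File path.
#' @return `write_image_png()` returns `path` invisibly;
#'   `read_image_png()` returns a `raster_image`.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  png::writePNG(matrix(as.numeric(image), nrow(image), ncol(image)), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  new_raster_image(m > 0.5, NA_real_, "png")
}
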