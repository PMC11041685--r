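# Reference constructions of the Sierpinski triangle, used as independent
# oracles for the dimension estimators: the stochastic chaos game, the parity
# pattern of Pascal's triangle, and exact recursive subdivision.

#' Chaos-game point set for a triangular iterated function system
#'
#' Iterates the midpoint map `p[t+1] = (p[t] + v[r]) / 2` with `r` drawn
#' uniformly from the three vertices; the invariant set is the Sierpinski
#' triangle spanned by the vertices (Hausdorff dimension log 3 / log 2).
#'
#' @param n_points Number of points returned (after burn-in).
#' @param seed Integer seed; the same seed reproduces the same point set.
#' @param vertices 3x2 numeric matrix of triangle vertices (rows). Default:
#'   unit-edge upward equilateral triangle.
#' @param burn_in Iterations discarded before recording (default 10).
#' @return A tibble with columns `x`, `y`.
#' @examples
#' pts <- chaos_game(1000, seed = 1)
#' @export
chaos_game <- function(n_points, seed,
                       vertices = rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                       burn_in = 10) {
  check_scalar_number(n_points, "n_points", integerish = TRUE)
  if (n_points < 1) stop_param("n_points must be >= 1")
  check_scalar_number(seed, "seed", integerish = TRUE)
  check_scalar_number(burn_in, "burn_in", integerish = TRUE)
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == c(3, 2))) {
    stop_geometry("vertices must be a 3x2 matrix")
  }
  area2 <- abs((vertices[2, 1] - vertices[1, 1]) * (vertices[3, 2] - vertices[1, 2]) -
               (vertices[3, 1] - vertices[1, 1]) * (vertices[2, 2] - vertices[1, 2]))
  if (area2 < 1e-12 * max(1, sum(vertices^2))) {
    stop_geometry("vertices are collinear")
  }

  n_total <- n_points + burn_in
  r <- withr::with_seed(as.integer(seed),
                        sample.int(3L, n_total, replace = TRUE))
  x <- numeric(n_total)
  y <- numeric(n_total)
  px <- mean(vertices[, 1])
  py <- mean(vertices[, 2])
  vx <- vertices[, 1]
  vy <- vertices[, 2]
  for (t in seq_len(n_total)) {
    px <- (px + vx[r[t]]) / 2
    py <- (py + vy[r[t]]) / 2
    x[t] <- px
    y[t] <- py
  }
  keep <- seq.int(burn_in + 1L, n_total)
  tibble::tibble(x = x[keep], y = y[keep])
}

#' Parity mask of Pascal's triangle
#'
#' Entry (r, c) (0-based) is `TRUE` iff the binomial coefficient
#' `choose(r, c)` is odd, computed via the bitwise identity
#' `(r AND c) == c` (Lucas' theorem mod 2), which avoids big-integer
#' arithmetic. The odd entries of the first `2^k` rows form a discrete
#' Sierpinski triangle with `3^k` filled cells.
#'
#' @param n_rows Number of rows (>= 1).
#' @return A lower-triangular logical matrix (`n_rows` x `n_rows`); entry
#'   `[r + 1, c + 1]` corresponds to `choose(r, c)`.
#' @examples
#' sum(pascal_parity(4))  # 9
#' @export
pascal_parity <- function(n_rows) {
  check_scalar_number(n_rows, "n_rows", integerish = TRUE)
  if (n_rows < 1) stop_param("n_rows must be >= 1")
  n_rows <- as.integer(n_rows)
  m <- matrix(FALSE, n_rows, n_rows)
  for (r in seq_len(n_rows) - 1L) {
    cc <- 0:r
    m[r + 1L, cc + 1L] <- bitwAnd(r, cc) == cc
  }
  m
}

#' Sierpinski triangle by recursive subdivision
#'
#' At each step every filled triangle is replaced by its three corner
#' half-scale triangles (the midpoint triangle is removed). Returns the
#' `3^depth` filled triangles at the requested depth.
#'
#' @param depth Subdivision depth (>= 0).
#' @param vertices 3x2 matrix of the outer triangle's vertices.
#' @return A tibble with one row per filled triangle and columns
#'   `x1, y1, x2, y2, x3, y3`.
#' @examples
#' nrow(sierpinski_subdivision(3))  # 27
#' @export
sierpinski_subdivision <- function(depth,
                                   vertices = rbind(c(0, 0), c(1, 0),
                                                    c(0.5, sqrt(3) / 2))) {
  check_scalar_number(depth, "depth", integerish = TRUE)
  if (depth < 0) stop_param("depth must be >= 0")
  vertices <- as.matrix(vertices)
  tri <- matrix(c(vertices[1, ], vertices[2, ], vertices[3, ]), nrow = 1)
  colnames(tri) <- c("x1", "y1", "x2", "y2", "x3", "y3")
  for (d in seq_len(depth)) {
    a <- tri[, c("x1", "y1"), drop = FALSE]
    b <- tri[, c("x2", "y2"), drop = FALSE]
    cc <- tri[, c("x3", "y3"), drop = FALSE]
    ab <- (a + b) / 2
    ac <- (a + cc) / 2
    bc <- (b + cc) / 2
    tri <- rbind(
      cbind(a, ab, ac),
      cbind(ab, b, bc),
      cbind(ac, bc, cc)
    )
    colnames(tri) <- c("x1", "y1", "x2", "y2", "x3", "y3")
  }
  tibble::as_tibble(tri)
}
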