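# Exhaustive polyhex enumeration on the triangular lattice of hexamer
# centres, and the interface-frustration scan over all connected layouts.
#
# Axial coordinates (a, b) map to the plane as a*e(0) + b*e(60) (unit
# spacing). Shapes are deduplicated up to the 12-element symmetry group of
# the lattice (rotations by 60 degrees and reflections). Because the fractal
# contact structure of a layout is only invariant under the orientation-
# preserving subgroup (corner dimers point along fixed directions), each
# free shape is scored in both of its orientation classes and the better
# one is kept.

HEX_DIRS <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 1L),
                  c(-1L, 0L), c(0L, -1L), c(1L, -1L))

# corner-dimer index (1..3 for corners at 90/210/330 degrees) serving each
# lattice direction k = 1..6 (angles 0,60,...,300)
CORNER_OF_DIR <- c(3L, 1L, 1L, 2L, 2L, 3L)

rot60 <- function(cells) cbind(-cells[, 2], cells[, 1] + cells[, 2])
reflect0 <- function(cells) cbind(cells[, 1] + cells[, 2], -cells[, 2])

canonical_polyhex <- function(cells) {
  best <- NULL
  cur <- cells
  for (refl in 0:1) {
    if (refl == 1) cur <- reflect0(cells)
    for (r in 1:6) {
      cur <- rot60(cur)
      norm <- cbind(cur[, 1] - min(cur[, 1]), cur[, 2] - min(cur[, 2]))
      norm <- norm[order(norm[, 1], norm[, 2]), , drop = FALSE]
      key <- paste(norm[, 1], norm[, 2], sep = ",", collapse = ";")
      if (is.null(best) || key < best$key) best <- list(key = key, cells = norm)
    }
  }
  best
}

# all free polyhexes with n cells, as a list of canonical cell matrices
enumerate_polyhexes <- function(n) {
  stopifnot(n >= 1)
  shapes <- list(matrix(c(0L, 0L), 1, 2))
  if (n == 1) return(shapes)
  for (size in 2:n) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    nxt <- list()
    for (s in shapes) {
      have <- paste(s[, 1], s[, 2], sep = ",")
      for (i in seq_len(nrow(s))) {
        for (k in 1:6) {
          cell <- s[i, ] + HEX_DIRS[k, ]
          ckey <- paste(cell[1], cell[2], sep = ",")
          if (ckey %in% have) next
          cand <- canonical_polyhex(rbind(s, cell))
          if (is.null(seen[[cand$key]])) {
            seen[[cand$key]] <- TRUE
            nxt[[length(nxt) + 1L]] <- cand$cells
          }
        }
      }
    }
    shapes <- nxt
  }
  shapes
}

# Maximum number of realizable bonds for a polyhex layout in a fixed
# orientation. The dimer-contact graph has degree <= 2 (each corner dimer
# serves two adjacent lattice directions), so it decomposes into paths and
# cycles: a path with E edges yields ceiling(E/2) bonds, a cycle floor(E/2).
# Junction groups (cycles of length 3 at down-triangle centres) are covered
# by the same rule: a 3-cycle yields one bond.
polyhex_max_bonds <- function(cells) {
  n <- nrow(cells)
  keys <- paste(cells[, 1], cells[, 2], sep = ",")
  idx <- seq_len(n)
  names(idx) <- keys

  # vertices: (cell i, corner c) encoded as 3*(i-1) + c; collect edges
  e1 <- integer(0); e2 <- integer(0)
  for (i in seq_len(n)) {
    for (k in 1:3) {  # directions 0, 60, 120 cover each pair once
      nb <- idx[paste(cells[i, 1] + HEX_DIRS[k, 1],
                      cells[i, 2] + HEX_DIRS[k, 2], sep = ",")]
      if (!is.na(nb)) {
        e1 <- c(e1, 3L * (i - 1L) + CORNER_OF_DIR[k])
        e2 <- c(e2, 3L * (nb - 1L) + CORNER_OF_DIR[k + 3L])
      }
    }
  }
  m <- length(e1)
  if (m == 0) return(0L)

  verts <- sort(unique(c(e1, e2)))
  vi <- match(c(e1, e2), verts)
  a <- vi[seq_len(m)]; b <- vi[m + seq_len(m)]
  nv <- length(verts)
  parent <- seq_len(nv)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (j in seq_len(m)) { ra <- find(a[j]); rb <- find(b[j]); if (ra != rb) parent[ra] <- rb }
  roots_v <- vapply(seq_len(nv), find, integer(1))
  roots_e <- roots_v[a]
  bonds <- 0L
  for (r in unique(roots_e)) {
    E <- sum(roots_e == r)
    V <- sum(roots_v == r)
    bonds <- bonds + if (E == V) E %/% 2L else (E + 1L) %/% 2L  # cycle : path
  }
  bonds
}

#' Scan all hexamer layouts for minimal interface frustration
#'
#' Enumerates every connected placement of `n` hexamers on the triangular
#' lattice of hexamer centres (free polyhexes, deduplicated up to rotation
#' and reflection), realizes the maximal bond set for each under the
#' passivation rules, and records, per `n`, the minimum number of
#' unsatisfied dimers and the layouts achieving it. Each free shape is
#' scored in both lattice orientation classes (the contact structure
#' distinguishes up- from down-pointing hexamer triangles) and the better
#' orientation counts.
#'
#' @param max_hexamers Largest layout size scanned (1..12; exhaustive
#'   enumeration grows quickly beyond 9).
#' @param params A [geometry_params()] object (hexamer width only scales
#'   the stored layouts).
#' @return A tibble with columns `n_hexamers`, `n_subunits`,
#'   `min_unsatisfied`, `n_shapes_scanned`, `n_optimal_shapes`, and a
#'   list-column `optimal_shapes` of hexamer-centre matrices (nm).
#' @examples
#' frustration_scan(3)
#' @export
frustration_scan <- function(max_hexamers, params = geometry_params()) {
  check_scalar_number(max_hexamers, "max_hexamers", integerish = TRUE)
  if (max_hexamers < 1) stop_param("max_hexamers must be >= 1")
  if (max_hexamers > 12) {
    stop_size_limit("exhaustive polyhex enumeration limited to 12 hexamers")
  }
  params <- as_geometry_params(params)
  w <- params$hexamer_width
  e0 <- c(1, 0); e60 <- c(cos(pi / 3), sin(pi / 3))

  out <- vector("list", max_hexamers)
  shapes <- list(matrix(c(0L, 0L), 1, 2))
  for (n in seq_len(max_hexamers)) {
    if (n > 1) {
      seen <- new.env(hash = TRUE, parent = emptyenv())
      nxt <- list()
      for (s in shapes) {
        have <- paste(s[, 1], s[, 2], sep = ",")
        for (i in seq_len(nrow(s))) for (k in 1:6) {
          cell <- s[i, ] + HEX_DIRS[k, ]
          if (paste(cell[1], cell[2], sep = ",") %in% have) next
          cand <- canonical_polyhex(rbind(s, cell))
          if (is.null(seen[[cand$key]])) {
            seen[[cand$key]] <- TRUE
            nxt[[length(nxt) + 1L]] <- cand$cells
          }
        }
      }
      shapes <- nxt
    }

    best <- Inf
    best_shapes <- list()
    for (s in shapes) {
      unsat <- 3L * n - 2L * max(polyhex_max_bonds(s),
                                 polyhex_max_bonds(rot60(s)))
      if (unsat < best) { best <- unsat; best_shapes <- list(s) }
      else if (unsat == best) best_shapes[[length(best_shapes) + 1L]] <- s
    }
    centres <- lapply(best_shapes, function(s) {
      xy <- cbind(s[, 1] * e0[1] + s[, 2] * e60[1],
                  s[, 1] * e0[2] + s[, 2] * e60[2]) * w
      colnames(xy) <- c("x", "y")
      xy
    })
    out[[n]] <- tibble::tibble(
      n_hexamers = n, n_subunits = 6L * n,
      min_unsatisfied = as.integer(best),
      n_shapes_scanned = length(shapes),
      n_optimal_shapes = length(best_shapes),
      optimal_shapes = list(centres)
    )
  }
  dplyr::bind_rows(out)
}
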