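# Coarse-grained assembly container and generators.
#
# An assembly is a hierarchy of tibbles: monomer beads grouped into dimers,
# dimers into hexameric rings, hexamers into fractal levels, plus the list of
# realized fractal bonds (dimer-id pairs). All generators build in the z = 0
# plane; all indices/ids are 0-based.

# Corner-dimer directions shared by every hexamer (degrees from +x).
# With a global orientation, a corner always sits 30 degrees away from any
# lattice direction (multiples of 60), so every pair of adjacent hexamers
# registers exactly one dimer-dimer contact, and three-way junction groups
# form only at the centres of down-pointing hexamer triangles.
CORNER_ANGLES <- c(90, 210, 330)

new_assembly <- function(hexamers, dimers, monomers, bonds, level, params,
                         provenance) {
  structure(
    list(
      hexamers = hexamers,
      dimers = dimers,
      monomers = monomers,
      fractal_bonds = bonds,
      level = level,
      params = params,
      provenance = provenance
    ),
    class = "assembly"
  )
}

#' @export
print.assembly <- function(x, ...) {
  lev <- if (is.numeric(x$level)) paste("level", x$level) else x$level
  cat(sprintf(
    "<assembly: %s> %d hexamers, %d dimers, %d monomers, %d fractal bonds\n",
    lev, nrow(x$hexamers), nrow(x$dimers), nrow(x$monomers),
    nrow(x$fractal_bonds)
  ))
  invisible(x)
}

# Instantiate monomer/dimer/hexamer tables from a tibble of hexamer centres.
instantiate_hexamers <- function(centers, params) {
  n_hex <- nrow(centers)
  hex_id <- rep(seq_len(n_hex) - 1L, each = 3L)
  dimer_local <- rep(0:2, n_hex)
  dimer_id <- seq_len(3L * n_hex) - 1L
  corner_deg <- CORNER_ANGLES[dimer_local + 1L]

  dimers <- tibble::tibble(
    id = dimer_id,
    monomer1 = 2L * dimer_id,
    monomer2 = 2L * dimer_id + 1L,
    hexamer_id = hex_id,
    corner_dx = cos(deg2rad(corner_deg)),
    corner_dy = sin(deg2rad(corner_deg)),
    slot = "open"
  )

  mono_dimer <- rep(dimer_id, each = 2L)
  mono_hex <- rep(hex_id, each = 2L)
  mono_angle <- rep(corner_deg, each = 2L) + c(-30, 30)
  cx <- centers$x[mono_hex + 1L]
  cy <- centers$y[mono_hex + 1L]
  monomers <- tibble::tibble(
    id = seq_along(mono_dimer) - 1L,
    dimer_id = mono_dimer,
    hexamer_id = mono_hex,
    x = cx + params$ring_radius * cos(deg2rad(mono_angle)),
    y = cy + params$ring_radius * sin(deg2rad(mono_angle)),
    z = 0,
    participates = FALSE
  )

  hexamers <- tibble::tibble(
    id = seq_len(n_hex) - 1L,
    dimer1 = 3L * (seq_len(n_hex) - 1L),
    dimer2 = 3L * (seq_len(n_hex) - 1L) + 1L,
    dimer3 = 3L * (seq_len(n_hex) - 1L) + 2L,
    x = centers$x,
    y = centers$y,
    z = 0,
    orientation = 90
  )

  list(hexamers = hexamers, dimers = dimers, monomers = monomers)
}

# The dimer of hexamer `hex` (0-based id) whose corner direction is nearest
# to angle `theta` (degrees); returns the 0-based dimer id.
facing_dimer <- function(hex, theta) {
  d <- abs(((CORNER_ANGLES - theta + 180) %% 360) - 180)
  3L * hex + (which.min(d) - 1L)
}

# Mark bonds between hexamer pairs: pick the facing corner dimer on each side
# and flag the monomer that faces the partner as the interface participant.
apply_hexamer_bonds <- function(parts, hex_pairs, centers, half_width) {
  bonds <- tibble::tibble(dimer1 = integer(), dimer2 = integer())
  if (nrow(hex_pairs) > 0) {
    d1 <- integer(nrow(hex_pairs))
    d2 <- integer(nrow(hex_pairs))
    for (i in seq_len(nrow(hex_pairs))) {
      a <- hex_pairs$hex1[i]
      b <- hex_pairs$hex2[i]
      theta <- rad2deg(atan2(centers$y[b + 1L] - centers$y[a + 1L],
                             centers$x[b + 1L] - centers$x[a + 1L]))
      d1[i] <- facing_dimer(a, theta)
      d2[i] <- facing_dimer(b, theta + 180)
      parts$dimers$slot[c(d1[i], d2[i]) + 1L] <- "bonded"
      # participating monomer: the bead of each bonded dimer closest to the
      # partner dimer's corner site ("only one monomer from each dimer
      # participates in the interaction")
      for (dd in list(c(d1[i], d2[i]), c(d2[i], d1[i]))) {
        own <- dd[1]; other <- dd[2]
        site <- dimer_corner_site(parts$dimers, other, centers, half_width)
        mids <- c(parts$dimers$monomer1[own + 1L], parts$dimers$monomer2[own + 1L])
        mx <- parts$monomers$x[mids + 1L]
        my <- parts$monomers$y[mids + 1L]
        pick <- which.min((mx - site[1])^2 + (my - site[2])^2)
        parts$monomers$participates[mids[pick] + 1L] <- TRUE
      }
    }
    bonds <- tibble::tibble(dimer1 = pmin(d1, d2), dimer2 = pmax(d1, d2))
  }
  list(parts = parts, bonds = bonds)
}

# Corner site of a dimer: hexamer centre + corner_direction * width/2.
dimer_corner_site <- function(dimers, dimer_id, centers, half_width) {
  row <- dimers[dimer_id + 1L, ]
  c(centers$x[row$hexamer_id + 1L] + row$corner_dx * half_width,
    centers$y[row$hexamer_id + 1L] + row$corner_dy * half_width)
}

#' Build a single hexamer (level-0 assembly)
#'
#' Three dimers (six monomer beads) arranged in a D3-symmetric hexameric
#' ring: monomers at 60-degree spacing on a circle of radius
#' `params$ring_radius`, dimer corner directions at 120-degree spacing.
#'
#' @param params A [geometry_params()] object.
#' @return An `assembly` with 6 monomers, 3 dimers, 1 hexamer and no
#'   fractal bonds.
#' @examples
#' hx <- build_hexamer()
#' nrow(hx$monomers)
#' @export
build_hexamer <- function(params = geometry_params()) {
  params <- as_geometry_params(params)
  build_sierpinski(0L, params)
}

# Recursive hexamer-centre layout of the Sierpinski hierarchy.
# Returns centres plus the hexamer-id bond pairs (one per copy pair).
sierpinski_centers <- function(level, width) {
  if (level == 0L) {
    return(list(centers = tibble::tibble(x = 0, y = 0),
                pairs = tibble::tibble(hex1 = integer(), hex2 = integer())))
  }
  prev <- sierpinski_centers(level - 1L, width)
  n_prev <- nrow(prev$centers)
  radius <- 2^(level - 1L) * width / sqrt(3)
  copies <- lapply(0:2, function(i) {
    off <- radius * unit2(90 + 120 * i)
    tibble::tibble(x = prev$centers$x + off[1], y = prev$centers$y + off[2])
  })
  centers <- dplyr::bind_rows(copies)
  pairs <- dplyr::bind_rows(lapply(0:2, function(i) {
    tibble::tibble(hex1 = prev$pairs$hex1 + i * n_prev,
                   hex2 = prev$pairs$hex2 + i * n_prev)
  }))
  # one new bond per copy pair: the two hexamers nearest the other copy's
  # centroid are the facing corner hexamers (distance exactly `width`)
  cent <- lapply(copies, function(cc) c(mean(cc$x), mean(cc$y)))
  for (i in 0:1) for (j in (i + 1):2) {
    ci <- copies[[i + 1L]]; cj <- copies[[j + 1L]]
    a <- which.min((ci$x - cent[[j + 1L]][1])^2 + (ci$y - cent[[j + 1L]][2])^2)
    b <- which.min((cj$x - cent[[i + 1L]][1])^2 + (cj$y - cent[[i + 1L]][2])^2)
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      hex1 = i * n_prev + a - 1L, hex2 = j * n_prev + b - 1L))
  }
  list(centers = centers, pairs = pairs)
}

#' Build a Sierpinski-order assembly
#'
#' Level k is built recursively from three level-(k-1) copies placed at the
#' corners of an upward equilateral triangle, with one fractal bond joining
#' each pair of copies through their facing corner dimers. Level 0 is the
#' bare hexamer; level 1 the 18mer; level 2 the 54mer with the central void.
#' The edge of a level-k assembly spans `2^k` hexamer widths and the subunit
#' count is `6 * 3^k` (18, 54, 162, ...).
#'
#' @param level Integer >= 0, the fractal order.
#' @param params A [geometry_params()] object.
#' @return An `assembly` with `3^level` hexamers and `(3^level - 1) * 3 / 2`
#'   fractal bonds.
#' @examples
#' a <- build_sierpinski(1)
#' nrow(a$monomers)       # 18
#' nrow(a$fractal_bonds)  # 3
#' @export
build_sierpinski <- function(level, params = geometry_params()) {
  check_scalar_number(level, "level", integerish = TRUE)
  if (level < 0) stop_param("level must be >= 0")
  level <- as.integer(level)
  params <- as_geometry_params(params)

  lay <- sierpinski_centers(level, params$hexamer_width)
  parts <- instantiate_hexamers(lay$centers, params)
  res <- apply_hexamer_bonds(parts, lay$pairs, lay$centers,
                             params$hexamer_width / 2)
  new_assembly(
    res$parts$hexamers, res$parts$dimers, res$parts$monomers, res$bonds,
    level = level, params = params,
    provenance = list(generator = "build_sierpinski",
                      args = list(level = level), seed = NA_integer_)
  )
}

#' Build a compact close-packed triangular assembly
#'
#' Hexamers close-packed into an apex-up triangle of `rows` rows
#' (`rows * (rows + 1) / 2` hexamers), the geometry of the 36mer-type
#' assemblies (rows = 3, edge 30 nm at defaults). Fractal bonds are *not*
#' assigned: use [find_candidate_contacts()] and [realize_bonds()] to decide
#' them under the passivation rules.
#'
#' @param rows Number of hexamer rows (>= 1).
#' @param params A [geometry_params()] object.
#' @return An `assembly` with no bonds assigned.
#' @examples
#' tri <- build_compact_triangle(3)
#' nrow(tri$monomers)  # 36
#' @export
build_compact_triangle <- function(rows, params = geometry_params()) {
  check_scalar_number(rows, "rows", integerish = TRUE)
  if (rows < 1) stop_param("rows must be >= 1")
  rows <- as.integer(rows)
  params <- as_geometry_params(params)
  w <- params$hexamer_width

  centers <- dplyr::bind_rows(lapply(seq_len(rows) - 1L, function(i) {
    tibble::tibble(x = (seq_len(i + 1L) - 1L - i / 2) * w,
                   y = -i * sqrt(3) / 2 * w)
  }))
  parts <- instantiate_hexamers(centers, params)
  new_assembly(
    parts$hexamers, parts$dimers, parts$monomers,
    tibble::tibble(dimer1 = integer(), dimer2 = integer()),
    level = "compact", params = params,
    provenance = list(generator = "build_compact_triangle",
                      args = list(rows = rows), seed = NA_integer_)
  )
}

#' Subunit count of a Sierpinski-order assembly
#'
#' @param level Integer >= 0.
#' @return `6 * 3^level` (6, 18, 54, 162, ...).
#' @examples
#' subunit_count(2)  # 54
#' @export
subunit_count <- function(level) {
  check_scalar_number(level, "level", integerish = TRUE)
  if (level < 0) stop_param("level must be >= 0")
  6 * 3^as.integer(level)
}

#' Validate assembly invariants
#'
#' Checks structural invariants of an assembly: two monomers per dimer,
#' three dimers per hexamer, Sierpinski stoichiometry when `level` is
#' numeric, bonds referencing existing dimers of different hexamers, no
#' dimer in two bonds, one participating monomer per bonded dimer, and no
#' monomer-sphere overlap between different hexamers beyond
#' `overlap_tolerance` (bonded interface beads interpenetrate slightly by
#' construction; the default tolerance allows that contact).
#'
#' @param assembly An `assembly`.
#' @param overlap_tolerance Maximum permitted sphere overlap (nm).
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_assembly <- function(assembly, overlap_tolerance = 1.6) {
  a <- assembly
  stopifnot(inherits(a, "assembly"))
  if (any(table(a$monomers$dimer_id) != 2)) {
    stop_geometry("each dimer must own exactly 2 monomers")
  }
  if (any(table(a$dimers$hexamer_id) != 3)) {
    stop_geometry("each hexamer must own exactly 3 dimers")
  }
  if (is.numeric(a$level)) {
    if (nrow(a$monomers) != subunit_count(a$level)) {
      stop_geometry("subunit count does not match 6 * 3^level")
    }
    if (nrow(a$hexamers) != 3^a$level) {
      stop_geometry("hexamer count does not match 3^level")
    }
  }
  b <- a$fractal_bonds
  if (nrow(b) > 0) {
    all_ids <- c(b$dimer1, b$dimer2)
    if (!all(all_ids %in% a$dimers$id)) {
      stop_geometry("bond references a non-existent dimer")
    }
    if (anyDuplicated(all_ids)) {
      stop_geometry("a dimer appears in two fractal bonds")
    }
    h1 <- a$dimers$hexamer_id[match(b$dimer1, a$dimers$id)]
    h2 <- a$dimers$hexamer_id[match(b$dimer2, a$dimers$id)]
    if (any(h1 == h2)) stop_geometry("bond joins dimers of the same hexamer")
    for (d in all_ids) {
      mids <- with(a$dimers[match(d, a$dimers$id), ], c(monomer1, monomer2))
      np <- sum(a$monomers$participates[match(mids, a$monomers$id)])
      if (np != 1) {
        stop_geometry("bonded dimer must have exactly one participating monomer")
      }
    }
  }
  # pairwise overlap between monomers of different hexamers
  m <- a$monomers
  if (nrow(m) > 1 && nrow(m) <= 2000) {
    dmat <- as.matrix(stats::dist(cbind(m$x, m$y, m$z)))
    same_hex <- outer(m$hexamer_id, m$hexamer_id, "==")
    ov <- 2 * a$params$monomer_radius - dmat
    ov[same_hex] <- -Inf
    diag(ov) <- -Inf
    if (max(ov) > overlap_tolerance) {
      stop_geometry(sprintf(
        "monomer spheres of different hexamers overlap by %.2f nm (> %.2f)",
        max(ov), overlap_tolerance))
    }
  }
  invisible(TRUE)
}

#' Monomer bead coordinates of an assembly
#'
#' @param assembly An `assembly`.
#' @return Numeric matrix (n x 3) of bead positions in nm, one row per
#'   monomer.
#' @examples
#' monomer_coords(build_hexamer())
#' @export
monomer_coords <- function(assembly) {
  cbind(assembly$monomers$x, assembly$monomers$y, assembly$monomers$z)
}
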