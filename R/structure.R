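# Rigid-body geometry: centres of mass, the dimer-dimer dihedral, rotation
# decomposition between conformations, triangle-closure gap analysis, and
# the radius of gyration.

#' Bead model
#'
#' A minimal coarse-grained model: bead positions (nm) with optional masses
#' (kDa, uniform by default).
#'
#' @param positions Numeric matrix (n x 3) or data frame with x, y, z.
#' @param masses Numeric vector of bead masses (recycled scalar allowed).
#' @return An object of class `bead_model`.
#' @examples
#' bm <- bead_model(monomer_coords(build_hexamer()))
#' @export
bead_model <- function(positions, masses = 1) {
  if (is.data.frame(positions)) {
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 1) {
    stop_param("positions must be an n x 3 matrix with n >= 1")
  }
  masses <- rep_len(masses, nrow(positions))
  if (any(masses <= 0)) stop_param("masses must be > 0")
  structure(list(positions = positions, masses = masses),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d beads, total mass %.1f\n",
              nrow(x$positions), sum(x$masses)))
  invisible(x)
}

#' Mass-weighted centre of mass
#'
#' @param model A `bead_model`.
#' @return Numeric length-3 vector (nm).
#' @examples
#' center_of_mass(bead_model(rbind(c(0, 0, 0), c(2, 0, 0))))
#' @export
center_of_mass <- function(model) {
  stopifnot(inherits(model, "bead_model"))
  if (sum(model$masses) <= 0) stop_param("zero total mass")
  colSums(model$positions * model$masses) / sum(model$masses)
}

#' Mass-weighted radius of gyration
#'
#' Root-mean-square (mass-weighted) distance of the beads from their centre
#' of mass.
#'
#' @param model A `bead_model`.
#' @return Rg in nm.
#' @examples
#' radius_of_gyration(bead_model(monomer_coords(build_hexamer())))
#' @export
radius_of_gyration <- function(model) {
  stopifnot(inherits(model, "bead_model"))
  com <- center_of_mass(model)
  d2 <- rowSums(sweep(model$positions, 2, com)^2)
  sqrt(sum(model$masses * d2) / sum(model$masses))
}

# four-point torsion, degrees in (-180, 180]
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12) stop_geometry("degenerate axis: coincident centres")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12) {
    stop_geometry("degenerate geometry: collinear points in torsion")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

#' Dihedral angle between two dimers
#'
#' The standard four-point torsion over (outer monomer of A, centre of mass
#' of A, centre of mass of B, outer monomer of B), measured about the axis
#' joining the two dimer centres of mass. The outer monomer is the
#' interface-participating bead of each dimer (set when a fractal bond is
#' formed), unless given explicitly.
#'
#' @param dimerA,dimerB Dimer ids (0-based) in `assembly`.
#' @param assembly An `assembly` with resolved monomer positions.
#' @param outerA,outerB Optional monomer ids overriding the participating
#'   beads.
#' @param absolute Report the unsigned angle (default `TRUE`); otherwise
#'   signed, right-handed about the A-to-B axis, in (-180, 180].
#' @return Angle in degrees.
#' @export
dihedral_between_dimers <- function(dimerA, dimerB, assembly,
                                    outerA = NULL, outerB = NULL,
                                    absolute = TRUE) {
  stopifnot(inherits(assembly, "assembly"))
  m <- assembly$monomers
  dim_row <- function(id) {
    r <- assembly$dimers[match(id, assembly$dimers$id), ]
    if (nrow(r) != 1 || is.na(r$id)) stop_param("unknown dimer id ", id)
    r
  }
  mono_pos <- function(id) {
    r <- m[match(id, m$id), ]
    c(r$x, r$y, r$z)
  }
  dimer_com <- function(r) (mono_pos(r$monomer1) + mono_pos(r$monomer2)) / 2
  outer_of <- function(r, override) {
    if (!is.null(override)) return(override)
    mids <- c(r$monomer1, r$monomer2)
    p <- m$participates[match(mids, m$id)]
    if (sum(p) != 1) {
      stop_param("dimer ", r$id, " has no designated outer monomer; ",
                 "pass outerA/outerB or realize its bond first")
    }
    mids[p]
  }
  ra <- dim_row(dimerA); rb <- dim_row(dimerB)
  ang <- torsion4(mono_pos(outer_of(ra, outerA)), dimer_com(ra),
                  dimer_com(rb), mono_pos(outer_of(rb, outerB)))
  if (absolute) abs(ang) else ang
}

# Kabsch optimal rotation matrix mapping `from` onto `to` (both centred)
kabsch_rotation <- function(from, to) {
  H <- t(from) %*% to
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

rotation_to_axis_angle <- function(R) {
  tr <- sum(diag(R))
  angle <- acos(pmin(pmax((tr - 1) / 2, -1), 1))
  if (angle < 1e-12) return(list(axis = c(0, 0, 1), angle_deg = 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(ax^2)) < 1e-9) {
    # angle ~ pi: axis from R + I
    M <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(M), 0))
    k <- which.max(ax)
    ax <- M[, k] / ax[k]
  }
  list(axis = ax / sqrt(sum(ax^2)), angle_deg = rad2deg(angle))
}

#' Rotation between two conformations
#'
#' Least-squares (Kabsch) superposition of `target` onto `reference` using
#' `aligned_subset`, followed by axis-angle decomposition of the residual
#' optimal rotation of `probe_subset`. This mirrors aligning a free hexamer
#' onto one dimer of an assembly and measuring how the unaligned dimers
#' have rotated.
#'
#' @param reference,target `bead_model`s with corresponding beads.
#' @param aligned_subset,probe_subset Integer row indices (1-based) of the
#'   beads used for alignment and probing; each needs >= 3 non-collinear
#'   beads.
#' @return List with `axis` (unit 3-vector) and `angle_deg`.
#' @export
rotation_between_conformations <- function(reference, target,
                                           aligned_subset, probe_subset) {
  stopifnot(inherits(reference, "bead_model"), inherits(target, "bead_model"))
  if (nrow(reference$positions) != nrow(target$positions)) {
    stop_param("reference and target must have equal bead counts")
  }
  check_subset <- function(idx, pos, nm) {
    if (length(idx) < 3) stop_geometry(nm, " needs >= 3 beads")
    p <- pos[idx, , drop = FALSE]
    if (min(svd(sweep(p, 2, colMeans(p)))$d[1:2]) < 1e-9) {
      stop_geometry(nm, " beads are collinear")
    }
  }
  check_subset(aligned_subset, reference$positions, "aligned_subset")
  check_subset(probe_subset, reference$positions, "probe_subset")

  ra <- reference$positions[aligned_subset, , drop = FALSE]
  ta <- target$positions[aligned_subset, , drop = FALSE]
  cr <- colMeans(ra); ct <- colMeans(ta)
  R1 <- kabsch_rotation(sweep(ta, 2, ct), sweep(ra, 2, cr))
  # apply global alignment to the target probe beads
  tp <- sweep(target$positions[probe_subset, , drop = FALSE], 2, ct) %*% t(R1)
  tp <- sweep(tp, 2, cr, "+")
  rp <- reference$positions[probe_subset, , drop = FALSE]
  R2 <- kabsch_rotation(sweep(tp, 2, colMeans(tp)),
                        sweep(rp, 2, colMeans(rp)))
  rotation_to_axis_angle(R2)
}

# --- triangle closure ------------------------------------------------------

# flat level-2 scaffold: three level-1 units with their inter-unit bond
# sites; returns per-unit monomer coordinates and the three bond sites
closure_scaffold <- function(params) {
  w <- params$hexamer_width
  radius <- 2 * w / sqrt(3)
  unit <- build_sierpinski(1L, params)
  units <- lapply(0:2, function(i) {
    off <- radius * unit2(90 + 120 * i)
    cbind(unit$monomers$x + off[1], unit$monomers$y + off[2], 0)
  })
  centroids <- lapply(units, colMeans)
  # bond site between units i and j: midpoint of the two facing hexamer
  # centres = midpoint of the segment joining the two nearest unit points
  hex_xy <- cbind(unit$hexamers$x, unit$hexamers$y)
  site <- function(i, j) {
    offi <- radius * unit2(90 + 120 * i); offj <- radius * unit2(90 + 120 * j)
    hi <- sweep(hex_xy, 2, -offi)  # hex centres of unit i
    hj <- sweep(hex_xy, 2, -offj)
    dd <- as.matrix(stats::dist(rbind(hi, hj)))[seq_len(3), 3 + seq_len(3)]
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    c((hi[ij[1], ] + hj[ij[2], ]) / 2, 0)
  }
  list(units = units, centroids = centroids,
       s01 = site(0, 1), s12 = site(1, 2), s02 = site(0, 2))
}

#' Triangle-closure gap of three hinged level-1 units
#'
#' Builds three rigid level-1 (18mer) units in the flat level-2 layout,
#' joins unit 1 to unit 2 and unit 2 to unit 3 at their corner interfaces
#' with a uniform out-of-plane fold (torsion about the inter-unit bond
#' axis), and returns the distance between the two corner sites that should
#' form the third interface. The gap is 0 in the plane and grows with the
#' fold angle: a triangle of units can only close when the inter-unit
#' dihedral relaxes toward planarity, which is why larger assemblies
#' require a smaller angle than the one inside an 18mer.
#'
#' @param dihedral_deg Fold angle at both hinges, degrees in (0, 180].
#' @param params A [geometry_params()] object.
#' @return Gap distance (nm).
#' @examples
#' closure_gap(60)   # order 10 nm: a 60-degree fold cannot close
#' @export
closure_gap <- function(dihedral_deg, params = geometry_params()) {
  check_scalar_number(dihedral_deg, "dihedral_deg")
  if (dihedral_deg <= 0 || dihedral_deg > 180) {
    stop_param("dihedral_deg must lie in (0, 180]")
  }
  params <- as_geometry_params(params)
  sc <- closure_scaffold(params)

  rotate_about <- function(pts, origin, axis, angle_deg) {
    R <- rotation_matrix(axis, angle_deg)
    sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, "+")
  }
  # keep unit 2 (index 1 here: bottom-left? unit order 0,1,2) -- fix unit 1
  # of the chain = units[[2]] and fold its two partners symmetrically
  axis01 <- (sc$centroids[[1]] - sc$centroids[[2]])
  axis21 <- (sc$centroids[[3]] - sc$centroids[[2]])
  s02a <- rotate_about(rbind(sc$s02), sc$s01, axis01, dihedral_deg)[1, ]
  s02c <- rotate_about(rbind(sc$s02), sc$s12, axis21, -dihedral_deg)[1, ]
  sqrt(sum((s02a - s02c)^2))
}

#' Closure root of the fold angle
#'
#' Bisection for the smallest fold angle at which the third-interface gap
#' of [closure_gap()] falls below `gap_tol`; with rigid planar units the
#' hinged triangle closes only as the fold angle approaches zero.
#'
#' @param params A [geometry_params()] object.
#' @param upper Upper bracket for the search (degrees), default the level-1
#'   dihedral.
#' @param gap_tol Closure threshold (nm).
#' @return Fold angle in degrees with `closure_gap(angle) < gap_tol`.
#' @export
closure_root <- function(params = geometry_params(), upper = NULL,
                         gap_tol = 0.1) {
  params <- as_geometry_params(params)
  if (is.null(upper)) upper <- params$dihedral_level1
  lo <- 1e-6; hi <- upper
  if (closure_gap(hi, params) < gap_tol) return(hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (closure_gap(mid, params) < gap_tol) lo <- mid else hi <- mid
  }
  lo
}
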