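#' Geometry parameters for coarse-grained assemblies
#'
#' Bundles the lengths and angles that define the coarse-grained building
#' block: a hexameric ring of three dimers (six monomer beads). All lengths
#' are in nanometres, all angles in degrees.
#'
#' The default `hexamer_width` of 10 nm is calibrated so that a three-hexamer
#' edge spans 30 nm, the printed edge length of the compact 36-subunit
#' triangle seen by negative-stain EM. The default `ring_radius` is
#' `hexamer_width / 3`: with that choice the radius of gyration of the
#' assembly doubles exactly from one fractal level to the next, so the
#' generated hierarchy is exactly self-similar (mass-radius slope
#' log 3 / log 2).
#'
#' @param hexamer_width Centre-to-centre distance of adjacent hexamers (nm).
#' @param monomer_radius Radius of a monomer bead (nm).
#' @param ring_radius Distance of monomer centres from the hexamer centre
#'   (nm). Defaults to `hexamer_width / 3` (exact level-to-level
#'   self-similarity, see Details).
#' @param dihedral_level1 Dimer-dimer dihedral at the fractal interface
#'   joining hexamers within an 18mer (degrees).
#' @param dihedral_level2 Dimer-dimer dihedral at the interface joining
#'   18mers within a 54mer (degrees).
#' @param planar Build assemblies in the z = 0 plane; out-of-plane dihedrals
#'   are applied only by the closure analysis ([closure_gap()]).
#'
#' @return An object of class `geometry_params` (a named list).
#' @examples
#' p <- geometry_params()
#' p$hexamer_width
#' @export
geometry_params <- function(hexamer_width = 10.0,
                            monomer_radius = 2.2,
                            ring_radius = hexamer_width / 3,
                            dihedral_level1 = 60,
                            dihedral_level2 = 34,
                            planar = TRUE) {
  check_scalar_number(hexamer_width, "hexamer_width", positive = TRUE)
  check_scalar_number(monomer_radius, "monomer_radius", positive = TRUE)
  check_scalar_number(ring_radius, "ring_radius", positive = TRUE)
  check_scalar_number(dihedral_level1, "dihedral_level1")
  check_scalar_number(dihedral_level2, "dihedral_level2")
  if (dihedral_level1 < 0 || dihedral_level1 > 180) {
    stop_param("dihedral_level1 must lie in [0, 180] degrees")
  }
  if (dihedral_level2 < 0 || dihedral_level2 > 180) {
    stop_param("dihedral_level2 must lie in [0, 180] degrees")
  }
  if (!is.logical(planar) || length(planar) != 1L || is.na(planar)) {
    stop_param("planar must be TRUE or FALSE")
  }
  structure(
    list(
      hexamer_width = hexamer_width,
      monomer_radius = monomer_radius,
      ring_radius = ring_radius,
      dihedral_level1 = dihedral_level1,
      dihedral_level2 = dihedral_level2,
      planar = planar
    ),
    class = "geometry_params"
  )
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("<geometry_params>\n")
  cat(sprintf("  hexamer_width:  %.3f nm\n", x$hexamer_width))
  cat(sprintf("  monomer_radius: %.3f nm\n", x$monomer_radius))
  cat(sprintf("  ring_radius:    %.3f nm\n", x$ring_radius))
  cat(sprintf("  dihedrals:      %.1f deg (level 1), %.1f deg (level 2)\n",
              x$dihedral_level1, x$dihedral_level2))
  cat(sprintf("  planar:         %s\n", x$planar))
  invisible(x)
}

as_geometry_params <- function(x) {
  if (inherits(x, "geometry_params")) return(x)
  if (is.list(x)) return(do.call(geometry_params, x))
  stop_param("cannot interpret `params` as geometry parameters")
}
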