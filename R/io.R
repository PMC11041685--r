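# File I/O: assembly JSON (the package's canonical interchange format),
# coarse-grained PDB bead models, event CSVs with JSON sidecars, and
# profile CSVs.

#' Write / read an assembly as JSON
#'
#' The canonical interchange format: monomer/dimer/hexamer tables, fractal
#' bonds, geometry parameters and provenance. The round trip reproduces
#' the assembly exactly (full double precision).
#'
#' @param assembly An `assembly`.
#' @param path Output path.
#' @return `write_assembly_json()` returns `path` invisibly;
#'   `read_assembly_json()` returns an `assembly`.
#' @export
write_assembly_json <- function(assembly, path) {
  stopifnot(inherits(assembly, "assembly"))
  payload <- list(
    format = "hexfract-assembly",
    version = 1L,
    level = assembly$level,
    params = unclass(assembly$params),
    provenance = assembly$provenance,
    hexamers = assembly$hexamers,
    dimers = assembly$dimers,
    monomers = assembly$monomers,
    fractal_bonds = assembly$fractal_bonds
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_assembly_json
#' @export
read_assembly_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "hexfract-assembly") {
    stop_param("not a hexfract assembly JSON file")
  }
  bonds <- tibble::as_tibble(p$fractal_bonds)
  if (nrow(bonds) == 0) bonds <- tibble::tibble(dimer1 = integer(),
                                                dimer2 = integer())
  prov <- p$provenance
  if (is.null(prov$seed)) prov["seed"] <- list(NA_integer_)
  new_assembly(
    hexamers = tibble::as_tibble(p$hexamers),
    dimers = tibble::as_tibble(p$dimers),
    monomers = tibble::as_tibble(p$monomers),
    bonds = bonds,
    level = p$level,
    params = do.call(geometry_params, p$params[
      c("hexamer_width", "monomer_radius", "ring_radius",
        "dihedral_level1", "dihedral_level2", "planar")]),
    provenance = prov
  )
}

#' Write a coarse-grained bead model in PDB format
#'
#' One HETATM record per monomer bead, coordinates converted from nm to
#' Angstrom, one chain per hexamer (A, B, C, ... recycled), residue number
#' = dimer id + 1.
#'
#' @param assembly An `assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_pdb <- function(assembly, path) {
  stopifnot(inherits(assembly, "assembly"))
  m <- assembly$monomers
  chain <- rep_len(LETTERS, max(m$hexamer_id) + 1L)[m$hexamer_id + 1L]
  lines <- sprintf(
    "HETATM%5d  C   BEA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    (m$id %% 99999L) + 1L, chain, (m$dimer_id %% 9999L) + 1L,
    m$x * 10, m$y * 10, m$z * 10
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a bead model from a PDB file
#'
#' Reads ATOM/HETATM coordinates (Angstrom) and returns a [bead_model()]
#' in nm.
#'
#' @param path PDB file path.
#' @param masses Bead masses (kDa), recycled.
#' @return A `bead_model`.
#' @export
read_bead_pdb <- function(path, masses = 1) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop_param("no ATOM/HETATM records in ", path)
  bead_model(cbind(at$x, at$y, at$z) / 10, masses)
}

#' Write / read mass events as CSV with a JSON metadata sidecar
#'
#' Single column `mass_kda`; the generator metadata (true fractions, error
#' model, seed) is stored next to the CSV as `<path>.json`.
#'
#' @param events An `mp_events` object.
#' @param path CSV path.
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns an `mp_events` object.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "mp_events"))
  utils::write.csv(data.frame(mass_kda = events$masses), path,
                   row.names = FALSE)
  jsonlite::write_json(events$metadata, paste0(path, ".json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  masses <- utils::read.csv(path)$mass_kda
  meta_path <- paste0(path, ".json")
  metadata <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(list(masses = masses, metadata = metadata), class = "mp_events")
}

#' Write / read a scattering profile as CSV
#'
#' Columns `q` (nm^-1) and `intensity` (plus `noise_sd` when present).
#'
#' @param profile A `scattering_profile`.
#' @param path CSV path.
#' @return `write_profile_csv()` returns `path` invisibly;
#'   `read_profile_csv()` returns a `scattering_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  scattering_profile(d$q, d$intensity,
                     noise_sd = if ("noise_sd" %in% names(d)) d$noise_sd)
}
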