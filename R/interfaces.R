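# Fractal-interface accounting: candidate dimer-dimer contacts, maximal bond
# realization under the passivation rules, and unsatisfied-dimer counts.
#
# Rules encoded here, following the observed interface geometry:
#   * a dimer can engage in at most one fractal bond (the second monomer's
#     termini face outward and passivate the edge);
#   * a junction group (>= 3 corner sites meeting at a point, as at the
#     centre of the compact 36mer) supports at most one bond -- the
#     interface cannot form a three-fold association. The rejected
#     alternative, a distinct C3 interface, can be switched on with
#     `allow_c3` for comparison.

#' Enumerate candidate fractal contacts of an assembly
#'
#' A dimer's corner site is its hexamer centre plus half a hexamer width
#' along the dimer's corner direction. Two dimers of *different* hexamers
#' whose corner sites lie within `contact_tolerance` form a candidate
#' contact. Junction groups are maximal sets of three or more dimers whose
#' corner sites cluster together (single linkage at the same tolerance).
#'
#' @param assembly An `assembly`.
#' @param contact_tolerance Maximum corner-site separation (nm); default
#'   0.15 * hexamer_width, chosen so adjacent hexamers in generated
#'   assemblies always register exactly one candidate contact.
#' @return An object of class `interface_graph`: a list with `sites`
#'   (tibble of dimer corner sites), `candidate_contacts` (tibble
#'   `dimer1`, `dimer2`, `dist`), `junction_groups` (list of integer
#'   vectors of dimer ids), `realized_bonds` (empty until
#'   [realize_bonds()]), `n_dimers`, and `contact_tolerance`.
#' @examples
#' g <- find_candidate_contacts(build_sierpinski(1))
#' nrow(g$candidate_contacts)  # 3
#' @export
find_candidate_contacts <- function(assembly,
                                    contact_tolerance = NULL) {
  stopifnot(inherits(assembly, "assembly"))
  d <- assembly$dimers
  if (is.null(d$corner_dx) || any(!is.finite(d$corner_dx))) {
    stop_geometry("assembly has no dimer corner directions")
  }
  w <- assembly$params$hexamer_width
  if (is.null(contact_tolerance)) contact_tolerance <- 0.15 * w
  check_scalar_number(contact_tolerance, "contact_tolerance", positive = TRUE)

  hx <- assembly$hexamers$x[match(d$hexamer_id, assembly$hexamers$id)]
  hy <- assembly$hexamers$y[match(d$hexamer_id, assembly$hexamers$id)]
  sites <- tibble::tibble(
    dimer_id = d$id,
    hexamer_id = d$hexamer_id,
    x = hx + d$corner_dx * w / 2,
    y = hy + d$corner_dy * w / 2
  )

  n <- nrow(sites)
  contacts <- tibble::tibble(dimer1 = integer(), dimer2 = integer(),
                             dist = numeric())
  if (n > 1) {
    dm <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
    near <- dm <= contact_tolerance
    near[outer(sites$hexamer_id, sites$hexamer_id, "==")] <- FALSE
    idx <- which(near & upper.tri(near), arr.ind = TRUE)
    if (nrow(idx) > 0) {
      contacts <- tibble::tibble(
        dimer1 = sites$dimer_id[idx[, 1]],
        dimer2 = sites$dimer_id[idx[, 2]],
        dist = dm[idx]
      )
      o <- order(pmin(contacts$dimer1, contacts$dimer2),
                 pmax(contacts$dimer1, contacts$dimer2))
      contacts <- contacts[o, ]
    }
  }

  # junction groups: connected components of the contact relation with >= 3
  # members (single-linkage clusters of corner sites)
  groups <- list()
  if (nrow(contacts) > 0) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(contacts))) {
      i <- match(contacts$dimer1[k], sites$dimer_id)
      j <- match(contacts$dimer2[k], sites$dimer_id)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      members <- sites$dimer_id[roots == r]
      if (length(members) >= 3) groups[[length(groups) + 1L]] <- sort(members)
    }
  }

  structure(
    list(
      sites = sites,
      candidate_contacts = contacts,
      junction_groups = groups,
      realized_bonds = tibble::tibble(dimer1 = integer(), dimer2 = integer()),
      n_dimers = n,
      contact_tolerance = contact_tolerance
    ),
    class = "interface_graph"
  )
}

#' @export
print.interface_graph <- function(x, ...) {
  cat(sprintf(
    "<interface_graph> %d dimers, %d candidate contacts, %d junction groups, %d realized bonds\n",
    x$n_dimers, nrow(x$candidate_contacts), length(x$junction_groups),
    nrow(x$realized_bonds)))
  invisible(x)
}

# Exact maximum "matching" on a contact list under (i) <= 1 bond per dimer
# and (ii) <= 1 bond per junction group. Works per connected component with
# depth-first branch and bound; contacts are pre-sorted lexicographically so
# the first optimum found is the lexicographic tie-break.
max_bond_set <- function(contacts, junction_of, enforce_junctions = TRUE) {
  m <- nrow(contacts)
  if (m == 0) return(integer(0))
  best <- integer(0)
  chosen <- logical(m)
  used_dimer <- new.env(hash = TRUE, parent = emptyenv())
  used_junction <- new.env(hash = TRUE, parent = emptyenv())

  dim1 <- as.character(contacts$dimer1)
  dim2 <- as.character(contacts$dimer2)
  junc <- junction_of  # character or NA per contact

  recurse <- function(i, count) {
    if (i > m) {
      if (count > length(best)) best <<- which(chosen)
      return(invisible(NULL))
    }
    if (count + (m - i + 1) <= length(best)) return(invisible(NULL))  # bound
    d1 <- dim1[i]; d2 <- dim2[i]; jg <- junc[i]
    free <- is.null(used_dimer[[d1]]) && is.null(used_dimer[[d2]]) &&
      (!enforce_junctions || is.na(jg) || is.null(used_junction[[jg]]))
    if (free) {
      used_dimer[[d1]] <- TRUE; used_dimer[[d2]] <- TRUE
      if (enforce_junctions && !is.na(jg)) used_junction[[jg]] <- TRUE
      chosen[i] <<- TRUE
      recurse(i + 1L, count + 1L)
      chosen[i] <<- FALSE
      rm(list = d1, envir = used_dimer); rm(list = d2, envir = used_dimer)
      if (enforce_junctions && !is.na(jg)) rm(list = jg, envir = used_junction)
    }
    recurse(i + 1L, count)
    invisible(NULL)
  }
  recurse(1L, 0L)
  best
}

#' Realize the maximal set of fractal bonds
#'
#' Selects a maximum-cardinality subset of the candidate contacts subject to
#' the passivation rules: each dimer participates in at most one bond and
#' each junction group hosts at most one bond. Solved exactly (branch and
#' bound per connected component); ties between optimal bond sets are broken
#' lexicographically by dimer id.
#'
#' @param graph An `interface_graph` from [find_candidate_contacts()].
#' @param allow_c3 If `TRUE`, lift the one-bond-per-junction rule (the
#'   hypothetical C3 three-way interface); default `FALSE`.
#' @param max_hexamers Size guard: error when the assembly behind the graph
#'   has more distinct hexamers than this (exact search limit).
#' @return The graph with `realized_bonds` filled in.
#' @examples
#' g <- realize_bonds(find_candidate_contacts(build_sierpinski(1)))
#' nrow(g$realized_bonds)  # 3
#' @export
realize_bonds <- function(graph, allow_c3 = FALSE, max_hexamers = 60) {
  stopifnot(inherits(graph, "interface_graph"))
  n_hex <- length(unique(graph$sites$hexamer_id))
  if (n_hex > max_hexamers) {
    stop_size_limit("exact bond realization limited to ", max_hexamers,
                    " hexamers (got ", n_hex, ")")
  }
  contacts <- graph$candidate_contacts
  if (nrow(contacts) == 0) {
    graph$realized_bonds <- tibble::tibble(dimer1 = integer(), dimer2 = integer())
    return(graph)
  }

  # junction membership per contact (a contact belongs to a junction group
  # when both dimers are members of the same group)
  junction_of <- rep(NA_character_, nrow(contacts))
  for (gi in seq_along(graph$junction_groups)) {
    members <- graph$junction_groups[[gi]]
    inside <- contacts$dimer1 %in% members & contacts$dimer2 %in% members
    junction_of[inside] <- as.character(gi)
  }

  # solve per connected component (components coupled through shared dimers
  # or shared junction groups)
  key <- ifelse(is.na(junction_of), paste0("c", seq_len(nrow(contacts))),
                paste0("j", junction_of))
  comp <- components_of_contacts(contacts, key)
  picked <- integer(0)
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp)
    sel <- max_bond_set(contacts[idx, ], junction_of[idx],
                        enforce_junctions = !allow_c3)
    picked <- c(picked, idx[sel])
  }
  rb <- contacts[sort(picked), c("dimer1", "dimer2")]
  graph$realized_bonds <- rb
  graph
}

# connected components of the contact graph: contacts are connected when
# they share a dimer or a junction key
components_of_contacts <- function(contacts, junction_key) {
  m <- nrow(contacts)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  # contacts sharing a dimer belong to one component
  dl <- c(contacts$dimer1, contacts$dimer2)
  il <- rep(seq_len(m), 2)
  for (grp in split(il, dl)) {
    if (length(grp) > 1) for (k in 2:length(grp)) link(grp[1], grp[k])
  }
  for (grp in split(seq_len(m), junction_key)) {
    if (length(grp) > 1) for (k in 2:length(grp)) link(grp[1], grp[k])
  }
  vapply(seq_len(m), find, integer(1))
}

#' Count unsatisfied fractal interfaces
#'
#' An unsatisfied dimer is one whose fractal-capable corner has no realized
#' bond. Returns `n_dimers - 2 * n_bonds`.
#'
#' @param x An `assembly` (uses its `fractal_bonds`) or an
#'   `interface_graph` with realized bonds.
#' @return Integer count of unsatisfied dimers.
#' @examples
#' count_unsatisfied(build_sierpinski(1))  # 3
#' @export
count_unsatisfied <- function(x) {
  if (inherits(x, "assembly")) {
    return(nrow(x$dimers) - 2L * nrow(x$fractal_bonds))
  }
  if (inherits(x, "interface_graph")) {
    return(x$n_dimers - 2L * nrow(x$realized_bonds))
  }
  stop_param("x must be an assembly or an interface_graph")
}
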