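# Independent oracles and small fixtures used across the suite.

# Pascal-parity oracle: iterative row addition mod 2, no binomials involved.
pascal_parity_oracle <- function(n_rows) {
  m <- matrix(FALSE, n_rows, n_rows)
  row <- 1L
  for (r in seq_len(n_rows)) {
    m[r, seq_len(r)] <- as.logical(row)
    row <- (c(row, 0L) + c(0L, row)) %% 2L
  }
  m
}

# Brute-force maximal bond set: enumerate every subset of candidate
# contacts and keep the largest one satisfying (i) <= 1 bond per dimer and
# (ii) <= 1 bond per junction group. Only usable for small graphs.
brute_force_max_bonds <- function(graph, enforce_junctions = TRUE) {
  ct <- graph$candidate_contacts
  m <- nrow(ct)
  if (m == 0) return(0L)
  stopifnot(m <= 16)
  best <- 0L
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (length(sel) <= best) next
    ids <- c(ct$dimer1[sel], ct$dimer2[sel])
    if (anyDuplicated(ids)) next
    if (enforce_junctions) {
      bad <- FALSE
      for (grp in graph$junction_groups) {
        inside <- ct$dimer1[sel] %in% grp & ct$dimer2[sel] %in% grp
        if (sum(inside) > 1) { bad <- TRUE; break }
      }
      if (bad) next
    }
    best <- length(sel)
  }
  best
}

# Rigid in-plane transformation of an assembly (rotation by `deg` about the
# origin plus translation), applied to every coordinate-bearing table.
transform_assembly <- function(a, deg = 0, dx = 0, dy = 0) {
  cs <- cos(deg * pi / 180); sn <- sin(deg * pi / 180)
  rot <- function(x, y) list(x = cs * x - sn * y, y = sn * x + cs * y)
  h <- rot(a$hexamers$x, a$hexamers$y)
  a$hexamers$x <- h$x + dx; a$hexamers$y <- h$y + dy
  m <- rot(a$monomers$x, a$monomers$y)
  a$monomers$x <- m$x + dx; a$monomers$y <- m$y + dy
  d <- rot(a$dimers$corner_dx, a$dimers$corner_dy)
  a$dimers$corner_dx <- d$x; a$dimers$corner_dy <- d$y
  a
}

# Box sizes spanning width/4 .. 8 px, log-spaced (used for the analytic
# dimension checks at matched resolution).
analytic_box_sizes <- function(width) {
  unique(round(exp(seq(log(width / 4), log(8), length.out = 12))))
}
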