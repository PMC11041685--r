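# Mass-action oligomer ladder (1, 2, 6, 18, 54 subunits) with pH and ligand
# linkage at the fractal interfaces.
#
# Each species' overall association constant is the product of its
# interface constants: a dimer has one dimeric interface, a hexamer adds
# three heterologous ring interfaces, an 18mer joins three hexamers through
# three level-1 fractal interfaces, and a 54mer joins three 18mers through
# three level-2 fractal interfaces on top of its nine level-1 ones.
# Protonation (driven by the interface histidine) and ligand binding (which
# drives the dimer rotation away from the fractal-competent conformation)
# weaken only the fractal interfaces.

LADDER_SPECIES <- tibble::tibble(
  n = c(1L, 2L, 6L, 18L, 54L),
  species = c("monomer", "dimer", "hexamer", "18mer", "54mer"),
  n_dim = c(0L, 1L, 3L, 9L, 27L),
  n_hex = c(0L, 0L, 3L, 9L, 27L),
  n_f1 = c(0L, 0L, 0L, 3L, 9L),
  n_f2 = c(0L, 0L, 0L, 0L, 3L)
)

#' Oligomer species ladder
#'
#' Defines the discrete species set (monomer, dimer, hexamer, 18mer, 54mer)
#' and the per-interface association constants from which each species'
#' overall formation constant is assembled.
#'
#' @param K_dim Dimeric-interface association constant (1/M).
#' @param K_hex Heterologous hexamer-ring interface constant (1/M).
#' @param K_f1 Level-1 fractal interface constant (1/M; joins hexamers into
#'   18mers).
#' @param K_f2 Level-2 fractal interface constant (1/M; joins 18mers into
#'   54mers). Must not exceed `K_f1`: the larger joins are weaker, which is
#'   why 54mers only appear at much higher concentration.
#' @return A `species_ladder` object.
#' @details The default constants are calibrated, not measured: deep
#'   `K_dim`/`K_hex` make free monomer and dimer negligible above ~10 nM,
#'   `K_f1` places ~85% of subunits in 18mers at 50 nM and pH 7.5, and
#'   `K_f2` keeps 54mers rare below ~1 uM. See
#'   `scripts/calibrate_ladder.R` for the calibration.
#' @examples
#' species_ladder()
#' @export
species_ladder <- function(K_dim = 1e14, K_hex = 1e14,
                           K_f1 = 1.54e6, K_f2 = 3.0e4) {
  for (k in c(K_dim, K_hex, K_f1, K_f2)) check_scalar_number(k, "K")
  if (any(c(K_dim, K_hex, K_f1, K_f2) < 0)) stop_param("constants must be >= 0")
  if (K_f2 > K_f1) stop_param("K_f2 must be <= K_f1 (level-2 joins are weaker)")
  structure(
    list(species = LADDER_SPECIES,
         K_dim = K_dim, K_hex = K_hex, K_f1 = K_f1, K_f2 = K_f2),
    class = "species_ladder"
  )
}

#' @export
print.species_ladder <- function(x, ...) {
  cat("<species_ladder> 1 / 2 / 6 / 18 / 54 subunits\n")
  cat(sprintf("  K_dim = %.3g, K_hex = %.3g, K_f1 = %.3g, K_f2 = %.3g (1/M)\n",
              x$K_dim, x$K_hex, x$K_f1, x$K_f2))
  invisible(x)
}

#' Solution conditions for the equilibrium model
#'
#' @param total_subunit_conc Total subunit concentration (M).
#' @param pH Solution pH.
#' @param pKa Protonation pKa of the fractal interface (default 8.2, an
#'   assumption placed between the day/night intracellular extremes 8.4 and
#'   7.3 so the assembly transition spans them).
#' @param n_protonatable Protonatable groups per fractal interface whose
#'   protonation is required for bonding (default 2, the two
#'   glutamate-histidine contacts).
#' @param ligand_conc Free ligand (substrate/product) concentration (M).
#' @param K_L Ligand dissociation constant from the open, non-fractal
#'   hexamer conformation (M).
#' @param coupling_order Ligand coupling order p per fractal interface
#'   (default 2: ligand binding drives the dimer rotation opposing fractal
#'   association on both sides of the interface).
#' @return A `conditions` object (named list).
#' @export
eq_conditions <- function(total_subunit_conc, pH = 7.5, pKa = 8.2,
                          n_protonatable = 2L, ligand_conc = 0,
                          K_L = 2e-4, coupling_order = 2L) {
  check_scalar_number(total_subunit_conc, "total_subunit_conc")
  if (total_subunit_conc < 0) stop_param("total_subunit_conc must be >= 0")
  check_scalar_number(pH, "pH")
  if (pH <= 0 || pH >= 14) stop_param("pH must lie in (0, 14)")
  check_scalar_number(pKa, "pKa")
  check_scalar_number(n_protonatable, "n_protonatable", integerish = TRUE)
  check_scalar_number(ligand_conc, "ligand_conc")
  if (ligand_conc < 0) stop_param("ligand_conc must be >= 0")
  check_scalar_number(K_L, "K_L", positive = TRUE)
  check_scalar_number(coupling_order, "coupling_order", integerish = TRUE)
  structure(
    list(total_subunit_conc = total_subunit_conc, pH = pH, pKa = pKa,
         n_protonatable = as.integer(n_protonatable),
         ligand_conc = ligand_conc, K_L = K_L,
         coupling_order = as.integer(coupling_order)),
    class = "eq_conditions"
  )
}

# natural-log effective overall constants for all ladder species
log_betas <- function(ladder, conditions) {
  sp <- ladder$species
  lg <- -conditions$n_protonatable *
    log1p(10^(conditions$pH - conditions$pKa))
  lh <- -conditions$coupling_order *
    log1p(conditions$ligand_conc / conditions$K_L)
  lf1 <- log(ladder$K_f1) + lg + lh
  lf2 <- log(ladder$K_f2) + lg + lh
  # 0 * log(0) must contribute nothing: a species without an interface type
  # is unaffected by that constant being zero
  term <- function(count, logk) ifelse(count == 0L, 0, count * logk)
  term(sp$n_dim, log(ladder$K_dim)) + term(sp$n_hex, log(ladder$K_hex)) +
    term(sp$n_f1, lf1) + term(sp$n_f2, lf2)
}

#' Effective overall association constant of a species
#'
#' The product of the species' interface constants, with every fractal
#' interface scaled by the protonation factor
#' `g = (1 + 10^(pH - pKa))^(-m)` and the ligand factor
#' `h = (1 + L / K_L)^(-p)`. Non-fractal interfaces are unaffected.
#'
#' @param ladder A [species_ladder()].
#' @param n Species stoichiometry (1, 2, 6, 18 or 54).
#' @param conditions An [eq_conditions()] object.
#' @param log10 Return the base-10 logarithm (recommended for the deep
#'   default ladder, whose 54mer constant overflows double precision).
#' @return Effective beta_n (units M^-(interfaces)), or its log10.
#' @examples
#' species_constant(species_ladder(10, 10, 10, 10), 18,
#'                  eq_conditions(1e-6, pH = 7))
#' @export
species_constant <- function(ladder, n, conditions, log10 = FALSE) {
  stopifnot(inherits(ladder, "species_ladder"))
  i <- match(n, ladder$species$n)
  if (is.na(i)) stop_param("unknown species n = ", n)
  lb <- log_betas(ladder, conditions)[i]
  if (log10) lb / log(10) else exp(lb)
}

#' Solve the mass-action equilibrium
#'
#' Solves the subunit conservation `sum(n * beta_n * m^n) = C_tot` for the
#' free monomer concentration `m` by bisection (the left side is strictly
#' increasing in `m`), then returns every species' concentration
#' `c_n = beta_n * m^n` and subunit fraction. All arithmetic is done on
#' log concentrations so that arbitrarily deep ladders are handled without
#' overflow.
#'
#' @param ladder A [species_ladder()].
#' @param conditions An [eq_conditions()] object with
#'   `total_subunit_conc > 0`.
#' @param max_iter Bisection iterations (default 200).
#' @return A `species_distribution` tibble: columns `n`, `species`, `conc`
#'   (M), `subunit_fraction`; conditions attached as attribute
#'   `conditions`.
#' @examples
#' d <- solve_equilibrium(species_ladder(), eq_conditions(50e-9))
#' d$subunit_fraction[d$n == 18]
#' @export
solve_equilibrium <- function(ladder, conditions, max_iter = 200) {
  stopifnot(inherits(ladder, "species_ladder"),
            inherits(conditions, "eq_conditions"))
  C <- conditions$total_subunit_conc
  if (C <= 0) stop_param("total_subunit_conc must be > 0")
  sp <- ladder$species
  lb <- log_betas(ladder, conditions)

  total_at <- function(lm) {
    sum(sp$n * exp(ifelse(is.finite(lb), lb + sp$n * lm, -Inf)))
  }
  hi <- log(C)            # m = C gives total >= C
  lo <- hi - 60 * log(10) # deep ladder: m can be ~50 decades below C
  if (total_at(lo) > C) lo <- hi - 400 * log(10)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (total_at(mid) > C) hi <- mid else lo <- mid
  }
  lm <- (lo + hi) / 2
  resid <- abs(total_at(lm) - C) / C
  if (resid > 1e-6) {
    stop("equilibrium solver did not converge: relative residual ",
         format(resid, digits = 3))
  }
  conc <- exp(ifelse(is.finite(lb), lb + sp$n * lm, -Inf))
  out <- tibble::tibble(
    n = sp$n, species = sp$species, conc = conc,
    subunit_fraction = sp$n * conc / sum(sp$n * conc)
  )
  attr(out, "conditions") <- conditions
  attr(out, "free_monomer") <- exp(lm)
  class(out) <- c("species_distribution", class(out))
  out
}

#' Titration curve over concentration, pH or ligand
#'
#' Solves the equilibrium along a grid of one condition variable and
#' returns the stacked species distributions.
#'
#' @param ladder A [species_ladder()].
#' @param conditions Baseline [eq_conditions()]; the scanned variable is
#'   overridden by `grid`.
#' @param variable One of `"total_conc"`, `"pH"`, `"ligand"`.
#' @param grid Sorted numeric grid of the scanned variable (non-empty).
#' @return A tibble with columns `value` (grid point), `n`, `species`,
#'   `conc`, `subunit_fraction`.
#' @examples
#' tc <- titration_curve(species_ladder(), eq_conditions(50e-9),
#'                       "pH", seq(7, 9.5, by = 0.5))
#' @export
titration_curve <- function(ladder, conditions,
                            variable = c("total_conc", "pH", "ligand"),
                            grid) {
  variable <- match.arg(variable)
  if (length(grid) < 1) stop_param("grid must be non-empty")
  if (is.unsorted(grid)) stop_param("grid must be sorted increasing")
  purrr::map_dfr(grid, function(v) {
    cnd <- conditions
    if (variable == "total_conc") cnd$total_subunit_conc <- v
    if (variable == "pH") cnd$pH <- v
    if (variable == "ligand") cnd$ligand_conc <- v
    d <- solve_equilibrium(ladder, cnd)
    dplyr::mutate(tibble::as_tibble(d), value = v, .before = 1)
  })
}

#' Subunit-fraction-weighted activity index
#'
#' Mean catalytic activity of the population relative to the fully
#' hexameric state: each species contributes its subunit fraction times its
#' relative activity. The default map gives fractal species (18mer, 54mer)
#' half the hexamer's activity, reproducing the observed two-fold activity
#' gap between the wild type and a hexamer-only variant when most subunits
#' are assembled.
#'
#' @param distribution A `species_distribution`.
#' @param relative_activity Named numeric vector (names = stoichiometries)
#'   of per-species relative activities in `[0, 1]`.
#' @return Scalar activity index in `[0, 1]`.
#' @examples
#' d <- solve_equilibrium(species_ladder(), eq_conditions(50e-9))
#' activity_index(d)
#' @export
activity_index <- function(distribution,
                           relative_activity = c("1" = 1, "2" = 1, "6" = 1,
                                                 "18" = 0.5, "54" = 0.5)) {
  d <- distribution
  if (any(relative_activity < 0 | relative_activity > 1)) {
    stop_param("relative activities must lie in [0, 1]")
  }
  key <- as.character(d$n)
  present <- d$subunit_fraction > 0
  if (!all(key[present] %in% names(relative_activity))) {
    stop_param("missing species in relative_activity map: ",
               paste(setdiff(key[present], names(relative_activity)),
                     collapse = ", "))
  }
  act <- relative_activity[key]
  act[is.na(act)] <- 0
  sum(d$subunit_fraction * act)
}
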