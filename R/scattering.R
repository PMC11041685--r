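# Small-angle scattering: the Debye forward model on bead models, Guinier
# fitting of low-q intensity, and the z-average apparent Rg of mixtures.

#' Scattering profile container
#'
#' @param q Momentum transfer grid (nm^-1), strictly increasing; q = 0 is
#'   allowed as a limit point.
#' @param intensity Intensities (> 0), same length as `q`.
#' @param noise_sd Optional per-point noise s.d.
#' @return A tibble of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, noise_sd = NULL) {
  if (length(q) != length(intensity)) stop_param("q and intensity lengths differ")
  if (any(q < 0)) stop_param("q must be >= 0")
  if (is.unsorted(q, strictly = TRUE)) stop_param("q must be strictly increasing")
  if (any(intensity <= 0)) stop_param("intensity must be > 0")
  out <- tibble::tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(noise_sd)) out$noise_sd <- rep_len(noise_sd, nrow(out))
  class(out) <- c("scattering_profile", class(out))
  out
}

#' Debye scattering profile of a bead model
#'
#' Exact isotropic intensity of a set of identical point scatterers:
#' `I(q) = sum_ij sin(q r_ij) / (q r_ij)` with the self terms equal to 1,
#' so `I(0) = n^2`.
#'
#' @param model A `bead_model`.
#' @param q_grid Momentum transfer grid (nm^-1), q >= 0.
#' @return A `scattering_profile`.
#' @examples
#' p <- debye_profile(bead_model(monomer_coords(build_hexamer())),
#'                    seq(0.02, 2, by = 0.02))
#' @export
debye_profile <- function(model, q_grid) {
  stopifnot(inherits(model, "bead_model"))
  n <- nrow(model$positions)
  if (length(q_grid) < 1) stop_param("empty q grid")
  r <- as.numeric(stats::dist(model$positions))
  intensity <- vapply(q_grid, function(q) {
    if (q == 0) return(n^2)
    qr <- q * r
    n + 2 * sum(ifelse(qr < 1e-12, 1, sin(qr) / qr))
  }, numeric(1))
  scattering_profile(q_grid, intensity)
}

#' Guinier fit of a scattering profile
#'
#' Linear fit of `ln I` versus `q^2` over the largest low-q window that
#' satisfies `q * Rg <= qRg_max`, iterated to self-consistency; returns
#' `Rg = sqrt(-3 * slope)` and the forward-scattering intercept `I0`.
#'
#' @param profile A `scattering_profile` (or tibble with `q`, `intensity`).
#' @param qRg_max Guinier validity bound (default 1.3).
#' @param min_points Minimum points required in the window.
#' @return A `guinier_fit`: list with `Rg`, `I0`, `n_points`, `q_window`.
#' @examples
#' pr <- scattering_profile(seq(0.01, 0.4, 0.01),
#'                          5 * exp(-seq(0.01, 0.4, 0.01)^2 * 16 / 3))
#' guinier_fit(pr)$Rg  # 4
#' @export
guinier_fit <- function(profile, qRg_max = 1.3, min_points = 5) {
  q <- profile$q
  I <- profile$intensity
  pos <- q > 0
  q <- q[pos]; I <- I[pos]
  if (length(q) < min_points) stop_param("need >= ", min_points, " points with q > 0")

  fit_window <- function(keep) {
    f <- stats::lm(log(I[keep]) ~ I(q[keep]^2))
    b <- stats::coef(f)
    if (b[2] >= 0) {
      stop(structure(class = c("hexfract_fit_error", "error", "condition"),
                     list(message = "no Guinier decay: non-negative slope",
                          call = sys.call(-1))))
    }
    list(Rg = sqrt(-3 * b[2]), I0 = exp(b[1]))
  }

  keep <- seq_len(max(min_points, min(10, length(q))))
  fit <- fit_window(keep)
  for (it in 1:50) {
    qmax <- qRg_max / fit$Rg
    new_keep <- seq_len(max(min_points, sum(q <= qmax)))
    if (identical(new_keep, keep)) break
    keep <- new_keep
    fit <- fit_window(keep)
  }
  structure(
    list(Rg = unname(fit$Rg), I0 = unname(fit$I0),
         n_points = length(keep), q_window = range(q[keep]),
         qRg_max = qRg_max),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.3f nm, I0 = %.4g (%d points, q <= %.3f)\n",
              x$Rg, x$I0, x$n_points, x$q_window[2]))
  invisible(x)
}

#' @rdname tidy.dimension_fit
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("Rg", "I0"), estimate = c(x$Rg, x$I0))
}

#' @rdname tidy.dimension_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(Rg = x$Rg, I0 = x$I0, n_points = x$n_points,
                 q_max = x$q_window[2], qRg_max = x$qRg_max)
}

#' Apparent radius of gyration of an oligomer mixture
#'
#' The z-average (forward-scattering-weighted) apparent Rg of a mixture:
#' `Rg_app^2 = sum(c_n M_n^2 Rg_n^2) / sum(c_n M_n^2)`, the quantity a
#' Guinier fit of the mixture's scattering reports, because each species
#' contributes to I(0) in proportion to its concentration times mass
#' squared.
#'
#' @param distribution A species distribution tibble with columns `n`
#'   (stoichiometry) and `conc` (molar concentration), e.g. from
#'   [solve_equilibrium()].
#' @param species_rg Named numeric vector of per-species Rg (names are the
#'   stoichiometries), or a named list of `bead_model`s.
#' @param monomer_mass Monomer mass used for the M_n weights (any unit;
#'   only relative masses matter).
#' @return Apparent Rg (nm).
#' @export
mixture_rg <- function(distribution, species_rg, monomer_mass = 44.3) {
  d <- distribution
  if (!all(c("n", "conc") %in% names(d))) {
    stop_param("distribution needs columns n and conc")
  }
  if (is.list(species_rg) && !is.numeric(species_rg)) {
    species_rg <- vapply(species_rg, radius_of_gyration, numeric(1))
  }
  key <- as.character(d$n)
  if (!all(key %in% names(species_rg))) {
    stop_param("missing species model for n = ",
               paste(setdiff(key, names(species_rg)), collapse = ", "))
  }
  rg <- as.numeric(species_rg[key])
  M <- d$n * monomer_mass
  wgt <- d$conc * M^2
  if (sum(wgt) <= 0) stop_param("distribution has no mass")
  sqrt(sum(wgt * rg^2) / sum(wgt))
}
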