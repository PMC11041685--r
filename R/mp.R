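# Mass-photometry quantification: histogram single-particle mass events,
# fit a fixed-anchor Gaussian mixture (one component per candidate
# oligomeric state, mean constrained near n * monomer mass), and convert
# particle counts to subunit fractions.

event_masses <- function(events) {
  if (inherits(events, "mp_events")) return(events$masses)
  if (is.data.frame(events)) return(events$mass)
  if (is.numeric(events)) return(events)
  stop_param("events must be an mp_events object, data frame or numeric vector")
}

#' Quantify oligomeric-state populations from mass events
#'
#' Histograms the event masses (Freedman-Diaconis bin width, floor 5 kDa)
#' and fits a joint Gaussian mixture by least squares, one component per
#' candidate stoichiometry with its mean constrained to
#' `n * monomer_mass * (1 +/- window_frac)` and free amplitude and width.
#' Particle counts are the component integrals, and the subunit fraction of
#' species n is `n * count_n / sum(k * count_k)`.
#'
#' @param events An `mp_events` object (from [simulate_mp()]), a numeric
#'   vector of masses (kDa), or a data frame with a `mass` column.
#' @param stoichiometries Candidate oligomer sizes (distinct integers).
#' @param monomer_mass Monomer mass (kDa).
#' @param window_frac Relative half-width of each mean constraint window.
#' @return An `mp_quant` object: tibble with one row per species (`n`,
#'   `mean`, `width`, `count`, `particle_fraction`, `subunit_fraction`)
#'   plus a goodness-of-fit attribute (`r_squared` of the histogram fit).
#' @examples
#' ev <- simulate_mp(c("6" = 0.5, "18" = 0.5), n_events = 2000, seed = 1)
#' quantify_mp(ev)
#' @export
quantify_mp <- function(events, stoichiometries = c(1, 2, 6, 18, 54),
                        monomer_mass = 44.3, window_frac = 0.1) {
  x <- event_masses(events)
  if (length(x) < 50) stop_param("need >= 50 events")
  if (any(x <= 0)) stop_param("event masses must be > 0")
  stoich <- sort(unique(as.integer(stoichiometries)))
  if (length(stoich) != length(stoichiometries)) {
    stop_param("stoichiometries must be distinct")
  }
  check_scalar_number(monomer_mass, "monomer_mass", positive = TRUE)
  check_scalar_number(window_frac, "window_frac", positive = TRUE)

  # Freedman-Diaconis bin width, floor 5 kDa. The rule is applied per
  # candidate mass window and the narrowest well-populated peak wins:
  # applying it to the pooled multimodal distribution gives bins far wider
  # than the individual peaks.
  per_window <- vapply(stoichiometries, function(n) {
    w <- x[abs(x - n * monomer_mass) <= window_frac * n * monomer_mass]
    if (length(w) < 30) return(NA_real_)
    2 * stats::IQR(w) / length(w)^(1 / 3)
  }, numeric(1))
  bw <- if (all(is.na(per_window))) {
    max(5, 2 * stats::IQR(x) / length(x)^(1 / 3))
  } else {
    max(5, min(per_window, na.rm = TRUE))
  }
  # half-bin start so the lowest population sits mid-bin, not on a break
  lo <- min(x) - bw / 2; hi <- max(x) + bw
  breaks <- seq(lo, hi, by = bw)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  xc <- h$mids; yc <- h$counts

  mu0 <- stoich * monomer_mass
  win_lo <- mu0 * (1 - window_frac)
  win_hi <- mu0 * (1 + window_frac)
  n_in <- vapply(seq_along(stoich),
                 function(k) sum(x >= win_lo[k] & x <= win_hi[k]), numeric(1))
  active <- which(n_in > 0)
  if (length(active) < length(stoich)) {
    warning("no events within the mass window of species n = ",
            paste(stoich[-active], collapse = ", "), "; count set to 0")
  }

  fitted_mean <- mu0
  fitted_sd <- rep(NA_real_, length(stoich))
  counts <- rep(0, length(stoich))
  r2 <- NA_real_
  if (length(active) > 0) {
    # bin-integrated Gaussian components: the expected count of component k
    # in a bin is N_k * (Phi(upper) - Phi(lower)), which stays exact when a
    # peak is narrower than the histogram bin
    sd0 <- pmax(4, 0.02 * mu0[active])
    par0 <- c(log(pmax(n_in[active], 1)), mu0[active], log(sd0))
    nk <- length(active)
    bl <- h$breaks[-length(h$breaks)]
    bu <- h$breaks[-1]
    model <- function(p) {
      nn <- exp(p[seq_len(nk)])
      mu <- p[nk + seq_len(nk)]
      sg <- exp(p[2 * nk + seq_len(nk)])
      rowSums(vapply(seq_len(nk), function(k) {
        nn[k] * (stats::pnorm(bu, mu[k], sg[k]) -
                   stats::pnorm(bl, mu[k], sg[k]))
      }, numeric(length(xc))))
    }
    obj <- function(p) sum((model(p) - yc)^2)
    lower <- c(rep(-10, nk), win_lo[active], rep(log(0.5), nk))
    upper <- c(rep(log(2 * length(x)), nk), win_hi[active],
               log(pmax(4 * sd0, 0.2 * mu0[active])))
    opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    fitted_mean[active] <- opt$par[nk + seq_len(nk)]
    fitted_sd[active] <- exp(opt$par[2 * nk + seq_len(nk)])
    counts[active] <- exp(opt$par[seq_len(nk)])
    ss_res <- obj(opt$par)
    ss_tot <- sum((yc - mean(yc))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  }

  out <- tibble::tibble(
    n = stoich,
    mean = fitted_mean,
    width = fitted_sd,
    count = counts,
    particle_fraction = if (sum(counts) > 0) counts / sum(counts) else counts,
    subunit_fraction = if (sum(stoich * counts) > 0) {
      stoich * counts / sum(stoich * counts)
    } else counts
  )
  attr(out, "r_squared") <- r2
  attr(out, "bin_width") <- bw
  attr(out, "n_events") <- length(x)
  class(out) <- c("mp_quant", class(out))
  out
}

#' @rdname tidy.dimension_fit
#' @export
glance.mp_quant <- function(x, ...) {
  tibble::tibble(r_squared = attr(x, "r_squared"),
                 bin_width = attr(x, "bin_width"),
                 n_events = attr(x, "n_events"))
}

#' Convert between subunit fractions and particle fractions
#'
#' A complex of n subunits counts once as a particle but n times in the
#' subunit tally, so `particle_fraction ~ subunit_fraction / n`
#' (renormalised) and vice versa. The two maps are mutually inverse.
#'
#' @param fractions Numeric vector of fractions summing to 1.
#' @param stoichiometries Matching oligomer sizes (> 0).
#' @return Numeric vector of converted fractions (sums to 1).
#' @examples
#' fractions_to_particles(c(0.25, 0.75), c(6, 18))  # 0.5, 0.5
#' @export
fractions_to_particles <- function(fractions, stoichiometries) {
  if (any(stoichiometries <= 0)) stop_param("stoichiometries must be > 0")
  if (abs(sum(fractions) - 1) > 1e-6) stop_param("fractions must sum to 1")
  p <- fractions / stoichiometries
  p / sum(p)
}

#' @rdname fractions_to_particles
#' @export
particles_to_fractions <- function(fractions, stoichiometries) {
  if (any(stoichiometries <= 0)) stop_param("stoichiometries must be > 0")
  if (abs(sum(fractions) - 1) > 1e-6) stop_param("fractions must sum to 1")
  s <- fractions * stoichiometries
  s / sum(s)
}
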