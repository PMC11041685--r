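# Seeded synthetic-data generators emulating the study's raw inputs:
# single-particle mass events, noisy small-angle scattering profiles, and
# degraded silhouette images. Every generator takes an explicit integer
# seed and records it; regeneration with the same arguments is
# bit-identical.

#' Simulate single-particle mass-photometry events
#'
#' Draws particles from the species distribution (particle fractions
#' proportional to molar concentrations) and adds Gaussian mass error with
#' `sd = max(sd_floor_kda, sd_frac * species mass)`, the typical
#' mass-photometry resolution model.
#'
#' @param distribution A `species_distribution` (from
#'   [solve_equilibrium()]), or a named numeric vector of particle
#'   fractions with stoichiometries as names (must sum to 1).
#' @param monomer_mass Monomer mass (kDa).
#' @param n_events Number of single-particle events.
#' @param error_model List with `sd_floor_kda` (default 4) and `sd_frac`
#'   (default 0.02).
#' @param seed Integer seed.
#' @return An `mp_events` object: list with `masses` (kDa) and `metadata`
#'   (true particle and subunit fractions, monomer mass, error model,
#'   seed).
#' @examples
#' ev <- simulate_mp(c("6" = 0.6, "18" = 0.35, "54" = 0.05),
#'                   n_events = 1000, seed = 7)
#' @export
simulate_mp <- function(distribution, monomer_mass = 44.3, n_events = 10000,
                        error_model = list(sd_floor_kda = 4, sd_frac = 0.02),
                        seed = 1) {
  check_scalar_number(n_events, "n_events", integerish = TRUE)
  if (n_events < 1) stop_param("n_events must be >= 1")
  check_scalar_number(seed, "seed", integerish = TRUE)

  if (inherits(distribution, "species_distribution") ||
      (is.data.frame(distribution) && all(c("n", "conc") %in% names(distribution)))) {
    keep <- distribution$conc > 0
    stoich <- distribution$n[keep]
    pf <- distribution$conc[keep] / sum(distribution$conc[keep])
  } else {
    pf <- as.numeric(distribution)
    stoich <- as.integer(names(distribution))
    if (any(is.na(stoich))) stop_param("distribution names must be stoichiometries")
    if (abs(sum(pf) - 1) > 1e-6) stop_param("particle fractions must sum to 1")
  }
  sd_of <- function(m) pmax(error_model$sd_floor_kda, error_model$sd_frac * m)

  masses <- withr::with_seed(as.integer(seed), {
    sp <- sample(seq_along(stoich), n_events, replace = TRUE, prob = pf)
    m0 <- stoich[sp] * monomer_mass
    stats::rnorm(n_events, mean = m0, sd = sd_of(m0))
  })
  structure(
    list(
      masses = masses,
      metadata = list(
        true_particle_fractions = stats::setNames(pf, stoich),
        true_subunit_fractions = stats::setNames(
          particles_to_fractions(pf, stoich), stoich),
        monomer_mass = monomer_mass,
        error_model = error_model,
        n_events = as.integer(n_events),
        seed = as.integer(seed)
      )
    ),
    class = "mp_events"
  )
}

#' @export
print.mp_events <- function(x, ...) {
  cat(sprintf("<mp_events> %d events, monomer %.1f kDa, seed %d\n",
              length(x$masses), x$metadata$monomer_mass, x$metadata$seed))
  invisible(x)
}

#' Simulate a noisy small-angle scattering profile
#'
#' Computes the Debye profile of a bead model (or the
#' concentration-weighted mixture profile of several species), applies
#' multiplicative Gaussian noise, and optionally averages over repeated
#' frames (one-second frames in the emulated acquisition; the per-point
#' noise then shrinks by sqrt(n_frames)).
#'
#' @param model A `bead_model`, or a list with elements `distribution`
#'   (tibble with `n`, `conc`) and `models` (named list of `bead_model`s
#'   keyed by stoichiometry).
#' @param q_grid Momentum transfer grid (nm^-1).
#' @param noise_frac Relative noise s.d. per frame (>= 0).
#' @param seed Integer seed.
#' @param n_frames Frames averaged (default 1; the emulated protocol used
#'   10).
#' @return A `scattering_profile` with attributes `seed`, `n_frames`,
#'   `noise_frac`.
#' @examples
#' bm <- bead_model(monomer_coords(build_sierpinski(1)))
#' simulate_saxs(bm, seq(0.02, 2, 0.02), noise_frac = 0.02, seed = 3)
#' @export
simulate_saxs <- function(model, q_grid, noise_frac = 0, seed = 1,
                          n_frames = 1) {
  if (noise_frac < 0) stop_param("noise_frac must be >= 0")
  check_scalar_number(seed, "seed", integerish = TRUE)
  check_scalar_number(n_frames, "n_frames", integerish = TRUE, positive = TRUE)

  if (inherits(model, "bead_model")) {
    base <- debye_profile(model, q_grid)$intensity
  } else if (is.list(model) && !is.null(model$distribution) &&
             !is.null(model$models)) {
    d <- model$distribution
    keep <- which(d$conc > 0)
    if (length(keep) == 0) stop_param("empty model set")
    base <- Reduce(`+`, lapply(keep, function(i) {
      bm <- model$models[[as.character(d$n[i])]]
      if (is.null(bm)) stop_param("missing bead model for n = ", d$n[i])
      d$conc[i] * debye_profile(bm, q_grid)$intensity
    }))
    base <- base / max(model$distribution$conc[keep])  # arbitrary units
  } else {
    stop_param("model must be a bead_model or list(distribution, models)")
  }

  intensity <- withr::with_seed(as.integer(seed), {
    frames <- vapply(seq_len(n_frames), function(f) {
      base * (1 + stats::rnorm(length(base), sd = noise_frac))
    }, numeric(length(base)))
    rowMeans(matrix(frames, nrow = length(base)))
  })
  intensity <- pmax(intensity, .Machine$double.xmin)
  out <- scattering_profile(q_grid, intensity,
                            noise_sd = base * noise_frac / sqrt(n_frames))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_frames") <- as.integer(n_frames)
  attr(out, "noise_frac") <- noise_frac
  out
}

#' Degrade a binary silhouette image
#'
#' Applies a Gaussian blur followed by re-thresholding at 0.5, then flips
#' pixels with salt-and-pepper probability `speckle_prob` -- a stain-like
#' robustness fixture for the box-counting pipeline.
#'
#' @param image A `raster_image`.
#' @param blur_px Gaussian blur sigma in pixels (0 = no blur).
#' @param speckle_prob Per-pixel flip probability (must be < 0.05; heavier
#'   speckle corrupts dimension estimates).
#' @param seed Integer seed.
#' @return A `raster_image`.
#' @examples
#' img <- rasterize(build_sierpinski(1), 128)
#' degrade_image(img, blur_px = 1, speckle_prob = 0.01, seed = 4)
#' @export
degrade_image <- function(image, blur_px = 0, speckle_prob = 0, seed = 1) {
  stopifnot(inherits(image, "raster_image"))
  if (blur_px < 0) stop_param("blur_px must be >= 0")
  if (speckle_prob < 0 || speckle_prob >= 0.05) {
    stop_param("speckle_prob must lie in [0, 0.05)")
  }
  check_scalar_number(seed, "seed", integerish = TRUE)
  m <- matrix(as.numeric(image), nrow(image), ncol(image))
  if (blur_px > 0) {
    m <- EBImage::gblur(m, sigma = blur_px)
  }
  out <- m > 0.5
  if (speckle_prob > 0) {
    flips <- withr::with_seed(as.integer(seed),
                              stats::runif(length(out)) < speckle_prob)
    out[flips] <- !out[flips]
  }
  new_raster_image(out, attr(image, "px_per_nm"), attr(image, "render_style"))
}
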