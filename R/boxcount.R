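# Box-counting (Hausdorff) dimension estimation with the fixed-grid scan:
# a non-overlapping regular grid at several box sizes and grid offsets;
# D is the slope of log(count) vs log(1/box size).

#' Default box-size schedule
#'
#' Nine integer box sizes evenly spaced from 85 to 17 px, the published
#' range and count of the fixed-grid scan applied to the class averages.
#' @return Integer vector of box sizes (px).
#' @export
default_box_sizes <- function() c(85L, 77L, 68L, 60L, 51L, 43L, 34L, 26L, 17L)

#' Count occupied boxes over a fixed grid
#'
#' Overlays the image with a non-overlapping regular grid for each box size
#' and offset and counts the boxes containing at least one foreground
#' pixel. Partial boxes at the image border are counted. The default three
#' offsets per size `s` are `(0,0)`, `(s/3, s/3)` and `(2s/3, 2s/3)`
#' (fractions of the box size, applied to both axes), standing in for the
#' three grid positions of the published protocol.
#'
#' @param image A `raster_image` (or logical matrix).
#' @param box_sizes_px Integer box sizes; default [default_box_sizes()].
#' @param offsets Either a numeric vector of fractional diagonal offsets
#'   (default `c(0, 1/3, 2/3)`) or a list of absolute integer 2-vectors
#'   applied to all sizes.
#' @return A `box_count_result`: list with `counts` (tibble `box_size`,
#'   `offset`, `count`) and the image dimensions.
#' @examples
#' img <- rasterize(build_sierpinski(1), 350)
#' bc <- box_count(img)
#' @export
box_count <- function(image, box_sizes_px = default_box_sizes(),
                      offsets = c(0, 1 / 3, 2 / 3)) {
  m <- as.matrix(image)
  if (!is.logical(m)) m <- m > 0.5
  if (!any(m)) stop_param("image has no foreground pixels")
  box_sizes_px <- as.integer(round(box_sizes_px))
  if (length(box_sizes_px) < 1) stop_param("need at least one box size")
  if (any(box_sizes_px < 2)) stop_param("box sizes must be >= 2 px")
  if (any(box_sizes_px > max(dim(m)))) {
    stop_param("box size exceeds image dimensions")
  }

  fg <- which(m) - 1L
  row0 <- fg %% nrow(m)
  col0 <- fg %/% nrow(m)

  fractional <- !is.list(offsets)
  n_off <- if (fractional) length(offsets) else length(offsets)
  res <- vector("list", length(box_sizes_px) * n_off)
  k <- 0L
  for (s in box_sizes_px) {
    for (oi in seq_len(n_off)) {
      if (fractional) {
        off <- floor(offsets[[oi]] * s)
        ox <- off; oy <- off
      } else {
        ox <- as.integer(offsets[[oi]][1]); oy <- as.integer(offsets[[oi]][2])
      }
      bid <- (row0 + oy) %/% s + ((col0 + ox) %/% s) * 1e6
      k <- k + 1L
      res[[k]] <- tibble::tibble(box_size = s, offset = oi,
                                 count = length(unique(bid)))
    }
  }
  structure(
    list(counts = dplyr::bind_rows(res), dim = dim(m),
         n_foreground = length(fg)),
    class = "box_count_result"
  )
}

#' @export
print.box_count_result <- function(x, ...) {
  cat(sprintf("<box_count_result> %d box sizes x %d offsets on %d x %d image\n",
              length(unique(x$counts$box_size)),
              length(unique(x$counts$offset)), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Fit the box-counting dimension
#'
#' With `aggregate = "per_offset"` (the fixed-grid scan protocol applied to
#' the class averages): ordinary least squares of `log(count)` on
#' `log(1 / box_size)` per grid offset; the reported dimension is the mean
#' slope over offsets, its s.d. the spread over offsets, and R-squared
#' comes from the pooled regression over all size/offset points.
#'
#' With `aggregate = "min_cover"`: the counts are first minimised over grid
#' offsets at each size, which discretises the covering-number definition
#' of the box dimension (the minimal number of boxes of side s needed to
#' cover the set). This estimator converges noticeably better on deep
#' mathematical fractals and is used for analytic-oracle checks.
#'
#' @param result A `box_count_result` from [box_count()].
#' @param aggregate `"per_offset"` (default) or `"min_cover"`.
#' @return A `dimension_fit`: list with `D`, `D_sd`, `R2`, `per_offset`
#'   (tibble of per-offset slopes) and the counts table. When the counts
#'   are constant a degenerate-fit warning is raised and `D = 0`.
#' @examples
#' fit <- fit_dimension(box_count(rasterize(build_sierpinski(1), 350)))
#' fit$D
#' @export
fit_dimension <- function(result, aggregate = c("per_offset", "min_cover")) {
  stopifnot(inherits(result, "box_count_result"))
  aggregate <- match.arg(aggregate)
  ct <- result$counts
  if (length(unique(ct$box_size)) < 3) stop_param("need >= 3 box sizes")
  if (all(ct$count == ct$count[1])) {
    warning("constant box counts: degenerate fit, D = 0")
    return(structure(list(D = 0, D_sd = 0, R2 = NA_real_,
                          per_offset = tibble::tibble(), counts = ct),
                     class = "dimension_fit"))
  }
  if (aggregate == "min_cover") {
    ct <- ct |>
      dplyr::group_by(.data$box_size) |>
      dplyr::summarise(count = min(.data$count), .groups = "drop") |>
      dplyr::mutate(offset = 0L)
  }
  ct$lx <- log(1 / ct$box_size)
  ct$ly <- log(ct$count)
  per <- ct |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(
      slope = stats::coef(stats::lm(ly ~ lx))[["lx"]],
      .groups = "drop"
    )
  pooled <- stats::lm(ly ~ lx, data = ct)
  structure(
    list(
      D = mean(per$slope),
      D_sd = if (nrow(per) > 1) stats::sd(per$slope) else 0,
      R2 = summary(pooled)$r.squared,
      per_offset = per,
      counts = ct[, c("box_size", "offset", "count")],
      aggregate = aggregate
    ),
    class = "dimension_fit"
  )
}

#' @export
print.dimension_fit <- function(x, ...) {
  cat(sprintf("<dimension_fit> D = %.3f +/- %.3f (s.d. over %d offsets), R^2 = %.4f\n",
              x$D, x$D_sd, nrow(x$per_offset), x$R2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dimension fit
#'
#' @param x A `dimension_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per grid offset with its slope estimate.
#'   `glance()`: a one-row tibble with `D`, `D_sd`, `R2` and the number of
#'   size/offset points.
#' @export
tidy.dimension_fit <- function(x, ...) {
  x$per_offset
}

#' @rdname tidy.dimension_fit
#' @export
glance.dimension_fit <- function(x, ...) {
  tibble::tibble(D = x$D, D_sd = x$D_sd, R2 = x$R2,
                 n_points = nrow(x$counts))
}

#' Mass-radius fractal dimension of a series of assemblies
#'
#' Regresses `log(subunit count)` on `log(Rg)` across assemblies of
#' consecutive fractal levels; for the Sierpinski hierarchy the mass
#' triples while the radius doubles per level, so the slope estimates
#' log 3 / log 2.
#'
#' @param assemblies List of at least three `assembly` objects.
#' @return The regression slope (dimension estimate).
#' @examples
#' mass_radius_dimension(lapply(0:2, build_sierpinski))
#' @export
mass_radius_dimension <- function(assemblies) {
  if (!is.list(assemblies) || length(assemblies) < 3) {
    stop_param("need at least 3 assemblies")
  }
  n <- vapply(assemblies, function(a) nrow(a$monomers), numeric(1))
  rg <- vapply(assemblies, function(a) {
    radius_of_gyration(bead_model(monomer_coords(a)))
  }, numeric(1))
  if (stats::sd(log(rg)) < 1e-12) {
    stop_geometry("degenerate fit: assemblies have identical Rg")
  }
  unname(stats::coef(stats::lm(log(n) ~ log(rg)))[2])
}
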