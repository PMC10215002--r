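#' 2D dose map
#'
#' Container for a rectangular 2D dose grid with uniform pixel spacing and a
#' pixel-center origin expressed in mm relative to the projection of the
#' isocenter (the beam central axis).  Film scans and simulated dose grids
#' both reduce to this unit; values may be percent of prescribed dose, Gy, or
#' raw scanner signal -- the pipeline is scale-invariant where it needs to be
#' and no calibration is applied implicitly.
#'
#' The value grid is stored as a matrix in image convention: `values[r, c]`
#' is the pixel with x-index `c - 1` and y-index `r - 1` (0-based), located
#' at `(x0 + (c-1)*dx, y0 + (r-1)*dy)`.  Columns run along the cross-plane
#' (X) axis, rows along the in-plane (Y) axis.
#'
#' @param values Numeric matrix, all values finite, at least one pixel.
#' @param spacing Numeric length-2 `(dx, dy)` in mm per pixel, both > 0.
#'   A single number is recycled to both axes.
#' @param origin Numeric length-2 `(x0, y0)`, mm position of the first pixel
#'   center (`values[1, 1]`) relative to the isocenter projection.
#' @param meta Named list of free-form tags (beam energy label, seed model,
#'   plane label such as `"BU"`/`"BD"`, ...).
#'
#' @return An object of class `dose_map`.
#' @seealso [dose_map_x()], [crop_to_field()], [read_dose_map()]
#' @export
#' @examples
#' m <- dose_map(matrix(100, 3, 3), spacing = 1, origin = c(-1, -1))
#' dose_map_x(m)
dose_map <- function(values, spacing, origin = NULL, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric matrix")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite dose value at pixel (row %d, col %d)",
                 bad[1L], bad[2L]))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (length(spacing) != 2L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be one or two strictly positive numbers (dx, dy)")
  if (is.null(origin)) {
    # default: grid centered on the isocenter
    origin <- c(-(ncol(values) - 1L) / 2 * spacing[1L],
                -(nrow(values) - 1L) / 2 * spacing[2L])
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite numbers (x0, y0)")
  stopifnot(is.list(meta))
  structure(list(values = values, spacing = spacing, origin = origin,
                 meta = meta),
            class = "dose_map")
}

#' @rdname dose_map
#' @param map A `dose_map`.
#' @export
is_dose_map <- function(map) inherits(map, "dose_map")

#' Pixel-center coordinates of a dose map
#'
#' @param map A [dose_map()].
#' @return `dose_map_x()` returns the x (cross-plane) coordinates of the
#'   columns; `dose_map_y()` the y (in-plane) coordinates of the rows; mm.
#' @export
dose_map_x <- function(map) {
  map$origin[1L] + (seq_len(ncol(map$values)) - 1L) * map$spacing[1L]
}

#' @rdname dose_map_x
#' @export
dose_map_y <- function(map) {
  map$origin[2L] + (seq_len(nrow(map$values)) - 1L) * map$spacing[2L]
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d pixels, spacing (%.4g, %.4g) mm\n",
              nrow(x$values), ncol(x$values), x$spacing[1L], x$spacing[2L]))
  cat(sprintf("  x: [%.3f, %.3f] mm, y: [%.3f, %.3f] mm\n",
              min(dose_map_x(x)), max(dose_map_x(x)),
              min(dose_map_y(x)), max(dose_map_y(x))))
  cat(sprintf("  values: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Crop a dose map to a centered square window
#'
#' Keeps the pixels whose centers satisfy `|x| <= half_width_mm` and
#' `|y| <= half_width_mm`, updating the origin consistently (no half-pixel
#' drift).  Cropping twice with the same window equals cropping once.
#'
#' @param map A [dose_map()].
#' @param half_width_mm Half-width of the window, mm.
#' @return The cropped `dose_map`.
#' @export
crop_to_field <- function(map, half_width_mm) {
  stopifnot(is_dose_map(map), is.numeric(half_width_mm),
            length(half_width_mm) == 1L, half_width_mm > 0)
  xs <- dose_map_x(map)
  ys <- dose_map_y(map)
  tol <- 1e-9
  if (half_width_mm > max(abs(c(xs, ys))) + tol)
    stop(sprintf(
      "crop window %.3f mm exceeds grid extent (x: [%.3f, %.3f], y: [%.3f, %.3f] mm)",
      half_width_mm, min(xs), max(xs), min(ys), max(ys)))
  keep_x <- which(abs(xs) <= half_width_mm + tol)
  keep_y <- which(abs(ys) <= half_width_mm + tol)
  if (!length(keep_x) || !length(keep_y))
    stop("crop window contains no pixel centers")
  dose_map(map$values[keep_y, keep_x, drop = FALSE], map$spacing,
           c(xs[keep_x[1L]], ys[keep_y[1L]]), map$meta)
}

#' 1D cross-plane dose profile
#'
#' A uniformly spaced 1D profile along the cross-plane (X) axis, x = 0 at
#' the field center.  Values are dose in percent (after normalization) or
#' raw signal.
#'
#' @param positions Strictly increasing, uniformly spaced positions, mm.
#' @param values Numeric vector, same length, all finite.
#' @param meta Named list of free-form tags.
#' @return An object of class `dose_profile`.
#' @export
dose_profile <- function(positions, values, meta = list()) {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values))
    stop("`positions` and `values` must have the same length")
  if (length(positions) < 1L) stop("empty profile")
  if (!all(is.finite(positions)) || !all(is.finite(values)))
    stop("profile positions and values must be finite")
  if (length(positions) > 1L) {
    d <- diff(positions)
    if (any(d <= 0)) stop("positions must be strictly increasing")
    bin <- d[1L]
    if (any(abs(d - bin) >= 1e-9))
      stop("positions must be uniformly spaced (max deviation ",
           format(max(abs(d - bin))), " mm)")
  } else {
    bin <- NA_real_
  }
  structure(list(positions = positions, values = values, bin = bin,
                 meta = meta),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  cat(sprintf("<dose_profile> %d points, bin %.4g mm, x: [%.3f, %.3f] mm\n",
              length(x$positions), x$bin, min(x$positions), max(x$positions)))
  invisible(x)
}

#' Relative dose-change profile
#'
#' Holds the signed relative dose change `delta` (percent) between a seeded
#' and a reference acquisition at matched positions: positive for build-up
#' (BU, upstream dose enhancement), negative for build-down (BD, downstream
#' dose reduction).
#'
#' @param positions Strictly increasing, uniformly spaced positions, mm.
#' @param delta Signed relative dose change at each position, percent.
#' @param meta Named list of labels (seed model, energy, BU/BD plane).
#' @return An object of class `perturbation_profile` (also a
#'   `dose_profile`; the `values` field aliases `delta`).
#' @export
perturbation_profile <- function(positions, delta, meta = list()) {
  p <- dose_profile(positions, delta, meta)
  p$delta <- p$values
  class(p) <- c("perturbation_profile", "dose_profile")
  p
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf(
    "<perturbation_profile> %d points, bin %.4g mm, delta: [%.3f, %.3f] %%\n",
    length(x$positions), x$bin, min(x$delta), max(x$delta)))
  invisible(x)
}

# rebuild a profile of the same class with new positions/values
profile_like <- function(template, positions, values) {
  if (inherits(template, "perturbation_profile"))
    perturbation_profile(positions, values, template$meta)
  else
    dose_profile(positions, values, template$meta)
}
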