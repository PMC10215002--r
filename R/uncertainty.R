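#' Combine uncertainty components in quadrature
#'
#' The combined standard uncertainty (k = 1) is the square root of the sum
#' of squared relative components.  Rounding happens only at presentation;
#' the raw value is returned.
#'
#' @param components Numeric vector of non-negative components, percent.
#' @return Combined uncertainty, percent (unrounded).
#' @export
#' @examples
#' combine_quadrature(c(1.5, 0.5, 1.5))       # film dosimetry chain: 2.18 -> 2.2
#' combine_quadrature(c(1.5, 0.5, 1.5, 1.5))  # + beam calibration:  2.65 -> 2.6
combine_quadrature <- function(components) {
  components <- as.numeric(components)
  if (!length(components)) stop("no components")
  if (any(!is.finite(components))) stop("components must be finite")
  if (any(components < 0))
    stop("negative uncertainty component: ",
         format(components[components < 0][1L]))
  sqrt(sum(components^2))
}

#' Uncertainty budget
#'
#' A named list of relative standard uncertainty components with their
#' quadrature combination at k = 1.  Printed values are rounded half-up to
#' one decimal, matching how such budgets are tabulated; the raw combined
#' value is kept in the object.
#'
#' @param components Named numeric vector, percent.
#' @return An object of class `uncertainty_budget` with fields
#'   `components` and `combined`.
#' @export
uncertainty_budget <- function(components) {
  if (is.null(names(components)) || any(!nzchar(names(components))))
    names(components) <- paste0("component_", seq_along(components))
  structure(list(components = components,
                 combined = combine_quadrature(components)),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("<uncertainty_budget> (k = 1)\n")
  for (nm in names(x$components))
    cat(sprintf("  %-40s %5.2f %%\n", nm, x$components[[nm]]))
  cat(sprintf("  %-40s %5.1f %%\n", "combined (quadrature)",
              round_half_up(x$combined, 1)))
  invisible(x)
}

#' Write / read an uncertainty budget as CSV
#'
#' Two columns `component,value_percent`, one row per component, plus a
#' final `combined` row (recomputed on read, not trusted).
#'
#' @param budget An [uncertainty_budget()].
#' @param path File path.
#' @export
write_budget <- function(budget, path) {
  stopifnot(inherits(budget, "uncertainty_budget"))
  df <- data.frame(component = c(names(budget$components), "combined"),
                   value_percent = c(unname(budget$components),
                                     budget$combined))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_budget
#' @export
read_budget <- function(path) {
  df <- utils::read.csv(path)
  df <- df[df$component != "combined", , drop = FALSE]
  uncertainty_budget(stats::setNames(df$value_percent, df$component))
}

#' Replicate-film standard error
#'
#' Estimates measurement uncertainty from replicate acquisitions: at each
#' position the standard error of the mean (sd / sqrt(n)) across the
#' replicates, expressed as percent of the per-position mean, then averaged
#' over the requested region.
#'
#' @param profiles List of >= 2 replicate [dose_profile()]s sharing one
#'   position grid.
#' @param region `(xmin, xmax)` interval in mm over which to summarize;
#'   default spans the whole profile.
#' @return Mean relative standard error over the region, percent.
#' @export
replicate_standard_error <- function(profiles, region = NULL) {
  if (length(profiles) < 2L) stop("need >= 2 replicate profiles")
  stopifnot(all(vapply(profiles, inherits, TRUE, "dose_profile")))
  x <- profiles[[1L]]$positions
  for (p in profiles[-1L])
    if (length(p$positions) != length(x) ||
        max(abs(p$positions - x)) >= 1e-9)
      stop("replicate profiles are on different position grids")
  if (is.null(region)) region <- range(x)
  sel <- x >= region[1L] - 1e-9 & x <= region[2L] + 1e-9
  if (!any(sel)) stop("region contains no samples")
  vals <- do.call(rbind, lapply(profiles, function(p) p$values[sel]))
  n <- nrow(vals)
  mu <- colMeans(vals)
  if (any(mu <= 0)) stop("non-positive mean value in region")
  se <- apply(vals, 2L, stats::sd) / sqrt(n)
  mean(100 * se / mu)
}
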