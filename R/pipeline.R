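#' Analysis run configuration
#'
#' Bundles the protocol constants.  Defaults follow the film protocol:
#' profiles normalized to the 40--60 mm flat band, reconstructed to 0.1 mm
#' bins, and fitted over a +/- 2.5 mm window about each peak.
#'
#' @param flat_band `(inner, outer)` mm of the flat normalization band.
#' @param rebin_mm Reconstruction bin size, mm.
#' @param fit_window_mm Fit window half-width about each peak, mm.
#' @param band_half_width_mm Averaging band half-width for profile
#'   extraction, mm.  The default 2 mm stays inside the uniform core of a
#'   capsule seed footprint, so averaging suppresses pixel noise without
#'   attenuating the cross-plane truth; use 0 for the single row through
#'   each seed center (radial footprints) or a wide band (e.g. 10 mm) for
#'   film-protocol emulation on seed-free regions.
#' @param analysis_half_width_mm Profiles are cropped to
#'   `|x| <=` this before the perturbation statistic, so the reference is
#'   positive everywhere (inside the field, away from the penumbra).
#' @param symmetrize Mirror-average profiles about x = 0 before analysis.
#'   Off by default: synthetic truth need not be symmetric; the film
#'   protocol's symmetry is an artifact of its axis averaging.
#' @param n_starts,seed Multi-start budget and base RNG seed for
#'   [fit_peak()]; per-seed fit seeds are `seed + seed index`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(flat_band = c(40, 60), rebin_mm = 0.1,
                       fit_window_mm = 2.5, band_half_width_mm = 2,
                       analysis_half_width_mm = 35, symmetrize = FALSE,
                       n_starts = 12, seed = 1) {
  stopifnot(rebin_mm > 0, fit_window_mm > 0, band_half_width_mm >= 0,
            analysis_half_width_mm > 0, n_starts >= 1)
  structure(list(flat_band = flat_band, rebin_mm = rebin_mm,
                 fit_window_mm = fit_window_mm,
                 band_half_width_mm = band_half_width_mm,
                 analysis_half_width_mm = analysis_half_width_mm,
                 symmetrize = isTRUE(symmetrize),
                 n_starts = n_starts, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the perturbation analysis end to end
#'
#' For each seed (or once, centered on the located peak, when no layout is
#' given) the stages are: axis averaging through the seed row ->
#' flat-area normalization -> rebinning -> optional symmetrization ->
#' crop to the in-field analysis window -> relative dose change ->
#' peak fit.  Results mirror the per-seed report schema; clusters of two
#' or more seeds also get a mean/SD summary.
#'
#' @param ref,seeded [dose_map()]s on a shared grid (pre-registered).
#' @param layout Optional [seed_layout()] of known seed positions; when
#'   `NULL` a single peak is located automatically.
#' @param plane `"BU"`, `"BD"`, or `NULL` to take the sign from
#'   [locate_peak()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `per_seed.csv`, `summary.csv` (clusters only) and `run_log.txt`
#'   recording every protocol constant used.
#' @param label Run label recorded in the report.
#' @return List of class `analysis_report`: `per_seed` (data frame),
#'   `summary` (or `NULL`), `fits` (list of `peak_fit`), `config`.
#' @export
run_analysis <- function(ref, seeded, layout = NULL, plane = NULL,
                         config = run_config(), out_dir = NULL,
                         label = "run") {
  stopifnot(is_dose_map(ref), is_dose_map(seeded),
            inherits(config, "run_config"))
  if (!identical(dim(ref$values), dim(seeded$values)) ||
      max(abs(ref$spacing - seeded$spacing)) >= 1e-9 ||
      max(abs(ref$origin - seeded$origin)) >= 1e-9)
    stop("analyze: ref and seeded maps must share one grid")
  if (!is.null(plane)) plane <- match.arg(plane, c("BU", "BD"))

  seeds <- if (is.null(layout)) matrix(c(0, 0), 1L)
           else layout$positions
  fits <- vector("list", nrow(seeds))
  rows <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    sx <- seeds[k, 1L]; sy <- seeds[k, 2L]
    step <- sprintf("seed %d at (%.3g, %.3g) mm", k, sx, sy)
    pr <- with_stage(paste("axis_average:", step), {
      bhw <- max(config$band_half_width_mm, 0)
      list(ref = axis_average(ref, band_half_width_mm = bhw,
                              band_center_mm = sy),
           seeded = axis_average(seeded, band_half_width_mm = bhw,
                                 band_center_mm = sy))
    })
    pr <- with_stage(paste("normalize_to_flat:", step),
      lapply(pr, normalize_to_flat, flat_band = config$flat_band))
    pr <- with_stage(paste("rebin:", step),
      lapply(pr, rebin, bin_mm = config$rebin_mm))
    if (config$symmetrize)
      pr <- with_stage(paste("symmetrize:", step), lapply(pr, symmetrize))
    pr <- with_stage(paste("crop:", step),
      lapply(pr, crop_profile, half_width_mm = config$analysis_half_width_mm))
    dd <- with_stage(paste("delta_dose:", step),
      delta_dose(pr$seeded, pr$ref))
    if (is.null(layout) || is.null(plane)) {
      loc <- with_stage(paste("locate_peak:", step),
        locate_peak(dd, search_half_width_mm = config$fit_window_mm,
                    center_mm = sx))
      mu0 <- loc$mu0
      sgn <- if (is.null(plane)) loc$sign else if (plane == "BU") +1 else -1
    } else {
      mu0 <- sx
      sgn <- if (plane == "BU") +1 else -1
    }
    fit <- with_stage(paste("fit_peak:", step),
      fit_peak(dd, mu0, sgn, window_half_width_mm = config$fit_window_mm,
               n_starts = config$n_starts, seed = config$seed + k))
    fits[[k]] <- fit
    rows[[k]] <- cbind(data.frame(label = label, seed = k,
                                  x_mm = sx, y_mm = sy),
                       as.data.frame(fit))
  }
  per_seed <- do.call(rbind, rows)
  summary <- if (length(fits) >= 2L) summarize_cluster(fits) else NULL

  report <- structure(list(per_seed = per_seed, summary = summary,
                           fits = fits, config = config, label = label),
                      class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> '%s': %d peak fit(s)\n", x$label,
              nrow(x$per_seed)))
  print(x$per_seed[, c("seed", "x_mm", "y_mm", "dose_difference_percent",
                       "fwhm_mm", "converged")], row.names = FALSE)
  if (!is.null(x$summary))
    cat(sprintf(
      "  cluster: dose difference %.1f +/- %.1f %%, FWHM %.2f +/- %.2f mm\n",
      x$summary$mean_dd, x$summary$sd_dd,
      x$summary$mean_fwhm, x$summary$sd_fwhm))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(df) {
    is_num <- vapply(df, is.numeric, TRUE)
    df[is_num] <- lapply(df[is_num], function(v) sprintf("%.12g", v))
    df
  }
  utils::write.csv(num(report$per_seed),
                   file.path(out_dir, "per_seed.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$summary))
    utils::write.csv(num(as.data.frame(report$summary)),
                     file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  cfg <- report$config
  writeLines(c(
    sprintf("label: %s", report$label),
    sprintf("flat_band_mm: %g %g", cfg$flat_band[1L], cfg$flat_band[2L]),
    sprintf("rebin_mm: %g", cfg$rebin_mm),
    sprintf("fit_window_mm: %g", cfg$fit_window_mm),
    sprintf("band_half_width_mm: %g", cfg$band_half_width_mm),
    sprintf("analysis_half_width_mm: %g", cfg$analysis_half_width_mm),
    sprintf("symmetrize: %s", cfg$symmetrize),
    sprintf("n_starts: %d", cfg$n_starts),
    sprintf("seed: %d", cfg$seed)),
    file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Generate and write a synthetic scene
#'
#' Delegates to [make_scene()] and writes `ref.txt` and `seeded.txt`
#' (matrix-text dose maps), `truth.csv` (per-seed ground truth) and
#' `scene_log.txt` (the generator parameters) to `out_dir`.
#'
#' @param config A [scene_config()].
#' @param out_dir Output directory.
#' @return The `synthetic_scene`, invisibly.
#' @export
run_synth <- function(config, out_dir) {
  scene <- make_scene(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dose_map(scene$ref, file.path(out_dir, "ref.txt"), "matrix-text")
  write_dose_map(scene$seeded, file.path(out_dir, "seeded.txt"),
                 "matrix-text")
  tt <- scene_truth_table(scene)
  tt[] <- lapply(tt, function(v) if (is.numeric(v)) sprintf("%.12g", v) else v)
  utils::write.csv(tt, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- scene$config
  writeLines(c(
    sprintf("pattern: %s", cfg$layout$pattern),
    sprintf("n_seeds: %d", nrow(cfg$layout$positions)),
    sprintf("plane: %s", cfg$plane),
    sprintf("noise_sd_percent: %g", cfg$noise_sd),
    sprintf("rng_seed: %d", cfg$rng_seed),
    sprintf("size_mm: %g", cfg$size_mm),
    sprintf("spacing_mm: %.12g", cfg$spacing_mm),
    sprintf("field_half_width_mm: %g", cfg$field_half_width_mm),
    sprintf("penumbra_mm: %g", cfg$penumbra_mm)),
    file.path(out_dir, "scene_log.txt"))
  invisible(scene)
}
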