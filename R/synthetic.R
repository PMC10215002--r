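#' Seed placement layout
#'
#' Positions of seed centers in the measurement plane.  Standard patterns:
#' a single seed at the field center, and square 3 x 3 / 5 x 5 arrays at a
#' given pitch (5 mm by default, typical inter-seed spacing in a prostate
#' implant; the close-contact slab geometry uses smaller pitches).
#'
#' @param pattern `"single"`, `"grid3x3"`, `"grid5x5"` or `"custom"`.
#' @param pitch Center-to-center spacing for grid patterns, mm.
#' @param positions For `pattern = "custom"`: two-column matrix of
#'   `(x, y)` seed centers, mm.
#' @param center `(x, y)` of the layout center, mm.
#' @return An object of class `seed_layout` with a `positions` matrix.
#' @export
seed_layout <- function(pattern = c("single", "grid3x3", "grid5x5", "custom"),
                        pitch = 5, positions = NULL, center = c(0, 0)) {
  pattern <- match.arg(pattern)
  if (pattern == "custom") {
    if (is.null(positions)) stop("custom layout needs `positions`")
    positions <- as.matrix(positions)
    if (ncol(positions) != 2L) stop("`positions` must be an (x, y) matrix")
  } else {
    stopifnot(pitch > 0)
    k <- switch(pattern, single = 0L, grid3x3 = 1L, grid5x5 = 2L)
    g <- (-k):k * pitch
    positions <- as.matrix(expand.grid(x = g + center[1L],
                                       y = g + center[2L]))
  }
  if (anyDuplicated(positions)) stop("duplicate seed positions")
  structure(list(pattern = pattern, pitch = pitch,
                 positions = unname(positions)),
            class = "seed_layout")
}

#' @export
print.seed_layout <- function(x, ...) {
  cat(sprintf("<seed_layout> %s, %d seeds, pitch %.3g mm\n",
              x$pattern, nrow(x$positions), x$pitch))
  invisible(x)
}

#' Flat reference field with penumbra
#'
#' Builds a square open-field dose map: an exact plateau at `dose` inside
#' the field, a raised-cosine falloff of total width `penumbra_mm` centered
#' on each field edge, and exactly zero outside.  `penumbra_mm = 0` gives a
#' hard step.  The plateau is exactly flat, so flat-area normalization of a
#' band inside it is an identity up to scale.
#'
#' @param size_mm Full grid side length, mm.
#' @param spacing_mm Pixel pitch, mm (default 25.4/150, a 150 dpi scan).
#' @param field_half_width_mm Half-width of the field, mm (50 mm emulates a
#'   10 x 10 cm2 field).
#' @param penumbra_mm Total width of the edge falloff, mm.
#' @param dose Plateau value (percent).
#' @return A [dose_map()] centered on the isocenter; `meta` records the
#'   field geometry.
#' @export
make_flat_field <- function(size_mm = 130, spacing_mm = 25.4 / 150,
                            field_half_width_mm = 50, penumbra_mm = 3,
                            dose = 100) {
  stopifnot(spacing_mm > 0, penumbra_mm >= 0, field_half_width_mm > 0,
            dose > 0)
  if (field_half_width_mm * 2 > size_mm)
    stop("field does not fit in the grid: need size_mm >= ",
         2 * field_half_width_mm)
  nh <- floor(size_mm / 2 / spacing_mm)
  coords <- (-nh):nh * spacing_mm
  edge <- field_edge_factor(abs(coords), field_half_width_mm, penumbra_mm)
  values <- dose * outer(edge, edge) # rows = y, cols = x
  dose_map(values, spacing_mm,
           c(coords[1L], coords[1L]),
           meta = list(field_half_width_mm = field_half_width_mm,
                       penumbra_mm = penumbra_mm, dose = dose))
}

# 1 on the plateau, raised-cosine over [fhw - p/2, fhw + p/2], 0 outside
field_edge_factor <- function(r, fhw, p) {
  if (p == 0) return(as.numeric(r <= fhw))
  inner <- fhw - p / 2
  out <- numeric(length(r))
  out[r <= inner] <- 1
  tr <- r > inner & r < fhw + p / 2
  out[tr] <- 0.5 * (1 + cos(pi * (r[tr] - inner) / p))
  out
}

#' Inject seed perturbations into a dose map
#'
#' Adds one localized perturbation per seed whose cross-plane section
#' through the seed center equals the seed's composite Gaussian-Lorentzian
#' perturbation term exactly: positive for the build-up (BU) plane,
#' negative for build-down (BD).  Overlapping footprints add linearly.
#'
#' Two footprint geometries:
#' \describe{
#'   \item{`"capsule"` (default)}{The cross-plane term is extruded along
#'     the in-plane (y) axis over the physical length of the seed's X-ray
#'     marker (`seed_length_mm`), with cosine end caps tapering to zero
#'     1 mm beyond it.  This emulates the elongated footprint a cylindrical
#'     marker rod leaves on an orthogonal film, and means every pixel row
#'     within `seed_length_mm / 2` of the seed center carries the identical
#'     cross-plane section -- so band averaging over the capsule core
#'     suppresses pixel noise without attenuating the truth.}
#'   \item{`"radial"`}{A radially symmetric footprint, `term(r)` with `r`
#'     the distance to the seed center; only the single row through the
#'     seed center reproduces the 1D term.}
#' }
#' In both geometries the in-plane/cross-plane tails are tapered smoothly
#' to zero between `cutoff_mm - 1` and `cutoff_mm`, reflecting the
#' observed confinement of seed perturbations to a few mm and keeping
#' footprints at typical (>= 5 mm) pitches exactly non-interacting.
#'
#' @param map A [dose_map()] (typically from [make_flat_field()]).
#' @param layout A [seed_layout()]; every seed must sit on the field
#'   plateau when the map records its field geometry.
#' @param truth List of [peak_model()]s, one per seed (a single model is
#'   recycled).  The model's amplitudes and widths shape the footprint; its
#'   `mu` and `sign` are ignored (the seed position and `plane` rule).
#' @param plane `"BU"` (positive) or `"BD"` (negative).
#' @param cutoff_mm Cross-plane support half-width, mm (taper over the
#'   last 1 mm).
#' @param footprint `"capsule"` or `"radial"`.
#' @param seed_length_mm Uniform core length of the capsule footprint, mm
#'   (about the length of a seed capsule).
#' @return The map with perturbations added; truth parameters are in
#'   `meta$truth`.
#' @export
inject_perturbations <- function(map, layout, truth, plane = c("BU", "BD"),
                                 cutoff_mm = 5,
                                 footprint = c("capsule", "radial"),
                                 seed_length_mm = 4.5) {
  stopifnot(is_dose_map(map), inherits(layout, "seed_layout"),
            cutoff_mm > 1, seed_length_mm > 0)
  plane <- match.arg(plane)
  footprint <- match.arg(footprint)
  n <- nrow(layout$positions)
  if (n == 0L) return(map)
  if (inherits(truth, "peak_model")) truth <- list(truth)
  if (length(truth) == 1L) truth <- rep(truth, n)
  if (length(truth) != n)
    stop(sprintf("truth list has %d models for %d seeds", length(truth), n))
  stopifnot(all(vapply(truth, inherits, TRUE, "peak_model")))

  fhw <- map$meta$field_half_width_mm
  pen <- map$meta$penumbra_mm %||% 0
  if (!is.null(fhw)) {
    lim <- fhw - pen / 2
    if (any(abs(layout$positions) > lim))
      stop("seed positions must lie on the field plateau (|x|,|y| <= ",
           format(lim), " mm)")
  }

  sgn <- if (plane == "BU") +1 else -1
  xs <- dose_map_x(map)
  ys <- dose_map_y(map)
  v <- map$values
  half_len <- seed_length_mm / 2
  for (k in seq_len(n)) {
    sx <- layout$positions[k, 1L]; sy <- layout$positions[k, 2L]
    m <- truth[[k]]
    centered <- peak_model(F0 = 0, M = m$M, H_G = m$H_G, H_L = m$H_L,
                           W_G = m$W_G, W_L = m$W_L, mu = 0, sign = +1)
    if (footprint == "radial") {
      ci <- which(abs(xs - sx) <= cutoff_mm)
      ri <- which(abs(ys - sy) <= cutoff_mm)
      if (!length(ci) || !length(ri)) next
      r <- sqrt(outer((ys[ri] - sy)^2, (xs[ci] - sx)^2, `+`))
      term <- perturbation_term(centered, as.vector(r)) *
        taper_factor(as.vector(r), cutoff_mm)
      v[ri, ci] <- v[ri, ci] + sgn * matrix(term, nrow = length(ri))
    } else {
      ci <- which(abs(xs - sx) <= cutoff_mm)
      ri <- which(abs(ys - sy) <= half_len + 1)
      if (!length(ci) || !length(ri)) next
      ux <- abs(xs[ci] - sx)
      section <- perturbation_term(centered, ux) *
        taper_factor(ux, cutoff_mm)
      axial <- end_cap_factor(abs(ys[ri] - sy), half_len)
      v[ri, ci] <- v[ri, ci] + sgn * outer(axial, section)
    }
  }
  out <- map
  out$values <- v
  out$meta$plane <- plane
  out$meta$truth <- truth
  out$meta$layout <- layout
  out
}

# capsule axial profile: 1 over the marker core, cosine cap over 1 mm
end_cap_factor <- function(dy, half_len) {
  out <- numeric(length(dy))
  out[dy <= half_len] <- 1
  tr <- dy > half_len & dy < half_len + 1
  out[tr] <- 0.5 * (1 + cos(pi * (dy[tr] - half_len)))
  out
}

# smooth compact-support taper: 1 for r <= cut-1, cosine to 0 at r = cut
taper_factor <- function(r, cutoff) {
  out <- numeric(length(r))
  out[r <= cutoff - 1] <- 1
  tr <- r > cutoff - 1 & r < cutoff
  out[tr] <- 0.5 * (1 + cos(pi * (r[tr] - (cutoff - 1))))
  out
}

#' Add film-like pixel noise
#'
#' Adds independent zero-mean Gaussian noise with per-pixel standard
#' deviation `sd_percent` of the local value (multiplicative noise, so
#' near-zero regions stay near zero).  2 percent emulates the overall
#' film-dosimetry uncertainty scale.  Bit-reproducible given `rng_seed`;
#' the caller's RNG state is untouched.
#'
#' @param map A [dose_map()].
#' @param sd_percent Relative noise level, percent (`>= 0`).
#' @param rng_seed Integer seed.
#' @return The noisy map.
#' @export
add_noise <- function(map, sd_percent, rng_seed) {
  stopifnot(is_dose_map(map), sd_percent >= 0)
  if (sd_percent == 0) return(map)
  v <- map$values
  eps <- local_rng(rng_seed, stats::rnorm(length(v)))
  map$values <- v + (sd_percent / 100) * v * matrix(eps, nrow = nrow(v))
  map
}

#' Synthetic scene configuration
#'
#' The stated world of the generator: a flat 10 x 10 cm2 field (plateau
#' 100 percent, half-width 50 mm) sampled at the 150 dpi film pitch, with
#' per-seed composite perturbations whose amplitudes and widths default to
#' the measured regime (|amplitude| 5-23 percent, FWHM 0.5-2.2 mm) and
#' pixel noise at the film-uncertainty level (2 percent).
#'
#' @param layout A [seed_layout()].
#' @param truth List of [peak_model()]s, one per seed, or `NULL` to draw
#'   them with [sample_peak_models()] from `rng_seed`.
#' @param plane `"BU"` or `"BD"`.
#' @param noise_sd Pixel noise, percent.
#' @param rng_seed Integer seed for truth draws and both noise fields.
#' @param size_mm,spacing_mm,field_half_width_mm,penumbra_mm,dose Field
#'   geometry, see [make_flat_field()].
#' @param amp_range,width_range Sampling ranges for drawn truth models.
#' @param footprint,seed_length_mm Footprint geometry, see
#'   [inject_perturbations()].
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(layout = seed_layout("single"),
                         truth = NULL,
                         plane = c("BU", "BD"),
                         noise_sd = 2,
                         rng_seed = 1,
                         size_mm = 130, spacing_mm = 25.4 / 150,
                         field_half_width_mm = 50, penumbra_mm = 3,
                         dose = 100,
                         amp_range = c(5, 23), width_range = c(0.5, 2.2),
                         footprint = c("capsule", "radial"),
                         seed_length_mm = 4.5) {
  plane <- match.arg(plane)
  footprint <- match.arg(footprint)
  stopifnot(inherits(layout, "seed_layout"), noise_sd >= 0)
  structure(list(layout = layout, truth = truth, plane = plane,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed),
                 size_mm = size_mm, spacing_mm = spacing_mm,
                 field_half_width_mm = field_half_width_mm,
                 penumbra_mm = penumbra_mm, dose = dose,
                 amp_range = amp_range, width_range = width_range,
                 footprint = footprint, seed_length_mm = seed_length_mm),
            class = "scene_config")
}

#' Draw random ground-truth peak models
#'
#' Total amplitude uniform on `amp_range`, Lorentzian ratio M uniform on
#' `[0, 1]`, both component FWHM uniform on `width_range`, center `mu`
#' uniform on `mu_range`, offset 0.
#'
#' @param n Number of models.
#' @param amp_range,width_range,mu_range Sampling intervals.
#' @param sign `+1` or `-1` for all models.
#' @param rng_seed Integer seed.
#' @return List of `n` [peak_model()]s.
#' @export
sample_peak_models <- function(n, amp_range = c(5, 23),
                               width_range = c(0.5, 2.2),
                               mu_range = c(0, 0), sign = +1, rng_seed = 1) {
  local_rng(rng_seed, {
    lapply(seq_len(n), function(i) {
      amp <- stats::runif(1, amp_range[1L], amp_range[2L])
      M <- stats::runif(1)
      peak_model_from_amplitudes(
        F0 = 0, A_G = (1 - M) * amp, A_L = M * amp,
        W_G = stats::runif(1, width_range[1L], width_range[2L]),
        W_L = stats::runif(1, width_range[1L], width_range[2L]),
        mu = stats::runif(1, mu_range[1L], mu_range[2L]), sign = sign)
    })
  })
}

#' Generate a paired reference/seeded scene
#'
#' Builds the reference map (flat field plus noise) and the seeded map
#' (same flat field plus the injected perturbations plus an independent
#' noise draw).  The two maps differ only by the perturbation terms and
#' their noise realizations; the recorded truth regenerates the noiseless
#' seeded map bit-exactly.
#'
#' @param config A [scene_config()].
#' @return List of class `synthetic_scene`: `ref` and `seeded`
#'   [dose_map()]s, `truth` (list of [peak_model()]s), `config`.
#' @export
make_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  flat <- make_flat_field(config$size_mm, config$spacing_mm,
                          config$field_half_width_mm, config$penumbra_mm,
                          config$dose)
  # snap seed centers to pixel centers so the cross-plane section through a
  # seed row is exactly the 1D composite term (truth comparisons rely on it)
  config$layout$positions <-
    round(config$layout$positions / config$spacing_mm) * config$spacing_mm
  if (anyDuplicated(config$layout$positions))
    stop("seed positions collide after snapping to the pixel grid")
  n <- nrow(config$layout$positions)
  truth <- config$truth
  if (is.null(truth))
    truth <- sample_peak_models(n, config$amp_range, config$width_range,
                                sign = if (config$plane == "BU") +1 else -1,
                                rng_seed = config$rng_seed)
  seeded <- inject_perturbations(flat, config$layout, truth, config$plane,
                                 footprint = config$footprint,
                                 seed_length_mm = config$seed_length_mm)
  ref <- add_noise(flat, config$noise_sd, config$rng_seed)
  seeded <- add_noise(seeded, config$noise_sd, config$rng_seed + 1L)
  structure(list(ref = ref, seeded = seeded, truth = truth,
                 config = config),
            class = "synthetic_scene")
}

#' Truth record of a scene as a data frame
#'
#' One row per seed: position, sign, amplitudes, widths, and the composite
#' FWHM the analysis should recover.
#'
#' @param scene A `synthetic_scene` from [make_scene()].
#' @return A data frame.
#' @export
scene_truth_table <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  pos <- scene$config$layout$positions
  do.call(rbind, lapply(seq_along(scene$truth), function(k) {
    m <- scene$truth[[k]]
    a <- peak_amplitudes(m)
    data.frame(seed = k, x_mm = pos[k, 1L], y_mm = pos[k, 2L],
               sign = m$sign,
               amplitude_percent = sum(a),
               A_G = a[[1L]], A_L = a[[2L]], M = m$M,
               W_G_mm = m$W_G, W_L_mm = m$W_L,
               fwhm_mm = peak_fwhm(m))
  }))
}
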