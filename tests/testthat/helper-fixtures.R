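# shared fixtures, all generated in code

# sample a model's perturbation curve on a uniform grid about its center
profile_from_model <- function(model, half_width = 2.5, bin = 0.1) {
  x <- model$mu + seq(-half_width, half_width, by = bin)
  perturbation_profile(round(x, 9), evaluate_model(model, x))
}

# dense-scan FWHM oracle, independent of the bisection path: evaluate the
# perturbation term on a fine grid and take the first half-crossing
fwhm_scan_oracle <- function(model, step = 1e-5) {
  amp <- sum(peak_amplitudes(model))
  half <- amp / 2
  upper <- 3 * max(model$W_G, model$W_L)
  repeat {
    x <- seq(0, upper, by = step)
    vals <- seedperturb:::perturbation_term(model, model$mu + x)
    i <- which(vals < half)
    if (length(i)) break
    upper <- upper * 2
  }
  # crossing between samples i-1 and i: midpoint, symmetric peak -> 2x
  2 * (x[i[1L]] - step / 2)
}

# small noiseless single-seed scene at MCS-like 0.1 mm resolution
tiny_scene <- function(truth, plane = "BU", noise_sd = 0, rng_seed = 1,
                       spacing_mm = 0.1) {
  make_scene(scene_config(layout = seed_layout("single"),
                          truth = list(truth), plane = plane,
                          noise_sd = noise_sd, rng_seed = rng_seed,
                          spacing_mm = spacing_mm))
}
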