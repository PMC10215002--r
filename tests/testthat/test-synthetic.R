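test_that("seed layouts have the right multiplicities", {
  expect_equal(nrow(seed_layout("single")$positions), 1)
  expect_equal(nrow(seed_layout("grid3x3")$positions), 9)
  expect_equal(nrow(seed_layout("grid5x5")$positions), 25)
  g <- seed_layout("grid3x3", pitch = 5)
  expect_true(all(g$positions %in% c(-5, 0, 5)))
  expect_error(seed_layout("custom", positions = rbind(c(0, 0), c(0, 0))),
               "duplicate")
  expect_error(seed_layout("custom"), "needs")
})

test_that("make_flat_field produces an exactly flat plateau", {
  f <- make_flat_field(size_mm = 130, spacing_mm = 0.5)
  xs <- dose_map_x(f)
  expect_equal(f$values[abs(dose_map_y(f)) < 1e-9, abs(xs) < 1e-9], 100)
  # plateau (inside field minus half penumbra) is exactly flat
  core <- abs(xs) <= 48.4
  expect_equal(mean(f$values[core, core]), 100, tolerance = 1e-9)
  expect_true(all(f$values[core, core] == 100))
  # hard step when penumbra = 0
  s <- make_flat_field(size_mm = 40, spacing_mm = 1,
                       field_half_width_mm = 10, penumbra_mm = 0)
  expect_true(all(s$values %in% c(0, 100)))
  expect_equal(s$values[abs(dose_map_y(s)) <= 10, abs(dose_map_x(s)) <= 10],
               matrix(100, 21, 21))
  expect_error(make_flat_field(size_mm = 50, field_half_width_mm = 50),
               "does not fit")
})

test_that("penumbra falloff is monotone and compactly supported", {
  f <- make_flat_field(size_mm = 120, spacing_mm = 0.25, penumbra_mm = 4)
  prof <- f$values[abs(dose_map_y(f)) < 1e-9, ]
  xs <- dose_map_x(f)
  right <- prof[xs >= 0]
  expect_true(all(diff(right) <= 1e-12))
  expect_true(all(prof[abs(xs) >= 52] == 0))
})

test_that("injected perturbations superpose linearly and hit their peak", {
  flat <- make_flat_field(size_mm = 60, spacing_mm = 0.25,
                          field_half_width_mm = 25, penumbra_mm = 0)
  m8 <- peak_model_from_amplitudes(A_G = 8, W_G = 1.2)
  for (fp in c("capsule", "radial")) {
    one <- inject_perturbations(flat, seed_layout("single"), list(m8),
                                plane = "BU", footprint = fp)
    expect_equal(max(one$values), 108)
    ctr <- which(abs(dose_map_x(one)) < 1e-9)
    expect_equal(one$values[ctr, ctr], 108)
  }
  # order independence / joint injection equality (exact)
  la <- seed_layout("custom", positions = cbind(-5, 0))
  lb <- seed_layout("custom", positions = cbind(5, 2))
  mA <- peak_model_from_amplitudes(A_G = 6, W_G = 1)
  mB <- peak_model_from_amplitudes(A_L = 9, W_L = 0.8)
  ab <- inject_perturbations(inject_perturbations(flat, la, list(mA), "BU"),
                             lb, list(mB), "BU")
  ba <- inject_perturbations(inject_perturbations(flat, lb, list(mB), "BU"),
                             la, list(mA), "BU")
  both <- inject_perturbations(
    flat, seed_layout("custom", positions = rbind(c(-5, 0), c(5, 2))),
    list(mA, mB), "BU")
  expect_identical(ab$values, ba$values)
  expect_equal(both$values, ab$values, tolerance = 1e-14)
  # empty layout leaves the map untouched
  none <- inject_perturbations(
    flat, seed_layout("custom", positions = matrix(0, 0, 2)), list(), "BU")
  expect_identical(none$values, flat$values)
  expect_error(inject_perturbations(flat, la, list(mA, mB), "BU"),
               "2 models for 1 seeds")
  expect_error(inject_perturbations(flat,
    seed_layout("custom", positions = cbind(40, 0)), list(mA), "BU"),
    "plateau")
})

test_that("capsule rows within the core carry the exact 1D section", {
  flat <- make_flat_field(size_mm = 60, spacing_mm = 0.25,
                          field_half_width_mm = 25, penumbra_mm = 0)
  truth <- peak_model_from_amplitudes(A_G = 4, A_L = 4, W_G = 1.6,
                                      W_L = 0.9)
  seeded <- inject_perturbations(flat, seed_layout("single"), list(truth),
                                 plane = "BD", footprint = "capsule")
  xs <- dose_map_x(seeded); ys <- dose_map_y(seeded)
  sect <- seedperturb:::perturbation_term(truth, xs) *
    seedperturb:::taper_factor(abs(xs), 5)
  for (y in c(0, 1, 2)) {
    row <- seeded$values[abs(ys - y) < 1e-9, ]
    expect_equal(row - flat$values[abs(ys - y) < 1e-9, ], -sect,
                 tolerance = 1e-12)
  }
  # radial: only the central row matches
  rad <- inject_perturbations(flat, seed_layout("single"), list(truth),
                              plane = "BU", footprint = "radial")
  expect_equal(rad$values[abs(ys) < 1e-9, ] -
                 flat$values[abs(ys) < 1e-9, ], sect, tolerance = 1e-12)
})

test_that("footprints at grid pitches do not interact", {
  flat <- make_flat_field(size_mm = 80, spacing_mm = 0.25,
                          field_half_width_mm = 35, penumbra_mm = 0)
  m <- peak_model_from_amplitudes(A_G = 5, A_L = 5, W_G = 2.2, W_L = 2.2)
  grid <- inject_perturbations(flat, seed_layout("grid3x3", pitch = 10),
                               list(m), "BU")
  single <- inject_perturbations(flat, seed_layout("single"), list(m), "BU")
  ys <- dose_map_y(grid); xs <- dose_map_x(grid)
  # the central seed's near-window is identical to the isolated seed's
  win_r <- abs(ys) <= 2.5; win_c <- abs(xs) <= 2.5
  expect_equal(grid$values[win_r, win_c], single$values[win_r, win_c],
               tolerance = 1e-14)
})

test_that("add_noise is reproducible, local, and correctly scaled", {
  flat <- make_flat_field(size_mm = 40, spacing_mm = 0.25,
                          field_half_width_mm = 18, penumbra_mm = 0)
  expect_identical(add_noise(flat, 0, 1)$values, flat$values)
  n1 <- add_noise(flat, 2, rng_seed = 123)
  n2 <- add_noise(flat, 2, rng_seed = 123)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, add_noise(flat, 2, 124)$values))
  # empirical plateau noise: sd 2.0 +/- 0.1 over >= 1e4 pixels
  core <- abs(dose_map_x(flat)) <= 15
  pix <- n1$values[core, core]
  expect_gte(length(pix), 1e4)
  expect_equal(sd(pix), 2, tolerance = 0.05)
  expect_equal(mean(pix), 100, tolerance = 0.1)
  # caller RNG state is untouched
  set.seed(555); before <- rnorm(1)
  set.seed(555); invisible(add_noise(flat, 2, 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("make_scene pairs differ only by perturbation and noise draws", {
  cfg <- scene_config(layout = seed_layout("single"), noise_sd = 0,
                      truth = list(peak_model_from_amplitudes(
                        A_G = 8, W_G = 1.5)),
                      size_mm = 110, spacing_mm = 0.5,
                      field_half_width_mm = 50)
  sc <- make_scene(cfg)
  # noiseless: seeded minus ref is exactly the injected footprint
  diff <- sc$seeded$values - sc$ref$values
  expect_equal(max(diff), 8)
  expect_true(all(diff >= -1e-12))
  # truth record regenerates the noiseless seeded map bit-exactly
  flat <- make_flat_field(cfg$size_mm, cfg$spacing_mm,
                          cfg$field_half_width_mm, cfg$penumbra_mm)
  again <- inject_perturbations(flat, sc$config$layout, sc$truth, "BU",
                                footprint = cfg$footprint,
                                seed_length_mm = cfg$seed_length_mm)
  expect_identical(again$values, sc$seeded$values)
  # no seeds, no noise: ref equals seeded
  null_cfg <- scene_config(
    layout = seed_layout("custom", positions = matrix(0, 0, 2)),
    truth = list(), noise_sd = 0, size_mm = 110, spacing_mm = 0.5)
  null_sc <- make_scene(null_cfg)
  expect_identical(null_sc$ref$values, null_sc$seeded$values)
})

test_that("scenes are bit-reproducible for a fixed seed", {
  cfg <- scene_config(layout = seed_layout("grid3x3", pitch = 8),
                      noise_sd = 2, rng_seed = 77,
                      size_mm = 110, spacing_mm = 0.5)
  s1 <- make_scene(cfg)
  s2 <- make_scene(cfg)
  expect_identical(s1$ref$values, s2$ref$values)
  expect_identical(s1$seeded$values, s2$seeded$values)
  expect_identical(scene_truth_table(s1), scene_truth_table(s2))
  tt <- scene_truth_table(s1)
  expect_equal(nrow(tt), 9)
  expect_true(all(tt$amplitude_percent >= 5 & tt$amplitude_percent <= 23))
  expect_true(all(tt$W_G_mm >= 0.5 & tt$W_G_mm <= 2.2))
})

test_that("sampled truth models respect their stated ranges", {
  ms <- sample_peak_models(50, amp_range = c(5, 23),
                           width_range = c(0.5, 2.2), sign = -1,
                           rng_seed = 3)
  amps <- vapply(ms, function(m) sum(peak_amplitudes(m)), 0)
  expect_true(all(amps >= 5 & amps <= 23))
  expect_true(all(vapply(ms, `[[`, 0, "sign") == -1))
  expect_identical(
    vapply(sample_peak_models(5, rng_seed = 8), `[[`, 0, "W_G"),
    vapply(sample_peak_models(5, rng_seed = 8), `[[`, 0, "W_G"))
})
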