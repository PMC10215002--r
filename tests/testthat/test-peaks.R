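test_that("model evaluation satisfies the analytic half-maximum identities", {
  for (rep in 1:20) {
    set.seed(rep)
    F0 <- runif(1, -2, 2); H <- runif(1, 1, 20)
    W <- runif(1, 0.3, 3); mu <- runif(1, -1, 1)
    s <- sample(c(-1, 1), 1)
    gauss <- peak_model(F0 = F0, M = 0, H_G = H, W_G = W, W_L = 1,
                        mu = mu, sign = s)
    expect_equal(evaluate_model(gauss, mu + W / 2), F0 + s * H / 2,
                 tolerance = 1e-12)
    expect_equal(evaluate_model(gauss, mu - W / 2), F0 + s * H / 2,
                 tolerance = 1e-12)
    lor <- peak_model(F0 = F0, M = 1, H_L = H, W_L = W, W_G = 1,
                      mu = mu, sign = s)
    expect_equal(evaluate_model(lor, mu + W / 2), F0 + s * H / 2,
                 tolerance = 1e-12)
    expect_equal(evaluate_model(lor, mu - W / 2), F0 + s * H / 2,
                 tolerance = 1e-12)
  }
})

test_that("the model peak value is offset plus signed amplitude", {
  set.seed(31)
  for (rep in 1:20) {
    M <- runif(1); HG <- runif(1, 0, 15); HL <- runif(1, 0, 15)
    s <- sample(c(-1, 1), 1)
    m <- peak_model(F0 = runif(1, -3, 3), M = M, H_G = HG, H_L = HL,
                    W_G = runif(1, 0.2, 3), W_L = runif(1, 0.2, 3),
                    mu = runif(1, -2, 2), sign = s)
    expect_equal(evaluate_model(m, m$mu),
                 m$F0 + s * ((1 - M) * HG + M * HL), tolerance = 1e-12)
    a <- peak_amplitudes(m)
    expect_equal(unname(a[1] + a[2]), (1 - M) * HG + M * HL)
  }
})

test_that("peak_model validates parameters", {
  expect_error(peak_model(M = 1.2))
  expect_error(peak_model(H_G = -1))
  expect_error(peak_model(W_G = 0))
  expect_error(peak_model(sign = 0))
  # amplitude-parameterized constructor reproduces the same curve
  m <- peak_model_from_amplitudes(A_G = 3, A_L = 5, W_G = 1.2, W_L = 0.7)
  expect_equal(m$M, 5 / 8)
  expect_equal(unname(peak_amplitudes(m)), c(3, 5))
})

test_that("composite FWHM has exact single-component limits", {
  expect_equal(peak_fwhm(peak_model(M = 0, H_G = 5, W_G = 1.7)), 1.7,
               tolerance = 1e-6)
  expect_equal(peak_fwhm(peak_model(M = 1, H_L = 5, W_L = 0.8)), 0.8,
               tolerance = 1e-6)
  expect_error(peak_fwhm(peak_model(M = 0, H_G = 0)), "amplitude is zero")
})

test_that("composite FWHM matches the dense-scan oracle on mixtures", {
  cases <- list(c(M = 0.5, WG = 2, WL = 1),
                c(M = 0.3, WG = 0.6, WL = 1.8),
                c(M = 0.8, WG = 1.1, WL = 0.5))
  for (cs in cases) {
    m <- peak_model(M = cs[["M"]], H_G = 6, H_L = 6,
                    W_G = cs[["WG"]], W_L = cs[["WL"]])
    expect_equal(peak_fwhm(m), fwhm_scan_oracle(m), tolerance = 1e-4)
  }
})

test_that("composite FWHM lies between the component widths", {
  set.seed(17)
  for (rep in 1:40) {
    m <- peak_model(M = runif(1), H_G = runif(1, 1, 10),
                    H_L = runif(1, 1, 10), W_G = runif(1, 0.3, 3),
                    W_L = runif(1, 0.3, 3))
    if (sum(peak_amplitudes(m)) == 0) next
    f <- peak_fwhm(m)
    expect_gte(f, min(m$W_G, m$W_L) - 1e-6)
    expect_lte(f, max(m$W_G, m$W_L) + 1e-6)
  }
})

test_that("composite FWHM is non-decreasing in M when W_G < W_L", {
  for (w in list(c(0.5, 1.5), c(1, 2), c(0.8, 2.2))) {
    fw <- vapply(seq(0, 1, 0.1), function(M)
      peak_fwhm(peak_model(M = M, H_G = 7, H_L = 7,
                           W_G = w[1], W_L = w[2])), 0)
    expect_true(all(diff(fw) >= -1e-9))
  }
})

test_that("locate_peak finds extrema and applies the documented tie rule", {
  x <- seq(-5, 5, 0.1)
  bump <- perturbation_profile(x, 8 * exp(-4 * log(2) * x^2))
  expect_equal(locate_peak(bump), list(mu0 = 0, sign = 1))
  dip <- perturbation_profile(x, -11 * exp(-4 * log(2) * ((x - 1.2) / 0.8)^2))
  loc <- locate_peak(dip)
  expect_equal(loc$mu0, 1.2)
  expect_equal(loc$sign, -1)
  # two equal-height bumps at +/- 0.5: tie broken toward negative x
  twin <- perturbation_profile(x, 5 * (abs(abs(x) - 0.5) < 1e-9))
  loc2 <- locate_peak(twin)
  # exhaustive scan oracle: max |delta|, ties by |x| then by x
  d <- twin$delta
  cand <- which(abs(d) == max(abs(d)))
  cand <- cand[order(abs(x[cand]), x[cand])]
  expect_equal(loc2$mu0, x[cand[1]])
  expect_equal(loc2$mu0, -0.5)
  expect_error(locate_peak(perturbation_profile(x, 0 * x)), "no peak")
  expect_error(locate_peak(bump, 0.5, center_mm = 100), "no samples")
})

test_that("fit_peak recovers a known noiseless model", {
  truth <- peak_model(F0 = 0, M = 0.4, H_G = 8, H_L = 8,
                      W_G = 1.6, W_L = 0.9, mu = 0, sign = +1)
  fit <- fit_peak(profile_from_model(truth), 0, +1, seed = 5)
  expect_true(fit$converged)
  expect_equal(fit$dose_difference, 8, tolerance = 1e-3)
  expect_equal(fit$fwhm, fwhm_scan_oracle(truth), tolerance = 1e-3)
  # optimality: the returned SSE cannot exceed the generating model's
  expect_lte(fit$sse, 1e-6)
})

test_that("fit_peak handles the null profile and enforces preconditions", {
  x <- seq(-2.5, 2.5, 0.1)
  null <- perturbation_profile(x, numeric(length(x)))
  fit <- fit_peak(null, 0, +1, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$dose_difference), 1e-6)
  expect_error(fit_peak(perturbation_profile(x[1:5], 1:5 / 5), 0, +1),
               ">= 8")
})

test_that("build-down fits report negative dose differences", {
  truth <- peak_model(F0 = 0, M = 0.3, H_G = 11.3, H_L = 11.3,
                      W_G = 0.8, W_L = 0.8, mu = 0, sign = -1)
  fit <- fit_peak(profile_from_model(truth), 0, -1, seed = 4)
  expect_lt(fit$dose_difference, 0)
  expect_equal(fit$dose_difference, -11.3, tolerance = 1e-3)
})

test_that("fit_peak is deterministic given its seed", {
  truth <- peak_model_from_amplitudes(A_G = 6, A_L = 4, W_G = 1.4,
                                      W_L = 0.7)
  pp <- profile_from_model(truth)
  f1 <- fit_peak(pp, 0, +1, seed = 99)
  f2 <- fit_peak(pp, 0, +1, seed = 99)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$sse, f2$sse)
})

test_that("noisy profiles are recovered with small bias", {
  # 2 percent noise on the profile, true height 10: bias over replicates
  truth <- peak_model_from_amplitudes(A_G = 5, A_L = 5, W_G = 1.5,
                                      W_L = 0.8)
  x <- seq(-2.5, 2.5, 0.1)
  base <- evaluate_model(truth, x)
  errs <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    pp <- perturbation_profile(x, base + rnorm(length(x), 0, 2))
    fit_peak(pp, 0, +1, seed = i)$dose_difference - 10
  }, 0)
  expect_lt(abs(mean(errs)), 1.5)
})

test_that("summarize_cluster computes mean and n-1 standard deviation", {
  mk <- function(dd, fw) structure(list(dose_difference = dd, fwhm = fw),
                                   class = "peak_fit")
  s <- summarize_cluster(list(mk(-10, 0.8), mk(-12, 0.6)))
  expect_equal(s$mean_dd, -11)
  expect_equal(s$sd_dd, sqrt(2))
  expect_equal(s$mean_fwhm, 0.7)
  same <- summarize_cluster(list(mk(5, 1), mk(5, 1), mk(5, 1)))
  expect_equal(same$sd_dd, 0)
  expect_equal(same$sd_fwhm, 0)
  expect_error(summarize_cluster(list(mk(1, 1))), ">= 2")
})
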