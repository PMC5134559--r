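test_that("initial guess lands within a decade of the generating parameters", {
  truth <- table1_params_25()
  sp <- spectrum_from_params(truth)
  g <- initial_guess(sp)
  ratio <- unlist(g) / unlist(truth)
  expect_true(all(ratio > 0.1 & ratio < 10))
  # guess respects the parameter invariants / bounds by construction
  b <- default_bounds()
  v <- unlist(g)
  expect_true(all(v >= b$lower[names(v)] & v <= b$upper[names(v)]))
})

test_that("initial guess rejects unusable spectra", {
  f <- default_frequency_grid()
  flat <- impedance_spectrum(f, complex(real = 500, imaginary = -1e-6 * f / f))
  expect_error(initial_guess(flat), "capacitive")
  narrow <- spectrum_from_params(table1_params_25(),
                                 grid = 10^seq(3, 2, by = -0.1))
  expect_error(initial_guess(narrow), "span")
  short <- spectrum_from_params(table1_params_25(), grid = c(1e5, 1e2, 1e-1))
  expect_error(initial_guess(short), "8 samples")
})

test_that("noiseless CNLS round trip recovers all seven parameters", {
  truth <- table1_params_25()
  fit <- fit_circuit(spectrum_from_params(truth))
  expect_true(fit$converged)
  expect_lt(max_rel_err(fit, truth), 1e-6)
  expect_lt(fit$sum_of_squares, 1e-18)
  # perfect fit: error estimates collapse to zero
  expect_true(all(fit$nrmse_percent < 1e-6))
  expect_true(all(parameter_errors(fit) < 1e-6))
})

test_that("chi-squared times degrees of freedom equals the sum of squares", {
  sp <- simulate_spectrum(table1_params_25(), noise = noise_spec(0.01, seed = 4))
  fit <- fit_circuit(sp)
  expect_equal(fit$chi_squared * (2 * fit$n_points - fit$n_free),
               fit$sum_of_squares, tolerance = 1e-14)
  simp <- fit_circuit(sp, "simplified")
  expect_equal(simp$chi_squared * (2 * simp$n_points - simp$n_free),
               simp$sum_of_squares, tolerance = 1e-14)
  expect_identical(simp$n_free, 3L)
})

test_that("accepted Levenberg-Marquardt iterations never increase the objective", {
  sp <- simulate_spectrum(table1_params_25(), noise = noise_spec(0.02, seed = 9))
  fit <- fit_circuit(sp)
  expect_true(all(diff(fit$rss_trace) <= 1e-12 * fit$rss_trace[1]))
})

test_that("modulus weighting makes the fit scale-equivariant", {
  truth <- table1_params_25()
  base <- spectrum_from_params(truth)
  sc <- 40
  scaled <- impedance_spectrum(base$frequency_hz, base$z * sc)
  fit <- fit_circuit(scaled)
  # scaling Z by c maps R, L -> c*R; C, Q -> Q/c; n unchanged
  expect_equal(fit$params$R_offset, truth$R_offset * sc, tolerance = 1e-8)
  expect_equal(fit$params$R_dl, truth$R_dl * sc, tolerance = 1e-8)
  expect_equal(fit$params$Q_dl, truth$Q_dl / sc, tolerance = 1e-8)
  expect_equal(fit$params$n_dl, truth$n_dl, tolerance = 1e-10)
})

test_that("error estimates scale linearly with the noise amplitude", {
  truth <- table1_params_25()
  ratios <- sapply(1:5, function(s) {
    fa <- fit_circuit(simulate_spectrum(truth, noise = noise_spec(0.005, seed = s)))
    fb <- fit_circuit(simulate_spectrum(truth, noise = noise_spec(0.01, seed = s)))
    fb$nrmse_percent[["Q_dl"]] / fa$nrmse_percent[["Q_dl"]]
  })
  expect_gt(median(ratios), 1.7)
  expect_lt(median(ratios), 2.3)
})

test_that("Q_dl error estimate stays small under 1 percent noise at high biomass", {
  truth <- table1_params_25()
  nr <- sapply(1:5, function(s) {
    fit <- fit_circuit(simulate_spectrum(truth, noise = noise_spec(0.01, seed = s)))
    fit$nrmse_percent[["Q_dl"]]
  })
  expect_lt(median(nr), 5)
})

test_that("model selection keeps the full circuit when R_dl is identifiable", {
  sp <- simulate_spectrum(table1_params_25(), noise = noise_spec(0.01, seed = 3))
  fit <- select_model(sp)
  expect_identical(fit$variant, "full")
})

test_that("model selection falls back to the simplified circuit at low biomass with truncated coverage", {
  sp <- simulate_spectrum(table1_params_1(),
                          grid = default_frequency_grid(1e6, 1),
                          noise = noise_spec(0.01, seed = 3))
  fit <- select_model(sp)
  expect_identical(fit$variant, "simplified")
  # the biomass-bearing parameters survive model reduction
  expect_true(is.finite(fit$params$Q_dl))
  expect_true(is.finite(fit$params$n_dl))
})

test_that("an infinite reduction threshold disables the fallback", {
  cfg <- fit_config(rdl_nrmse_threshold = Inf)
  sp <- simulate_spectrum(table1_params_1(),
                          grid = default_frequency_grid(1e6, 1),
                          noise = noise_spec(0.01, seed = 3))
  fit <- select_model(sp, cfg)
  expect_identical(fit$variant, "full")
})

test_that("simplified fits use the sub-media-arc band and recover the CPE", {
  truth <- table1_params_1()
  fit <- fit_circuit(spectrum_from_params(truth), "simplified")
  expect_lte(max(fit$spectrum$frequency_hz), fit$config$simplified_max_hz)
  expect_lt(abs(fit$params$Q_dl / truth$Q_dl - 1), 0.02)
  # the offset absorbs the media resistance below the arc
  expect_lt(abs(fit$params$R_offset - (truth$R_offset + truth$R_media)) /
              truth$R_offset, 0.2)
})

test_that("fit methods are coherent: predict, fitted, residuals, coef, summary", {
  sp <- simulate_spectrum(table1_params_25(), noise = noise_spec(0.01, seed = 2))
  fit <- fit_circuit(sp)
  expect_length(coef(fit), 7L)
  expect_identical(fitted(fit), predict(fit))
  expect_equal(residuals(fit), sp$z - predict(fit))
  expect_length(residuals(fit, type = "weighted"), 2L * length(sp))
  z5 <- predict(fit, frequency = c(1, 10, 100, 1e3, 1e4))
  expect_length(z5, 5L)
  s <- summary(fit)
  expect_gt(s$c_dl, 0)
  expect_output(print(fit), "CNLS")
  reps <- simulate(fit, nsim = 2, seed = 5)
  expect_length(reps, 2L)
  expect_false(identical(reps[[1]]$z, reps[[2]]$z))
})

test_that("fitting refuses spectra with too few samples", {
  sp <- spectrum_from_params(table1_params_25(), grid = c(1e5, 1e3, 1e1))
  expect_error(fit_circuit(sp), "too few|8 samples")
})
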