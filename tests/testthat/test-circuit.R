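test_that("CPE impedance reduces to an ideal capacitor at n = 1", {
  # omega = 1 rad/s, Q = 20 uF: Z = 1/(i*omega*C) = -50000i
  z <- cpe_impedance(2e-5, 1, 1 / (2 * pi))
  expect_equal(Re(z), 0)
  expect_equal(Im(z), -50000)
  # phase is exactly -90 degrees at every frequency
  for (f in 10^seq(-1, 6)) {
    expect_equal(Arg(cpe_impedance(3.3e-6, 1, f)), -pi / 2)
  }
})

test_that("CPE impedance matches the polar-form oracle at fractional n", {
  # oracle: 1/((i)^0.5 * 1e-3) with (i)^0.5 = exp(i*pi/4)
  z <- cpe_impedance(1e-3, 0.5, 1 / (2 * pi))
  oracle <- 1000 * exp(-1i * pi / 4)
  expect_equal(z, oracle, tolerance = 1e-12)
  expect_equal(Re(z), 707.10678, tolerance = 1e-6)
  expect_equal(Im(z), -707.10678, tolerance = 1e-6)
})

test_that("CPE phase angle is -n*90 degrees and Im <= 0 across random cases", {
  set.seed(7)
  for (k in 1:25) {
    q <- 10^runif(1, -6, -4)
    n <- runif(1, 0.05, 1)
    f <- 10^runif(1, -1, 6)
    z <- cpe_impedance(q, n, f)
    expect_equal(Arg(z), -n * pi / 2, tolerance = 1e-12)
    expect_lte(Im(z), 0)
  }
})

test_that("CPE impedance rejects non-positive arguments", {
  expect_error(cpe_impedance(0, 0.8, 10), "Q_dl")
  expect_error(cpe_impedance(1e-5, 0, 10), "n_dl")
  expect_error(cpe_impedance(1e-5, 1.2, 10), "n_dl")
  expect_error(cpe_impedance(1e-5, 0.8, -1), "frequency")
})

test_that("parallel combination handles resistors, mixed, open and singular cases", {
  expect_equal(parallel_impedance(1000 + 0i, 1000 + 0i), 500 + 0i)
  # exact complex arithmetic oracle: 1000 || (a - ai), a = 1000/sqrt(2)
  a <- 1000 / sqrt(2)
  num <- 1000 * complex(real = a, imaginary = -a)
  oracle <- num / (1000 + complex(real = a, imaginary = -a))
  got <- parallel_impedance(1000 + 0i, complex(real = a, imaginary = -a))
  expect_equal(got, oracle, tolerance = 1e-14)
  expect_equal(Re(got), 500.0, tolerance = 1e-3)
  expect_equal(Im(got), -207.10678, tolerance = 1e-6)
  # open branch sentinel
  expect_equal(parallel_impedance(42 - 7i, complex(real = Inf)), 42 - 7i)
  expect_error(parallel_impedance(100 + 0i, -100 + 0i), "singular")
})

test_that("full circuit approaches R_offset at high frequency (L = 0)", {
  p <- table1_params_25()
  p$L_setup <- 0
  z <- circuit_impedance(p, 1e12)
  expect_equal(Re(z), 218.6, tolerance = 1e-4)
  expect_lt(abs(Im(z)), 1e-2)
})

test_that("full circuit with n = 1 approaches the sum of resistances at low frequency", {
  p <- circuit_params(L_setup = 0, R_offset = 218.6, R_media = 78.6,
                      C_media = 1.66e-5, R_dl = 3.95e5, Q_dl = 2.14e-5,
                      n_dl = 1)
  z <- circuit_impedance(p, 1e-9)
  expect_equal(Re(z), 218.6 + 78.6 + 3.95e5, tolerance = 1e-6)
})

test_that("simplified circuit is a resistor plus CPE", {
  p <- circuit_params(R_offset = 100, Q_dl = 1e-5, n_dl = 1)
  z <- circuit_impedance(p, 1 / (2 * pi), variant = "simplified")
  expect_equal(z, complex(real = 100, imaginary = -1e5))
  # full variant must refuse to run without the media element
  expect_error(circuit_impedance(p, 10, variant = "full"), "R_media")
})

test_that("spectrum synthesis preserves the grid and matches pointwise evaluation", {
  p <- table1_params_25()
  grid <- default_frequency_grid()
  expect_length(grid, 71L)
  sp <- spectrum_from_params(p, grid)
  expect_s3_class(sp, "impedance_spectrum")
  expect_length(sp, 71L)
  expect_identical(sp$frequency_hz, grid)
  # oracle equivalence: pointwise re-evaluation to machine precision
  expect_identical(sp$z, circuit_impedance(p, grid))
  # single-point grid
  expect_length(spectrum_from_params(p, 42), 1L)
  expect_error(spectrum_from_params(p, numeric(0)), "nonempty")
})

test_that("Nyquist trace rises steeply at low frequency (capacitive tail)", {
  sp <- spectrum_from_params(table1_params_25())
  im_at <- function(f) -Im(sp$z[which.min(abs(sp$frequency_hz - f))])
  expect_gt(im_at(0.1), im_at(10))
  # -Im increases monotonically as frequency decreases below the shoulder
  low <- sp$frequency_hz < 10
  expect_true(all(diff(-Im(sp$z[low])) > 0))
})

test_that("effective capacitance reproduces the reference conversions", {
  # independently computed: (R^(1-n) * Q)^(1/n)
  expect_equal(effective_capacitance(3.95e5, 2.14e-5, 0.82),
               (3.95e5^0.18 * 2.14e-5)^(1 / 0.82), tolerance = 1e-15)
  # reference values printed to 3 significant figures
  expect_equal(effective_capacitance(3.95e5, 2.14e-5, 0.82), 3.42e-5,
               tolerance = 0.005 / 3.42)
  expect_equal(effective_capacitance(4.44e6, 1.62e-5, 0.87), 3.07e-5,
               tolerance = 0.005 / 3.07)
})

test_that("effective capacitance equals Q at n = 1 and increases in Q", {
  set.seed(11)
  for (k in 1:20) {
    r <- 10^runif(1, 1, 8)
    q <- 10^runif(1, -6, -4)
    expect_equal(effective_capacitance(r, q, 1), q)
    # strictly increasing in Q at fixed R, n
    expect_gt(effective_capacitance(r, q * 1.01, 0.85),
              effective_capacitance(r, q, 0.85))
  }
  expect_error(effective_capacitance(1e5, 1e-5, 0.01), "overflow")
})

test_that("circuit_params enforces its invariants", {
  expect_error(circuit_params(R_offset = -1, Q_dl = 1e-5, n_dl = 0.8),
               "R_offset")
  expect_error(circuit_params(R_offset = 100, Q_dl = 1e-5, n_dl = 1.5),
               "n_dl")
  expect_error(circuit_params(L_setup = -1e-6, R_offset = 100, Q_dl = 1e-5,
                              n_dl = 0.8), "L_setup")
  expect_error(circuit_params(R_offset = 100, R_media = -5, Q_dl = 1e-5,
                              n_dl = 0.8), "R_media")
})
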