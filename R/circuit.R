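#' Equivalent-circuit parameters
#'
#' Parameter set of the sensor's equivalent circuit: a series inductance and
#' resistance correcting for the measurement setup (`L_setup`, `R_offset`),
#' a parallel RC element for the media contribution (`R_media`, `C_media`),
#' and a parallel connection of a resistance and a constant-phase element
#' for the electrode double layer (`R_dl`, `Q_dl`, `n_dl`). The simplified
#' circuit variant uses only `R_offset`, `Q_dl` and `n_dl`; the remaining
#' fields may then be `NA`.
#'
#' @param L_setup setup inductance, H (>= 0).
#' @param R_offset setup/series resistance, Ohm (> 0).
#' @param R_media media resistance, Ohm (> 0 or NA).
#' @param C_media media capacitance, F (> 0 or NA).
#' @param R_dl double-layer resistance, Ohm (> 0 or NA).
#' @param Q_dl CPE coefficient, F s^(n-1) (> 0).
#' @param n_dl CPE exponent, dimensionless, in (0, 1].
#' @return An object of class `circuit_params` (a named list).
#' @examples
#' # high-biomass parameter magnitudes typical of an E. coli suspension
#' circuit_params(L_setup = 2.18e-6, R_offset = 218.6, R_media = 78.6,
#'                C_media = 1.66e-5, R_dl = 3.95e5, Q_dl = 2.14e-5, n_dl = 0.82)
#' @export
circuit_params <- function(L_setup = 0, R_offset, R_media = NA_real_,
                           C_media = NA_real_, R_dl = NA_real_, Q_dl, n_dl) {
  p <- list(L_setup = as.numeric(L_setup), R_offset = as.numeric(R_offset),
            R_media = as.numeric(R_media), C_media = as.numeric(C_media),
            R_dl = as.numeric(R_dl), Q_dl = as.numeric(Q_dl),
            n_dl = as.numeric(n_dl))
  if (!is.finite(p$L_setup) || p$L_setup < 0) {
    stop("L_setup must be finite and >= 0", call. = FALSE)
  }
  for (nm in c("R_offset", "Q_dl")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(nm, " must be finite and > 0", call. = FALSE)
    }
  }
  if (!is.finite(p$n_dl) || p$n_dl <= 0 || p$n_dl > 1) {
    stop("n_dl must lie in (0, 1]", call. = FALSE)
  }
  for (nm in c("R_media", "C_media", "R_dl")) {
    if (!is.na(p[[nm]]) && (!is.finite(p[[nm]]) || p[[nm]] <= 0)) {
      stop(nm, " must be > 0 (or NA when unused)", call. = FALSE)
    }
  }
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters:\n")
  v <- unlist(x)
  print(signif(v, 4))
  invisible(x)
}

param_names <- function(variant = c("full", "simplified")) {
  variant <- match.arg(variant)
  if (variant == "full") {
    c("L_setup", "R_offset", "R_media", "C_media", "R_dl", "Q_dl", "n_dl")
  } else {
    c("R_offset", "Q_dl", "n_dl")
  }
}

#' Constant-phase-element impedance
#'
#' Impedance of a CPE, `Z = 1 / ((i*omega)^n * Q)` with `omega = 2*pi*f`
#' in rad/s. `n = 1` recovers an ideal capacitor `1/(i*omega*Q)`; the phase
#' angle is `-n * 90` degrees at every frequency.
#'
#' @param Q_dl CPE coefficient, F s^(n-1) (> 0).
#' @param n_dl CPE exponent in (0, 1].
#' @param frequency frequency in Hz (> 0); may be a vector.
#' @return Complex impedance in Ohm, same length as `frequency`.
#' @examples
#' cpe_impedance(2e-5, 1, 1 / (2 * pi))  # ideal 20 uF capacitor at omega = 1
#' @export
cpe_impedance <- function(Q_dl, n_dl, frequency) {
  if (!is.finite(Q_dl) || Q_dl <= 0) stop("Q_dl must be > 0", call. = FALSE)
  if (!is.finite(n_dl) || n_dl <= 0 || n_dl > 1) {
    stop("n_dl must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("frequency must be > 0", call. = FALSE)
  }
  omega <- 2 * pi * frequency
  # (i*omega)^n = omega^n * exp(i*n*pi/2); explicit polar form keeps the
  # phase exact at n = 1 instead of round-tripping through complex log
  denom <- omega^n_dl * complex(modulus = 1, argument = n_dl * pi / 2) * Q_dl
  1 / denom
}

#' Parallel combination of two impedances
#'
#' Returns `z_a * z_b / (z_a + z_b)`. A non-finite argument is treated as an
#' open branch, so the other impedance is returned unchanged.
#'
#' @param z_a,z_b complex impedances, Ohm (vectors recycle as usual).
#' @return Complex impedance of the parallel connection.
#' @export
parallel_impedance <- function(z_a, z_b) {
  z_a <- as.complex(z_a)
  z_b <- as.complex(z_b)
  open_a <- !is.finite(Re(z_a)) | !is.finite(Im(z_a))
  open_b <- !is.finite(Re(z_b)) | !is.finite(Im(z_b))
  s <- z_a + z_b
  if (any(!open_a & !open_b & s == 0)) {
    stop("singular parallel combination: z_a + z_b = 0", call. = FALSE)
  }
  out <- z_a * z_b / s
  out[open_a] <- z_b[open_a]
  out[open_b] <- z_a[open_b]
  out
}

#' Impedance of the full or simplified equivalent circuit
#'
#' Full circuit:
#' `Z = i*omega*L_setup + R_offset + (R_media || 1/(i*omega*C_media)) +
#'  (R_dl || Z_CPE)`.
#' Simplified circuit (used when `R_dl` is not identifiable):
#' `Z = R_offset + Z_CPE`.
#'
#' @param params a [circuit_params] object.
#' @param frequency frequency in Hz (> 0); may be a vector.
#' @param variant `"full"` or `"simplified"`.
#' @return Complex impedance in Ohm.
#' @export
circuit_impedance <- function(params, frequency,
                              variant = c("full", "simplified")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "circuit_params"))
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("frequency must be > 0", call. = FALSE)
  }
  z_cpe <- cpe_impedance(params$Q_dl, params$n_dl, frequency)
  if (variant == "simplified") {
    return(params$R_offset + z_cpe)
  }
  for (nm in c("R_media", "C_media", "R_dl")) {
    if (is.na(params[[nm]])) {
      stop("full circuit needs ", nm, call. = FALSE)
    }
  }
  omega <- 2 * pi * frequency
  z_media <- parallel_impedance(complex(real = params$R_media),
                                1 / (1i * omega * params$C_media))
  z_dl <- parallel_impedance(complex(real = params$R_dl), z_cpe)
  1i * omega * params$L_setup + params$R_offset + z_media + z_dl
}

#' Synthesize a noise-free spectrum from circuit parameters
#'
#' Evaluates [circuit_impedance()] over a frequency grid and wraps the
#' result as an [impedance_spectrum].
#'
#' @inheritParams circuit_impedance
#' @param grid frequency grid in Hz, all positive; see
#'   [default_frequency_grid()].
#' @param label label stored in the spectrum metadata.
#' @return An [impedance_spectrum] with one sample per grid point.
#' @export
spectrum_from_params <- function(params, grid = default_frequency_grid(),
                                 variant = c("full", "simplified"),
                                 label = "") {
  if (length(grid) < 1L) stop("frequency grid must be nonempty", call. = FALSE)
  z <- circuit_impedance(params, grid, variant)
  impedance_spectrum(grid, z, label = label)
}

#' Default logarithmic frequency grid
#'
#' Ten points per decade from 1 MHz down to 0.1 Hz (71 points), the sweep
#' this sensor's measurements use.
#'
#' @param f_max,f_min grid end points in Hz.
#' @param points_per_decade grid density.
#' @return Numeric vector of frequencies in Hz, descending.
#' @export
default_frequency_grid <- function(f_max = 1e6, f_min = 1e-1,
                                   points_per_decade = 10) {
  10^seq(log10(f_max), log10(f_min), by = -1 / points_per_decade)
}

#' Effective double-layer capacitance of an R-CPE element
#'
#' Converts a CPE coefficient into an effective capacitance,
#' `C = (R^(1-n) * Q)^(1/n)`. At `n = 1` this reduces to `C = Q` for any R.
#'
#' @param R_dl double-layer resistance, Ohm (> 0).
#' @param Q_dl CPE coefficient, F s^(n-1) (> 0).
#' @param n_dl CPE exponent in (0, 1]; values below 0.05 are rejected to
#'   guard the `1/n` exponent against overflow.
#' @return Effective capacitance in F.
#' @examples
#' effective_capacitance(3.95e5, 2.14e-5, 0.82)
#' @export
effective_capacitance <- function(R_dl, Q_dl, n_dl) {
  if (any(!is.finite(R_dl)) || any(R_dl <= 0)) stop("R_dl must be > 0", call. = FALSE)
  if (any(!is.finite(Q_dl)) || any(Q_dl <= 0)) stop("Q_dl must be > 0", call. = FALSE)
  if (any(!is.finite(n_dl)) || any(n_dl > 1)) {
    stop("n_dl must lie in (0, 1]", call. = FALSE)
  }
  if (any(n_dl < 0.05)) {
    stop("n_dl below 0.05: effective capacitance would overflow", call. = FALSE)
  }
  (R_dl^(1 - n_dl) * Q_dl)^(1 / n_dl)
}
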