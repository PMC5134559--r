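#' Measurement-noise specification for synthetic spectra
#'
#' Proportional complex Gaussian noise: each impedance sample is multiplied
#' by `1 + eps` with `eps = sigma * (N1 + i*N2)`, `N1`, `N2` independent
#' standard normals. An optional loop artifact emulates the
#' negative-differential-resistance Nyquist loops seen in flow-through
#' measurements: below `loop_onset_hz` the trace is pulled back toward the
#' origin, shrinking linearly in log-frequency down to a fraction
#' `loop_foldback` at the bottom of the sweep.
#'
#' @param relative_sigma per-component relative noise level (>= 0).
#' @param seed integer RNG seed.
#' @param loop_onset_hz onset frequency of the loop artifact, or `NULL`
#'   for none.
#' @param loop_foldback fractional fold-back of the loop at the lowest
#'   frequency (e.g. 0.1 for a 10 percent fold).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(relative_sigma = 0.01, seed = 1L,
                       loop_onset_hz = NULL, loop_foldback = 0) {
  stopifnot(relative_sigma >= 0, loop_foldback >= 0)
  structure(list(relative_sigma = relative_sigma, seed = as.integer(seed),
                 loop_onset_hz = loop_onset_hz,
                 loop_foldback = loop_foldback),
            class = "noise_spec")
}

#' Simulate a measured spectrum from circuit parameters
#'
#' Forward-evaluates the circuit and applies the noise model. With
#' `relative_sigma = 0` and no loop artifact the result is bit-identical
#' to [spectrum_from_params()]; with a fixed seed the output is
#' reproducible.
#'
#' @inheritParams spectrum_from_params
#' @param noise a [noise_spec].
#' @return An [impedance_spectrum].
#' @export
simulate_spectrum <- function(params, grid = default_frequency_grid(),
                              noise = noise_spec(),
                              variant = c("full", "simplified"),
                              label = "") {
  variant <- match.arg(variant)
  sp <- spectrum_from_params(params, grid, variant, label = label)
  z <- sp$z
  f <- sp$frequency_hz
  if (noise$relative_sigma > 0) {
    eps <- with_seed(noise$seed, {
      complex(real = stats::rnorm(length(z), 0, noise$relative_sigma),
              imaginary = stats::rnorm(length(z), 0, noise$relative_sigma))
    })
    z <- z * (1 + eps)
  }
  if (!is.null(noise$loop_onset_hz) && noise$loop_foldback > 0) {
    below <- which(f < noise$loop_onset_hz)
    if (length(below)) {
      i0 <- min(below) - 1L
      z0 <- if (i0 >= 1L) z[i0] else z[min(below)]
      lf <- log10(f[below])
      prog <- (log10(noise$loop_onset_hz) - lf) /
        (log10(noise$loop_onset_hz) - min(lf))
      # stylised loop: the sub-onset trace collapses toward the origin
      # instead of rising, so Re(Z) folds back with decreasing frequency
      z[below] <- z0 * (1 - noise$loop_foldback * prog)
    }
  }
  impedance_spectrum(f, z, label = label)
}

#' Fed-batch cultivation scenario
#'
#' Defines a simulated cultivation: piecewise-exponential biomass growth (a
#' batch phase at `mu_batch` followed by a slower, feed-controlled phase at
#' `mu_fedbatch`), the true linear map from biomass to the double-layer CPE
#' coefficient, and anchor values pinning how the remaining double-layer
#' parameters move with biomass. The defaults span 1 to about 40 g/L, the
#' biomass range over which the sensor was characterised.
#'
#' @param x0 initial biomass, g/L.
#' @param mu_batch batch-phase specific growth rate, 1/h.
#' @param t_batch batch-phase duration, h.
#' @param mu_fedbatch fed-batch specific growth rate, 1/h.
#' @param t_fedbatch fed-batch duration, h.
#' @param sampling_interval spectrum sampling interval, h.
#' @param calib_true numeric `c(slope_k, intercept_q0)`: the true
#'   `Q_dl = slope_k * dcw + intercept_q0` map. The default slope is the
#'   resuspension-calibration slope 1.8e-7 F s^(n-1) per g/L; the intercept
#'   is set so `Q_dl(1 g/L)` equals the low-biomass reference value
#'   1.62e-5.
#' @param rdl_anchors numeric `c(r_at_1, r_at_25)`: double-layer resistance
#'   at 1 and 25 g/L; `log10(R_dl)` interpolates linearly in biomass
#'   between (and extrapolates beyond) these anchors.
#' @return An object of class `cultivation_scenario`.
#' @export
cultivation_scenario <- function(x0 = 1, mu_batch = 0.55, t_batch = 4,
                                 mu_fedbatch = 0.10, t_fedbatch = 15,
                                 sampling_interval = 0.5,
                                 calib_true = c(slope_k = 1.8e-7,
                                                intercept_q0 = 1.602e-5),
                                 rdl_anchors = c(r_at_1 = 4.44e6,
                                                 r_at_25 = 3.95e5)) {
  stopifnot(x0 > 0, mu_batch > 0, mu_fedbatch > 0, t_batch >= 0,
            t_fedbatch >= 0, sampling_interval > 0,
            length(calib_true) == 2, length(rdl_anchors) == 2,
            all(rdl_anchors > 0))
  x_end <- x0 * exp(mu_batch * t_batch + mu_fedbatch * t_fedbatch)
  if (x0 < 0.1 || x_end > 50) {
    stop("biomass must stay within 0.1-50 g/L over the scenario ",
         "(ends at ", signif(x_end, 3), " g/L)", call. = FALSE)
  }
  structure(list(x0 = x0, mu_batch = mu_batch, t_batch = t_batch,
                 mu_fedbatch = mu_fedbatch, t_fedbatch = t_fedbatch,
                 sampling_interval = sampling_interval,
                 calib_true = c(slope_k = unname(calib_true[1L]),
                                intercept_q0 = unname(calib_true[2L])),
                 rdl_anchors = c(r_at_1 = unname(rdl_anchors[1L]),
                                 r_at_25 = unname(rdl_anchors[2L]))),
            class = "cultivation_scenario")
}

#' @export
print.cultivation_scenario <- function(x, ...) {
  cat("Fed-batch scenario: x0 =", x$x0, "g/L; batch mu =", x$mu_batch,
      "/h for", x$t_batch, "h; fed-batch mu =", x$mu_fedbatch, "/h for",
      x$t_fedbatch, "h\n")
  cat("  sampling every", x$sampling_interval, "h; final biomass",
      signif(biomass_trajectory(x, x$t_batch + x$t_fedbatch), 3), "g/L\n")
  invisible(x)
}

#' Biomass time course of a scenario
#'
#' Piecewise exponential growth: `x0 * exp(mu_batch * t)` during the batch
#' phase, continuing continuously at `mu_fedbatch` afterwards.
#'
#' @param scenario a [cultivation_scenario].
#' @param t time(s) in h, within `[0, t_batch + t_fedbatch]`.
#' @return Biomass in g/L.
#' @export
biomass_trajectory <- function(scenario, t) {
  stopifnot(inherits(scenario, "cultivation_scenario"))
  if (any(t < 0 | t > scenario$t_batch + scenario$t_fedbatch)) {
    stop("t outside the cultivation [0, ",
         scenario$t_batch + scenario$t_fedbatch, "] h", call. = FALSE)
  }
  x_batch_end <- scenario$x0 * exp(scenario$mu_batch * scenario$t_batch)
  ifelse(t <= scenario$t_batch,
         scenario$x0 * exp(scenario$mu_batch * t),
         x_batch_end * exp(scenario$mu_fedbatch * (t - scenario$t_batch)))
}

#' Circuit parameters as a function of biomass
#'
#' Maps a biomass value to the full circuit parameter set: `Q_dl` follows
#' the scenario's true calibration line; `log10(R_dl)` interpolates
#' linearly in biomass between the 1 g/L and 25 g/L anchors; `n_dl`
#' interpolates between 0.87 (1 g/L) and 0.82 (25 g/L), clipped to
#' `[0.75, 0.95]`; the setup and media elements are held at their
#' high-biomass reference magnitudes (they do not track biomass).
#'
#' @param dcw biomass, g/L.
#' @param scenario a [cultivation_scenario].
#' @return A [circuit_params] object.
#' @export
params_for_biomass <- function(dcw, scenario = cultivation_scenario()) {
  stopifnot(inherits(scenario, "cultivation_scenario"), length(dcw) == 1L,
            is.finite(dcw), dcw > 0)
  q_dl <- scenario$calib_true[["slope_k"]] * dcw +
    scenario$calib_true[["intercept_q0"]]
  lr1 <- log10(scenario$rdl_anchors[["r_at_1"]])
  lr25 <- log10(scenario$rdl_anchors[["r_at_25"]])
  r_dl <- 10^(lr1 + (dcw - 1) / (25 - 1) * (lr25 - lr1))
  n_dl <- 0.87 + (dcw - 1) / (25 - 1) * (0.82 - 0.87)
  n_dl <- min(max(n_dl, 0.75), 0.95)
  circuit_params(L_setup = 2.18e-6, R_offset = 218.6, R_media = 78.6,
                 C_media = 1.66e-5, R_dl = r_dl, Q_dl = q_dl, n_dl = n_dl)
}

#' Simulate an online-monitored cultivation
#'
#' Produces one record per sampling time: the true biomass from
#' [biomass_trajectory()], the circuit parameters from
#' [params_for_biomass()], and a noisy spectrum from
#' [simulate_spectrum()]. Per-record noise seeds are derived
#' deterministically from `noise$seed`, so a scenario-seed pair fully
#' reproduces the run.
#'
#' @param scenario a [cultivation_scenario].
#' @param noise a [noise_spec].
#' @param grid frequency grid for the simulated spectra.
#' @return An object of class `eis_cultivation`: a list with vectors
#'   `time` (h), `dcw_true` (g/L), list `spectra`, and placeholder vectors
#'   `q_fitted`, `dcw_predicted` (NA until filled by [fit_cultivation()]
#'   and [predict.dcw_calibration()]).
#' @export
simulate_cultivation <- function(scenario = cultivation_scenario(),
                                 noise = noise_spec(),
                                 grid = default_frequency_grid()) {
  stopifnot(inherits(scenario, "cultivation_scenario"),
            inherits(noise, "noise_spec"))
  t_end <- scenario$t_batch + scenario$t_fedbatch
  times <- seq(0, t_end, by = scenario$sampling_interval)
  spectra <- vector("list", length(times))
  dcw <- biomass_trajectory(scenario, times)
  for (k in seq_along(times)) {
    nk <- noise
    nk$seed <- (noise$seed + 7919L * k) %% .Machine$integer.max
    spectra[[k]] <- simulate_spectrum(params_for_biomass(dcw[k], scenario),
                                      grid = grid, noise = nk,
                                      label = sprintf("t=%.2fh", times[k]))
  }
  structure(list(time = times, dcw_true = dcw, spectra = spectra,
                 q_fitted = rep(NA_real_, length(times)),
                 variant = rep(NA_character_, length(times)),
                 dcw_predicted = rep(NA_real_, length(times)),
                 scenario = scenario, noise = noise),
            class = "eis_cultivation")
}

#' @export
print.eis_cultivation <- function(x, ...) {
  cat("Simulated cultivation:", length(x$time), "records over",
      max(x$time), "h;", signif(min(x$dcw_true), 3), "to",
      signif(max(x$dcw_true), 3), "g/L\n")
  if (any(!is.na(x$q_fitted))) {
    cat("  fitted spectra:", sum(!is.na(x$q_fitted)), "of", length(x$time),
        "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.eis_cultivation <- function(x, ...) {
  data.frame(time = x$time, dcw_true = x$dcw_true, q_fitted = x$q_fitted,
             variant = x$variant, dcw_predicted = x$dcw_predicted)
}

#' Fit every spectrum of a simulated cultivation
#'
#' Runs [select_model()] on each record and fills `q_fitted` and `variant`.
#'
#' @param cultivation an `eis_cultivation`.
#' @param config a [fit_config].
#' @return The cultivation with `q_fitted` and `variant` populated.
#' @export
fit_cultivation <- function(cultivation, config = fit_config()) {
  stopifnot(inherits(cultivation, "eis_cultivation"))
  for (k in seq_along(cultivation$spectra)) {
    fit <- select_model(cultivation$spectra[[k]], config)
    cultivation$q_fitted[k] <- fit$params$Q_dl
    cultivation$variant[k] <- fit$variant
  }
  cultivation
}
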