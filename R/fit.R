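#' Fitting configuration for the CNLS estimator
#'
#' @param weighting residual weighting scheme. `"modulus"` (default) weights
#'   each complex point by `1/|Z|^2`, balancing the several-decade dynamic
#'   range between the media arc and the double-layer branch; `"unit"` uses
#'   no weights; `"proportional"` weights real and imaginary components
#'   separately by their own squared magnitude.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param tolerance relative tolerance on the objective (ftol).
#' @param rdl_nrmse_threshold percent NRMSE of `R_dl` above which
#'   [select_model()] falls back to the simplified circuit. Default 30,
#'   between the error levels observed at identifiable and non-identifiable
#'   double-layer resistances.
#' @param n_starts number of seeded multi-starts around the initial guess.
#' @param seed seed for the multi-start perturbations.
#' @param simplified_max_hz when fitting the simplified circuit, only
#'   samples at or below this frequency are used (default 10 Hz). Below the
#'   media arc the media element is purely resistive and folds into the
#'   series offset, which is exactly what the simplified circuit assumes;
#'   including the arc itself would bias the CPE estimate.
#' @param bounds list with numeric vectors `lower` and `upper` named by
#'   circuit parameter; see [default_bounds()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(weighting = c("modulus", "unit", "proportional"),
                       max_iterations = 100L, tolerance = 1e-12,
                       rdl_nrmse_threshold = 30, n_starts = 5L, seed = 1L,
                       simplified_max_hz = 10, bounds = default_bounds()) {
  weighting <- match.arg(weighting)
  stopifnot(tolerance > 0, max_iterations >= 1, n_starts >= 1,
            rdl_nrmse_threshold > 0, simplified_max_hz > 0,
            all(bounds$lower > 0 | names(bounds$lower) == "L_setup"),
            all(bounds$upper >= bounds$lower))
  structure(list(weighting = weighting,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 rdl_nrmse_threshold = rdl_nrmse_threshold,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 simplified_max_hz = simplified_max_hz,
                 bounds = bounds),
            class = "fit_config")
}

#' Default box bounds for the circuit parameters
#'
#' Wide bounds on the natural scale; all parameters except `n_dl` are
#' optimized in log space, so the lower bounds are strictly positive.
#'
#' @return List with vectors `lower` and `upper`.
#' @export
default_bounds <- function() {
  list(lower = c(L_setup = 1e-12, R_offset = 1e-3, R_media = 1e-3,
                 C_media = 1e-15, R_dl = 1e-1, Q_dl = 1e-12, n_dl = 0.05),
       upper = c(L_setup = 1e-2, R_offset = 1e7, R_media = 1e7,
                 C_media = 1, R_dl = 1e12, Q_dl = 1, n_dl = 1))
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

params_to_vec <- function(params, variant) {
  unlist(params)[param_names(variant)]
}

vec_to_params <- function(theta, variant) {
  p <- list(L_setup = 0, R_offset = NA_real_, R_media = NA_real_,
            C_media = NA_real_, R_dl = NA_real_, Q_dl = NA_real_,
            n_dl = NA_real_)
  p[names(theta)] <- as.list(unname(theta))
  do.call(circuit_params, p)
}

# optimizer space: log for every parameter except n_dl
to_phi <- function(theta) {
  phi <- log(theta)
  phi["n_dl"] <- theta["n_dl"]
  phi
}
from_phi <- function(phi) {
  theta <- exp(phi)
  theta["n_dl"] <- phi["n_dl"]
  theta
}

# component weights (sqrt scale) for the stacked residual vector
residual_weights <- function(z, weighting) {
  n <- length(z)
  eps <- .Machine$double.eps * max(Mod(z))
  switch(weighting,
         unit = list(re = rep(1, n), im = rep(1, n)),
         modulus = {
           w <- 1 / pmax(Mod(z), eps)
           list(re = w, im = w)
         },
         proportional = list(re = 1 / pmax(abs(Re(z)), eps),
                             im = 1 / pmax(abs(Im(z)), eps)))
}

# complex model derivatives dZ/dtheta on the natural scale, one column per
# free parameter; used for the analytic Jacobian and the error estimates
circuit_gradient <- function(theta, freq, variant) {
  omega <- 2 * pi * freq
  q <- theta[["Q_dl"]]
  n <- theta[["n_dl"]]
  z_cpe <- 1 / (omega^n * complex(modulus = 1, argument = n * pi / 2) * q)
  d_cpe_q <- -z_cpe / q
  d_cpe_n <- -z_cpe * (log(omega) + 1i * pi / 2)
  if (variant == "simplified") {
    return(cbind(R_offset = rep(1 + 0i, length(freq)),
                 Q_dl = d_cpe_q, n_dl = d_cpe_n))
  }
  rm_ <- theta[["R_media"]]
  cm <- theta[["C_media"]]
  rdl <- theta[["R_dl"]]
  den_m <- 1 + 1i * omega * rm_ * cm
  den_d <- rdl + z_cpe
  frac_r <- (z_cpe / den_d)^2           # dZ_dl/dR_dl
  frac_c <- (rdl / den_d)^2             # dZ_dl/dZ_cpe
  cbind(L_setup = 1i * omega,
        R_offset = rep(1 + 0i, length(freq)),
        R_media = 1 / den_m^2,
        C_media = -1i * omega * rm_^2 / den_m^2,
        R_dl = frac_r,
        Q_dl = frac_c * d_cpe_q,
        n_dl = frac_c * d_cpe_n)
}

make_objective <- function(spectrum, variant, weighting) {
  freq <- spectrum$frequency_hz
  z_meas <- spectrum$z
  w <- residual_weights(z_meas, weighting)
  resid_fn <- function(phi) {
    theta <- from_phi(phi)
    z_mod <- circuit_impedance(vec_to_params(theta, variant), freq, variant)
    c(w$re * (Re(z_meas) - Re(z_mod)), w$im * (Im(z_meas) - Im(z_mod)))
  }
  jac_fn <- function(phi) {
    theta <- from_phi(phi)
    g <- circuit_gradient(theta, freq, variant)
    # chain rule for the log reparameterisation
    scale <- theta
    scale["n_dl"] <- 1
    g <- sweep(g, 2, scale[colnames(g)], `*`)
    -rbind(w$re * Re(g), w$im * Im(g))
  }
  list(resid = resid_fn, jac = jac_fn)
}

#' Heuristic starting values for the circuit fit
#'
#' Reads rough parameter magnitudes off the spectrum: the series resistance
#' from Re(Z) at the highest frequency, the setup inductance from Im(Z)
#' there, the CPE exponent from the log-log slope of the low-frequency
#' -Im(Z) tail, and the CPE coefficient from |Z| at the lowest frequency.
#' For the full circuit the CPE and total low-frequency offset are then
#' refined by a quick simplified-circuit fit of the sub-media-arc band,
#' from which the media shoulder height (offset difference) and its
#' half-build frequency give `R_media` and `C_media`; `R_dl` starts at ten
#' times the largest observed Re(Z). All values are clipped to `bounds`.
#'
#' @param spectrum an [impedance_spectrum] spanning at least three decades.
#' @param variant circuit variant the guess is intended for.
#' @param bounds box bounds, as in [fit_config()].
#' @return A [circuit_params] object satisfying the bounds.
#' @export
initial_guess <- function(spectrum, variant = c("full", "simplified"),
                          bounds = default_bounds()) {
  variant <- match.arg(variant)
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequency_hz          # descending
  z <- spectrum$z
  if (length(f) < 8L) {
    stop("spectrum too short for an initial guess (need >= 8 samples)",
         call. = FALSE)
  }
  span_needed <- if (variant == "full") 1e3 else 10
  if (max(f) / min(f) < span_needed) {
    stop("spectrum frequency span too narrow for a ", variant,
         " circuit guess", call. = FALSE)
  }
  if (max(abs(Im(z)) / Mod(z)) < 0.01) {
    stop("degenerate spectrum: no capacitive signature", call. = FALSE)
  }
  clip <- function(x, nm) {
    min(max(x, bounds$lower[[nm]], na.rm = TRUE), bounds$upper[[nm]])
  }
  r_offset <- clip(Re(z[1L]), "R_offset")
  # CPE exponent from the slope of the low-frequency -Im tail, where the
  # double-layer branch dominates and -Im(Z) ~ omega^(-n)
  n_tail <- length(f)
  tail_idx <- seq.int(max(1L, n_tail - 9L), n_tail)
  neg_im <- pmax(-Im(z[tail_idx]), .Machine$double.eps)
  slope <- stats::coef(stats::lm(log(neg_im) ~ log(f[tail_idx])))[[2L]]
  n_dl <- min(max(-slope, 0.6), 0.99)
  # CPE coefficient from |Z| at the lowest frequency relative to the offset
  omega_low <- 2 * pi * f[length(f)]
  q_dl <- clip(1 / (omega_low^n_dl * max(Mod(z[length(z)] - r_offset),
                                         .Machine$double.eps)), "Q_dl")
  if (variant == "simplified") {
    return(circuit_params(L_setup = 0, R_offset = r_offset,
                          Q_dl = q_dl, n_dl = n_dl))
  }
  # setup inductance from the inductive Im at the top of the sweep
  im_top <- Im(z[1L])
  l_setup <- clip(if (im_top > 0) im_top / (2 * pi * f[1L]) else 1e-6,
                  "L_setup")
  # refine the CPE and the total low-frequency real-axis offset with a
  # quick simplified-circuit fit of the sub-media-arc band; the media
  # shoulder height is the offset difference between that band and the
  # top of the sweep
  offset_low <- r_offset
  simp <- tryCatch(
    fit_circuit(spectrum, "simplified",
                fit_config(n_starts = 1L, max_iterations = 50L,
                           bounds = bounds)),
    error = function(e) NULL)
  if (!is.null(simp) && simp$converged) {
    q_dl <- clip(simp$params$Q_dl, "Q_dl")
    n_dl <- min(max(simp$params$n_dl, 0.6), 0.99)
    offset_low <- simp$params$R_offset
  }
  # fall back to a shoulder a fraction of the offset high when the offset
  # difference is swamped by the CPE/offset trade-off of the band fit
  r_media <- clip(max(offset_low - r_offset, 0.3 * r_offset), "R_media")
  # media capacitance from the frequency where the shoulder is half-built
  re_cpe_est <- cos(n_dl * pi / 2) / ((2 * pi * f)^n_dl * q_dl)
  re_media_est <- Re(z) - r_offset - pmin(re_cpe_est, Mod(z))
  above_half <- which(re_media_est >= r_media / 2)
  f_half <- if (length(above_half)) max(f[above_half]) else
    sqrt(max(f) * min(f))
  c_media <- clip(1 / (2 * pi * f_half * r_media), "C_media")
  # keep the media time constant in the regime of a high-frequency shoulder
  tau <- r_media * c_media
  if (tau < 1e-4 || tau > 1e-2) c_media <- clip(1.3e-3 / r_media, "C_media")
  r_dl <- clip(10 * max(Re(z)), "R_dl")
  circuit_params(L_setup = l_setup, R_offset = r_offset, R_media = r_media,
                 C_media = c_media, R_dl = r_dl, Q_dl = q_dl, n_dl = n_dl)
}

nrmse_from_fit <- function(jac, ss, n_points, free) {
  p <- length(free)
  dof <- 2 * n_points - p
  out <- rep(NA_real_, p)
  names(out) <- free
  jtj <- crossprod(jac)
  cov_phi <- tryCatch(solve(jtj) * ss / dof, error = function(e) NULL)
  if (is.null(cov_phi)) return(out)     # rank-deficient linearisation
  se_phi <- sqrt(pmax(diag(cov_phi), 0))
  # log-scale standard errors are already relative; n_dl is fit linearly
  out[] <- 100 * se_phi
  out
}

#' Fit the equivalent circuit to a measured spectrum (CNLS)
#'
#' Complex nonlinear least squares: minimises the weighted sum of squared
#' real and imaginary residuals over the free circuit parameters, using
#' bounded Levenberg-Marquardt (via [minpack.lm::nls.lm]) with an analytic
#' Jacobian. All parameters except `n_dl` are optimised in log space. A
#' seeded multi-start around [initial_guess()] guards against local minima;
#' the best objective wins, ties broken by the lower `Q_dl` error estimate.
#'
#' Reported diagnostics: the weighted `sum_of_squares`; `chi_squared`, the
#' sum of squares divided by the degrees of freedom `2 * n_points -
#' n_free_params`; and `nrmse_percent`, the percent relative standard error
#' of each free parameter obtained from the curvature of the objective at
#' the optimum.
#'
#' @param spectrum an [impedance_spectrum] (>= 8 samples over >= 3 decades).
#' @param variant `"full"` or `"simplified"`.
#' @param config a [fit_config].
#' @param start optional [circuit_params] starting point; defaults to
#'   [initial_guess()].
#' @return An object of class `eis_fit` with elements `params`, `variant`,
#'   `nrmse_percent`, `chi_squared`, `sum_of_squares`, `n_points`,
#'   `converged`, `n_free`, `config` and the data. Non-convergence is
#'   reported through `converged = FALSE`, not an error.
#' @examples
#' truth <- circuit_params(L_setup = 2.18e-6, R_offset = 218.6,
#'                         R_media = 78.6, C_media = 1.66e-5,
#'                         R_dl = 3.95e5, Q_dl = 2.14e-5, n_dl = 0.82)
#' sp <- spectrum_from_params(truth)
#' fit <- fit_circuit(sp)
#' coef(fit)
#' @export
fit_circuit <- function(spectrum, variant = c("full", "simplified"),
                        config = fit_config(), start = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(spectrum, "impedance_spectrum"),
            inherits(config, "fit_config"))
  free <- param_names(variant)
  if (variant == "simplified") {
    # the simplified circuit only describes the sub-media-arc band
    keep <- which(spectrum$frequency_hz <= config$simplified_max_hz)
    if (length(keep) < 8L) {
      keep <- utils::tail(seq_along(spectrum$frequency_hz), 8L)
    }
    spectrum <- impedance_spectrum(spectrum$frequency_hz[keep],
                                   spectrum$z[keep],
                                   amplitude_mv = spectrum$amplitude_mv,
                                   label = spectrum$label)
  }
  n_points <- length(spectrum)
  if (2 * n_points <= length(free) + 1) {
    stop("too few samples to fit ", length(free), " parameters", call. = FALSE)
  }
  obj <- make_objective(spectrum, variant, config$weighting)
  if (is.null(start)) start <- initial_guess(spectrum, variant, config$bounds)
  theta0 <- params_to_vec(start, variant)
  lower_n <- config$bounds$lower[free]
  upper_n <- config$bounds$upper[free]
  theta0 <- pmin(pmax(theta0, lower_n), upper_n)
  phi0 <- to_phi(theta0)
  lower <- to_phi(lower_n)
  upper <- to_phi(upper_n)

  # multi-start: first from the heuristic guess, the rest from seeded
  # log-space perturbations of it
  starts <- list(phi0)
  if (config$n_starts > 1L) {
    perts <- with_seed(config$seed, lapply(seq_len(config$n_starts - 1L),
      function(k) {
        d <- stats::runif(length(phi0), -log(3), log(3))
        d[names(phi0) == "n_dl"] <- stats::runif(1, -0.07, 0.07)
        pmin(pmax(phi0 + d, lower), upper)
      }))
    starts <- c(starts, perts)
  }

  best <- NULL
  for (phi_start in starts) {
    res <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = phi_start, lower = lower, upper = upper,
                         fn = obj$resid, jac = obj$jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iterations,
                           ftol = config$tolerance, ptol = 1e-14,
                           gtol = 0))),
      error = function(e) NULL)
    if (is.null(res)) next
    ss <- res$deviance
    if (is.null(best) || ss < best$deviance * (1 - 1e-12)) {
      best <- res
    } else if (ss < best$deviance * (1 + 1e-12)) {
      # objective tie: prefer the lower Q_dl error estimate
      nr_new <- nrmse_from_fit(obj$jac(res$par), ss, n_points, free)
      nr_old <- nrmse_from_fit(obj$jac(best$par), best$deviance, n_points, free)
      if (isTRUE(nr_new[["Q_dl"]] < nr_old[["Q_dl"]])) best <- res
    }
    if (best$deviance < n_points * 1e-20) break   # exact fit reached
  }
  if (is.null(best)) {
    stop("all optimisation starts failed", call. = FALSE)
  }
  theta_hat <- from_phi(best$par)
  jac_hat <- obj$jac(best$par)
  ss <- best$deviance
  nrmse <- nrmse_from_fit(jac_hat, ss, n_points, free)
  structure(
    list(params = vec_to_params(theta_hat, variant),
         variant = variant,
         nrmse_percent = nrmse,
         chi_squared = ss / (2 * n_points - length(free)),
         sum_of_squares = ss,
         n_points = n_points,
         n_free = length(free),
         converged = best$info %in% 1:4,
         info = best$info,
         message = best$message,
         rss_trace = best$rsstrace,
         jacobian = jac_hat,
         spectrum = spectrum,
         config = config),
    class = "eis_fit")
}

#' Fit with automatic model reduction
#'
#' Fits the full circuit; when the double-layer resistance is not
#' identifiable — its percent NRMSE exceeds `config$rdl_nrmse_threshold`,
#' is unavailable, or the full fit fails — refits the simplified circuit
#' (series resistance plus CPE) and returns that instead. The CPE
#' coefficient `Q_dl`, the biomass-bearing parameter, is populated either
#' way.
#'
#' @inheritParams fit_circuit
#' @return An `eis_fit`, tagged with the variant that was retained.
#' @export
select_model <- function(spectrum, config = fit_config()) {
  full <- tryCatch(fit_circuit(spectrum, "full", config),
                   error = function(e) e)
  if (inherits(full, "eis_fit") && full$converged) {
    nr <- full$nrmse_percent[["R_dl"]]
    if (!is.na(nr) && nr <= config$rdl_nrmse_threshold) return(full)
  }
  simp <- tryCatch(fit_circuit(spectrum, "simplified", config),
                   error = function(e) e)
  if (inherits(simp, "eis_fit")) return(simp)
  stop("both circuit fits failed; full: ",
       conditionMessage(if (inherits(full, "condition")) full else
         simpleCondition(full$message)),
       "; simplified: ", conditionMessage(simp), call. = FALSE)
}

#' Per-parameter percent error estimates of a fit
#'
#' Percent relative standard error of each free parameter, from the local
#' linearisation of the weighted residuals at the optimum. Entries are `NA`
#' when the linearisation is rank deficient.
#'
#' @param result a converged `eis_fit`.
#' @return Named numeric vector of percent errors.
#' @export
parameter_errors <- function(result) {
  stopifnot(inherits(result, "eis_fit"))
  if (!result$converged) stop("fit did not converge", call. = FALSE)
  nrmse_from_fit(result$jacobian, result$sum_of_squares, result$n_points,
                 param_names(result$variant))
}

#' @export
coef.eis_fit <- function(object, ...) {
  params_to_vec(object$params, object$variant)
}

#' @export
print.eis_fit <- function(x, ...) {
  cat("Equivalent-circuit CNLS fit (", x$variant, " variant, ",
      x$config$weighting, " weighting)\n", sep = "")
  tab <- data.frame(estimate = signif(coef(x), 4),
                    nrmse_pct = signif(x$nrmse_percent, 3))
  print(tab)
  cat("chi-squared:", format(x$chi_squared, digits = 5),
      "  sum of squares:", format(x$sum_of_squares, digits = 5),
      "  points:", x$n_points, "\n")
  if (!x$converged) cat("WARNING: fit did not converge (info ", x$info, ")\n",
                        sep = "")
  invisible(x)
}

#' @export
summary.eis_fit <- function(object, ...) {
  out <- list(fit = object,
              c_dl = if (object$variant == "full")
                effective_capacitance(object$params$R_dl, object$params$Q_dl,
                                      object$params$n_dl) else NA_real_)
  class(out) <- "summary.eis_fit"
  out
}

#' @export
print.summary.eis_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$c_dl)) {
    cat("effective double-layer capacitance:",
        format(x$c_dl, digits = 4), "F\n")
  }
  invisible(x)
}

#' Model impedance at new frequencies
#'
#' @param object an `eis_fit`.
#' @param frequency frequencies in Hz; defaults to the fitted spectrum's.
#' @param ... unused.
#' @return Complex impedance vector.
#' @export
predict.eis_fit <- function(object, frequency = NULL, ...) {
  if (is.null(frequency)) frequency <- object$spectrum$frequency_hz
  circuit_impedance(object$params, frequency, object$variant)
}

#' @export
fitted.eis_fit <- function(object, ...) predict(object)

#' Residuals of a circuit fit
#'
#' @param object an `eis_fit`.
#' @param type `"complex"` for raw complex residuals (measured minus
#'   model), `"weighted"` for the stacked weighted residual vector that the
#'   optimiser minimised.
#' @param ... unused.
#' @export
residuals.eis_fit <- function(object, type = c("complex", "weighted"), ...) {
  type <- match.arg(type)
  z_meas <- object$spectrum$z
  z_mod <- predict(object)
  if (type == "complex") return(z_meas - z_mod)
  w <- residual_weights(z_meas, object$config$weighting)
  c(w$re * (Re(z_meas) - Re(z_mod)), w$im * (Im(z_meas) - Im(z_mod)))
}

#' Nyquist plot of data and fitted model
#'
#' @param x an `eis_fit`.
#' @param ... passed to the underlying plot call.
#' @export
plot.eis_fit <- function(x, ...) {
  plot(x$spectrum, ...)
  z <- predict(x)
  graphics::lines(Re(z), -Im(z), col = "red3")
  graphics::legend("topleft", legend = c("data", "fit"),
                   pch = c(1, NA), lty = c(NA, 1),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Simulate noisy spectra from a fitted circuit
#'
#' Draws replicate spectra from the fitted parameters with proportional
#' complex Gaussian noise, via [simulate_spectrum()].
#'
#' @param object an `eis_fit`.
#' @param nsim number of spectra.
#' @param seed RNG seed.
#' @param relative_sigma per-component relative noise level.
#' @param ... unused.
#' @return A list of [impedance_spectrum] objects.
#' @export
simulate.eis_fit <- function(object, nsim = 1, seed = 1,
                             relative_sigma = 0.01, ...) {
  lapply(seq_len(nsim), function(k) {
    simulate_spectrum(object$params, grid = object$spectrum$frequency_hz,
                      noise = noise_spec(relative_sigma = relative_sigma,
                                         seed = seed + k - 1L),
                      variant = object$variant)
  })
}
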