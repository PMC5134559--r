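#' Linear calibration of the CPE coefficient against dry cell weight
#'
#' Ordinary least squares of the fitted double-layer CPE coefficient
#' `Q_dl` on dry cell weight: `q = slope_k * dcw + intercept_q0`. The
#' inverse map, [predict.dcw_calibration()], turns an online `Q_dl`
#' reading into a biomass estimate. The fit is order-invariant and, by
#' default, includes an intercept for the cell-free background signal; a
#' through-origin variant is available.
#'
#' @param dcw dry cell weight values, g/L (>= 0), at least two distinct.
#' @param q_dl CPE coefficients, F s^(n-1) (> 0), same length.
#' @param through_origin force a zero intercept.
#' @param dcw_valid_range biomass range over which the calibration is
#'   considered valid; predictions outside it warn about extrapolation.
#' @return An object of class `dcw_calibration` with elements `slope_k`,
#'   `intercept_q0`, `r_squared`, `n_points`, `dcw_range`, `q_range`,
#'   `through_origin`, `viability_fraction`.
#' @examples
#' dcw <- seq(1, 40, length.out = 10)
#' cal <- fit_dcw_calibration(dcw, 1.8e-7 * dcw + 1.5e-5)
#' predict(cal, q_dl = 1.95e-5)
#' @export
fit_dcw_calibration <- function(dcw, q_dl, through_origin = FALSE,
                                dcw_valid_range = c(1, 40)) {
  dcw <- as.numeric(dcw)
  q_dl <- as.numeric(q_dl)
  if (length(dcw) != length(q_dl)) {
    stop("'dcw' and 'q_dl' must have the same length", call. = FALSE)
  }
  if (length(dcw) < 2L) stop("need at least two calibration points", call. = FALSE)
  if (any(!is.finite(dcw)) || any(dcw < 0)) stop("dcw must be >= 0", call. = FALSE)
  if (any(!is.finite(q_dl)) || any(q_dl <= 0)) stop("q_dl must be > 0", call. = FALSE)
  if (length(unique(dcw)) < 2L) {
    stop("degenerate design: all dcw values identical", call. = FALSE)
  }
  fit <- if (through_origin) stats::lm(q_dl ~ dcw + 0) else stats::lm(q_dl ~ dcw)
  cf <- stats::coef(fit)
  slope <- unname(cf[["dcw"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  # R^2 about the mean in both cases, so the two variants are comparable
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((q_dl - mean(q_dl))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - ssr / sst)) else 1
  if (length(dcw) == 2L && !through_origin) r2 <- 1
  structure(list(slope_k = slope, intercept_q0 = intercept, r_squared = r2,
                 n_points = length(dcw), dcw_range = range(dcw),
                 q_range = range(q_dl), dcw_valid_range = dcw_valid_range,
                 through_origin = through_origin, viability_fraction = 1),
            class = "dcw_calibration")
}

#' @export
print.dcw_calibration <- function(x, ...) {
  cat("DCW calibration: q_dl =", format(x$slope_k, digits = 4), "* dcw +",
      format(x$intercept_q0, digits = 4), "\n")
  cat("  R-squared:", format(x$r_squared, digits = 4),
      "  points:", x$n_points,
      "  dcw range:", paste(signif(x$dcw_range, 3), collapse = " - "),
      "g/L\n")
  invisible(x)
}

#' @export
coef.dcw_calibration <- function(object, ...) {
  c(slope_k = object$slope_k, intercept_q0 = object$intercept_q0)
}

#' Predict dry cell weight from an online CPE coefficient
#'
#' Inverts the calibration line: `dcw = (q_dl - intercept_q0) / slope_k`,
#' scaled by the viability fraction (default 1, i.e. dry cell weight and
#' viable cell concentration treated as equivalent). Negative estimates are
#' clamped to zero with a warning unless `clamp = FALSE`; predictions
#' outside the calibration's validity range warn about extrapolation.
#'
#' @param object a `dcw_calibration`.
#' @param q_dl CPE coefficient(s), F s^(n-1).
#' @param clamp clamp negative estimates to 0.
#' @param viability_fraction fraction of cells viable; divides into the
#'   DCW-equivalent estimate for callers with flow-cytometry data.
#' @param ... unused.
#' @return Numeric vector of dry cell weight estimates, g/L.
#' @export
predict.dcw_calibration <- function(object, q_dl, clamp = TRUE,
                                    viability_fraction = object$viability_fraction,
                                    ...) {
  if (object$slope_k == 0) stop("calibration slope is zero", call. = FALSE)
  dcw <- (as.numeric(q_dl) - object$intercept_q0) / object$slope_k
  dcw <- dcw * viability_fraction
  if (clamp && any(dcw < 0)) {
    warning("negative DCW estimate clamped to 0", call. = FALSE)
    dcw <- pmax(dcw, 0)
  }
  rng <- object$dcw_valid_range
  slack <- 1e-8 * diff(rng)
  if (any(dcw < rng[1L] - slack | dcw > rng[2L] + slack)) {
    warning("prediction outside the calibrated biomass range (",
            rng[1L], "-", rng[2L], " g/L): extrapolation", call. = FALSE)
  }
  dcw
}

#' Saturating (logarithmic) comparator fit for optical density signals
#'
#' Fits `signal = a * log(dcw) + b`, the saturating response of an inline
#' optical density probe whose linear range is exceeded at high biomass.
#' Serves as a comparator for the linear impedance calibration.
#'
#' @param dcw dry cell weight values, g/L, all > 0, at least three.
#' @param signal probe signal at each `dcw`.
#' @return An object of class `saturating_model` with elements `a`, `b`,
#'   `r_squared`, `n_points`, `narrow_support` (TRUE when the dcw values
#'   span less than one decade).
#' @export
fit_saturating_comparator <- function(dcw, signal) {
  dcw <- as.numeric(dcw)
  signal <- as.numeric(signal)
  if (length(dcw) != length(signal)) {
    stop("'dcw' and 'signal' must have the same length", call. = FALSE)
  }
  if (length(dcw) < 3L) stop("need at least three points", call. = FALSE)
  if (any(!is.finite(dcw)) || any(dcw <= 0)) {
    stop("dcw must be > 0 for the logarithmic fit", call. = FALSE)
  }
  fit <- stats::lm(signal ~ log(dcw))
  cf <- stats::coef(fit)
  sst <- sum((signal - mean(signal))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  narrow <- max(dcw) / min(dcw) < 10
  if (narrow) {
    warning("dcw values span less than one decade: saturating fit has ",
            "narrow support", call. = FALSE)
  }
  structure(list(a = unname(cf[["log(dcw)"]]), b = unname(cf[["(Intercept)"]]),
                 r_squared = r2, n_points = length(dcw),
                 narrow_support = narrow),
            class = "saturating_model")
}

#' @export
print.saturating_model <- function(x, ...) {
  cat("Saturating comparator: signal =", format(x$a, digits = 4),
      "* ln(dcw) +", format(x$b, digits = 4), "\n")
  cat("  R-squared:", format(x$r_squared, digits = 4),
      "  points:", x$n_points,
      if (x$narrow_support) "  [narrow support]" else "", "\n")
  invisible(x)
}

#' @export
predict.saturating_model <- function(object, dcw, ...) {
  if (any(dcw <= 0)) stop("dcw must be > 0", call. = FALSE)
  object$a * log(dcw) + object$b
}

#' Detect negative-differential-resistance loops in a spectrum
#'
#' Flow-through measurements can show Nyquist loops at low frequency in
#' which Re(Z) falls back as the frequency decreases (negative differential
#' resistance), an electrode artifact that corrupts the double-layer fit.
#' Below `onset_hz`, the detector tracks the running maximum of Re(Z) along
#' the downward sweep and flags the spectrum when Re(Z) drops below that
#' maximum by more than `tolerance` times the local `|Z|`. Flagged spectra
#' should be excluded from calibration.
#'
#' @param spectrum an [impedance_spectrum].
#' @param onset_hz only frequencies below this are examined (default 10 Hz).
#' @param tolerance allowed relative fall-back before flagging, as a
#'   fraction of the local impedance modulus (default 0.02); `Inf` disables
#'   the detector.
#' @return A list with `flagged` (logical), `band` (range of offending
#'   frequencies in Hz, or NULL), `n_violations`, and `max_drop_rel` (the
#'   largest observed fall-back relative to the local `|Z|`).
#' @export
detect_negative_differential_resistance <- function(spectrum, onset_hz = 10,
                                                    tolerance = 0.02) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  idx <- which(spectrum$frequency_hz < onset_hz)
  if (length(idx) < 2L || !is.finite(tolerance)) {
    return(list(flagged = FALSE, band = NULL, n_violations = 0L,
                max_drop_rel = 0))
  }
  re <- Re(spectrum$z[idx])            # ordered high to low frequency
  modz <- Mod(spectrum$z[idx])
  runmax <- cummax(re)
  drop_rel <- (runmax - re) / modz
  viol <- drop_rel > tolerance
  list(flagged = any(viol),
       band = if (any(viol)) range(spectrum$frequency_hz[idx][viol]) else NULL,
       n_violations = sum(viol),
       max_drop_rel = max(drop_rel))
}

#' Write a DCW calibration to a YAML text document
#'
#' @param model a `dcw_calibration`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_dcw_calibration <- function(model, path) {
  stopifnot(inherits(model, "dcw_calibration"))
  doc <- list(slope_k = model$slope_k, intercept_q0 = model$intercept_q0,
              r_squared = model$r_squared, n_points = model$n_points,
              dcw_range = as.numeric(model$dcw_range),
              q_range = as.numeric(model$q_range),
              dcw_valid_range = as.numeric(model$dcw_valid_range),
              through_origin = model$through_origin,
              viability_fraction = model$viability_fraction,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a DCW calibration written by [write_dcw_calibration()]
#'
#' @param path file to read.
#' @return A `dcw_calibration`.
#' @export
read_dcw_calibration <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  need <- c("slope_k", "intercept_q0", "r_squared", "n_points")
  if (!all(need %in% names(doc))) {
    stop("not a calibration document: ", path, call. = FALSE)
  }
  structure(list(slope_k = doc$slope_k, intercept_q0 = doc$intercept_q0,
                 r_squared = doc$r_squared, n_points = doc$n_points,
                 dcw_range = as.numeric(doc$dcw_range),
                 q_range = as.numeric(doc$q_range),
                 dcw_valid_range = as.numeric(doc$dcw_valid_range %||% c(1, 40)),
                 through_origin = isTRUE(doc$through_origin),
                 viability_fraction = doc$viability_fraction %||% 1),
            class = "dcw_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
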