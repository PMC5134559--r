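#' Impedance spectrum container
#'
#' An `impedance_spectrum` holds one electrochemical impedance measurement:
#' paired frequencies and complex impedances, plus the excitation amplitude
#' and a free-text label. Frequencies are stored in descending order (the
#' usual sweep direction, high to low); ascending input is reordered.
#'
#' @param frequency_hz numeric vector of measurement frequencies in Hz,
#'   strictly positive, no duplicates, strictly monotone.
#' @param z complex vector of impedances in Ohm, same length as
#'   `frequency_hz`, all finite. Capacitive samples have `Im(z) < 0`.
#' @param amplitude_mv excitation amplitude in mV (metadata, optional).
#' @param label free-text label (metadata, optional).
#' @return An object of class `impedance_spectrum`: a list with elements
#'   `frequency_hz`, `z`, `amplitude_mv`, `label`.
#' @examples
#' f <- 10^seq(6, -1, by = -0.5)
#' sp <- impedance_spectrum(f, complex(real = 200, imaginary = -1 / (2 * pi * f * 1e-5)))
#' sp
#' @export
impedance_spectrum <- function(frequency_hz, z, amplitude_mv = NA_real_,
                               label = "") {
  frequency_hz <- as.numeric(frequency_hz)
  z <- as.complex(z)
  if (length(frequency_hz) < 1L) {
    stop("an impedance spectrum needs at least one sample", call. = FALSE)
  }
  if (length(z) != length(frequency_hz)) {
    stop("'frequency_hz' and 'z' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop("frequencies must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(Re(z))) || any(!is.finite(Im(z)))) {
    stop("impedances must be finite", call. = FALSE)
  }
  if (anyDuplicated(frequency_hz)) {
    stop("duplicate frequencies are not allowed", call. = FALSE)
  }
  d <- diff(frequency_hz)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("frequencies must be strictly monotone", call. = FALSE)
  }
  if (length(d) && d[1L] > 0) {      # normalise to descending sweep order
    frequency_hz <- rev(frequency_hz)
    z <- rev(z)
  }
  structure(
    list(frequency_hz = frequency_hz, z = z,
         amplitude_mv = as.numeric(amplitude_mv), label = as.character(label)),
    class = "impedance_spectrum"
  )
}

#' Number of frequency samples in a spectrum
#' @param x an `impedance_spectrum`.
#' @export
length.impedance_spectrum <- function(x) length(x$frequency_hz)

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequency_hz,
             z_real_ohm = Re(x$z),
             z_imag_ohm = Im(x$z))
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat("Impedance spectrum")
  if (nzchar(x$label)) cat(" '", x$label, "'", sep = "")
  cat(": ", length(x), " samples, ",
      format(max(x$frequency_hz), digits = 3), " Hz to ",
      format(min(x$frequency_hz), digits = 3), " Hz",
      sep = "")
  if (is.finite(x$amplitude_mv)) cat(", amplitude ", x$amplitude_mv, " mV", sep = "")
  cat("\n")
  cat("  |Z| range: ", format(min(Mod(x$z)), digits = 4), " - ",
      format(max(Mod(x$z)), digits = 4), " Ohm\n", sep = "")
  invisible(x)
}

#' Nyquist plot of a spectrum
#'
#' Plots -Im(Z) against Re(Z) (EIS convention: capacitive arcs point up).
#'
#' @param x an `impedance_spectrum`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.impedance_spectrum <- function(x, ...) {
  graphics::plot(Re(x$z), -Im(x$z),
                 xlab = expression(paste("Re(Z) [", Omega, "]")),
                 ylab = expression(paste("-Im(Z) [", Omega, "]")),
                 ...)
  invisible(x)
}

#' Read an impedance spectrum from CSV
#'
#' The on-disk dialect is comma-separated with a dot decimal mark, a header
#' row `frequency_hz,z_real_ohm,z_imag_ohm`, and optional metadata lines
#' prefixed by `#` of the form `# key: value` (keys `amplitude_mV`,
#' `label`, `timestamp`). Frequencies may be stored ascending or
#' descending; they are normalised to descending on read.
#'
#' @param path file to read.
#' @return An [impedance_spectrum].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^\\s*#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("spectrum file has no data rows: ", path, call. = FALSE)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  need <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% header)) {
    stop("spectrum file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(header))
  for (i in seq_along(rows)) {
    r <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(r) != length(header) || any(is.na(r))) {
      stop("malformed row at data line ", i + 1L, " of ", path, call. = FALSE)
    }
    vals[i, ] <- r
  }
  colnames(vals) <- header
  amp <- if (!is.null(meta[["amplitude_mV"]])) as.numeric(meta[["amplitude_mV"]]) else NA_real_
  lab <- if (!is.null(meta[["label"]])) meta[["label"]] else ""
  impedance_spectrum(vals[, "frequency_hz"],
                     complex(real = vals[, "z_real_ohm"],
                             imaginary = vals[, "z_imag_ohm"]),
                     amplitude_mv = amp, label = lab)
}

#' Write an impedance spectrum to CSV
#'
#' Values are written at full double precision (`%.17g`) so that
#' `read_spectrum(write_spectrum(x, f))` is the identity.
#'
#' @param spectrum an [impedance_spectrum].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  if (is.finite(spectrum$amplitude_mv)) {
    writeLines(sprintf("# amplitude_mV: %.17g", spectrum$amplitude_mv), con)
  }
  if (nzchar(spectrum$label)) {
    writeLines(paste0("# label: ", spectrum$label), con)
  }
  writeLines("frequency_hz,z_real_ohm,z_imag_ohm", con)
  writeLines(sprintf("%.17g,%.17g,%.17g",
                     spectrum$frequency_hz, Re(spectrum$z), Im(spectrum$z)),
             con)
  invisible(path)
}
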