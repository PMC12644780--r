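#' Impedance spectrum object
#'
#' Container for a measured (or simulated) electrical impedance spectrum:
#' an ascending frequency grid with one complex impedance value per
#' frequency. Capacitive behaviour corresponds to a negative imaginary
#' part (the convention of a Nyquist plot showing \eqn{-\mathrm{Im}(Z)}
#' against \eqn{\mathrm{Re}(Z)}).
#'
#' Rows are sorted by ascending frequency on construction. Duplicate
#' frequencies are an error. Fewer than 3 points is an error; fewer than
#' 8 points, or any non-positive real part, triggers a validation warning
#' (such spectra are unusual for passive tissue but are not rejected).
#'
#' @param frequencies numeric vector of frequencies in Hz, strictly positive.
#' @param impedance complex vector of impedance values in ohms, same length.
#' @param meta named list of free-form provenance (sample id, field
#'   amplitude in V/cm, pre/post flag, drive voltage, ...).
#' @return An object of class `impedance_spectrum` with elements
#'   `frequencies`, `impedance`, `meta`.
#' @examples
#' f <- 10^seq(1, 5, length.out = 30)
#' z <- 100 + 500 / (1 + 1i * 2 * pi * f * 1e-4)
#' s <- impedance_spectrum(f, z)
#' s
#' @export
impedance_spectrum <- function(frequencies, impedance, meta = list()) {
  if (!is.numeric(frequencies)) stop("`frequencies` must be numeric")
  impedance <- as.complex(impedance)
  if (length(impedance) != length(frequencies)) {
    stop("`impedance` length (", length(impedance),
         ") does not match `frequencies` length (", length(frequencies), ")")
  }
  if (length(frequencies) < 3) stop("spectrum needs at least 3 points")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("frequencies must be finite and strictly positive")
  }
  ord <- order(frequencies)
  frequencies <- frequencies[ord]
  impedance <- impedance[ord]
  if (any(diff(frequencies) == 0)) {
    stop("duplicate frequencies in spectrum")
  }
  if (length(frequencies) < 8) {
    warning("spectrum has fewer than 8 points; results may be unreliable")
  }
  if (any(Re(impedance) <= 0)) {
    warning("spectrum has non-positive real parts; not physical for passive tissue")
  }
  structure(list(frequencies = frequencies, impedance = impedance,
                 meta = meta),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  n <- length(x$frequencies)
  cat("<impedance_spectrum> ", n, " points, ",
      format(min(x$frequencies), digits = 4), " Hz - ",
      format(max(x$frequencies), digits = 4), " Hz\n", sep = "")
  cat("  |Z| range: ", format(min(Mod(x$impedance)), digits = 4), " - ",
      format(max(Mod(x$impedance)), digits = 4), " ohm\n", sep = "")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.impedance_spectrum <- function(x) length(x$frequencies)

#' Default acquisition frequency grid
#'
#' 300 points evenly spaced on a logarithmic scale between 20 Hz and
#' 400 kHz, matching a typical low-voltage tissue acquisition.
#'
#' @param n number of points.
#' @param f_min,f_max band limits in Hz.
#' @return numeric vector of frequencies in Hz.
#' @export
default_frequencies <- function(n = 300, f_min = 20, f_max = 4e5) {
  exp(seq(log(f_min), log(f_max), length.out = n))
}

#' Read an impedance spectrum from CSV
#'
#' The canonical dialect uses columns `frequency_hz`, `z_real_ohm`,
#' `z_imag_ohm` with the imaginary part stored as measured (capacitive
#' points negative). Instruments exporting \eqn{-\mathrm{Im}(Z)} as
#' positive numbers are handled by `imag_sign = -1`.
#'
#' @param path CSV file path.
#' @param dialect named list mapping roles to column names:
#'   `frequency`, `real`, `imag`, plus `imag_sign` (+1 if the column holds
#'   Im(Z) as measured, -1 if it holds -Im(Z)).
#' @return An [impedance_spectrum()]; the sign convention applied is
#'   recorded in `meta$imag_sign`.
#' @export
read_spectrum <- function(path,
                          dialect = list(frequency = "frequency_hz",
                                         real = "z_real_ohm",
                                         imag = "z_imag_ohm",
                                         imag_sign = 1)) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  dialect <- utils::modifyList(
    list(frequency = "frequency_hz", real = "z_real_ohm",
         imag = "z_imag_ohm", imag_sign = 1),
    dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (role in c("frequency", "real", "imag")) {
    col <- dialect[[role]]
    if (!col %in% names(df)) {
      stop("missing column '", col, "' (", role, ") in ", path)
    }
  }
  cols <- c(dialect$frequency, dialect$real, dialect$imag)
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      stop("non-numeric value in column '", col, "' at data row ",
           if (length(bad)) bad[1] else "?", " of ", path)
    }
  }
  sgn <- if (identical(dialect$imag_sign, -1) || identical(dialect$imag_sign, -1L)) -1 else 1
  impedance_spectrum(
    frequencies = df[[dialect$frequency]],
    impedance = complex(real = df[[dialect$real]],
                        imaginary = sgn * df[[dialect$imag]]),
    meta = list(source = path, imag_sign = sgn))
}

#' Write an impedance spectrum to CSV
#'
#' Uses the canonical dialect (`frequency_hz`, `z_real_ohm`, `z_imag_ohm`,
#' imaginary part as measured). Values are written with 15 significant
#' digits so that `read_spectrum(write_spectrum(s))` round-trips to at
#' least 12 significant digits.
#'
#' @param spectrum an [impedance_spectrum()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  df <- data.frame(
    frequency_hz = format(spectrum$frequencies, digits = 15, scientific = TRUE),
    z_real_ohm = format(Re(spectrum$impedance), digits = 15, scientific = TRUE),
    z_imag_ohm = format(Im(spectrum$impedance), digits = 15, scientific = TRUE))
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("failed to write spectrum to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}
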