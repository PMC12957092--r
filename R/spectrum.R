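#' Construct a spectrum object
#'
#' A `spectrum` is a sampled one-dimensional trace: an axis (wavelength in
#' nm, diffraction angle in degrees 2-theta, or wavenumber in cm^-1) and a
#' signal (absorbance, counts, or molar extinction). The axis is sorted to
#' ascending order and duplicated axis values are averaged, so the stored
#' axis is strictly increasing.
#'
#' @param axis Numeric vector of axis values (length >= 3 after duplicate
#'   averaging).
#' @param signal Numeric vector of signal values, same length as `axis`.
#' @param axis_kind One of `"wavelength_nm"`, `"two_theta_deg"`,
#'   `"wavenumber_cm1"`, or `"time_ns"` (for decay traces).
#' @param label Optional free-text label.
#' @return An object of class `spectrum`: a list with elements `axis`,
#'   `signal`, `axis_kind`, `label`.
#' @export
#' @examples
#' s <- spectrum(c(350, 360, 370), c(0.1, 0.2, 0.1), "wavelength_nm")
#' s$axis
spectrum <- function(axis, signal,
                     axis_kind = c("wavelength_nm", "two_theta_deg",
                                   "wavenumber_cm1", "time_ns"),
                     label = "") {
  axis_kind <- match.arg(axis_kind)
  if (!is.numeric(axis) || !is.numeric(signal)) {
    stop("axis and signal must be numeric")
  }
  if (length(axis) != length(signal)) {
    stop("axis and signal must have equal length")
  }
  if (anyNA(axis) || anyNA(signal)) stop("axis and signal must not contain NA")
  ord <- order(axis)
  axis <- axis[ord]
  signal <- signal[ord]
  if (anyDuplicated(axis)) {
    signal <- as.numeric(tapply(signal, factor(axis, levels = unique(axis)), mean))
    axis <- unique(axis)
  }
  if (length(axis) < 3) stop("a spectrum needs at least 3 distinct axis points")
  structure(
    list(axis = axis, signal = signal, axis_kind = axis_kind,
         label = as.character(label)[1]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, axis [%g, %g] (%s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$axis), min(x$axis), max(x$axis), x$axis_kind))
  invisible(x)
}

#' Read a two-column spectral trace from delimited text
#'
#' Parses a two-column text file (axis, signal). The delimiter is
#' auto-detected among comma, semicolon, tab and whitespace unless given.
#' One leading non-numeric header line is skipped. Rows are sorted by
#' ascending axis and duplicated axis values are averaged.
#'
#' @param path Path to the file.
#' @param axis_kind Axis kind, declared by the caller (never guessed from
#'   the data). See [spectrum()].
#' @param delim Optional delimiter; `NULL` auto-detects.
#' @param label Optional label; defaults to the file name.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, axis_kind, delim = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty file: ", path)
  if (is.null(delim)) {
    probe <- lines[min(2L, length(lines))]
    delim <- if (grepl(",", probe, fixed = TRUE)) "," else
      if (grepl(";", probe, fixed = TRUE)) ";" else
      if (grepl("\t", probe, fixed = TRUE)) "\t" else "[[:space:]]+"
  }
  parse_row <- function(line) {
    parts <- strsplit(trimws(line), delim)[[1]]
    parts <- parts[nzchar(parts)]
    suppressWarnings(as.numeric(parts))
  }
  rows <- lapply(lines, parse_row)
  ok <- vapply(rows, function(r) length(r) >= 2 && !anyNA(r[1:2]), logical(1))
  start <- 1L
  if (!ok[1]) start <- 2L  # one optional header line
  bad <- which(!ok[seq(start, length(ok))]) + start - 1L
  if (length(bad) > 0) {
    stop("unparseable rows at line(s): ", paste(bad, collapse = ", "))
  }
  rows <- rows[seq(start, length(rows))]
  if (length(rows) < 3) stop("fewer than 3 data points in ", path)
  m <- do.call(rbind, lapply(rows, function(r) r[1:2]))
  spectrum(m[, 1], m[, 2], axis_kind = axis_kind, label = label)
}

#' Write a spectrum to two-column delimited text
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @param delim Delimiter (default comma).
#' @param header Write a `axis,signal` header line? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, delim = ",", header = FALSE) {
  stopifnot(inherits(spec, "spectrum"))
  lines <- paste(format(spec$axis, trim = TRUE, digits = 12),
                 format(spec$signal, trim = TRUE, digits = 12), sep = delim)
  if (header) lines <- c(paste("axis", "signal", sep = delim), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Wavelength/energy/wavenumber conversions
#'
#' `nm_to_ev()` converts a wavelength in nm to a transition energy in eV
#' (E = 1239.842 / lambda); `ev_to_nm()` is its exact inverse.
#' `nm_to_wavenumber()` converts nm to cm^-1 (10^7 / lambda);
#' `wavenumber_to_nm()` is its inverse.
#'
#' @param wavelength_nm Wavelength(s) in nm, > 0.
#' @param energy_ev Energy in eV, > 0.
#' @param wavenumber_cm1 Wavenumber in cm^-1, > 0.
#' @return Numeric vector of converted values.
#' @export
#' @examples
#' nm_to_ev(300.01)        # 4.1327 eV
#' nm_to_wavenumber(346)   # 28901.73 cm^-1
nm_to_ev <- function(wavelength_nm) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  photophysical_constants()$hc_ev_nm / wavelength_nm
}

#' @rdname nm_to_ev
#' @export
ev_to_nm <- function(energy_ev) {
  if (any(energy_ev <= 0)) stop("energy must be positive")
  photophysical_constants()$hc_ev_nm / energy_ev
}

#' @rdname nm_to_ev
#' @export
nm_to_wavenumber <- function(wavelength_nm) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  1e7 / wavelength_nm
}

#' @rdname nm_to_ev
#' @export
wavenumber_to_nm <- function(wavenumber_cm1) {
  if (any(wavenumber_cm1 <= 0)) stop("wavenumber must be positive")
  1e7 / wavenumber_cm1
}

#' Locate a band maximum and its width
#'
#' Finds the dominant maximum of a spectrum (optionally inside a window),
#' refines the position with a 3-point parabolic fit when the maximum is
#' an interior grid point, and measures the full width at half maximum by
#' linear interpolation at half height above the local baseline (the
#' minimum signal inside the window). Ties are broken toward the smaller
#' axis value.
#'
#' @param spec A [spectrum()].
#' @param window Optional numeric length-2 axis interval.
#' @return A `band_descriptor`: list with `peak_position`, `peak_height`
#'   (above zero, at the refined position), `fwhm` (axis units, `NA` if a
#'   half-height crossing is missing on either side), `area` (trapezoidal
#'   over the window), and `edge` (`TRUE` if the maximum sat on the window
#'   edge, in which case no refinement is applied).
#' @export
#' @examples
#' s <- gen_band_spectrum(420, 30, 1, generator_spec(1, "none",
#'        grid_start = 300, grid_stop = 560, grid_step = 1))
#' peak_maximum(s)$peak_position
peak_maximum <- function(spec, window = NULL) {
  stopifnot(inherits(spec, "spectrum"))
  x <- spec$axis
  y <- spec$signal
  if (!is.null(window)) {
    if (length(window) != 2) stop("window must be a length-2 interval")
    window <- sort(window)
    keep <- x >= window[1] & x <= window[2]
    if (sum(keep) < 3) stop("window must contain at least 3 points")
    x <- x[keep]
    y <- y[keep]
  }
  if (diff(range(y)) == 0) stop("no peak: flat signal")
  i <- which(y == max(y))[1]  # tie -> smallest axis value
  n <- length(x)
  edge <- i == 1L || i == n
  if (!edge) {
    # parabolic refinement: exact quadratic through the 3 points at the top
    xi <- x[(i - 1):(i + 1)]
    yi <- y[(i - 1):(i + 1)]
    cf <- unname(solve(cbind(1, xi, xi^2), yi))
    if (cf[3] < 0) {
      pos <- -cf[2] / (2 * cf[3])
      height <- cf[1] + cf[2] * pos + cf[3] * pos^2
    } else {
      pos <- x[i]
      height <- y[i]
    }
  } else {
    warning("maximum at window edge; no parabolic refinement")
    pos <- x[i]
    height <- y[i]
  }
  baseline <- min(y)
  half <- baseline + (height - baseline) / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(i)) else seq(i, n)
    below <- which(y[idx] <= half)
    if (length(below) == 0) return(NA_real_)
    j2 <- idx[below[1]]          # first point at/below half moving outward
    j1 <- if (side == "left") j2 + 1L else j2 - 1L
    if (j1 < 1 || j1 > n || y[j1] == y[j2]) return(x[j2])
    x[j1] + (half - y[j1]) * (x[j2] - x[j1]) / (y[j2] - y[j1])
  }
  xl <- cross("left")
  xr <- cross("right")
  fwhm <- if (is.na(xl) || is.na(xr)) NA_real_ else xr - xl
  structure(
    list(peak_position = pos, peak_height = height, fwhm = fwhm,
         area = trapezoid(x, y), edge = edge),
    class = "band_descriptor"
  )
}

#' @export
print.band_descriptor <- function(x, ...) {
  cat(sprintf("<band> max %.4g (height %.4g), fwhm %.4g, area %.4g%s\n",
              x$peak_position, x$peak_height, x$fwhm, x$area,
              if (isTRUE(x$edge)) " [edge]" else ""))
  invisible(x)
}

# trapezoidal rule on an ordered grid
trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Robust center of a broad band: parabolic vertex fitted over all points in
# the top (1 - frac) cap of the band. Averaging over the cap suppresses
# per-point noise, and the vertex is unbiased for any symmetric band.
# Returns the input band descriptor with a refined position/height, or
# unchanged when the cap is too small or the curvature is not concave.
refine_band_center <- function(band, x, y, frac = 0.75) {
  thresh <- min(y) + frac * (band$peak_height - min(y))
  top <- y >= thresh
  if (sum(top) < 5 || isTRUE(band$edge)) return(band)
  xt <- x[top]
  yt <- y[top]
  cf <- unname(stats::coef(stats::lm(yt ~ xt + I(xt^2))))
  if (anyNA(cf) || cf[3] >= 0) return(band)
  vertex <- -cf[2] / (2 * cf[3])
  if (vertex < min(xt) || vertex > max(xt)) return(band)
  band$peak_position <- vertex
  band$peak_height <- cf[1] + cf[2] * vertex + cf[3] * vertex^2
  band
}

#' Trapezoidal band integral over an axis range
#'
#' Integrates the signal over the clipped range with the trapezoidal rule.
#' The range edges are interpolated linearly so the integral is additive
#' over adjacent ranges and invariant to grid refinement for
#' piecewise-linear signals.
#'
#' @param spec A [spectrum()].
#' @param range Numeric length-2 axis interval; must intersect the axis span.
#' @return The integral (signal x axis units).
#' @export
integrate_band <- function(spec, range) {
  stopifnot(inherits(spec, "spectrum"), length(range) == 2)
  range <- sort(range)
  lo <- max(range[1], min(spec$axis))
  hi <- min(range[2], max(spec$axis))
  if (lo >= hi) stop("range does not intersect the spectrum axis")
  inside <- spec$axis > lo & spec$axis < hi
  x <- c(lo, spec$axis[inside], hi)
  y <- stats::approx(spec$axis, spec$signal, xout = x)$y
  trapezoid(x, y)
}

#' Molar extinction from absorbance (Beer-Lambert)
#'
#' epsilon = A / (c l). When given a [spectrum()] the conversion is applied
#' pointwise to the signal.
#'
#' @param absorbance Dimensionless absorbance (numeric vector or a
#'   [spectrum()] whose signal is absorbance).
#' @param concentration_m Molar concentration, mol L^-1, > 0.
#' @param pathlength_cm Optical path length in cm, > 0 (default 1).
#' @return Molar extinction in M^-1 cm^-1 (same shape as the input).
#' @export
#' @examples
#' molar_extinction(0.0396, 5e-6)  # ~7911 M^-1 cm^-1
molar_extinction <- function(absorbance, concentration_m, pathlength_cm = 1) {
  if (concentration_m <= 0 || pathlength_cm <= 0) {
    stop("concentration and pathlength must be positive")
  }
  if (inherits(absorbance, "spectrum")) {
    out <- absorbance
    out$signal <- absorbance$signal / (concentration_m * pathlength_cm)
    return(out)
  }
  absorbance / (concentration_m * pathlength_cm)
}
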