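#' Fit a Gaussian diffraction peak
#'
#' Nonlinear least squares of a Gaussian plus a constant baseline to one
#' dominant peak inside a 2-theta window. The angular FWHM beta is
#' returned in radians (converted from the fitted FWHM in degrees), ready
#' for [scherrer_size()].
#'
#' @param pattern A [spectrum()] with `axis_kind == "two_theta_deg"`.
#' @param window Length-2 interval in degrees containing one dominant peak
#'   (>= 7 points).
#' @param hkl Optional reflection label (e.g. `"(111)"`).
#' @return An `xrd_peak`: list with `two_theta_center` (deg), `fwhm_beta`
#'   (rad), `fwhm_deg`, `height` (counts above baseline), `baseline`,
#'   `sigma_deg`, and `hkl`.
#' @export
fit_gaussian_peak <- function(pattern, window, hkl = NULL) {
  stopifnot(inherits(pattern, "spectrum"))
  if (pattern$axis_kind != "two_theta_deg") {
    stop("pattern must be on a 2-theta (degrees) axis")
  }
  window <- sort(window)
  keep <- pattern$axis >= window[1] & pattern$axis <= window[2]
  if (sum(keep) < 7) stop("window must contain at least 7 points")
  x <- pattern$axis[keep]
  y <- pattern$signal[keep]
  # starting values: half-height width first (robust when baseline noise
  # inflates the second moment), second moment as fallback
  b0 <- min(y)
  h0 <- max(y) - b0
  c0 <- x[which.max(y)]
  s_fwhm <- tryCatch({
    bd <- peak_maximum(spectrum(x, y, "two_theta_deg"))
    bd$fwhm / (2 * sqrt(2 * log(2)))
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  w <- pmax(y - b0, 0)
  s_mom <- sqrt(sum(w * (x - c0)^2) / sum(w))
  starts <- c(s_fwhm, s_mom, diff(range(x)) / 10)
  starts <- unique(starts[is.finite(starts) & starts > 0])
  fit <- NULL
  last_err <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ h * exp(-(x - cen)^2 / (2 * s^2)) + b,
        start = list(h = h0, cen = c0, s = s0, b = b0),
        lower = c(0, min(x), diff(range(x)) / 1e4, -Inf),
        upper = c(Inf, max(x), diff(range(x)), Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("Gaussian peak fit did not converge: ", last_err,
         " (residual sd of flat model: ", signif(stats::sd(y), 4), ")")
  }
  cf <- stats::coef(fit)
  fwhm_deg <- 2 * sqrt(2 * log(2)) * cf[["s"]]
  structure(
    list(two_theta_center = cf[["cen"]],
         fwhm_beta = fwhm_deg * pi / 180,
         fwhm_deg = fwhm_deg,
         height = cf[["h"]],
         baseline = cf[["b"]],
         sigma_deg = cf[["s"]],
         hkl = hkl),
    class = "xrd_peak"
  )
}

#' @export
print.xrd_peak <- function(x, ...) {
  cat(sprintf("<xrd peak>%s 2theta %.3f deg, beta %.5g rad (%.4f deg), height %.4g\n",
              if (!is.null(x$hkl)) paste0(" ", x$hkl) else "",
              x$two_theta_center, x$fwhm_beta, x$fwhm_deg, x$height))
  invisible(x)
}

#' Debye-Scherrer crystallite size
#'
#' D = K lambda / (beta cos theta), with theta = 2theta/2 in radians,
#' lambda in nm, and beta the angular FWHM in radians; D is returned in
#' nm. Defaults: Cu K-alpha-1 wavelength 0.15406 nm and shape constant
#' K = 0.98.
#'
#' @param peak An `xrd_peak` from [fit_gaussian_peak()], or a numeric FWHM
#'   beta in radians (then `two_theta_deg` is required).
#' @param two_theta_deg Peak position in degrees 2-theta (taken from the
#'   peak object when omitted); must satisfy 0 < theta < 90 deg.
#' @param wavelength_nm X-ray wavelength in nm.
#' @param k Scherrer shape constant.
#' @return Mean crystallite size D in nm.
#' @export
#' @examples
#' scherrer_size(0.0030, two_theta_deg = 38.2)  # ~53.3 nm
scherrer_size <- function(peak, two_theta_deg = NULL,
                          wavelength_nm = photophysical_constants()$xray_wavelength_nm,
                          k = photophysical_constants()$scherrer_k) {
  if (inherits(peak, "xrd_peak")) {
    beta <- peak$fwhm_beta
    if (is.null(two_theta_deg)) two_theta_deg <- peak$two_theta_center
  } else {
    beta <- peak
    if (is.null(two_theta_deg)) stop("two_theta_deg required with a bare beta")
  }
  if (any(beta <= 0)) stop("beta must be positive")
  theta <- two_theta_deg / 2 * pi / 180
  if (any(theta <= 0) || any(theta >= pi / 2)) stop("theta must lie in (0, 90) degrees")
  k * wavelength_nm / (beta * cos(theta))
}

#' Characterize a surface plasmon resonance band
#'
#' Locates the dominant visible band of a nanoparticle UV-vis spectrum
#' (350-700 nm window by default) and reports its maximum and FWHM. Silver
#' colloids show the band near 420 nm, gold colloids near 525 nm.
#'
#' Plasmon bands are broad (FWHM of tens of nm), so after the grid search
#' the band center is refined by a parabolic vertex fit over all points in
#' the top quarter of the band (above baseline + 75% of the band height)
#' rather than the 3-point refinement of [peak_maximum()]: averaging over
#' the whole cap makes the center estimate robust to per-point noise, and
#' the vertex is unbiased for any symmetric band shape.
#'
#' @param uvvis A [spectrum()] on a wavelength axis.
#' @param window Wavelength search window, nm.
#' @return A `band_descriptor` (see [peak_maximum()]) with the refined
#'   `peak_position`.
#' @export
spr_characterize <- function(uvvis, window = c(350, 700)) {
  stopifnot(inherits(uvvis, "spectrum"))
  if (uvvis$axis_kind != "wavelength_nm") stop("SPR analysis needs a wavelength axis")
  window <- c(max(window[1], min(uvvis$axis)), min(window[2], max(uvvis$axis)))
  band <- peak_maximum(uvvis, window = window)
  keep <- uvvis$axis >= window[1] & uvvis$axis <= window[2]
  refine_band_center(band, uvvis$axis[keep], uvvis$signal[keep])
}

#' FCC d-spacing consistency of a reflection list
#'
#' Converts a list of 2-theta peak positions to d-spacings via Bragg's law
#' and checks them against the ideal face-centered-cubic ratios of the
#' (111), (200), (220), (311) reflections. Used as a sanity check that a
#' nanoparticle pattern indexes as FCC.
#'
#' @param two_theta_deg Numeric vector of four peak positions (degrees),
#'   in (111), (200), (220), (311) order.
#' @param wavelength_nm X-ray wavelength, nm.
#' @return A list: `d_nm` (d-spacings), `a_nm` (per-reflection lattice
#'   constants), and `max_rel_dev` (largest relative deviation of the
#'   lattice constants from their mean).
#' @export
#' @examples
#' fcc_consistency(c(38.21, 44.41, 64.5, 77.4))$max_rel_dev
fcc_consistency <- function(two_theta_deg,
                            wavelength_nm = photophysical_constants()$xray_wavelength_nm) {
  if (length(two_theta_deg) != 4) stop("expect the four (111),(200),(220),(311) peaks")
  hkl <- rbind(c(1, 1, 1), c(2, 0, 0), c(2, 2, 0), c(3, 1, 1))
  d <- wavelength_nm / (2 * sin(two_theta_deg / 2 * pi / 180))
  a <- d * sqrt(rowSums(hkl^2))
  list(d_nm = d, a_nm = a, max_rel_dev = max(abs(a - mean(a)) / mean(a)))
}
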