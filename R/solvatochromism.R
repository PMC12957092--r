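#' Bundled solvent photophysics table for the triazine dye study
#'
#' Nine solvents with their dielectric constants, refractive indices,
#' normalized Reichardt polarities E_T(N), viscosities (where reported),
#' the dye's absorption/emission maxima, molar extinction coefficients,
#' fluorescence quantum yields, and the published derived columns (Stokes
#' shift, orientation polarizability, oscillator strength, transition
#' dipole) kept for cross-checking. The E_T(N) scale is anchored at
#' water = 1 and tetramethylsilane = 0.
#'
#' @return A data.frame, one row per solvent.
#' @export
#' @examples
#' head(triazine_solvent_table())
triazine_solvent_table <- function() {
  path <- system.file("extdata", "triazine_solvents.csv", package = "photophyskit")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Orientation polarizability of a solvent
#'
#' Delta f = (eps - 1)/(2 eps + 1) - (n^2 - 1)/(2 n^2 + 1), the solvent
#' descriptor that drives the Lippert-Mataga solvatochromic slope.
#'
#' @param eps Static dielectric constant, >= 1.
#' @param n Refractive index, >= 1.
#' @return Delta f (dimensionless). Vectorized.
#' @export
#' @examples
#' orientation_polarizability(46.68, 1.479)  # 0.263 (DMSO)
orientation_polarizability <- function(eps, n) {
  if (any(eps < 1) || any(n < 1)) stop("eps and n must be >= 1")
  (eps - 1) / (2 * eps + 1) - (n^2 - 1) / (2 * n^2 + 1)
}

#' Stokes shift in wavenumbers
#'
#' Delta nu = 10^7 (1/lambda_abs - 1/lambda_em) cm^-1; positive when the
#' emission maximum lies to the red of the absorption maximum.
#'
#' @param lambda_abs_nm Absorption maximum, nm, > 0.
#' @param lambda_em_nm Emission maximum, nm, > 0.
#' @return Stokes shift in cm^-1. Vectorized.
#' @export
#' @examples
#' stokes_shift(346, 465.5)  # 7419.5 cm^-1 (DMSO)
stokes_shift <- function(lambda_abs_nm, lambda_em_nm) {
  if (any(lambda_abs_nm <= 0) || any(lambda_em_nm <= 0)) {
    stop("wavelengths must be positive")
  }
  1e7 * (1 / lambda_abs_nm - 1 / lambda_em_nm)
}

#' Build a solvatochromic series
#'
#' Combines per-solvent constants with the dye's absorption and emission
#' maxima. The Stokes shift and orientation polarizability columns are
#' always recomputed from the maxima and (eps, n) — never read from input
#' tables — so there is one source of truth.
#'
#' @param solvent Character vector of solvent names.
#' @param eps,n Solvent dielectric constants and refractive indices.
#' @param etn Normalized Reichardt polarity E_T(N) (may be `NA` if only a
#'   Lippert fit is wanted).
#' @param lambda_abs_nm,lambda_em_nm Dye absorption/emission maxima (nm);
#'   every emission maximum must be red of its absorption maximum.
#' @return A data.frame of class `solvatochromic_series` with derived
#'   columns `stokes_cm1` and `delta_f`.
#' @export
solvatochromic_series <- function(solvent, eps, n, etn = NA_real_,
                                  lambda_abs_nm, lambda_em_nm) {
  df <- data.frame(solvent = as.character(solvent), eps = eps, n = n,
                   etn = etn, lambda_abs_nm = lambda_abs_nm,
                   lambda_em_nm = lambda_em_nm, stringsAsFactors = FALSE)
  if (nrow(df) < 3) stop("a solvatochromic series needs at least 3 solvents")
  if (any(df$lambda_em_nm <= df$lambda_abs_nm)) {
    stop("every emission maximum must lie red of the absorption maximum")
  }
  df$stokes_cm1 <- stokes_shift(df$lambda_abs_nm, df$lambda_em_nm)
  df$delta_f <- orientation_polarizability(df$eps, df$n)
  class(df) <- c("solvatochromic_series", "data.frame")
  df
}

#' Read a solvatochromic series from CSV
#'
#' Expects named columns `solvent,eps,n,etn,lambda_abs_nm,lambda_em_nm`
#' (`etn` optional).
#'
#' @param path CSV path.
#' @return A [solvatochromic_series()].
#' @export
read_solvatochromic_series <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("solvent", "eps", "n", "lambda_abs_nm", "lambda_em_nm")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  solvatochromic_series(tab$solvent, tab$eps, tab$n,
                        if ("etn" %in% names(tab)) tab$etn else NA_real_,
                        tab$lambda_abs_nm, tab$lambda_em_nm)
}

# shared OLS helper: unweighted simple linear regression with free intercept.
# Summary statistics are computed directly so exact (zero-residual) fits do
# not trigger summary.lm() warnings; r_squared is 1 for an exact fit of
# constant data.
linear_fit <- function(x, y) {
  if (length(x) < 3) stop("at least 3 points required for a linear fit")
  if (stats::var(x) == 0) stop("zero variance in the regressor")
  fit <- stats::lm(y ~ x)
  res <- unname(stats::residuals(fit))
  n <- length(x)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((x - mean(x))^2)
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = sqrt(rss / (n - 2) / sxx),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       n_points = n,
       residuals = res)
}

fit_result <- function(fit, derived_name, derived_value, units, flag = NULL) {
  structure(c(fit, list(derived_quantity = stats::setNames(derived_value, derived_name),
                        units = units, flag = flag)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit> slope %.6g +/- %.3g, intercept %.6g, R2 %.4f, n %d\n",
              x$slope, x$slope_se, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  %s = %.6g %s%s\n", names(x$derived_quantity),
              x$derived_quantity, x$units,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Lippert-Mataga dipole-moment change
#'
#' Ordinary least squares of the Stokes shift (cm^-1) on the orientation
#' polarizability Delta f; the excited-ground dipole change is recovered
#' from the slope m as Delta mu = sqrt(m h c a^3 / 2), evaluated in CGS
#' (slope in cm^-1, cavity radius in cm, result in esu cm) and converted
#' to Debye. A negative slope yields Delta mu = 0 with a flag.
#'
#' @param series A [solvatochromic_series()] (>= 3 solvents).
#' @param onsager_radius_angstrom Onsager cavity radius a, Angstrom, > 0.
#' @param exclude Optional character vector of solvent names to drop
#'   before fitting.
#' @return A `fit_result` whose `derived_quantity` is `delta_mu_debye`.
#' @export
lippert_fit <- function(series, onsager_radius_angstrom, exclude = NULL) {
  stopifnot(inherits(series, "solvatochromic_series"))
  if (onsager_radius_angstrom <= 0) stop("cavity radius must be positive")
  if (!is.null(exclude)) series <- series[!series$solvent %in% exclude, ]
  fit <- linear_fit(series$delta_f, series$stokes_cm1)
  k <- photophysical_constants()
  a_cm <- onsager_radius_angstrom * 1e-8
  flag <- NULL
  if (fit$slope < 0) {
    dmu <- 0
    flag <- "negative slope; Delta mu set to 0"
  } else {
    dmu <- sqrt(fit$slope * k$h_erg_s * k$c_cm_s * a_cm^3 / 2) / k$debye_esu_cm
  }
  fit_result(fit, "delta_mu_debye", dmu, "D", flag)
}

#' Reichardt dipole-moment change
#'
#' Ordinary least squares of the Stokes shift (cm^-1) on the normalized
#' solvent polarity E_T(N); the dipole change follows from the slope m as
#' Delta mu = sqrt(m * 81 / ((6.2/a)^3 * 11307.6)) Debye, referenced to
#' the betaine probe (a_B = 6.2 Angstrom, mu_B = 9 D).
#'
#' @inheritParams lippert_fit
#' @return A `fit_result` whose `derived_quantity` is `delta_mu_debye`.
#' @export
reichardt_fit <- function(series, onsager_radius_angstrom, exclude = NULL) {
  stopifnot(inherits(series, "solvatochromic_series"))
  if (onsager_radius_angstrom <= 0) stop("cavity radius must be positive")
  if (!is.null(exclude)) series <- series[!series$solvent %in% exclude, ]
  if (anyNA(series$etn)) stop("E_T(N) missing for some solvents")
  fit <- linear_fit(series$etn, series$stokes_cm1)
  k <- photophysical_constants()
  flag <- NULL
  if (fit$slope < 0) {
    dmu <- 0
    flag <- "negative slope; Delta mu set to 0"
  } else {
    dmu <- sqrt(fit$slope * k$reichardt_mu_b^2 /
                  ((k$reichardt_a_b / onsager_radius_angstrom)^3 * k$reichardt_factor))
  }
  fit_result(fit, "delta_mu_debye", dmu, "D", flag)
}

#' Reichardt polarity conversions
#'
#' `et_normalized_from_et30()` maps the molar transition energy E_T(30)
#' (kcal mol^-1) onto the normalized scale E_T(N) = (E_T - 30.7)/32.4
#' (water = 1, TMS = 0). `et30_from_lambda()` computes E_T(30) =
#' 28591 / lambda_max from the betaine probe's absorption maximum in nm.
#'
#' @param et30_kcal_mol E_T(30) value(s), kcal mol^-1.
#' @param lambda_max_nm Betaine absorption maximum, nm, > 0.
#' @return Numeric vector.
#' @export
#' @examples
#' et_normalized_from_et30(55.4)  # 0.762 (methanol)
#' et30_from_lambda(453.2)        # 63.09 kcal/mol
et_normalized_from_et30 <- function(et30_kcal_mol) {
  k <- photophysical_constants()
  (et30_kcal_mol - k$et_offset) / k$et_scale
}

#' @rdname et_normalized_from_et30
#' @export
et30_from_lambda <- function(lambda_max_nm) {
  if (any(lambda_max_nm <= 0)) stop("wavelength must be positive")
  photophysical_constants()$et_numerator / lambda_max_nm
}

#' Oscillator strength from a molar extinction spectrum
#'
#' f = 4.32e-10 * integral of epsilon(nu) d nu, with the spectrum on a
#' wavenumber axis (cm^-1) and epsilon in M^-1 cm^-1.
#'
#' @param extinction_spectrum A [spectrum()] with
#'   `axis_kind == "wavenumber_cm1"` and non-negative signal.
#' @param range Optional wavenumber interval over which to integrate
#'   (default: the full axis span).
#' @return Dimensionless oscillator strength.
#' @export
oscillator_strength <- function(extinction_spectrum, range = NULL) {
  stopifnot(inherits(extinction_spectrum, "spectrum"))
  if (extinction_spectrum$axis_kind != "wavenumber_cm1") {
    stop("oscillator strength needs a wavenumber (cm^-1) axis")
  }
  if (any(extinction_spectrum$signal < 0)) stop("extinction must be >= 0")
  if (is.null(range)) range <- range(extinction_spectrum$axis)
  photophysical_constants()$oscillator_prefactor *
    integrate_band(extinction_spectrum, range)
}

#' Transition dipole moment from oscillator strength
#'
#' mu_12 = sqrt(f / (4.72e-7 * E_max)) Debye, with E_max the absorption
#' maximum in cm^-1.
#'
#' @param f Oscillator strength, >= 0.
#' @param e_max_cm1 Transition energy at the absorption maximum, cm^-1, > 0.
#' @return Transition dipole moment in Debye.
#' @export
#' @examples
#' transition_dipole(0.23, nm_to_wavenumber(358.5))  # ~4.18 D
transition_dipole <- function(f, e_max_cm1) {
  if (any(f < 0)) stop("oscillator strength must be >= 0")
  if (any(e_max_cm1 <= 0)) stop("transition energy must be positive")
  sqrt(f / (photophysical_constants()$transition_dipole_factor * e_max_cm1))
}

#' Relative fluorescence quantum yield
#'
#' Phi_s = Phi_r (I_s/I_r) (A_r/A_s) (n_s^2/n_r^2), relative to a
#' reference fluorophore (e.g. quinine sulfate in 0.5 M H2SO4,
#' Phi = 0.54). A warning is emitted when either absorbance exceeds 0.1,
#' where reabsorption starts to bias the comparison.
#'
#' @param i_sample,i_ref Integrated emission areas of sample/reference, > 0.
#' @param a_sample,a_ref Absorbances at the excitation wavelength, > 0.
#' @param n_sample,n_ref Solvent refractive indices.
#' @param phi_ref Reference quantum yield (default 0.54).
#' @return The sample quantum yield Phi_s.
#' @export
quantum_yield_relative <- function(i_sample, i_ref, a_sample, a_ref,
                                   n_sample, n_ref, phi_ref = 0.54) {
  vals <- c(i_sample, i_ref, a_sample, a_ref, n_sample, n_ref, phi_ref)
  if (any(vals <= 0)) stop("all intensities, absorbances and indices must be positive")
  if (a_sample > 0.1 || a_ref > 0.1) {
    warning("absorbance above 0.1: reabsorption may bias the relative yield")
  }
  phi_ref * (i_sample / i_ref) * (a_ref / a_sample) * (n_sample^2 / n_ref^2)
}
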