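#' Physical constants used throughout the package
#'
#' Returns the frozen set of physical constants the analysis chain relies
#' on. The solvatochromic unit chain is CGS (erg s, cm s^-1, esu cm) with a
#' single conversion to Debye at the boundary (1 D = 1e-18 esu cm).
#'
#' @return A named list:
#' \describe{
#'   \item{h_erg_s}{Planck constant, erg s.}
#'   \item{c_cm_s}{Speed of light in vacuum, cm s^-1.}
#'   \item{n_avogadro}{Avogadro constant, mol^-1.}
#'   \item{hc_ev_nm}{Product h*c expressed in eV nm, for nm <-> eV
#'     conversion (CODATA rounding, 1239.842).}
#'   \item{debye_esu_cm}{One Debye in esu cm (1e-18).}
#'   \item{reichardt_factor}{Slope prefactor of the Reichardt dipole
#'     correlation (11307.6).}
#'   \item{reichardt_a_b}{Onsager radius of Reichardt's betaine dye, in
#'     Angstrom (6.2).}
#'   \item{reichardt_mu_b}{Dipole-moment change of Reichardt's betaine
#'     dye, in Debye (9).}
#'   \item{et_numerator}{Numerator of the E_T(30) wavelength relation,
#'     kcal mol^-1 nm (28591).}
#'   \item{et_offset, et_scale}{Affine constants of the normalized
#'     E_T(N) polarity scale (30.7 and 32.4 kcal mol^-1; water = 1,
#'     tetramethylsilane = 0).}
#'   \item{n0_per_cm3_m}{Avogadro number per (cm^3 M), i.e. molecules per
#'     cm^3 at 1 mol L^-1 (6.02214076e20); used by the Perrin model so
#'     the active-sphere volume lands in cm^3.}
#'   \item{oscillator_prefactor}{Prefactor of the oscillator-strength
#'     integral over the molar extinction spectrum (4.32e-10).}
#'   \item{transition_dipole_factor}{Denominator factor linking f, the
#'     transition energy in cm^-1 and mu_12^2 in Debye^2 (4.72e-7).}
#'   \item{xray_wavelength_nm}{Default X-ray wavelength, Cu K-alpha-1,
#'     0.15406 nm.}
#'   \item{scherrer_k}{Default Scherrer shape constant, 0.98.}
#' }
#' @export
#' @examples
#' photophysical_constants()$hc_ev_nm
photophysical_constants <- function() {
  list(
    h_erg_s = 6.62607015e-27,
    c_cm_s = 2.99792458e10,
    n_avogadro = 6.02214076e23,
    hc_ev_nm = 1239.842,
    debye_esu_cm = 1e-18,
    reichardt_factor = 11307.6,
    reichardt_a_b = 6.2,
    reichardt_mu_b = 9,
    et_numerator = 28591,
    et_offset = 30.7,
    et_scale = 32.4,
    n0_per_cm3_m = 6.02214076e20,
    oscillator_prefactor = 4.32e-10,
    transition_dipole_factor = 4.72e-7,
    xray_wavelength_nm = 0.15406,
    scherrer_k = 0.98
  )
}
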