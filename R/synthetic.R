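#' Generator specification for synthetic data
#'
#' Bundles the seed, noise model and (optional) grid definition shared by
#' all synthetic-data generators. Each generator derives its own
#' pseudo-random stream from `(seed, operation name)`, so results do not
#' depend on call order, and an identical spec always yields bit-identical
#' output.
#'
#' Noise-model conventions: for spectra, `additive_gaussian` adds noise
#' with standard deviation `sigma * max(clean signal)` (sigma is relative)
#' and `multiplicative_gaussian` multiplies each point by
#' `1 + N(0, sigma)`. For solvatochromic series the additive sigma is
#' absolute, in cm^-1 on the Stokes shift.
#'
#' @param seed Integer seed.
#' @param noise_model One of `"none"`, `"additive_gaussian"`,
#'   `"multiplicative_gaussian"`.
#' @param sigma Noise scale (see conventions above).
#' @param grid_start,grid_stop,grid_step Optional grid definition in axis
#'   units.
#' @return A list of class `generator_spec`.
#' @export
#' @examples
#' generator_spec(1, "multiplicative_gaussian", sigma = 0.05)
generator_spec <- function(seed,
                           noise_model = c("none", "additive_gaussian",
                                           "multiplicative_gaussian"),
                           sigma = 0,
                           grid_start = NULL, grid_stop = NULL, grid_step = NULL) {
  noise_model <- match.arg(noise_model)
  if (noise_model != "none" && sigma <= 0) {
    stop("sigma must be positive for a noisy generator")
  }
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 sigma = sigma, grid_start = grid_start,
                 grid_stop = grid_stop, grid_step = grid_step),
            class = "generator_spec")
}

# derive a stream seed from (seed, operation name) and run `expr` under it,
# restoring the caller's RNG state afterwards
with_stream <- function(spec, op, expr) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  # double arithmetic: seed * 7919 can exceed the 32-bit integer range
  stream_seed <- as.integer((abs(as.numeric(spec$seed)) * 7919 + h) %% 2147483647)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed)
  expr
}

spec_grid <- function(spec, default_start, default_stop, default_step) {
  start <- if (is.null(spec$grid_start)) default_start else spec$grid_start
  stop_ <- if (is.null(spec$grid_stop)) default_stop else spec$grid_stop
  step <- if (is.null(spec$grid_step)) default_step else spec$grid_step
  seq(start, stop_, by = step)
}

apply_noise <- function(clean, spec) {
  switch(spec$noise_model,
         none = clean,
         additive_gaussian = clean +
           stats::rnorm(length(clean), 0, spec$sigma * max(abs(clean))),
         multiplicative_gaussian = clean *
           (1 + stats::rnorm(length(clean), 0, spec$sigma)))
}

#' Synthesize a Gaussian optical band
#'
#' One Gaussian band on a wavelength grid, plus noise per the generator
#' spec. The grid must cover center +/- 4 sigma.
#'
#' @param center_nm Band center, nm.
#' @param sigma_nm Gaussian width, nm, > 0 (FWHM = 2.3548 sigma).
#' @param amplitude Peak amplitude.
#' @param spec A [generator_spec()]; default grid is
#'   `center +/- 5 sigma` at 1 nm steps.
#' @return A [spectrum()] on a wavelength axis.
#' @export
gen_band_spectrum <- function(center_nm, sigma_nm, amplitude, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (sigma_nm <= 0) stop("sigma must be positive")
  grid <- spec_grid(spec, center_nm - 5 * sigma_nm, center_nm + 5 * sigma_nm, 1)
  if (min(grid) > center_nm - 4 * sigma_nm || max(grid) < center_nm + 4 * sigma_nm) {
    stop("grid too narrow: must cover center +/- 4 sigma")
  }
  clean <- amplitude * exp(-(grid - center_nm)^2 / (2 * sigma_nm^2))
  signal <- if (amplitude == 0) clean else with_stream(spec, "gen_band_spectrum",
                                                       apply_noise(clean, spec))
  spectrum(grid, signal, "wavelength_nm",
           label = sprintf("synthetic band %g nm", center_nm))
}

#' Synthesize a solvatochromic series from the Lippert forward model
#'
#' Stokes shifts are generated on the line
#' `Delta nu_i = (2 Delta mu^2 / (h c a^3)) Delta f_i + intercept` (CGS
#' units, Delta mu in Debye, a in Angstrom), with optional additive
#' Gaussian noise (`sigma` in cm^-1). The absorption maximum is fixed at
#' 360 nm and each emission maximum is solved so that [stokes_shift()]
#' reproduces the generated Stokes shift exactly.
#'
#' @param delta_mu_debye Target dipole-moment change, Debye, >= 0.
#' @param onsager_radius_angstrom Cavity radius a, Angstrom, > 0.
#' @param intercept_cm1 Intercept of the line, cm^-1.
#' @param solvents Data.frame with columns `solvent`, `eps`, `n` and
#'   optionally `etn` (>= 3 rows); defaults to [triazine_solvent_table()].
#' @param spec A [generator_spec()].
#' @return A [solvatochromic_series()].
#' @export
gen_solvatochromic_series <- function(delta_mu_debye, onsager_radius_angstrom,
                                      intercept_cm1 = 5000,
                                      solvents = triazine_solvent_table(),
                                      spec = generator_spec(1, "none")) {
  stopifnot(inherits(spec, "generator_spec"))
  if (delta_mu_debye < 0) stop("delta mu must be >= 0")
  if (nrow(solvents) < 3) stop("at least 3 solvents required")
  k <- photophysical_constants()
  a_cm <- onsager_radius_angstrom * 1e-8
  slope <- 2 * (delta_mu_debye * k$debye_esu_cm)^2 / (k$h_erg_s * k$c_cm_s * a_cm^3)
  df <- orientation_polarizability(solvents$eps, solvents$n)
  dnu <- slope * df + intercept_cm1
  if (spec$noise_model == "additive_gaussian") {
    dnu <- with_stream(spec, "gen_solvatochromic_series",
                       dnu + stats::rnorm(length(dnu), 0, spec$sigma))
  } else if (spec$noise_model == "multiplicative_gaussian") {
    dnu <- with_stream(spec, "gen_solvatochromic_series",
                       dnu * (1 + stats::rnorm(length(dnu), 0, spec$sigma)))
  }
  lambda_abs <- 360
  inv_em <- 1 / lambda_abs - dnu / 1e7
  if (any(inv_em <= 0) || any(dnu <= 0)) {
    stop("generated Stokes shifts imply non-physical emission maxima")
  }
  solvatochromic_series(solvents$solvent, solvents$eps, solvents$n,
                        if ("etn" %in% names(solvents)) solvents$etn else NA_real_,
                        rep(lambda_abs, nrow(solvents)), 1 / inv_em)
}

#' Synthesize a solvatochromic series from the Reichardt forward model
#'
#' As [gen_solvatochromic_series()], but the generating line is
#' `Delta nu_i = m E_T(N)_i + intercept` with
#' `m = Delta mu^2 (6.2/a)^3 11307.6 / 81`.
#'
#' @inheritParams gen_solvatochromic_series
#' @return A [solvatochromic_series()].
#' @export
gen_reichardt_series <- function(delta_mu_debye, onsager_radius_angstrom,
                                 intercept_cm1 = 5000,
                                 solvents = triazine_solvent_table(),
                                 spec = generator_spec(1, "none")) {
  stopifnot(inherits(spec, "generator_spec"))
  if (delta_mu_debye < 0) stop("delta mu must be >= 0")
  if (nrow(solvents) < 3 || anyNA(solvents$etn)) {
    stop("at least 3 solvents with E_T(N) required")
  }
  k <- photophysical_constants()
  slope <- delta_mu_debye^2 * (k$reichardt_a_b / onsager_radius_angstrom)^3 *
    k$reichardt_factor / k$reichardt_mu_b^2
  dnu <- slope * solvents$etn + intercept_cm1
  if (spec$noise_model == "additive_gaussian") {
    dnu <- with_stream(spec, "gen_reichardt_series",
                       dnu + stats::rnorm(length(dnu), 0, spec$sigma))
  } else if (spec$noise_model == "multiplicative_gaussian") {
    dnu <- with_stream(spec, "gen_reichardt_series",
                       dnu * (1 + stats::rnorm(length(dnu), 0, spec$sigma)))
  }
  inv_em <- 1 / 360 - dnu / 1e7
  if (any(inv_em <= 0) || any(dnu <= 0)) {
    stop("generated Stokes shifts imply non-physical emission maxima")
  }
  solvatochromic_series(solvents$solvent, solvents$eps, solvents$n,
                        solvents$etn, rep(360, nrow(solvents)), 1 / inv_em)
}

#' Synthesize a quenching/enhancement titration
#'
#' Intensities follow the chosen law — Stern-Volmer
#' `I = I0 / (1 + K_SV [Q])`, Perrin `I = I0 exp(-V N0 [Q])`, or a linear
#' enhancement ramp up to `max_factor` — with multiplicative noise per the
#' generator spec. Lifetimes are attached noiselessly: constant at `tau0`
#' for a static series, or scaled by the clean I/I0 ratio for a dynamic
#' one.
#'
#' @param mode `"stern_volmer"`, `"perrin"`, or `"enhancement"`.
#' @param parameter K_SV in M^-1, V in cm^3, or the top enhancement
#'   factor, respectively; >= 0.
#' @param q_grid Quencher concentrations, mol L^-1, starting at 0,
#'   ascending.
#' @param i0 Unquenched intensity (default 1000).
#' @param spec A [generator_spec()].
#' @param dynamic If `TRUE`, lifetimes track the intensity ratio
#'   (collisional quenching); otherwise they stay at `tau0_ns` (static).
#' @param tau0_ns Unquenched lifetime, ns.
#' @return A [quenching_series()].
#' @export
gen_quenching_series <- function(mode = c("stern_volmer", "perrin", "enhancement"),
                                 parameter, q_grid, i0 = 1000,
                                 spec = generator_spec(1, "none"),
                                 dynamic = FALSE, tau0_ns = 2.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "generator_spec"))
  if (parameter < 0) stop("parameter must be >= 0")
  if (q_grid[1] != 0 || is.unsorted(q_grid, strictly = TRUE)) {
    stop("q_grid must start at 0 and be ascending")
  }
  n0 <- photophysical_constants()$n0_per_cm3_m
  clean <- switch(mode,
                  stern_volmer = i0 / (1 + parameter * q_grid),
                  perrin = i0 * exp(-parameter * n0 * q_grid),
                  enhancement = i0 * (1 + (parameter - 1) * q_grid / max(q_grid)))
  intensity <- with_stream(spec, paste0("gen_quenching_series_", mode), {
    out <- apply_noise(clean, spec)
    pmax(out, .Machine$double.eps * i0)
  })
  lifetimes <- if (dynamic) tau0_ns * clean / i0 else rep(tau0_ns, length(q_grid))
  quenching_series(q_grid, intensity, lifetime_ns = lifetimes, tau0_ns = tau0_ns)
}

#' Synthesize a powder XRD pattern with Scherrer-broadened peaks
#'
#' Gaussian peaks whose angular FWHM follows the inverted Scherrer
#' relation `beta = K lambda / (D cos theta)` for a chosen crystallite
#' size D, on a constant baseline, plus noise per the generator spec.
#'
#' @param peaks Data.frame with columns `two_theta` (degrees) and `height`
#'   (relative intensities).
#' @param crystallite_d_nm Crystallite size D, nm, > 0.
#' @param wavelength_nm X-ray wavelength, nm.
#' @param spec A [generator_spec()]; default grid 30-80 degrees at 0.02.
#' @param k Scherrer constant.
#' @param baseline Constant background level (fraction of the tallest
#'   peak; default 0.02).
#' @return A [spectrum()] on a 2-theta axis.
#' @export
gen_xrd_pattern <- function(peaks, crystallite_d_nm,
                            wavelength_nm = photophysical_constants()$xray_wavelength_nm,
                            spec = generator_spec(1, "none"),
                            k = photophysical_constants()$scherrer_k,
                            baseline = 0.02) {
  stopifnot(inherits(spec, "generator_spec"),
            all(c("two_theta", "height") %in% names(peaks)))
  if (crystallite_d_nm <= 0) stop("crystallite size must be positive")
  grid <- spec_grid(spec, 30, 80, 0.02)
  if (any(peaks$two_theta < min(grid)) || any(peaks$two_theta > max(grid))) {
    stop("all peaks must lie within the grid")
  }
  hmax <- max(peaks$height)
  clean <- rep(baseline * hmax, length(grid))
  for (i in seq_len(nrow(peaks))) {
    theta <- peaks$two_theta[i] / 2 * pi / 180
    beta_rad <- k * wavelength_nm / (crystallite_d_nm * cos(theta))
    fwhm_deg <- beta_rad * 180 / pi
    s <- fwhm_deg / (2 * sqrt(2 * log(2)))
    clean <- clean + peaks$height[i] * exp(-(grid - peaks$two_theta[i])^2 / (2 * s^2))
  }
  signal <- with_stream(spec, "gen_xrd_pattern", apply_noise(clean, spec))
  spectrum(grid, signal, "two_theta_deg",
           label = sprintf("synthetic XRD, D = %g nm", crystallite_d_nm))
}

#' Silver/gold nanoparticle reflection lists
#'
#' The four FCC Bragg reflections (111), (200), (220), (311) of citrate
#' silver and gold colloids, with representative relative intensities.
#'
#' @param metal `"ag"` or `"au"`.
#' @return Data.frame with `two_theta`, `height`, `hkl`.
#' @export
#' @examples
#' nanoparticle_reflections("ag")
nanoparticle_reflections <- function(metal = c("ag", "au")) {
  metal <- match.arg(metal)
  if (metal == "ag") {
    data.frame(two_theta = c(38.21, 44.41, 64.5, 77.4),
               height = c(100, 40, 30, 28),
               hkl = c("(111)", "(200)", "(220)", "(311)"))
  } else {
    data.frame(two_theta = c(38.1, 44.2, 65.5, 77.7),
               height = c(100, 35, 25, 25),
               hkl = c("(111)", "(200)", "(220)", "(311)"))
  }
}

#' Synthesize a monoexponential fluorescence decay trace
#'
#' counts = A exp(-t / tau) plus noise per the generator spec (after
#' noise, counts are clipped to stay positive so the log-linear fit is
#' defined).
#'
#' @param tau_ns Lifetime, ns, > 0.
#' @param amplitude Initial count rate (default 1e4).
#' @param spec A [generator_spec()]; default grid 0 to 8 tau at tau/25
#'   steps.
#' @return A [spectrum()] with `axis_kind == "time_ns"`.
#' @export
gen_decay_trace <- function(tau_ns, amplitude = 1e4,
                            spec = generator_spec(1, "none")) {
  stopifnot(inherits(spec, "generator_spec"))
  if (tau_ns <= 0) stop("tau must be positive")
  grid <- spec_grid(spec, 0, 8 * tau_ns, tau_ns / 25)
  clean <- amplitude * exp(-grid / tau_ns)
  signal <- with_stream(spec, "gen_decay_trace", {
    out <- apply_noise(clean, spec)
    pmax(out, .Machine$double.eps * amplitude)
  })
  spectrum(grid, signal, "time_ns", label = sprintf("decay tau = %g ns", tau_ns))
}
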