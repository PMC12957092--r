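#' Build a quenching titration series
#'
#' Quencher concentrations with the fluorophore's emission intensities
#' (and optional lifetimes). Concentrations must be non-negative, strictly
#' increasing, and start at 0; the intensity at `[Q] = 0` is taken as I0.
#'
#' @param q_molar Quencher concentrations, mol L^-1.
#' @param intensity Emission intensities (> 0) at each concentration.
#' @param lifetime_ns Optional excited-state lifetimes (ns) at each
#'   concentration.
#' @param tau0_ns Unquenched fluorophore lifetime (ns); defaults to
#'   `lifetime_ns[1]` when lifetimes are given.
#' @return A data.frame of class `quenching_series`, with the unquenched
#'   lifetime in `attr(, "tau0_ns")`.
#' @export
quenching_series <- function(q_molar, intensity, lifetime_ns = NULL,
                             tau0_ns = NULL) {
  if (length(q_molar) != length(intensity)) {
    stop("q_molar and intensity must have equal length")
  }
  if (any(q_molar < 0)) stop("concentrations must be non-negative")
  if (is.unsorted(q_molar, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  if (q_molar[1] != 0) stop("the first concentration must be 0 (defines I0)")
  if (any(intensity <= 0)) stop("intensities must be positive")
  df <- data.frame(q_molar = q_molar, intensity = intensity)
  if (!is.null(lifetime_ns)) {
    if (length(lifetime_ns) != length(q_molar)) {
      stop("lifetime_ns must match q_molar in length")
    }
    if (any(lifetime_ns <= 0)) stop("lifetimes must be positive")
    df$lifetime_ns <- lifetime_ns
    if (is.null(tau0_ns)) tau0_ns <- lifetime_ns[1]
  }
  attr(df, "tau0_ns") <- tau0_ns
  class(df) <- c("quenching_series", "data.frame")
  df
}

#' Read a quenching titration from CSV
#'
#' Expects named columns `q_molar,intensity` and optionally `lifetime_ns`.
#'
#' @param path CSV path.
#' @param tau0_ns Optional unquenched lifetime (ns).
#' @return A [quenching_series()].
#' @export
read_quenching_series <- function(path, tau0_ns = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("q_molar", "intensity") %in% names(tab))) {
    stop("missing columns: need q_molar and intensity")
  }
  quenching_series(tab$q_molar, tab$intensity,
                   if ("lifetime_ns" %in% names(tab)) tab$lifetime_ns else NULL,
                   tau0_ns)
}

#' Stern-Volmer fit
#'
#' Ordinary least squares of I0/I on the quencher concentration with a
#' free intercept; the Stern-Volmer constant K_SV is the slope. A warning
#' flags an intercept deviating from 1 by more than 5%.
#'
#' @param series A [quenching_series()] with at least 3 nonzero
#'   concentrations.
#' @return A `fit_result` whose `derived_quantity` is `ksv_m1` (M^-1).
#' @export
stern_volmer_fit <- function(series) {
  stopifnot(inherits(series, "quenching_series"))
  if (sum(series$q_molar > 0) < 3) {
    stop("at least 3 nonzero quencher concentrations required")
  }
  i0 <- series$intensity[1]
  y <- i0 / series$intensity
  fit <- linear_fit(series$q_molar, y)
  flag <- NULL
  if (abs(fit$intercept - 1) > 0.05) {
    flag <- "intercept deviates from 1 by more than 5%"
    warning(flag)
  }
  fit_result(fit, "ksv_m1", fit$slope, "M^-1", flag)
}

#' Bimolecular quenching rate constant
#'
#' k_q = K_SV / tau_f, with the unquenched lifetime converted from ns to s.
#'
#' @param ksv_m1 Stern-Volmer constant, M^-1.
#' @param tau_f_ns Unquenched excited-state lifetime, ns, > 0.
#' @return k_q in M^-1 s^-1.
#' @export
#' @examples
#' bimolecular_rate(6.7e9, 2.1)  # 3.19e18 M^-1 s^-1
bimolecular_rate <- function(ksv_m1, tau_f_ns) {
  if (any(tau_f_ns <= 0)) stop("lifetime must be positive")
  ksv_m1 / (tau_f_ns * 1e-9)
}

#' Classify the quenching mechanism
#'
#' Applies, in order: enhancement when the fitted Stern-Volmer slope is
#' negative; superquenching when K_SV >= 1e7 M^-1 (the accepted
#' 1e7-1e10 M^-1 range and above); otherwise static when the lifetimes
#' vary by less than 5% across the titration while intensity drops, or
#' dynamic when tau0/tau tracks I0/I within 10%. The k_q/k_d ratio is
#' reported when a diffusion rate constant is supplied (a ratio above 10
#' asserts a bound/static mechanism).
#'
#' @param ksv_m1 Fitted Stern-Volmer constant (slope), M^-1.
#' @param kq_m1s1 Optional bimolecular quenching rate constant, M^-1 s^-1.
#' @param kd_m1s1 Optional diffusion-limited rate constant, M^-1 s^-1, > 0.
#' @param series Optional [quenching_series()] carrying lifetimes, used
#'   for the lifetime-invariance diagnostic.
#' @return A list: `classification` (one of `"enhancement"`,
#'   `"superquenching"`, `"static"`, `"dynamic"`), `mechanism`
#'   (`"static"`, `"dynamic"` or `"unknown"`), `lifetime_invariant`
#'   (logical or `NA` when lifetimes are missing), and `kq_kd_ratio`.
#' @export
classify_quenching <- function(ksv_m1, kq_m1s1 = NULL, kd_m1s1 = NULL,
                               series = NULL) {
  if (!is.null(kd_m1s1) && kd_m1s1 <= 0) stop("kd must be positive")
  ratio <- if (!is.null(kq_m1s1) && !is.null(kd_m1s1)) kq_m1s1 / kd_m1s1 else NA_real_

  lifetime_invariant <- NA
  tau_tracks_intensity <- NA
  if (!is.null(series) && !is.null(series$lifetime_ns)) {
    tau <- series$lifetime_ns
    lifetime_invariant <- (max(tau) - min(tau)) / mean(tau) < 0.05
    ratio_i <- series$intensity[1] / series$intensity
    ratio_t <- tau[1] / tau
    tau_tracks_intensity <- all(abs(ratio_t - ratio_i) <= 0.10 * ratio_i)
  }

  intensity_drops <- !is.null(series) &&
    utils::tail(series$intensity, 1) < series$intensity[1]

  mechanism <- if (isTRUE(lifetime_invariant) && intensity_drops) {
    "static"
  } else if (isTRUE(tau_tracks_intensity)) {
    "dynamic"
  } else if (is.na(lifetime_invariant) && !is.na(ratio) && ratio > 10) {
    "static"
  } else if (is.na(lifetime_invariant)) {
    "unknown"
  } else {
    "unknown"
  }

  classification <- if (ksv_m1 < 0) {
    "enhancement"
  } else if (ksv_m1 >= 1e7) {
    "superquenching"
  } else if (mechanism %in% c("static", "dynamic")) {
    mechanism
  } else {
    "dynamic"
  }

  list(classification = classification, mechanism = mechanism,
       lifetime_invariant = lifetime_invariant, kq_kd_ratio = ratio)
}

#' Perrin active-sphere fit
#'
#' Ordinary least squares of ln(I0/I) on the quencher concentration; the
#' slope equals V N0 with the active-sphere volume V in cm^3 and N0 the
#' number of molecules per cm^3 at 1 M (6.02214076e20), so
#' V = slope / N0. The sphere radius follows from
#' [radius_from_volume()].
#'
#' @inheritParams stern_volmer_fit
#' @return A `fit_result` whose `derived_quantity` is `perrin_v_cm3`,
#'   with the radius in the `perrin_r_nm` element.
#' @export
perrin_fit <- function(series) {
  stopifnot(inherits(series, "quenching_series"))
  if (sum(series$q_molar > 0) < 3) {
    stop("at least 3 nonzero quencher concentrations required")
  }
  i0 <- series$intensity[1]
  y <- log(i0 / series$intensity)
  fit <- linear_fit(series$q_molar, y)
  n0 <- photophysical_constants()$n0_per_cm3_m
  v <- max(fit$slope, 0) / n0
  out <- fit_result(fit, "perrin_v_cm3", v, "cm^3",
                    if (fit$slope < 0) "negative slope; V set to 0" else NULL)
  out$perrin_r_nm <- radius_from_volume(v)
  out
}

#' Active-sphere radius from its volume
#'
#' r = (3 V / 4 pi)^(1/3), converted cm -> nm.
#'
#' @param v_cm3 Sphere volume in cm^3, >= 0.
#' @return Radius in nm.
#' @export
#' @examples
#' radius_from_volume(8.52e-15)  # ~127 nm
radius_from_volume <- function(v_cm3) {
  if (any(v_cm3 < 0)) stop("volume must be >= 0")
  (3 * v_cm3 / (4 * pi))^(1 / 3) * 1e7
}

#' Fluorophore-quencher contact radius
#'
#' Simple sum R = R_fluorophore + R_quencher; used to compare against the
#' Perrin active-sphere radius. An active sphere exceeding the contact
#' distance indicates that (radiative/non-radiative) energy transfer, not
#' contact, drives the quenching.
#'
#' @param r_fluorophore_nm,r_quencher_nm Molecular radii in nm, >= 0.
#' @param perrin_r_nm Optional Perrin active-sphere radius (nm) for the
#'   comparison flag.
#' @return A list: `contact_r_nm`, and when `perrin_r_nm` is given,
#'   `exceeds_contact` plus a human-readable `flag`.
#' @export
#' @examples
#' contact_radius(0.41, 25, perrin_r_nm = 126)
contact_radius <- function(r_fluorophore_nm, r_quencher_nm, perrin_r_nm = NULL) {
  if (r_fluorophore_nm < 0 || r_quencher_nm < 0) stop("radii must be >= 0")
  out <- list(contact_r_nm = r_fluorophore_nm + r_quencher_nm)
  if (!is.null(perrin_r_nm)) {
    out$exceeds_contact <- perrin_r_nm > out$contact_r_nm
    out$flag <- if (out$exceeds_contact) {
      "active sphere exceeds contact distance: energy-transfer quenching"
    } else {
      "active sphere within contact distance"
    }
  }
  out
}

#' Full quenching report
#'
#' Runs the Stern-Volmer and Perrin chains on one titration and assembles
#' the classification. The report satisfies k_q = K_SV / tau_f and
#' V = (4/3) pi r^3 exactly.
#'
#' @param series A [quenching_series()].
#' @param tau0_ns Unquenched lifetime, ns (falls back to
#'   `attr(series, "tau0_ns")`).
#' @param kd_m1s1 Optional diffusion-limited rate constant, M^-1 s^-1.
#' @param r_fluorophore_nm,r_quencher_nm Optional molecular radii (nm) for
#'   the contact-radius comparison.
#' @return A list of class `quenching_report`.
#' @export
quenching_report <- function(series, tau0_ns = attr(series, "tau0_ns"),
                             kd_m1s1 = NULL, r_fluorophore_nm = NULL,
                             r_quencher_nm = NULL) {
  sv <- stern_volmer_fit(series)
  ksv <- unname(sv$derived_quantity)
  kq <- if (!is.null(tau0_ns)) bimolecular_rate(ksv, tau0_ns) else NULL
  pe <- perrin_fit(series)
  cls <- classify_quenching(ksv, kq, kd_m1s1, series)
  rep <- list(
    ksv_m1 = ksv, ksv_se = sv$slope_se, ksv_r_squared = sv$r_squared,
    kq_m1s1 = kq, kd_m1s1 = kd_m1s1, tau0_ns = tau0_ns,
    perrin_v_cm3 = unname(pe$derived_quantity), perrin_r_nm = pe$perrin_r_nm,
    perrin_r_squared = pe$r_squared,
    classification = cls$classification, mechanism = cls$mechanism,
    lifetime_invariant = cls$lifetime_invariant, kq_kd_ratio = cls$kq_kd_ratio
  )
  if (!is.null(r_fluorophore_nm) && !is.null(r_quencher_nm)) {
    rep <- c(rep, contact_radius(r_fluorophore_nm, r_quencher_nm,
                                 perrin_r_nm = rep$perrin_r_nm))
  }
  class(rep) <- "quenching_report"
  rep
}

#' @export
print.quenching_report <- function(x, ...) {
  cat(sprintf("<quenching report> K_SV %.4g M^-1 (R2 %.3f), %s\n",
              x$ksv_m1, x$ksv_r_squared, x$classification))
  if (!is.null(x$kq_m1s1)) cat(sprintf("  k_q %.4g M^-1 s^-1 (tau0 %.3g ns)\n",
                                       x$kq_m1s1, x$tau0_ns))
  cat(sprintf("  Perrin V %.4g cm^3, r %.4g nm; mechanism %s\n",
              x$perrin_v_cm3, x$perrin_r_nm, x$mechanism))
  invisible(x)
}

#' Metal-enhanced fluorescence curve
#'
#' Per-point enhancement factors I/I0 along a nanoparticle titration, with
#' a monotonicity summary. When full emission spectra are supplied for the
#' first and last points, the emission red-shift is measured as the
#' difference of their [peak_maximum()] positions.
#'
#' @param series A [quenching_series()] (>= 2 points; here rising
#'   intensities mean enhancement).
#' @param spectra Optional list of two [spectrum()] objects (no-particle
#'   and top-concentration emission spectra) for the peak-shift estimate.
#'   Band centers are located with [peak_maximum()] and refined over the
#'   top quarter of each band (emission bands are broad, so the multi-point
#'   vertex is far less noise-sensitive than a 3-point refinement).
#' @return A list: `factors` (I/I0 per point), `max_factor`, `monotone`
#'   (`"increasing"`, `"decreasing"` or `"mixed"`), and `peak_shift_nm`
#'   when spectra are given.
#' @export
enhancement_curve <- function(series, spectra = NULL) {
  stopifnot(inherits(series, "quenching_series"))
  if (nrow(series) < 2) stop("at least 2 points required")
  i0 <- series$intensity[1]
  if (i0 == 0) stop("I0 must be nonzero")
  factors <- series$intensity / i0
  d <- diff(factors)
  monotone <- if (all(d >= 0)) "increasing" else if (all(d <= 0)) "decreasing" else "mixed"
  out <- list(factors = factors, max_factor = max(factors), monotone = monotone)
  if (!is.null(spectra)) {
    stopifnot(length(spectra) == 2)
    center <- function(sp) {
      band <- peak_maximum(sp)
      refine_band_center(band, sp$axis, sp$signal)$peak_position
    }
    out$peak_shift_nm <- center(spectra[[2]]) - center(spectra[[1]])
  }
  out
}

#' Normalized spectral overlap
#'
#' Overlap between two spectra on wavelength axes: each spectrum is
#' normalized to unit area, both are linearly interpolated onto the common
#' grid, and the integral of the pointwise minimum is returned. The result
#' lies in [0, 1]: 1 for identical shapes, 0 for disjoint bands (with a
#' warning). Symmetric in its arguments and invariant to intensity
#' scaling.
#'
#' @param emission,plasmon Two [spectrum()] objects on wavelength axes
#'   with intersecting ranges.
#' @return Overlap fraction in [0, 1].
#' @export
overlap_integral <- function(emission, plasmon) {
  stopifnot(inherits(emission, "spectrum"), inherits(plasmon, "spectrum"))
  if (emission$axis_kind != "wavelength_nm" || plasmon$axis_kind != "wavelength_nm") {
    stop("overlap is defined on wavelength axes")
  }
  lo <- max(min(emission$axis), min(plasmon$axis))
  hi <- min(max(emission$axis), max(plasmon$axis))
  if (lo >= hi) {
    warning("disjoint wavelength ranges: overlap is 0")
    return(0)
  }
  a1 <- trapezoid(emission$axis, emission$signal)
  a2 <- trapezoid(plasmon$axis, plasmon$signal)
  if (a1 <= 0 || a2 <= 0) stop("spectra must have positive area")
  grid <- sort(unique(c(emission$axis[emission$axis >= lo & emission$axis <= hi],
                        plasmon$axis[plasmon$axis >= lo & plasmon$axis <= hi],
                        lo, hi)))
  y1 <- stats::approx(emission$axis, emission$signal / a1, xout = grid)$y
  y2 <- stats::approx(plasmon$axis, plasmon$signal / a2, xout = grid)$y
  trapezoid(grid, pmin(y1, y2))
}

#' Monoexponential lifetime fit
#'
#' Least squares of ln(counts) on time for an idealized (instrument
#' response neglected) decay trace; tau = -1/slope.
#'
#' @param decay A [spectrum()] with `axis_kind == "time_ns"` and positive
#'   counts (>= 10 points).
#' @return A `fit_result` whose `derived_quantity` is `tau_ns`.
#' @export
fit_monoexponential_decay <- function(decay) {
  stopifnot(inherits(decay, "spectrum"))
  if (decay$axis_kind != "time_ns") stop("decay trace must be on a time (ns) axis")
  if (length(decay$axis) < 10) stop("at least 10 points required")
  if (any(decay$signal <= 0)) stop("counts must be positive (remove background first)")
  fit <- linear_fit(decay$axis, log(decay$signal))
  if (fit$slope >= 0) stop("non-decaying trace: cannot fit a lifetime")
  fit_result(fit, "tau_ns", -1 / fit$slope, "ns")
}
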