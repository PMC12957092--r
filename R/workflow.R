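#' Run a named analysis workflow
#'
#' Dispatches one of the package's end-to-end workflows and returns a
#' machine-readable report (optionally written as JSON). Every report
#' echoes its inputs, the physical constants used, and a schema version,
#' so runs are auditable and byte-reproducible given the same config and
#' seed.
#'
#' Workflows:
#' \describe{
#'   \item{solvatochromism}{Input: series CSV
#'     (`solvent,eps,n,etn,lambda_abs_nm,lambda_em_nm`). Recomputes the
#'     Stokes-shift and orientation-polarizability columns and runs both
#'     dipole estimators ([lippert_fit()], [reichardt_fit()]). Params:
#'     `onsager_radius_angstrom` (required), `exclude` (solvent names).}
#'   \item{quench}{Input: titration CSV (`q_molar,intensity[,lifetime_ns]`).
#'     Runs the Stern-Volmer/Perrin chain via [quenching_report()].
#'     Params: `tau0_ns`, `kd_m1s1`, `r_fluorophore_nm`, `r_quencher_nm`.}
#'   \item{mef}{Input: titration CSV. Runs [enhancement_curve()].}
#'   \item{xrd}{Input: two-column pattern (2-theta, counts). Params:
#'     `window` (length 2, degrees; required), `wavelength_nm`, `k`.
#'     Runs [fit_gaussian_peak()] + [scherrer_size()].}
#'   \item{qy}{No input file; params `i_sample,i_ref,a_sample,a_ref,
#'     n_sample,n_ref,phi_ref` feed [quantum_yield_relative()].}
#'   \item{simulate}{Params: `generator` (one of `band`, `solvatochromic`,
#'     `quenching`, `xrd`, `decay`), `seed`, plus the generator's own
#'     arguments as a list in `args`; writes the result to `output_data`
#'     as CSV when given.}
#' }
#'
#' @param config A list: `workflow` (name), `input` (path, where needed),
#'   `params` (named list of overrides), `output` (optional JSON report
#'   path), `output_data` (optional CSV path, simulate only).
#' @return The report, a named list, invisibly when written to disk.
#' @export
run_workflow <- function(config) {
  stopifnot(is.list(config), !is.null(config[["workflow"]]))
  wf <- match.arg(config[["workflow"]],
                  c("solvatochromism", "quench", "mef", "xrd", "qy", "simulate"))
  params <- if (is.null(config[["params"]])) list() else config[["params"]]
  if (!is.null(config[["input"]]) && !file.exists(config[["input"]])) {
    stop("workflow '", wf, "': input file not found: ", config[["input"]])
  }
  body <- tryCatch(
    switch(wf,
           solvatochromism = wf_solvatochromism(config[["input"]], params),
           quench = wf_quench(config[["input"]], params),
           mef = wf_mef(config[["input"]], params),
           xrd = wf_xrd(config[["input"]], params),
           qy = wf_qy(params),
           simulate = wf_simulate(params, config[["output_data"]])),
    error = function(e) {
      stop("workflow '", wf, "' failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  report <- c(list(schema_version = "1.0", workflow = wf,
                   input = if (is.null(config[["input"]])) NA else config[["input"]],
                   params = params,
                   constants = photophysical_constants()),
              body)
  if (!is.null(config[["output"]])) {
    jsonlite::write_json(report, config[["output"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    return(invisible(report))
  }
  report
}

wf_solvatochromism <- function(input, params) {
  series <- read_solvatochromic_series(input)
  a <- params$onsager_radius_angstrom
  if (is.null(a)) stop("params$onsager_radius_angstrom is required")
  exclude <- params$exclude
  lip <- lippert_fit(series, a, exclude = exclude)
  rei <- if (anyNA(series$etn)) NULL else reichardt_fit(series, a, exclude = exclude)
  list(
    table = as.data.frame(series),
    excluded_solvents = if (is.null(exclude)) character(0) else exclude,
    lippert = fit_as_list(lip),
    reichardt = if (is.null(rei)) NULL else fit_as_list(rei)
  )
}

fit_as_list <- function(f) {
  list(slope = f$slope, slope_se = f$slope_se, intercept = f$intercept,
       r_squared = f$r_squared, n_points = f$n_points,
       delta_mu_debye = unname(f$derived_quantity),
       flag = if (is.null(f$flag)) NA else f$flag)
}

wf_quench <- function(input, params) {
  series <- read_quenching_series(input, tau0_ns = params$tau0_ns)
  rep <- quenching_report(series,
                          tau0_ns = if (is.null(params$tau0_ns))
                            attr(series, "tau0_ns") else params$tau0_ns,
                          kd_m1s1 = params$kd_m1s1,
                          r_fluorophore_nm = params$r_fluorophore_nm,
                          r_quencher_nm = params$r_quencher_nm)
  unclass(rep)
}

wf_mef <- function(input, params) {
  series <- read_quenching_series(input)
  enhancement_curve(series)
}

wf_xrd <- function(input, params) {
  if (is.null(params$window)) stop("params$window (degrees interval) is required")
  pattern <- read_spectrum(input, axis_kind = "two_theta_deg",
                           delim = params$delim)
  wl <- if (is.null(params$wavelength_nm))
    photophysical_constants()$xray_wavelength_nm else params$wavelength_nm
  k <- if (is.null(params[["k"]])) photophysical_constants()$scherrer_k else params[["k"]]
  peak <- fit_gaussian_peak(pattern, window = params$window)
  list(two_theta_center = peak$two_theta_center,
       fwhm_beta_rad = peak$fwhm_beta, fwhm_deg = peak$fwhm_deg,
       height = peak$height,
       crystallite_d_nm = scherrer_size(peak, wavelength_nm = wl, k = k),
       wavelength_nm = wl, scherrer_k = k)
}

wf_qy <- function(params) {
  need <- c("i_sample", "i_ref", "a_sample", "a_ref", "n_sample", "n_ref")
  missing_p <- setdiff(need, names(params))
  if (length(missing_p) > 0) {
    stop("missing params: ", paste(missing_p, collapse = ", "))
  }
  phi_ref <- if (is.null(params$phi_ref)) 0.54 else params$phi_ref
  list(phi_sample = quantum_yield_relative(params$i_sample, params$i_ref,
                                           params$a_sample, params$a_ref,
                                           params$n_sample, params$n_ref,
                                           phi_ref),
       phi_ref = phi_ref)
}

wf_simulate <- function(params, output_data) {
  gen <- match.arg(params$generator,
                   c("band", "solvatochromic", "quenching", "xrd", "decay"))
  spec <- do.call(generator_spec, params$spec)
  args <- if (is.null(params$args)) list() else params$args
  obj <- switch(gen,
                band = do.call(gen_band_spectrum, c(args, list(spec = spec))),
                solvatochromic = do.call(gen_solvatochromic_series,
                                         c(args, list(spec = spec))),
                quenching = do.call(gen_quenching_series, c(args, list(spec = spec))),
                xrd = do.call(gen_xrd_pattern, c(args, list(spec = spec))),
                decay = do.call(gen_decay_trace, c(args, list(spec = spec))))
  if (!is.null(output_data)) {
    if (inherits(obj, "spectrum")) {
      write_spectrum(obj, output_data)
    } else {
      utils::write.csv(as.data.frame(obj), output_data, row.names = FALSE)
    }
  }
  list(generator = gen, n = if (inherits(obj, "spectrum"))
    length(obj$axis) else nrow(obj),
    written = if (is.null(output_data)) NA else output_data)
}

#' Compare a report against an expected-values fixture
#'
#' Flattens a (possibly nested) report to named numeric leaves, then
#' checks each fixture key against the report value at the stated
#' tolerance. Nested keys use `.` as separator (e.g. `"lippert.slope"`).
#'
#' @param report A named list, e.g. from [run_workflow()].
#' @param fixture Data.frame with columns `key`, `expected`, and either
#'   `tol_abs` or `tol_rel` (or both; a comparison passes if it passes
#'   either stated tolerance).
#' @return Data.frame with columns `key`, `expected`, `actual`, `delta`,
#'   `pass`, plus a `summary` attribute (`n_pass`, `n_fail`). An empty
#'   fixture passes vacuously with a warning. Fixture keys absent from the
#'   report raise an error.
#' @export
validate_against_fixture <- function(report, fixture) {
  stopifnot(is.data.frame(fixture), all(c("key", "expected") %in% names(fixture)))
  if (nrow(fixture) == 0) {
    warning("empty fixture: vacuous pass")
    out <- data.frame(key = character(0), expected = numeric(0),
                      actual = numeric(0), delta = numeric(0),
                      pass = logical(0))
    attr(out, "summary") <- c(n_pass = 0L, n_fail = 0L)
    return(out)
  }
  leaves <- flatten_numeric(report)
  missing_keys <- setdiff(fixture$key, names(leaves))
  if (length(missing_keys) > 0) {
    stop("fixture keys missing from report: ", paste(missing_keys, collapse = ", "))
  }
  actual <- as.numeric(leaves[fixture$key])
  delta <- actual - fixture$expected
  tol_abs <- if ("tol_abs" %in% names(fixture)) fixture$tol_abs else NA_real_
  tol_rel <- if ("tol_rel" %in% names(fixture)) fixture$tol_rel else NA_real_
  pass_abs <- !is.na(tol_abs) & abs(delta) <= tol_abs
  pass_rel <- !is.na(tol_rel) & abs(delta) <= tol_rel * abs(fixture$expected)
  pass <- pass_abs | pass_rel
  out <- data.frame(key = fixture$key, expected = fixture$expected,
                    actual = actual, delta = delta, pass = pass)
  attr(out, "summary") <- c(n_pass = sum(pass), n_fail = sum(!pass))
  out
}

# recursively flatten a report into a named numeric vector ('.'-separated keys)
flatten_numeric <- function(x, prefix = "") {
  if (is.numeric(x)) {
    nm <- if (length(x) > 1) {
      inner <- if (is.null(names(x))) seq_along(x) else names(x)
      paste(prefix, inner, sep = ".")
    } else prefix
    return(stats::setNames(as.numeric(x), nm))
  }
  if (is.list(x) && !is.data.frame(x)) {
    parts <- lapply(seq_along(x), function(i) {
      nm <- if (is.null(names(x)) || !nzchar(names(x)[i])) as.character(i) else names(x)[i]
      flatten_numeric(x[[i]], if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm)
    })
    return(do.call(c, parts))
  }
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, logical(1))]
    key <- if ("solvent" %in% names(x)) x$solvent else seq_len(nrow(x))
    parts <- lapply(names(num), function(cn) {
      stats::setNames(as.numeric(num[[cn]]),
                      paste(prefix, cn, key, sep = "."))
    })
    return(do.call(c, parts))
  }
  stats::setNames(numeric(0), character(0))
}
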