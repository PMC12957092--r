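# cached atomic-weight table (IUPAC 2021 conventional values, bundled as
# plain text so molecular weights reproduce bit-stably)
.pk_env <- new.env(parent = emptyenv())

atomic_weights <- function() {
  if (is.null(.pk_env$weights)) {
    path <- system.file("extdata", "atomic_weights.csv", package = "photophyskit")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .pk_env$weights <- stats::setNames(tab$weight, tab$element)
  }
  .pk_env$weights
}

#' Parse a molecular formula into element counts
#'
#' Accepts simple Hill-style formulas without parentheses, e.g.
#' `"C12H12N4OS2"`. Implicit count 1 is allowed.
#'
#' @param formula Formula string.
#' @return A named integer vector of element counts (class `composition`).
#' @export
#' @examples
#' parse_formula("C12H12N4OS2")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  formula <- trimws(formula)
  if (!nzchar(formula)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stray <- gsub("([A-Z][a-z]?)([0-9]*)", "", formula)
    stop("malformed formula token: '", stray, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(tokens, "")))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(sym, names(atomic_weights()))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(cnt < 1)) stop("element counts must be >= 1")
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  structure(stats::setNames(as.integer(counts), names(counts)),
            class = "composition")
}

#' Molecular weight of a composition
#'
#' Sum of element counts times the bundled standard atomic weights.
#'
#' @param comp A `composition` from [parse_formula()], or a formula string.
#' @return Molecular weight in g mol^-1 (full precision; round to 2 d.p.
#'   for reporting).
#' @export
#' @examples
#' molecular_weight("C12H12N4OS2")  # 292.38 to 2 d.p.
molecular_weight <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  if (length(comp) == 0) stop("empty composition")
  w <- atomic_weights()
  sum(unclass(comp) * w[names(comp)])
}

#' Elemental mass percentages of a composition
#'
#' @inheritParams molecular_weight
#' @return Named numeric vector of mass percentages (sums to 100).
#' @export
#' @examples
#' mass_percent("C12H12N4OS2")["C"]  # 49.30 to 2 d.p.
mass_percent <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  w <- atomic_weights()
  masses <- unclass(comp) * w[names(comp)]
  100 * masses / sum(masses)
}

#' Onsager cavity radius from molar mass and density (Suppan)
#'
#' a = (3 M / (4 pi delta N_A))^(1/3), returned in Angstrom. The density
#' is a required parameter: it is never silently assumed.
#'
#' @param molar_mass_g_mol Molar mass, g mol^-1, > 0.
#' @param density_g_cm3 Density, g cm^-3, > 0.
#' @return Cavity radius in Angstrom.
#' @export
#' @examples
#' onsager_radius(292.38, 1.68)  # ~4.10 Angstrom
onsager_radius <- function(molar_mass_g_mol, density_g_cm3) {
  if (molar_mass_g_mol <= 0 || density_g_cm3 <= 0) {
    stop("molar mass and density must be positive")
  }
  na <- photophysical_constants()$n_avogadro
  a_cm <- (3 * molar_mass_g_mol / (4 * pi * density_g_cm3 * na))^(1 / 3)
  a_cm * 1e8
}

#' Binding energy per atom from total energies
#'
#' BE = (sum_e N_e E_e - E_total) / N_total, where N_e are the element
#' counts, E_e the isolated-atom total energies and E_total the compound
#' total energy (all in eV).
#'
#' @inheritParams molecular_weight
#' @param atom_energies_ev Named numeric vector of per-atom total energies
#'   (eV), covering every element in `comp`.
#' @param total_energy_ev Total energy of the compound, eV.
#' @return Binding energy per atom, eV.
#' @export
#' @examples
#' binding_energy_per_atom("H2", c(H = -10), -25)  # 2.5 eV/atom
binding_energy_per_atom <- function(comp, atom_energies_ev, total_energy_ev) {
  if (is.character(comp)) comp <- parse_formula(comp)
  missing_e <- setdiff(names(comp), names(atom_energies_ev))
  if (length(missing_e) > 0) {
    stop("missing atom energies for: ", paste(missing_e, collapse = ", "))
  }
  n_total <- sum(unclass(comp))
  (sum(unclass(comp) * atom_energies_ev[names(comp)]) - total_energy_ev) / n_total
}
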