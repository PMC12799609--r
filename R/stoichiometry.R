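#' Parse a molecular formula
#'
#' Parses an empirical formula string such as `"NaHCO3"` or the fractional
#' single-cell composition `"C4.09H7.13O1.89N0.76"` into a `mol_formula`
#' object: a named numeric vector of element counts. Counts may be
#' non-integer, as is standard for measured biomass elemental compositions.
#' An element appearing more than once accumulates. Parentheses, hydrate
#' dots and isotope markers are deliberately rejected: none of the species
#' handled here (substrates, VFAs, biomass, PHB monomer) need them.
#'
#' @param text Formula string: element symbols each optionally followed by an
#'   integer or decimal count (absent count means 1).
#' @param name Display name, defaults to `text`.
#' @param charge Integer net charge, informational; used only by reaction
#'   balance diagnostics (e.g. acetate parsed from `"C2H3O2"`, `charge = -1`).
#' @return A `mol_formula`: named numeric vector of counts with attributes
#'   `name` and `charge`.
#' @examples
#' parse_formula("NaHCO3")
#' parse_formula("C4.09H7.13O1.89N0.76")
#' parse_formula("C2H3O2", name = "acetate", charge = -1)
#' @export
parse_formula <- function(text, name = text, charge = 0L) {
  if (inherits(text, "mol_formula")) return(text)
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("formula string must be a single non-empty character value",
         call. = FALSE)
  }
  if (grepl("[()\\[\\]·*.]", gsub("(?<=[0-9])\\.(?=[0-9])", "", text, perl = TRUE),
            perl = TRUE)) {
    stop("parentheses, hydrates and adduct notation are not supported: '",
         text, "'", call. = FALSE)
  }
  known <- names(atomic_masses())
  rx <- "([A-Z][a-z]?)([0-9]*\\.?[0-9]*)"
  starts <- gregexpr(rx, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, gregexpr(rx, text, perl = TRUE))[[1]]
  if (length(tokens) == 0 || paste(tokens, collapse = "") != text) {
    stop("cannot parse formula '", text, "'", call. = FALSE)
  }
  sym <- sub(rx, "\\1", tokens, perl = TRUE)
  cnt <- sub(rx, "\\2", tokens, perl = TRUE)
  bad <- setdiff(sym, known)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "),
         " in '", text, "'", call. = FALSE)
  }
  n <- ifelse(cnt == "", 1, suppressWarnings(as.numeric(cnt)))
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("element counts must be finite and non-negative in '", text, "'",
         call. = FALSE)
  }
  counts <- tapply(n, factor(sym, levels = unique(sym)), sum)
  counts <- counts[counts > 0]
  if (!length(counts)) {
    stop("formula '", text, "' has no element with positive count",
         call. = FALSE)
  }
  out <- as.numeric(counts)
  names(out) <- names(counts)
  structure(out, name = name, charge = as.integer(charge),
            class = "mol_formula")
}

#' Canonical string form of a formula
#'
#' Insertion order is preserved (Hill order is not imposed); trailing `1`
#' counts are dropped and fractional counts are printed as given, so
#' `parse_formula(formula_string(f))` recovers `f`.
#'
#' @param f A `mol_formula` (or a string, which is parsed first).
#' @return A single formula string.
#' @examples
#' formula_string(parse_formula("C60H87N12O23P"))
#' @export
formula_string <- function(f) {
  f <- parse_formula(f)
  num <- vapply(unclass(f), function(x) {
    if (x == 1) "" else format(x, scientific = FALSE, trim = TRUE)
  }, character(1))
  paste0(names(f), num, collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", attr(x, "name"), ": ", formula_string(x), sep = "")
  ch <- attr(x, "charge")
  if (!is.null(ch) && ch != 0) cat(" (charge ", ch, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Molar mass of a formula
#'
#' @param f A `mol_formula` or formula string.
#' @param masses Atomic mass table from [atomic_masses()].
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("NaHCO3")
#' molar_mass("C4H6O2") # PHB monomer
#' @export
molar_mass <- function(f, masses = atomic_masses()) {
  f <- parse_formula(f)
  missing <- setdiff(names(f), names(masses))
  if (length(missing)) {
    stop("no atomic mass for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(unclass(f) * masses[names(f)])
}

#' Mass fraction of one element in a compound
#'
#' The basis of every carbon-content computation in the ledger: e.g. carbon
#' is 14.3% of sodium bicarbonate by mass, 40% of acetic acid and 54.5% of
#' butyric acid.
#'
#' @inheritParams molar_mass
#' @param element Element symbol.
#' @return Fraction in `[0, 1]`; 0 when the element is absent from `f`.
#' @examples
#' element_mass_fraction("NaHCO3", "C")
#' element_mass_fraction("C2H4O2", "C")
#' @export
element_mass_fraction <- function(f, element, masses = atomic_masses()) {
  f <- parse_formula(f)
  if (!element %in% names(masses)) {
    stop("no atomic mass for element '", element, "'", call. = FALSE)
  }
  if (!element %in% names(f)) return(0)
  unname(unclass(f)[element] * masses[element]) / molar_mass(f, masses)
}

#' Convert compound concentration to element-mass concentration
#'
#' E.g. 6 g/L sodium bicarbonate carries 0.858 gC/L of carbon.
#'
#' @param conc Compound concentration (g/L), non-negative.
#' @inheritParams element_mass_fraction
#' @return Element-mass concentration (g element / L).
#' @examples
#' concentration_to_element(6, "NaHCO3", "C")
#' @export
concentration_to_element <- function(conc, f, element,
                                     masses = atomic_masses()) {
  if (any(conc < 0)) stop("concentration must be non-negative", call. = FALSE)
  conc * element_mass_fraction(f, element, masses)
}

#' Convert element-mass concentration back to compound concentration
#'
#' Inverse of [concentration_to_element()]; used to report polymer mass from
#' ledger carbon (0.22 gC/L of PHB carbon corresponds to 0.39 g/L polymer).
#'
#' @param elem_mass Element-mass concentration (g element / L).
#' @inheritParams element_mass_fraction
#' @return Compound concentration (g/L).
#' @examples
#' element_to_concentration(0.22, "C4H6O2", "C")
#' @export
element_to_concentration <- function(elem_mass, f, element,
                                     masses = atomic_masses()) {
  if (any(elem_mass < 0)) stop("element mass must be non-negative", call. = FALSE)
  frac <- element_mass_fraction(f, element, masses)
  if (frac == 0) {
    stop("element '", element, "' is absent from the formula; cannot invert",
         call. = FALSE)
  }
  elem_mass / frac
}

#' Elemental composition table
#'
#' Tidy per-element breakdown of a compound: counts, per-element mass and
#' mass fraction (fractions sum to 1).
#'
#' @inheritParams molar_mass
#' @return A tibble with columns `element`, `count`, `mass_g_mol`,
#'   `mass_fraction`.
#' @examples
#' formula_composition("C60H87N12O23P")
#' @export
formula_composition <- function(f, masses = atomic_masses()) {
  f <- parse_formula(f)
  mm <- molar_mass(f, masses)
  tibble::tibble(
    element = names(f),
    count = as.numeric(unclass(f)),
    mass_g_mol = as.numeric(unclass(f) * masses[names(f)]),
    mass_fraction = .data$mass_g_mol / mm
  )
}
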