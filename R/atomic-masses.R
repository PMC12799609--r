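#' Standard atomic masses
#'
#' Returns the table of standard atomic weights (g/mol) used throughout the
#' package for molar-mass and element-fraction arithmetic. Values are IUPAC
#' conventional atomic weights to at least three decimals. A user-supplied
#' YAML file of `symbol: mass` pairs can extend or override the defaults.
#'
#' @param path Optional path to a YAML file mapping element symbols to
#'   atomic masses (g/mol). Entries override or extend the built-in table.
#' @return A named numeric vector, element symbol -> atomic mass (g/mol).
#' @examples
#' atomic_masses()[c("C", "H", "O")]
#' @export
atomic_masses <- function(path = NULL) {
  masses <- c(
    H  = 1.008,   C  = 12.011, N  = 14.007, O  = 15.999,
    Na = 22.990,  Mg = 24.305, P  = 30.974, S  = 32.06,
    Cl = 35.45,   K  = 39.098, Ca = 40.078, Fe = 55.845,
    Mn = 54.938,  Zn = 65.38,  Cu = 63.546, Co = 58.933,
    Ni = 58.693,  Mo = 95.95,  Se = 78.971, B  = 10.81,
    Si = 28.085,  F  = 18.998, I  = 126.904
  )
  if (!is.null(path)) {
    extra <- yaml::read_yaml(path)
    if (length(extra)) {
      vals <- vapply(extra, as.numeric, numeric(1))
      if (any(!is.finite(vals)) || any(vals <= 0)) {
        stop("atomic masses in '", path, "' must be finite and positive",
             call. = FALSE)
      }
      masses[names(vals)] <- vals
    }
  }
  stopifnot(all(masses > 0))
  masses
}
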