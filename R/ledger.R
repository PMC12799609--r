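#' Build a table of carbon streams
#'
#' A carbon stream is one carbon carrier crossing the reactor boundary: an
#' input (dissolved CO2, bicarbonate, inoculum biomass) or an output (VFAs,
#' biomass, PHB polymer, residual metabolites). Each stream carries either a
#' compound concentration plus molecular formula, or a direct elemental
#' carbon concentration (gC/L) — exactly one of the two.
#'
#' @param name Stream label.
#' @param role `"input"` or `"output"`.
#' @param category One of `"dissolved_gas"`, `"substrate"`, `"biomass"`,
#'   `"vfa"`, `"polymer"`, `"metabolites"`.
#' @param conc_g_per_l Compound concentration (g/L); requires `formula`.
#' @param formula Molecular formula (string or [parse_formula()] result).
#' @param carbon_gc_per_l Direct carbon concentration (gC/L).
#' @return A one-row tibble; rows from repeated calls combine with
#'   [dplyr::bind_rows()].
#' @examples
#' carbon_stream("bicarbonate", "input", "substrate",
#'               conc_g_per_l = 6, formula = "NaHCO3")
#' @export
carbon_stream <- function(name, role = c("input", "output"),
                          category = c("substrate", "dissolved_gas",
                                       "biomass", "vfa", "polymer",
                                       "metabolites"),
                          conc_g_per_l = NA_real_, formula = NULL,
                          carbon_gc_per_l = NA_real_) {
  role <- match.arg(role)
  category <- match.arg(category)
  has_compound <- is.finite(conc_g_per_l)
  has_direct <- is.finite(carbon_gc_per_l)
  if (has_compound == has_direct) {
    stop("stream '", name, "': give exactly one of conc_g_per_l (+ formula) ",
         "or carbon_gc_per_l", call. = FALSE)
  }
  if (has_compound && is.null(formula)) {
    stop("stream '", name, "': conc_g_per_l needs a formula", call. = FALSE)
  }
  if ((has_compound && conc_g_per_l < 0) || (has_direct && carbon_gc_per_l < 0)) {
    stop("stream '", name, "': quantities must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    name = name, role = role, category = category,
    conc_g_per_l = conc_g_per_l,
    formula = if (is.null(formula)) NA_character_ else formula_string(formula),
    carbon_gc_per_l = carbon_gc_per_l
  )
}

#' Elemental carbon carried by each stream
#'
#' Adds a `gc_per_l` column: direct carbon values pass through; compound
#' streams are converted via the carbon mass fraction of their formula.
#'
#' @param streams A tibble of [carbon_stream()] rows.
#' @param masses Atomic mass table.
#' @return `streams` with a `gc_per_l` column appended.
#' @examples
#' stream_carbon(carbon_stream("bicarbonate", "input", "substrate",
#'                             conc_g_per_l = 6, formula = "NaHCO3"))
#' @export
stream_carbon <- function(streams, masses = atomic_masses()) {
  gc <- purrr::pmap_dbl(
    streams[c("name", "conc_g_per_l", "formula", "carbon_gc_per_l")],
    function(name, conc_g_per_l, formula, carbon_gc_per_l) {
      if (is.finite(carbon_gc_per_l)) return(carbon_gc_per_l)
      frac <- element_mass_fraction(formula, "C", masses)
      if (frac == 0) {
        stop("stream '", name, "' has a carbon-free formula (", formula, ")",
             call. = FALSE)
      }
      concentration_to_element(conc_g_per_l, formula, "C", masses)
    }
  )
  dplyr::mutate(streams, gc_per_l = gc)
}

#' Partition a total VFA titer into acetic and butyric acid
#'
#' The broth's VFA pool is dominated by acetic and butyric acid in a fixed
#' ratio (default 1.5:1, interpreted as a mass ratio). The split is
#' `acetic = total * r / (r + 1)`, `butyric = total / (r + 1)`; carbon
#' content follows from the carbon mass fractions of C2H4O2 and C4H8O2
#' (0.400 and 0.545).
#'
#' @param total_vfa Total VFA concentration (g/L), >= 0.
#' @param ratio_acetic_to_butyric Mass ratio, > 0 (default 1.5).
#' @param masses Atomic mass table.
#' @return A tibble with one row per acid: `acid`, `conc_g_per_l`,
#'   `carbon_gc_per_l`.
#' @examples
#' vfa_partition(3.467)
#' @export
vfa_partition <- function(total_vfa, ratio_acetic_to_butyric = 1.5,
                          masses = atomic_masses()) {
  if (total_vfa < 0) stop("total_vfa must be non-negative", call. = FALSE)
  if (ratio_acetic_to_butyric <= 0) stop("ratio must be positive", call. = FALSE)
  r <- ratio_acetic_to_butyric
  acetic <- total_vfa * r / (r + 1)
  butyric <- total_vfa / (r + 1)
  tibble::tibble(
    acid = c("acetic", "butyric"),
    conc_g_per_l = c(acetic, butyric),
    carbon_gc_per_l = c(
      concentration_to_element(acetic, "C2H4O2", "C", masses),
      concentration_to_element(butyric, "C4H8O2", "C", masses)
    )
  )
}

#' Carbon mass balance over input and output streams
#'
#' Sums elemental carbon over the input and output streams of a reactor
#' cycle. When no explicit `metabolites` output stream is supplied, the
#' unassigned remainder `total_in - total_out_known` is reported as the
#' residual metabolites term and closure is 1 by construction (the residual
#' is the balancing term). When an explicit metabolites stream is present,
#' closure is `total_out / total_in` and the gap is reported. A negative
#' residual (outputs exceeding inputs) is flagged as over-closure, never
#' clipped.
#'
#' @param streams A tibble of [carbon_stream()] rows (both roles).
#' @param masses Atomic mass table.
#' @return A `carbon_ledger` object; see [tidy.carbon_ledger()] and
#'   [glance.carbon_ledger()].
#' @examples
#' streams <- dplyr::bind_rows(
#'   carbon_stream("bicarbonate", "input", "substrate",
#'                 conc_g_per_l = 6, formula = "NaHCO3"),
#'   carbon_stream("inoculum", "input", "biomass", carbon_gc_per_l = 0.45),
#'   carbon_stream("acetic acid", "output", "vfa", carbon_gc_per_l = 0.48)
#' )
#' carbon_balance(streams)
#' @export
carbon_balance <- function(streams, masses = atomic_masses()) {
  if (!nrow(streams) || !any(streams$role == "input")) {
    stop("a ledger needs at least one input stream", call. = FALSE)
  }
  per <- stream_carbon(streams, masses)
  total_in <- sum(per$gc_per_l[per$role == "input"])
  out <- per[per$role == "output", ]
  explicit_met <- any(out$category == "metabolites")
  total_out_known <- sum(out$gc_per_l[out$category != "metabolites"])
  total_out_explicit <- sum(out$gc_per_l)
  if (total_in == 0 && total_out_explicit > 0) {
    stop("zero total input carbon with non-zero outputs", call. = FALSE)
  }
  if (explicit_met) {
    residual <- sum(out$gc_per_l[out$category == "metabolites"])
    closure <- if (total_in > 0) total_out_explicit / total_in else 1
  } else {
    residual <- total_in - total_out_known
    closure <- 1
  }
  flags <- character(0)
  if (residual < 0) flags <- c(flags, "over_closure: outputs exceed inputs")
  if (!explicit_met) flags <- c(flags, "residual_is_balancing_term")
  structure(
    list(
      streams = per,
      total_in = total_in,
      total_out_known = total_out_known,
      residual_metabolites = residual,
      closure = closure,
      explicit_metabolites = explicit_met,
      flags = flags
    ),
    class = "carbon_ledger"
  )
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat("<carbon_ledger>\n")
  print(tidy(x))
  cat(sprintf("total in: %.4g gC/L | known out: %.4g gC/L | residual metabolites: %.4g gC/L | closure: %.4g\n",
              x$total_in, x$total_out_known, x$residual_metabolites, x$closure))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a carbon ledger into its per-stream table
#'
#' @param x A `carbon_ledger`.
#' @param ... Unused.
#' @return Tibble of streams with their `gc_per_l` carbon content.
#' @method tidy carbon_ledger
#' @export
tidy.carbon_ledger <- function(x, ...) x$streams

#' One-row summary of a carbon ledger
#'
#' @param x A `carbon_ledger`.
#' @param ... Unused.
#' @return One-row tibble: totals, residual, closure, flags.
#' @method glance carbon_ledger
#' @export
glance.carbon_ledger <- function(x, ...) {
  tibble::tibble(
    total_in_gc_per_l = x$total_in,
    total_out_known_gc_per_l = x$total_out_known,
    residual_metabolites_gc_per_l = x$residual_metabolites,
    closure = x$closure,
    explicit_metabolites = x$explicit_metabolites,
    flags = paste(x$flags, collapse = "; ")
  )
}

#' Net fermentable VFA yield
#'
#' `Y = delta_COD / VSS` (g COD released as soluble products per g volatile
#' suspended solids), the standard acidogenic-fermentation yield.
#'
#' @param cod_delta Soluble COD increase (g COD/L), >= 0.
#' @param vss Volatile suspended solids (g VSS/L), > 0.
#' @return Yield (g COD / g VSS).
#' @examples
#' fermentable_yield(0.54, 10)
#' @export
fermentable_yield <- function(cod_delta, vss) {
  if (any(vss <= 0)) stop("vss must be positive", call. = FALSE)
  if (any(cod_delta < 0)) stop("cod_delta must be non-negative", call. = FALSE)
  cod_delta / vss
}

#' Intracellular PHB content
#'
#' `%PHB = 100 * PHB / DCW`: polymer mass as a percentage of dry cell weight.
#'
#' @param phb PHB concentration (g/L), `0 <= phb <= dcw`.
#' @param dcw Dry cell weight (g/L), > 0.
#' @return Percentage in `[0, 100]`.
#' @examples
#' percent_phb(0.182, 4.45)
#' percent_phb(0.236, 4.21)
#' @export
percent_phb <- function(phb, dcw) {
  if (any(dcw <= 0)) stop("dcw must be positive", call. = FALSE)
  if (any(phb < 0)) stop("phb must be non-negative", call. = FALSE)
  if (any(phb > dcw)) {
    stop("phb exceeds dry cell weight; impossible accumulation", call. = FALSE)
  }
  100 * phb / dcw
}

#' Read a ledger scenario from YAML
#'
#' Expected layout: a `streams:` list with entries `{name, role, category,
#' conc_g_per_l + formula | carbon_gc_per_l}` (mg units accepted as
#' `conc_mg_per_l` / `carbon_mgc_per_l`), plus optional scalars `vfa_total_g_per_l`,
#' `vfa_ratio_acetic_to_butyric`, `cod_delta_g_per_l`, `vss_g_per_l`,
#' `dcw_g_per_l`, `phb_g_per_l`.
#'
#' @param path YAML file path.
#' @return A list with `streams` (tibble) and `scalars` (named list).
#' @export
read_ledger_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$streams)) {
    stop("scenario YAML '", path, "' must contain a 'streams' list",
         call. = FALSE)
  }
  rows <- purrr::map_dfr(doc$streams, function(e) {
    conc <- e$conc_g_per_l %||%
      (if (!is.null(e$conc_mg_per_l)) e$conc_mg_per_l / 1000 else NA_real_)
    carb <- e$carbon_gc_per_l %||%
      (if (!is.null(e$carbon_mgc_per_l)) e$carbon_mgc_per_l / 1000 else NA_real_)
    carbon_stream(e$name, e$role, e$category,
                  conc_g_per_l = conc %||% NA_real_,
                  formula = e$formula,
                  carbon_gc_per_l = carb %||% NA_real_)
  })
  scalars <- doc[setdiff(names(doc), "streams")]
  list(streams = rows, scalars = scalars)
}

#' Export a ledger's per-stream carbon as CSV
#'
#' @param x A `carbon_ledger`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(x, path) {
  stopifnot(inherits(x, "carbon_ledger"))
  utils::write.csv(as.data.frame(tidy(x)), path, row.names = FALSE)
  invisible(path)
}
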