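#' Per-cycle enrichment metrics
#'
#' Reduces each culture x generation x cycle time series to its end-point
#' metrics: pH and OD600 change, % bicarbonate reduction
#' (`100 * (start - end) / start`), final headspace CO2 consumption, end-point
#' VFA titer, and intracellular PHB content (% of DCW). Reduction metrics
#' whose start value is zero are undefined and returned as `NA` with a flag
#' column.
#'
#' @param dataset A tidy enrichment dataset as produced by
#'   [generate_enrichment()] (or measured data with the same columns).
#' @return A tibble with one row per culture x generation x cycle.
#' @examples
#' ds <- generate_enrichment(enrichment_config(), seed = 1)
#' summarize_generation(ds)
#' @export
summarize_generation <- function(dataset) {
  needed <- c("culture", "generation", "cycle", "time_h")
  missing <- setdiff(needed, names(dataset))
  if (length(missing)) {
    stop("dataset lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dataset |>
    dplyr::group_by(.data$culture, .data$generation, .data$cycle) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      delta_ph = dplyr::last(.data$ph) - dplyr::first(.data$ph),
      delta_od600 = dplyr::last(.data$od600) - dplyr::first(.data$od600),
      bicarb_start = dplyr::first(.data$bicarbonate_g_per_l),
      bicarb_reduction_pct = ifelse(
        .data$bicarb_start > 0,
        100 * (dplyr::first(.data$bicarbonate_g_per_l) -
                 dplyr::last(.data$bicarbonate_g_per_l)) / .data$bicarb_start,
        NA_real_
      ),
      co2_consumed_pct = dplyr::last(.data$co2_consumed_pct),
      vfa_end_g_per_l = dplyr::last(.data$vfa_g_per_l),
      phb_pct_dcw = ifelse(
        dplyr::last(.data$dcw_g_per_l) > 0,
        100 * dplyr::last(.data$phb_g_per_l) / dplyr::last(.data$dcw_g_per_l),
        NA_real_
      ),
      undefined_reduction = .data$bicarb_start <= 0,
      .groups = "drop"
    ) |>
    dplyr::select(-"bicarb_start")
}

#' Generation-level means of per-cycle metrics
#'
#' Averages the [summarize_generation()] metrics over cycles within each
#' culture x generation.
#'
#' @param dataset A tidy enrichment dataset (see [summarize_generation()]).
#' @return A tibble with one row per culture x generation.
#' @examples
#' ds <- generate_enrichment(enrichment_config(), seed = 1)
#' generation_means(ds)
#' @export
generation_means <- function(dataset) {
  summarize_generation(dataset) |>
    dplyr::group_by(.data$culture, .data$generation) |>
    dplyr::summarise(
      dplyr::across(
        c("delta_ph", "delta_od600", "bicarb_reduction_pct",
          "co2_consumed_pct", "vfa_end_g_per_l", "phb_pct_dcw"),
        ~ mean(.x, na.rm = TRUE)
      ),
      n_cycles = dplyr::n(),
      .groups = "drop"
    )
}
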