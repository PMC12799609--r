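#' Plot one metric of an enrichment dataset
#'
#' Within-cycle trajectories of a chosen measurement, faceted by generation
#' with one coloured line per culture and a thin line per cycle.
#'
#' @param dataset A tidy enrichment dataset (see [generate_enrichment()]).
#' @param metric Column to plot, as a string (default `"bicarbonate_g_per_l"`).
#' @return A ggplot object.
#' @examples
#' ds <- generate_enrichment(enrichment_config(), seed = 1)
#' plot_enrichment(ds, "od600")
#' @export
plot_enrichment <- function(dataset, metric = "bicarbonate_g_per_l") {
  if (!metric %in% names(dataset)) {
    stop("no column '", metric, "' in dataset", call. = FALSE)
  }
  ggplot2::ggplot(
    dataset,
    ggplot2::aes(x = .data$time_h, y = .data[[metric]],
                 colour = .data$culture,
                 group = interaction(.data$culture, .data$cycle))
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~generation) +
    ggplot2::labs(x = "time (h)", y = metric, colour = "culture") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of a carbon ledger
#'
#' Per-stream elemental carbon (gC/L), inputs and outputs side by side, with
#' the residual metabolites term appended to the outputs.
#'
#' @param object A `carbon_ledger` from [carbon_balance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carbon_ledger
#' @export
autoplot.carbon_ledger <- function(object, ...) {
  df <- tidy(object)[, c("name", "role", "gc_per_l")]
  if (!object$explicit_metabolites) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      name = "residual metabolites", role = "output",
      gc_per_l = object$residual_metabolites
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$gc_per_l,
                                   fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~role, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "carbon (gC/L)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Sums-of-squares share plot for an ANOVA fit
#'
#' Shows each term's share of the total sum of squares — a quick visual of
#' how much of the variation the design factors explain.
#'
#' @param object An `ss_anova` from [one_way_anova()] or [two_way_anova()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ss_anova
#' @export
autoplot.ss_anova <- function(object, ...) {
  df <- tidy(object)
  df$share <- df$sumsq / sum(df$sumsq)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "share of total SS") +
    ggplot2::theme_minimal()
}
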