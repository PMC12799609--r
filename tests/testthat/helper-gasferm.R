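# shared test helpers: random formula generation and a canonical AC-reactor
# stream table built in code

random_formula <- function(seed) {
  set.seed(seed)
  pool <- c("C", "H", "O", "N", "P", "Na", "S", "Cl")
  k <- sample(2:5, 1)
  els <- sample(pool, k)
  counts <- round(stats::runif(k, 0.5, 60), sample(0:2, k, replace = TRUE))
  counts[counts == 0] <- 1
  paste0(els, ifelse(counts == 1, "", format(counts, trim = TRUE)),
         collapse = "")
}

ac_streams <- function() {
  dplyr::bind_rows(
    carbon_stream("sodium bicarbonate", "input", "substrate",
                  conc_g_per_l = 6, formula = "NaHCO3"),
    carbon_stream("inoculum biomass", "input", "biomass",
                  carbon_gc_per_l = 0.45),
    carbon_stream("dissolved CO2 in", "input", "dissolved_gas",
                  carbon_gc_per_l = 0.048),
    carbon_stream("acetic acid", "output", "vfa", carbon_gc_per_l = 0.48),
    carbon_stream("butyric acid", "output", "vfa", carbon_gc_per_l = 0.324),
    carbon_stream("dissolved CO2 out", "output", "dissolved_gas",
                  carbon_gc_per_l = 0.025),
    carbon_stream("biomass out", "output", "biomass",
                  carbon_gc_per_l = 0.3455)
  )
}

quiet_sparged_volume <- function(...) {
  suppressMessages(sparged_volume(...))
}

formula_counts <- function(f) {
  stats::setNames(as.numeric(unclass(f)), names(f))
}
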