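#!/usr/bin/env Rscript

# Per-chemical contribution analysis for the environmental mixture on
# testosterone: place each fitted component on the mixture-concentration
# axis, band the simulated mixture experiment, and classify every
# contribution curve and model prediction against the band. Repeats the
# comparison against the antagonistic (10-fold shifted) mixture data.
#
# Reads:  results/data, results/fits   (from 01/02)
# Writes: results/contributions/{contributions,comparisons}.csv

suppressMessages(library(mixhill))
suppressMessages(library(dplyr))

out <- "results/contributions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fits <- read_fit_table("results/fits/mixture1_testosterone_fits.csv")
mix <- suppressWarnings(read_mixture_table(mixhill_example("mixture1")))
eff <- effective_components(fits, mix)
grid <- lseq(1e-3, 1e3, 200)

contribs <- lapply(names(eff), function(ch) {
  p <- mix$mass_fraction[mix$chemical == ch]
  crv <- contribution_curve(eff[[ch]], p, grid)
  tibble::tibble(chemical = ch, fraction = p,
                 concentration_uM = crv$concentration_uM,
                 effect_pct = crv$effect_pct)
})
readr::write_csv(bind_rows(contribs), file.path(out, "contributions.csv"))

classify <- function(mix_file, tag) {
  mixd <- read_response_table(file.path("results/data", mix_file))[[1]]
  mfit <- fit_hill(mixd)
  band <- confidence_band(mfit, grid = lseq(0.04, 30, 60), nboot = 500,
                          seed = 11)
  rows <- lapply(names(eff), function(ch) {
    p <- mix$mass_fraction[mix$chemical == ch]
    cmp <- compare_to_band(contribution_curve(eff[[ch]], p, grid), band)
    tibble::tibble(dataset = tag, curve = ch, verdict = cmp$verdict,
                   frac_inside = cmp$frac_inside)
  })
  for (model in c("CA", "IA", "GCA")) {
    crv <- switch(model,
      CA  = ca_predict(eff, mix),
      IA  = ia_predict(eff, mix, conc_grid = grid),
      GCA = gca_predict(eff, mix, conc_grid = grid))
    cmp <- compare_to_band(crv, band)
    rows[[length(rows) + 1]] <- tibble::tibble(
      dataset = tag, curve = paste0("model:", model),
      verdict = cmp$verdict, frac_inside = cmp$frac_inside)
  }
  bind_rows(rows)
}

comparisons <- bind_rows(
  classify("mixture1_testosterone_mixture.csv", "observed"),
  classify("mixture1_testosterone_mixture_antagonistic.csv", "antagonistic"))
readr::write_csv(comparisons, file.path(out, "comparisons.csv"))
print(comparisons, n = Inf)
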