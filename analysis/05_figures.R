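#!/usr/bin/env Rscript

# Figure: simulated environmental-mixture testosterone data with its
# confidence band, the three model predictions and the per-chemical
# contribution curves on the mixture-concentration axis.
#
# Reads:  results/data, results/fits   (from 01/02)
# Writes: results/figures/mixture1_testosterone.png

suppressMessages(library(mixhill))

out <- "results/figures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fits <- read_fit_table("results/fits/mixture1_testosterone_fits.csv")
mix <- suppressWarnings(read_mixture_table(mixhill_example("mixture1")))
eff <- effective_components(fits, mix)
grid <- lseq(0.04, 30, 120)

mixd <- read_response_table(
  "results/data/mixture1_testosterone_mixture.csv")[[1]]
band <- confidence_band(fit_hill(mixd), grid = grid, nboot = 500, seed = 11)

predictions <- list(
  CA  = ca_predict(eff, mix),
  IA  = ia_predict(eff, mix, conc_grid = grid),
  GCA = gca_predict(eff, mix, conc_grid = grid))
contributions <- lapply(names(eff), function(ch)
  contribution_curve(eff[[ch]], mix$mass_fraction[mix$chemical == ch], grid))
names(contributions) <- names(eff)

p <- plot_mixture_analysis(mixd, band, predictions, contributions,
                           title = "Environmental mixture, testosterone")
ggplot2::ggsave(file.path(out, "mixture1_testosterone.png"), p,
                width = 8, height = 5, dpi = 150)
message("figure written to ", file.path(out, "mixture1_testosterone.png"))
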