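#!/usr/bin/env Rscript

# Simulate the single-chemical and mixture assay campaigns from the truth
# registry: triplicate concentration-response data for every component of
# both mixtures on testosterone, plus a GCA-generated mixture experiment
# for the environmental mixture and an opposing-direction scenario
# (potency-adjusted mixture, estradiol) that the pipeline must refuse.
#
# Writes: results/data/*.csv

suppressMessages(library(mixhill))

seed <- 20240101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

reg <- truth_registry()

simulate_campaign <- function(endpoint, context, file, seed0) {
  singles <- reg[reg$endpoint == endpoint & reg$context == context &
                   reg$subject == "component", ]
  singles <- singles[!duplicated(singles$chemical), ]
  datasets <- lapply(seq_len(nrow(singles)), function(i)
    generate_single(singles[i, ], noise_sd = 10, seed = seed0 + i))
  write_response_table(datasets, file.path(out, file))
  message(sprintf("%s / %s: %d chemicals -> %s",
                  context, endpoint, nrow(singles), file))
}

simulate_campaign("testosterone", "mixture1", "mixture1_testosterone_singles.csv", seed)
simulate_campaign("testosterone", "mixture2", "mixture2_testosterone_singles.csv", seed + 100)
simulate_campaign("estradiol",    "mixture2", "mixture2_estradiol_singles.csv",    seed + 200)

# mixture experiments: environmental mixture on testosterone, generated
# under GCA; one antagonistic variant (10-fold right shift)
m1 <- suppressWarnings(read_mixture_table(mixhill_example("mixture1")))
fits1 <- effective_components(registry_fits("testosterone", "mixture1"), m1)
mixd <- generate_mixture(fits1, m1, model = "GCA", noise_sd = 10,
                         seed = seed + 300)
write_response_table(mixd, file.path(out, "mixture1_testosterone_mixture.csv"))
anta <- generate_mixture(fits1, m1, model = "GCA", antagonism_shift = 10,
                         noise_sd = 10, seed = seed + 301)
write_response_table(anta, file.path(out, "mixture1_testosterone_mixture_antagonistic.csv"))
message("mixture experiments written")
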