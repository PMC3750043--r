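#!/usr/bin/env Rscript

# Fit constrained Hill curves to every simulated single-chemical dataset,
# applying the Kruskal-Wallis gate first, and write one fit table per
# campaign.
#
# Reads:  results/data/*_singles.csv   (from 01_simulate.R)
# Writes: results/fits/*_fits.csv

suppressMessages(library(mixhill))

data_dir <- "results/data"
out <- "results/fits"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (f in list.files(data_dir, pattern = "_singles\\.csv$")) {
  datasets <- read_response_table(file.path(data_dir, f))
  ft <- fit_table(datasets)
  dest <- file.path(out, sub("_singles\\.csv$", "_fits.csv", f))
  write_fit_table(ft$table, dest)
  n_sig <- sum(ft$table$significant)
  message(sprintf("%s: %d/%d chemicals significant -> %s",
                  f, n_sig, nrow(ft$table), dest))
  print(ft$table)
}
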