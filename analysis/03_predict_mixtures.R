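#!/usr/bin/env Rscript

# Predict mixture concentration-response curves under CA, IA and GCA from
# the fitted single-chemical curves, after checking model applicability.
# Also records the CA effect floors and the GCA asymptote.
#
# Reads:  results/fits/*_fits.csv   (from 02_fit_singles.R)
# Writes: results/predictions/{applicability,predictions,summary}.csv

suppressMessages(library(mixhill))
suppressMessages(library(dplyr))

out <- "results/predictions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenarios <- tibble::tribble(
  ~fits_file,                         ~mixture,   ~label,
  "mixture1_testosterone_fits.csv",  "mixture1", "mixture1_testosterone",
  "mixture2_testosterone_fits.csv",  "mixture2", "mixture2_testosterone",
  "mixture2_estradiol_fits.csv",     "mixture2", "mixture2_estradiol"
)

applicability <- list(); predictions <- list(); summary <- list()
conc_grid <- lseq(1e-3, 1e3, 200)

for (i in seq_len(nrow(scenarios))) {
  sc <- scenarios[i, ]
  fits <- read_fit_table(file.path("results/fits", sc$fits_file))
  mix <- suppressWarnings(read_mixture_table(mixhill_example(sc$mixture)))
  eff <- effective_components(fits, mix)
  rep <- check_applicability(eff)
  applicability[[sc$label]] <- tibble::tibble(
    scenario = sc$label, verdict = rep$verdict,
    models = paste(rep$models_allowed, collapse = ";"),
    n_effective = length(eff))
  message(sprintf("%s: %s (models: %s)", sc$label, rep$verdict,
                  paste(rep$models_allowed, collapse = ", ")))
  if (rep$verdict == "opposing") next

  for (model in rep$models_allowed) {
    crv <- switch(model,
      CA  = ca_predict(eff, mix),
      IA  = ia_predict(eff, mix, conc_grid = conc_grid),
      GCA = gca_predict(eff, mix, conc_grid = conc_grid))
    predictions[[paste(sc$label, model)]] <- tibble::tibble(
      scenario = sc$label, model = model,
      concentration_uM = crv$concentration_uM, effect_pct = crv$effect_pct)
  }
  summary[[sc$label]] <- tibble::tibble(
    scenario = sc$label,
    ca_floor_pct = ca_effect_floor(eff),
    gca_asymptote_pct = if ("GCA" %in% rep$models_allowed)
      gca_asymptote(eff, mix) else NA_real_)
}

readr::write_csv(bind_rows(applicability), file.path(out, "applicability.csv"))
readr::write_csv(bind_rows(predictions), file.path(out, "predictions.csv"))
readr::write_csv(bind_rows(summary), file.path(out, "summary.csv"))
print(bind_rows(summary))
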