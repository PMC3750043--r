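# mixhill

Mixture-effect prediction for steroidogenesis concentration–response data.

H295R steroidogenesis assays measure hormone production (as % of solvent
control) for a chemical over a concentration series, in triplicate. Given
constrained Hill fits for each chemical in a fixed-ratio mixture, `mixhill`
predicts the mixture's concentration–response curve under three classical
models and compares predictions — and each component's individual
contribution — against a confidence band around the experimentally observed
mixture response.

## The models

Each single chemical is fitted with a three-parameter logistic with slope
fixed at 1 and bottom fixed at the control level (100 %):

    E(c) = 100 + (top − 100) · c / (EC50 + c)

Inhibitory plateaus are pinned to the minimum per-concentration mean; a
Kruskal–Wallis gate (α = 0.05) must pass before any fit. For a mixture with
fractions *pᵢ* of total concentration *X*:

- **Concentration addition (CA)** — `X(e) = 1 / Σᵢ pᵢ/xᵢ(e)` where `xᵢ(e)`
  is the component's inverse Hill curve. Only defined down to the shallowest
  component plateau (the *effect floor*).
- **Independent action (IA)** — `E(X) = 100 · Πᵢ eᵢ(pᵢX)/100`, for
  all-inhibitory mixtures.
- **Generalized concentration addition (GCA)** —
  `E(X) = (100 + Σᵢ topᵢ qᵢ) / (1 + Σᵢ qᵢ)` with `qᵢ = pᵢX/EC50ᵢ`, which
  extends partial agonists beyond their plateau and has a closed-form
  high-concentration asymptote.

Mixtures whose effective components act in opposite directions are refused
by all three predictors.

## Worked example

Predict the testosterone response of the packaged 12-component
environmental mixture from its component curve parameters:

```r
library(mixhill)

mix  <- read_mixture_table(mixhill_example("mixture1"))
#> Warning: mixture fractions sum to 0.999
fits <- effective_components(registry_fits("testosterone", "mixture1"), mix)
names(fits)
#> [1] "BPA"           "OMC"           "epoxiconazole" "linuron"
#> [5] "prochloraz"

check_applicability(fits)
#> <applicability_report> testosterone: all_inhibitory; models allowed: CA, IA, GCA

ca_effect_floor(fits)      # CA cannot predict below the shallowest plateau
#> [1] 60
gca_asymptote(fits, mix)   # GCA continues down to its asymptote
#> [1] 14.95943

gca <- gca_predict(fits, mix, conc_grid = lseq(0.04, 30, 5))
data.frame(conc_uM = gca$concentration_uM, effect_pct = gca$effect_pct)
#>     conc_uM effect_pct
#> 1  0.040000   97.06632
#> 2  0.209327   86.60384
#> 3  1.095445   57.94166
#> 4  5.732657   28.85338
#> 5 30.000000   18.01872

ca <- ca_predict(fits, mix, effect_grid = c(90, 75, 62))
data.frame(effect_pct = ca$effect_pct, conc_uM = ca$concentration_uM)
#>   effect_pct   conc_uM
#> 1         90 0.1491871
#> 2         75 0.4661467
#> 3         62 0.9043539
```

The same workflow runs from raw response tables: `read_response_table()` →
`fit_table()` → `check_applicability()` → predictions → `contribution_curve()`
/ `confidence_band()` / `compare_to_band()`, or in one call via
`run_config()` + `run_pipeline()`. A synthetic generator
(`truth_registry()`, `generate_single()`, `generate_mixture()`) emulates the
triplicate assay design so the whole pipeline can be exercised without raw
assay data. See the vignette source in `vignettes/mixture-models.Rmd` for
the methods in full.

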