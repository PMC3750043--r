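# Synthetic H295R-style concentration-response data.
#
# The generator emulates the assay design used throughout the package:
# triplicate responses at seven log-spaced concentrations between 0.04 and
# 30 uM plus a concentration-0 control, responses expressed in % of control,
# with additive normal noise on that scale. A built-in truth registry holds
# the published EC50/Emax values for both study mixtures and their
# constituents so every pipeline stage can be exercised without raw data.

#' Registry of published single-chemical and mixture curve parameters
#'
#' One row per chemical x hormone x mixture context, holding the reported
#' curve direction, EC50 (uM) and maximal effect level (% of control).
#' Chemicals reported as having no significant effect carry
#' `direction = "none"`. Where two irreconcilable fits were reported for the
#' same chemical (DDE on progesterone), both rows are kept and distinguished
#' by `note`; neither is privileged.
#'
#' @return a tibble with columns `chemical`, `endpoint`, `context`,
#'   `subject` ("component" or "mixture"), `direction`, `ec50_uM`,
#'   `top_pct`, `method`, `note`.
#' @export
truth_registry <- function() {
  r <- function(chemical, endpoint, context, subject, direction,
                ec50 = NA_real_, top = NA_real_, method = "DELFIA",
                note = NA_character_) {
    tibble::tibble(chemical = chemical, endpoint = endpoint,
                   context = context, subject = subject,
                   direction = direction, ec50_uM = ec50, top_pct = top,
                   method = method, note = note)
  }
  none <- function(chemicals, endpoint, context, method = "DELFIA") {
    do.call(rbind, lapply(chemicals, r, endpoint = endpoint,
                          context = context, subject = "component",
                          direction = "none", method = method))
  }
  dplyr::bind_rows(
    # Mixture 1 as a whole, eight-hormone screen (LC-MS/MS except estradiol)
    r("mixture1", "progesterone", "mixture1", "mixture", "stimulatory",
      16, 1200, "LC-MS/MS", "tentative Emax; plateau not reached"),
    r("mixture1", "17a-OH-progesterone", "mixture1", "mixture", "none",
      method = "LC-MS/MS"),
    r("mixture1", "cortisol", "mixture1", "mixture", "inhibitory",
      1.5, 18, "LC-MS/MS"),
    r("mixture1", "dehydroepiandrosterone", "mixture1", "mixture",
      "inhibitory", 0.43, 17, "LC-MS/MS"),
    r("mixture1", "androstenedione", "mixture1", "mixture", "inhibitory",
      1.5, 9, "LC-MS/MS"),
    r("mixture1", "testosterone", "mixture1", "mixture", "inhibitory",
      2.4, 16, "LC-MS/MS"),
    r("mixture1", "estrone", "mixture1", "mixture", "none",
      method = "LC-MS/MS"),
    r("mixture1", "estradiol", "mixture1", "mixture", "none"),

    # Mixture 1 constituents & mixture, progesterone (DELFIA)
    r("DDE", "progesterone", "mixture1", "component", "inhibitory",
      0.002, 18, note = "modelled data set"),
    r("DDE", "progesterone", "mixture1", "component", "inhibitory",
      14, 16, note = "independent data set"),
    r("prochloraz", "progesterone", "mixture1", "component", "stimulatory",
      0.30, 2200),
    r("mixture1", "progesterone", "mixture1", "mixture", "stimulatory",
      10, 770),
    none(c("BPA", "butylparaben", "DBP", "DEHP", "epoxiconazole",
           "linuron", "4-MBC", "OMC", "procymidone", "vinclozolin"),
         "progesterone", "mixture1"),

    # Mixture 1 constituents & mixture, testosterone (DELFIA)
    r("BPA", "testosterone", "mixture1", "component", "inhibitory",
      3.5, 20),
    r("epoxiconazole", "testosterone", "mixture1", "component",
      "inhibitory", 1.5, 21),
    r("linuron", "testosterone", "mixture1", "component", "inhibitory",
      13, 58),
    r("OMC", "testosterone", "mixture1", "component", "inhibitory",
      3.4, 60),
    r("prochloraz", "testosterone", "mixture1", "component", "inhibitory",
      0.04, 9),
    r("mixture1", "testosterone", "mixture1", "mixture", "inhibitory",
      0.6, 20),
    none(c("butylparaben", "DBP", "DDE", "DEHP", "4-MBC", "procymidone",
           "vinclozolin"), "testosterone", "mixture1"),

    # Mixture 1 constituents & mixture, estradiol (DELFIA)
    r("BPA", "estradiol", "mixture1", "component", "stimulatory",
      6.6, 230),
    r("linuron", "estradiol", "mixture1", "component", "stimulatory",
      4.0, 127),
    r("procymidone", "estradiol", "mixture1", "component", "stimulatory",
      11, 146),
    r("4-MBC", "estradiol", "mixture1", "component", "stimulatory",
      3.5, 134, note = "not reproducible; considered a chance finding"),
    r("epoxiconazole", "estradiol", "mixture1", "component", "inhibitory",
      0.8, 45),
    r("prochloraz", "estradiol", "mixture1", "component", "inhibitory",
      0.13, 78),
    none(c("butylparaben", "DBP", "DDE", "OMC", "vinclozolin"),
         "estradiol", "mixture1"),
    r("DEHP", "estradiol", "mixture1", "component", "none",
      note = "non-monotonic in one data set; not reproduced"),
    r("mixture1", "estradiol", "mixture1", "mixture", "none"),

    # Mixture 2 constituents & mixture, progesterone
    r("tebuconazole", "progesterone", "mixture2", "component",
      "inhibitory", 0.13, 44),
    r("prochloraz", "progesterone", "mixture2", "component", "stimulatory",
      0.27, 465),
    r("mixture2", "progesterone", "mixture2", "mixture", "stimulatory",
      6.3, 255),
    none(c("mancozeb", "procymidone", "epoxiconazole"), "progesterone",
         "mixture2"),

    # Mixture 2 constituents & mixture, testosterone
    r("epoxiconazole", "testosterone", "mixture2", "component",
      "inhibitory", 1.0, 8),
    r("procymidone", "testosterone", "mixture2", "component", "inhibitory",
      3.4, 16),
    r("prochloraz", "testosterone", "mixture2", "component", "inhibitory",
      0.011, 1),
    r("tebuconazole", "testosterone", "mixture2", "component",
      "inhibitory", 0.011, 44),
    r("mixture2", "testosterone", "mixture2", "mixture", "inhibitory",
      0.28, 12),
    none("mancozeb", "testosterone", "mixture2"),

    # Mixture 2 constituents & mixture, estradiol
    r("epoxiconazole", "estradiol", "mixture2", "component", "inhibitory",
      0.48, 8),
    r("prochloraz", "estradiol", "mixture2", "component", "inhibitory",
      0.044, 1),
    r("tebuconazole", "estradiol", "mixture2", "component", "inhibitory",
      4.0, 41),
    r("mancozeb", "estradiol", "mixture2", "component", "stimulatory",
      5.7, 284),
    r("procymidone", "estradiol", "mixture2", "component", "stimulatory",
      8.0, 278),
    r("mixture2", "estradiol", "mixture2", "mixture", "inhibitory",
      1.1, 12)
  )
}

#' Hill fit records for the registry entries of one endpoint and mixture
#'
#' Convenience accessor: turns registry rows into the named `hill_fit` list
#' the mixture predictors consume. Rows with `direction = "none"` become
#' non-significant records; duplicate rows for one chemical (independent
#' data sets) are resolved by `note` or, by default, the first row.
#'
#' @param endpoint hormone label.
#' @param context "mixture1" or "mixture2".
#' @param subject "component" (default) or "mixture".
#' @param registry a registry tibble, by default [truth_registry()].
#' @return named list of `hill_fit` records.
#' @export
registry_fits <- function(endpoint, context, subject = "component",
                          registry = truth_registry()) {
  rows <- registry[registry$endpoint == endpoint &
                     registry$context == context &
                     registry$subject == subject, ]
  if (nrow(rows) == 0)
    mh_stop(sprintf("no registry entries for %s / %s", endpoint, context),
            "mixhill_input_error")
  rows <- rows[!duplicated(rows$chemical), ]
  fits <- lapply(seq_len(nrow(rows)), function(i) {
    with(rows[i, ], hill_fit(chemical, top = top_pct, ec50 = ec50_uM,
                             endpoint = endpoint, direction = direction))
  })
  stats::setNames(fits, rows$chemical)
}

#' Default assay concentration design
#'
#' Seven log-spaced test concentrations from 0.04 to 30 uM, matching the
#' tested range of the emulated assay. The concentration-0 control is added
#' by the generators.
#'
#' @return numeric vector of 7 concentrations (uM).
#' @export
default_concentrations <- function() {
  lseq(0.04, 30, 7)
}

# Noise and row assembly shared by the generators. Responses are % of
# control and must stay positive; additive normal draws are floored at 0.1.
assemble_dataset <- function(chemical, endpoint, truth_effect,
                             concentrations, n_rep, noise_sd, seed) {
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(c(0, concentrations), each = n_rep)
  mu <- rep(c(100, truth_effect), each = n_rep)
  resp <- mu + stats::rnorm(length(mu), 0, noise_sd)
  tibble::tibble(
    chemical = chemical,
    endpoint = endpoint,
    concentration_uM = conc,
    replicate = rep(seq_len(n_rep), times = length(concentrations) + 1),
    response_pct = pmax(resp, 0.1)
  )
}

#' Simulate a single-chemical concentration-response dataset
#'
#' Responses are drawn from the chemical's Hill truth plus additive normal
#' noise on the %-of-control scale; control rows at concentration 0 are
#' included. A truth with `direction = "none"` yields flat control-level
#' data.
#'
#' @param truth a one-row data frame or list with `chemical`, `endpoint`,
#'   `direction`, `ec50_uM`, `top_pct` (e.g. a [truth_registry()] row).
#' @param concentrations non-zero test concentrations (uM).
#' @param n_rep replicates per concentration (default 3).
#' @param noise_sd additive noise SD in % of control (default 10).
#' @param seed optional RNG seed; identical seeds give identical datasets.
#' @return a response dataset tibble.
#' @export
generate_single <- function(truth, concentrations = default_concentrations(),
                            n_rep = 3, noise_sd = 10, seed = NULL) {
  stopifnot(n_rep >= 1, noise_sd >= 0)
  truth <- as.list(tibble::as_tibble(truth)[1, ])
  eff <- if (identical(truth$direction, "none")) {
    rep(100, length(concentrations))
  } else {
    f <- hill_fit(truth$chemical, top = truth$top_pct,
                  ec50 = truth$ec50_uM, endpoint = truth$endpoint,
                  direction = truth$direction)
    hill_effect(f, concentrations)
  }
  assemble_dataset(truth$chemical, truth$endpoint, eff, concentrations,
                   n_rep, noise_sd, seed)
}

# Deterministic mixture truth curve as a function of total concentration.
mixture_truth_effect <- function(fits, mixture, model, concentrations,
                                 toy_opposing = FALSE) {
  p <- component_fractions(mixture)
  if (toy_opposing) {
    # NOT from the study: a toy extension for opposing-direction mixtures,
    # multiplying fraction-of-control terms (sums of signed log-effects).
    lg <- rowSums(vapply(fits, function(f) {
      log(hill_effect(f, p[[f$chemical]] * concentrations) / 100)
    }, numeric(length(concentrations))))
    return(100 * exp(lg))
  }
  switch(model,
    IA = ia_predict(fits, mixture, conc_grid = concentrations)$effect_pct,
    GCA = gca_predict(fits, mixture, conc_grid = concentrations)$effect_pct,
    CA = {
      floor_e <- ca_effect_floor(fits)
      lo <- min(100, floor_e); hi <- max(100, floor_e)
      grid <- seq(lo + 1e-4, hi - 1e-4, length.out = 2000)
      curve <- ca_predict(fits, mixture, effect_grid = grid)
      # interpolate effect vs log-concentration; clamp at the CA plateau
      stats::approx(log10(curve$concentration_uM), curve$effect_pct,
                    xout = log10(concentrations), rule = 2)$y
    },
    mh_stop(sprintf("unknown ground-truth model '%s'", model),
            "mixhill_input_error")
  )
}

#' Simulate an experimental mixture concentration-response dataset
#'
#' Draws mixture responses from a chosen reference-model truth curve. An
#' `antagonism_shift > 1` multiplies the concentration axis, i.e. the
#' simulated mixture needs shift-fold more total concentration to reach a
#' given effect than the model predicts — emulating antagonistic deviation.
#'
#' @param fits named list of effective component `hill_fit`s.
#' @param mixture a `mixture_definition`.
#' @param model ground-truth model: "GCA" (default), "CA" or "IA".
#' @param antagonism_shift fold-shift of the concentration axis, >= 1.
#' @param concentrations,n_rep,noise_sd,seed as in [generate_single()].
#' @param toy_opposing set `TRUE` to allow opposing-direction components via
#'   a clearly non-standard multiplicative toy rule (refused otherwise).
#' @return a response dataset tibble (chemical = the mixture name).
#' @export
generate_mixture <- function(fits, mixture, model = c("GCA", "CA", "IA"),
                             antagonism_shift = 1,
                             concentrations = default_concentrations(),
                             n_rep = 3, noise_sd = 10, seed = NULL,
                             toy_opposing = FALSE) {
  model <- match.arg(model)
  stopifnot(antagonism_shift >= 1)
  if (!toy_opposing) assert_applicable(fits, model)
  eff <- mixture_truth_effect(fits, mixture, model,
                              concentrations / antagonism_shift,
                              toy_opposing = toy_opposing)
  endpoint <- fits[[1]]$endpoint
  assemble_dataset(attr(mixture, "mixture_name") %||% "mixture", endpoint,
                   eff, concentrations, n_rep, noise_sd, seed)
}
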