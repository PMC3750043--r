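# Fixed-ratio mixture effect prediction under Concentration Addition (CA),
# Independent Action (IA) and Generalized Concentration Addition (GCA).
#
# All three models consume the constrained Hill fits of the individual
# chemicals plus the mixture's component fractions. CA solves, for each
# effect level e, 1 / X(e) = sum_i p_i / x_i(e); IA multiplies surviving
# fractions of control; GCA evaluates the slope-1 closed form
# E(X) = (100 + sum_i top_i q_i) / (1 + sum_i q_i), q_i = p_i X / EC50_i,
# which admits partial-efficacy components over the full concentration range.

#' Define a fixed-ratio mixture
#'
#' @param components a data frame with columns `chemical`, `mass_fraction`
#'   and optionally `molecular_weight` (g/mol).
#' @param name mixture label.
#' @param fraction_type "mass" (default) or "molar"; [mass_to_molar()]
#'   produces the latter.
#' @return a `mixture_definition` (tibble subclass).
#' @export
mixture_definition <- function(components, name = "mixture",
                               fraction_type = c("mass", "molar")) {
  fraction_type <- match.arg(fraction_type)
  components <- tibble::as_tibble(components)
  check_columns(components, c("chemical", "mass_fraction"),
                "mixture definition")
  if (anyDuplicated(components$chemical))
    mh_stop("duplicate chemical in mixture definition",
            "mixhill_input_error")
  if (any(!is.finite(components$mass_fraction)) ||
      any(components$mass_fraction <= 0))
    mh_stop("mixture fractions must be positive", "mixhill_input_error")
  s <- sum(components$mass_fraction)
  if (s < 0.99 || s > 1.01)
    mh_stop(sprintf("mixture fractions sum to %.4g; expected ~1", s),
            "mixhill_input_error")
  structure(components, mixture_name = name, fraction_type = fraction_type,
            class = c("mixture_definition", class(components)))
}

#' Convert mass fractions to molar fractions
#'
#' Component shares of a total molar mixture concentration are proportional
#' to mass_fraction / molecular_weight. The converted fractions are
#' renormalized to sum exactly to 1.
#'
#' @param mixture a `mixture_definition` with molecular weights for every
#'   component.
#' @return a `mixture_definition` with `fraction_type = "molar"`.
#' @export
mass_to_molar <- function(mixture) {
  stopifnot(inherits(mixture, "mixture_definition"))
  if (!"molecular_weight" %in% names(mixture) ||
      any(!is.finite(mixture$molecular_weight)))
    mh_stop("molecular_weight required for every component",
            "mixhill_input_error")
  mol <- mixture$mass_fraction / mixture$molecular_weight
  out <- mixture
  out$mass_fraction <- mol / sum(mol)
  attr(out, "fraction_type") <- "molar"
  out
}

# Named fraction vector for a mixture.
component_fractions <- function(mixture) {
  stats::setNames(mixture$mass_fraction, mixture$chemical)
}

#' Select the effective components of a mixture
#'
#' Keeps only the components whose single-chemical data passed the
#' significance gate (and hence have a fitted curve). Non-effective
#' components still occupy mixture mass but contribute no effect term to any
#' model.
#'
#' @param fits named list of `hill_fit` records, one per mixture component
#'   (records with `direction = "none"` are allowed and dropped).
#' @param mixture a `mixture_definition`.
#' @return named list of the significant `hill_fit`s, in mixture order.
#' @export
effective_components <- function(fits, mixture) {
  stopifnot(inherits(mixture, "mixture_definition"))
  missing <- setdiff(mixture$chemical, names(fits))
  if (length(missing) > 0)
    mh_stop(sprintf("no fit record for mixture component(s): %s",
                    paste(missing, collapse = ", ")),
            "mixhill_input_error")
  keep <- vapply(mixture$chemical, function(ch) {
    f <- fits[[ch]]
    isTRUE(f$significant) && f$direction != "none"
  }, logical(1))
  fits[mixture$chemical[keep]]
}

#' Check which mixture models may be applied
#'
#' The prediction models are only applicable when all effective components
#' act in the same direction; mixtures with opposing stimulatory and
#' inhibitory components are refused outright. IA is additionally restricted
#' to inhibitory mixtures, where the product of surviving fractions retains
#' its probabilistic meaning.
#'
#' @param fits list of effective `hill_fit`s (see [effective_components()]).
#' @param endpoint optional hormone label recorded in the report.
#' @return an `applicability_report` with `verdict` (one of
#'   "all_inhibitory", "all_stimulatory", "opposing", "none_effective") and
#'   `models_allowed`.
#' @export
check_applicability <- function(fits, endpoint = NULL) {
  if (is.null(endpoint)) {
    eps <- unique(stats::na.omit(
      vapply(fits, function(f) f$endpoint %||% NA_character_, character(1))))
    endpoint <- if (length(eps) == 1) eps else NA_character_
  }
  dirs <- vapply(fits, function(f) f$direction, character(1))
  dirs <- dirs[dirs != "none"]
  verdict <- if (length(dirs) == 0) "none_effective"
  else if (all(dirs == "inhibitory")) "all_inhibitory"
  else if (all(dirs == "stimulatory")) "all_stimulatory"
  else "opposing"
  models <- switch(verdict,
    all_inhibitory = c("CA", "IA", "GCA"),
    all_stimulatory = c("CA", "GCA"),
    character(0)
  )
  structure(
    list(
      endpoint = endpoint,
      chemicals = vapply(fits, function(f) f$chemical, character(1)),
      directions = vapply(fits, function(f) f$direction, character(1)),
      verdict = verdict,
      models_allowed = models
    ),
    class = "applicability_report"
  )
}

#' @export
print.applicability_report <- function(x, ...) {
  cat(sprintf("<applicability_report> %s: %s; models allowed: %s\n",
              x$endpoint, x$verdict,
              if (length(x$models_allowed)) paste(x$models_allowed, collapse = ", ")
              else "none"))
  invisible(x)
}

# Shared precondition for the predictors.
assert_applicable <- function(fits, model) {
  rep <- check_applicability(fits)
  if (rep$verdict == "none_effective")
    mh_stop("no effective components: nothing to predict",
            "mixhill_applicability_error")
  if (rep$verdict == "opposing")
    mh_stop(
      "mixture contains components with opposing effect directions; no prediction model is applicable",
      "mixhill_applicability_error")
  if (!(model %in% rep$models_allowed))
    mh_stop(
      sprintf("%s is not applicable to an %s mixture%s", model, rep$verdict,
              if (model == "IA")
                " (surviving fractions above 100% of control lose their probabilistic meaning)"
              else ""),
      "mixhill_applicability_error")
  rep
}

new_prediction_curve <- function(conc, effect, model, floor, truncated) {
  out <- tibble::tibble(concentration_uM = conc, effect_pct = effect)
  structure(out, model = model, effect_floor = floor, truncated = truncated,
            class = c("prediction_curve", class(out)))
}

#' @export
print.prediction_curve <- function(x, ...) {
  cat(sprintf("<prediction_curve> %s: %d points, effect floor %.4g%%%s\n",
              attr(x, "model"), nrow(x), attr(x, "effect_floor"),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  NextMethod()
}

#' Most extreme effect level predictable by CA (and IA)
#'
#' CA is defined only where every component can, on its own, produce the
#' requested effect, so the plateau closest to the control level bounds the
#' predictable range: the maximum of the component tops for inhibitory
#' mixtures, the minimum for stimulatory ones.
#'
#' @param fits list of effective `hill_fit`s with a uniform direction.
#' @return effect floor (inhibitory) or ceiling (stimulatory) in % of
#'   control.
#' @export
ca_effect_floor <- function(fits) {
  rep <- check_applicability(fits)
  if (!(rep$verdict %in% c("all_inhibitory", "all_stimulatory")))
    mh_stop("effect floor requires a uniform-direction component set",
            "mixhill_applicability_error")
  tops <- vapply(fits, function(f) f$top, numeric(1))
  if (rep$verdict == "all_inhibitory") max(tops) else min(tops)
}

#' Concentration Addition prediction
#'
#' For each effect level e the total mixture concentration satisfies
#' `1 / X(e) = sum_i p_i / x_i(e)` where `x_i(e)` is the concentration at
#' which component i alone produces e and `p_i` its fraction of the total
#' mixture concentration. Effect levels beyond any component's plateau are
#' excluded and the curve flagged as truncated.
#'
#' @param fits list of effective `hill_fit`s (uniform direction).
#' @param mixture a `mixture_definition`.
#' @param effect_grid effect levels (% of control); default 200 levels from
#'   just inside the control level to just inside the predictable floor.
#' @return a `prediction_curve` with attributes `effect_floor` and
#'   `truncated`.
#' @export
ca_predict <- function(fits, mixture, effect_grid = NULL) {
  assert_applicable(fits, "CA")
  floor_e <- ca_effect_floor(fits)
  p <- component_fractions(mixture)
  if (is.null(effect_grid)) {
    effect_grid <- if (floor_e < 100)
      seq(99.5, floor_e + 0.5, length.out = 200)
    else seq(100.5, floor_e - 0.5, length.out = 200)
  }
  valid <- effect_grid > min(100, floor_e) & effect_grid < max(100, floor_e)
  truncated <- any(!valid)
  e <- effect_grid[valid]
  if (length(e) == 0)
    mh_stop("no effect level in the requested grid is predictable by CA",
            "mixhill_domain_error")
  X <- vapply(e, function(ei) {
    inv <- vapply(fits, function(f) inverse_hill_safe(f, ei), numeric(1))
    1 / sum(p[names(fits)] / inv)
  }, numeric(1))
  ord <- order(X)
  new_prediction_curve(X[ord], e[ord], "CA", floor_e, truncated)
}

#' Independent Action prediction
#'
#' Bliss independence on the fraction-of-control scale: at total mixture
#' concentration X each component is present at `p_i * X` and the surviving
#' fractions multiply, `E(X) = 100 * prod_i e_i(p_i X) / 100`. Only defined
#' for all-inhibitory mixtures.
#'
#' @param fits list of effective `hill_fit`s (all inhibitory).
#' @param mixture a `mixture_definition`.
#' @param conc_grid total mixture concentrations (uM); default 200 points
#'   log-spaced over 1e-3 to 1e3.
#' @return a `prediction_curve`; its `effect_floor` is
#'   `100 * prod(top_i / 100)`.
#' @export
ia_predict <- function(fits, mixture, conc_grid = NULL) {
  assert_applicable(fits, "IA")
  p <- component_fractions(mixture)
  conc_grid <- conc_grid %||% lseq(1e-3, 1e3, 200)
  surv <- vapply(fits, function(f) {
    hill_effect(f, p[[f$chemical]] * conc_grid) / 100
  }, numeric(length(conc_grid)))
  surv <- matrix(surv, nrow = length(conc_grid))
  E <- 100 * apply(surv, 1, prod)
  floor_e <- 100 * prod(vapply(fits, function(f) f$top, numeric(1)) / 100)
  new_prediction_curve(conc_grid, E, "IA", floor_e, FALSE)
}

#' Generalized Concentration Addition prediction
#'
#' Slope-1 closed form that admits partial-efficacy components:
#' `E(X) = (100 + sum_i top_i q_i) / (1 + sum_i q_i)` with
#' `q_i = p_i X / EC50_i`. Reduces to the component's own Hill curve for a
#' single chemical and is never truncated.
#'
#' @inheritParams ia_predict
#' @return a `prediction_curve`; its `effect_floor` is [gca_asymptote()].
#' @export
gca_predict <- function(fits, mixture, conc_grid = NULL) {
  assert_applicable(fits, "GCA")
  p <- component_fractions(mixture)
  conc_grid <- conc_grid %||% lseq(1e-3, 1e3, 200)
  num <- rep(100, length(conc_grid))
  den <- rep(1, length(conc_grid))
  for (f in fits) {
    q <- p[[f$chemical]] * conc_grid / f$ec50
    num <- num + f$top * q
    den <- den + q
  }
  new_prediction_curve(conc_grid, num / den, "GCA",
                       gca_asymptote(fits, mixture), FALSE)
}

#' High-concentration asymptote of the GCA prediction
#'
#' The limit of the GCA curve as total concentration grows: the
#' potency-weighted mean of the component plateaus,
#' `sum_i (p_i / EC50_i) top_i / sum_i (p_i / EC50_i)`.
#'
#' @inheritParams ia_predict
#' @return asymptotic effect in % of control.
#' @export
gca_asymptote <- function(fits, mixture) {
  assert_applicable(fits, "GCA")
  p <- component_fractions(mixture)
  w <- vapply(fits, function(f) p[[f$chemical]] / f$ec50, numeric(1))
  tops <- vapply(fits, function(f) f$top, numeric(1))
  sum(w * tops) / sum(w)
}
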