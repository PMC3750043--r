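# Constrained Hill (three-parameter logistic) fitting for single-chemical
# concentration-response data on the %-of-control scale.
#
# The curve is E(c) = bottom + (top - bottom) * c / (EC50 + c) with the Hill
# slope fixed at 1 and the bottom fixed at 100% (the control level). Only the
# EC50 is estimated freely; the plateau ("top") is constrained by the observed
# per-concentration means: fixed at the strongest mean effect for inhibitory
# data, bounded above by the largest mean for stimulatory data.

#' Construct a Hill fit record
#'
#' Builds a fit object directly from known parameters, e.g. published
#' EC50/Emax pairs, without touching raw data. Objects produced by
#' [fit_hill()] carry the same fields plus the fitting diagnostics.
#'
#' @param chemical chemical identifier.
#' @param top plateau effect in % of control (<100 inhibitory, >100
#'   stimulatory).
#' @param ec50 half-maximal concentration in uM (> 0).
#' @param endpoint hormone label, e.g. "testosterone".
#' @param significant logical; whether the underlying data passed the
#'   significance gate. Defaults to `TRUE` unless `direction` is "none".
#' @param direction "inhibitory", "stimulatory" or "none"; inferred from
#'   `top` when missing.
#' @return an object of class `hill_fit`.
#' @export
hill_fit <- function(chemical, top = NA_real_, ec50 = NA_real_,
                     endpoint = NA_character_, significant = NULL,
                     direction = NULL) {
  if (is.null(direction)) {
    direction <- if (is.na(top)) "none" else if (top > 100) "stimulatory"
    else "inhibitory"
  }
  direction <- match.arg(direction, c("inhibitory", "stimulatory", "none"))
  if (direction != "none") {
    if (!is.finite(ec50) || ec50 <= 0)
      mh_stop(sprintf("ec50 must be a positive concentration (chemical %s)",
                      chemical), "mixhill_input_error")
    if (!is.finite(top) || top < 0)
      mh_stop(sprintf("top must be a non-negative %% of control (chemical %s)",
                      chemical), "mixhill_input_error")
    if (direction == "inhibitory" && top >= 100)
      mh_stop("inhibitory fits require top < 100", "mixhill_input_error")
    if (direction == "stimulatory" && top <= 100)
      mh_stop("stimulatory fits require top > 100", "mixhill_input_error")
  }
  structure(
    list(
      chemical = as.character(chemical),
      endpoint = as.character(endpoint),
      bottom = 100,
      top = as.numeric(top),
      ec50 = as.numeric(ec50),
      hill_slope = 1,
      direction = direction,
      significant = significant %||% (direction != "none"),
      p_value = NA_real_,
      rss = NA_real_,
      data = NULL,
      pars = NULL,
      vcov = NULL
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$direction == "none") {
    cat(sprintf("<hill_fit> %s / %s: no significant effect\n",
                x$chemical, x$endpoint))
  } else {
    cat(sprintf(
      "<hill_fit> %s / %s: %s, EC50 = %g uM, top = %g%% of control\n",
      x$chemical, x$endpoint, x$direction, x$ec50, x$top))
  }
  invisible(x)
}

# Validate a response dataset (one chemical x endpoint).
validate_response_data <- function(data) {
  check_columns(data, c("concentration_uM", "response_pct"),
                "response dataset")
  if (nrow(data) == 0)
    mh_stop("response dataset is empty", "mixhill_input_error")
  if (any(!is.finite(data$concentration_uM)) ||
      any(data$concentration_uM < 0))
    mh_stop("concentrations must be finite and >= 0 (0 = control)",
            "mixhill_input_error")
  if (any(!is.finite(data$response_pct)) || any(data$response_pct <= 0))
    mh_stop("responses must be finite and > 0 (% of control)",
            "mixhill_input_error")
  invisible(data)
}

#' Kruskal-Wallis significance gate
#'
#' Tests whether responses differ across concentration groups (including the
#' concentration-0 control) with the non-parametric Kruskal-Wallis rank test.
#' Datasets that fail the gate must not be curve-fitted; [fit_hill()] enforces
#' this.
#'
#' @param data a response dataset with columns `concentration_uM` and
#'   `response_pct` (plus optional `chemical`, `endpoint`, `replicate`).
#' @param alpha significance level (default 0.05).
#' @return a list with `p_value` and `significant`.
#' @export
significance_gate <- function(data, alpha = 0.05) {
  validate_response_data(data)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  groups <- factor(data$concentration_uM)
  if (nlevels(groups) < 2)
    mh_stop("need at least 2 concentration groups (incl. control)",
            "mixhill_input_error")
  if (any(table(groups) < 2))
    mh_stop("need at least 2 replicates in every concentration group",
            "mixhill_input_error")
  if (length(unique(data$response_pct)) == 1L) {
    # all responses tied: the rank statistic is undefined, no separation
    return(list(p_value = 1, significant = FALSE))
  }
  kt <- stats::kruskal.test(data$response_pct, groups)
  p <- kt$p.value
  if (!is.finite(p)) p <- 1
  list(p_value = p, significant = p < alpha)
}

# Per-concentration mean responses for the non-zero concentrations.
concentration_means <- function(data) {
  d <- data[data$concentration_uM > 0, ]
  agg <- stats::aggregate(d$response_pct, list(conc = d$concentration_uM),
                          mean)
  names(agg) <- c("concentration_uM", "mean_response")
  agg[order(agg$concentration_uM), ]
}

# Infer response direction from per-concentration means. The most extreme
# deviation from the control level decides; roughly balanced large deviations
# on both sides are ambiguous and refused (non-monotonic data are out of
# scope for this curve model).
infer_direction <- function(means) {
  dev_up <- max(means$mean_response) - 100
  dev_down <- 100 - min(means$mean_response)
  if (min(dev_up, dev_down) > 10 &&
      min(dev_up, dev_down) > 0.5 * max(dev_up, dev_down)) {
    mh_stop(
      "response direction is ambiguous: per-concentration means straddle 100% with no dominant trend",
      "mixhill_direction_error"
    )
  }
  if (dev_up >= dev_down) "stimulatory" else "inhibitory"
}

# Core constrained least-squares fit on the log10(EC50) axis. With the
# slope and bottom fixed, the plateau enters the model linearly, so for
# stimulatory data it is profiled out analytically (subject to its upper
# bound) and the solve is one-dimensional in log10(EC50) in both cases:
# a deterministic coarse grid scan followed by Brent refinement.
fit_hill_core <- function(conc, resp, direction, top_constraint) {
  pos <- conc[conc > 0]
  lo <- log10(min(pos)) - 4
  hi <- log10(max(pos)) + 4
  # occupancy g in [0, 1); E = 100 + (top - 100) * g
  profile <- function(lec) {
    g <- conc / (10^lec + conc)
    if (direction == "inhibitory") {
      top <- top_constraint
    } else {
      amp <- sum(g * (resp - 100)) / sum(g^2)
      amp <- min(max(amp, 1e-9), top_constraint - 100)
      top <- 100 + amp
    }
    list(top = top, rss = sum((resp - 100 - (top - 100) * g)^2))
  }
  grid <- seq(lo, hi, length.out = 61)
  rss_grid <- vapply(grid, function(l) profile(l)$rss, numeric(1))
  i <- which.min(rss_grid)
  bracket <- c(grid[max(i - 1, 1)], grid[min(i + 1, length(grid))])
  opt <- stats::optimize(function(l) profile(l)$rss, bracket, tol = 1e-10)
  lec <- opt$minimum
  sol <- profile(lec)
  if (!is.finite(sol$rss))
    mh_stop("Hill fit failed: non-finite residual sum of squares",
            "mixhill_fit_error")
  # Jacobian-based parameter covariance for delta-method bands
  pars <- if (direction == "inhibitory") c(lec = lec)
          else c(top = sol$top, lec = lec)
  pred_fun <- function(p, cc) {
    top <- if ("top" %in% names(p)) p[["top"]] else top_constraint
    100 + (top - 100) * cc / (10^p[["lec"]] + cc)
  }
  eps <- 1e-6
  J <- vapply(seq_along(pars), function(j) {
    pp <- pars
    pp[j] <- pp[j] + eps
    (pred_fun(pp, conc) - pred_fun(pars, conc)) / eps
  }, numeric(length(conc)))
  J <- matrix(J, nrow = length(conc))
  dof <- max(length(conc) - length(pars), 1)
  sigma2 <- sol$rss / dof
  V <- tryCatch(sigma2 * solve(crossprod(J)),
                error = function(e) matrix(0, length(pars), length(pars)))
  dimnames(V) <- list(names(pars), names(pars))
  list(ec50 = 10^lec, top = sol$top, rss = sol$rss, pars = pars, vcov = V)
}

#' Fit a constrained Hill curve to a single-chemical dataset
#'
#' Three-parameter logistic with Hill slope 1 and bottom fixed at 100% of
#' control. For inhibitory responses the plateau is fixed at the lowest
#' per-concentration mean; for stimulatory responses it is estimated subject
#' to an upper bound at the highest per-concentration mean. Datasets that do
#' not pass the Kruskal-Wallis gate are refused.
#'
#' @param data response dataset (columns `concentration_uM`, `response_pct`,
#'   optionally `chemical`, `endpoint`).
#' @param alpha significance level for the gate.
#' @param gate set `FALSE` to skip the significance gate (e.g. when it was
#'   already run).
#' @return a `hill_fit` with fitting diagnostics (`rss`, `p_value`, residual
#'   data) attached.
#' @export
fit_hill <- function(data, alpha = 0.05, gate = TRUE) {
  validate_response_data(data)
  means <- concentration_means(data)
  if (nrow(means) < 3)
    mh_stop("need >= 3 distinct non-zero concentrations",
            "mixhill_input_error")
  p_value <- NA_real_
  if (gate) {
    g <- significance_gate(data, alpha)
    p_value <- g$p_value
    if (!g$significant)
      mh_stop(
        sprintf("dataset is not significant (Kruskal-Wallis p = %.3g >= %g); no curve is fitted",
                g$p_value, alpha),
        "mixhill_not_significant"
      )
  }
  direction <- infer_direction(means)
  top_constraint <- if (direction == "inhibitory") min(means$mean_response)
                    else max(means$mean_response)
  core <- fit_hill_core(data$concentration_uM, data$response_pct,
                        direction, top_constraint)
  fit <- hill_fit(
    chemical = if ("chemical" %in% names(data)) data$chemical[1] else NA,
    top = core$top, ec50 = core$ec50,
    endpoint = if ("endpoint" %in% names(data)) data$endpoint[1] else NA,
    significant = TRUE, direction = direction
  )
  fit$p_value <- p_value
  fit$rss <- core$rss
  fit$data <- data
  fit$pars <- core$pars
  fit$vcov <- core$vcov
  fit
}

#' Evaluate a fitted Hill curve
#'
#' @param fit a `hill_fit`.
#' @param concentration concentrations in uM (vectorized, >= 0).
#' @return effect in % of control; `E(0) = 100`, `E(Inf) = top`.
#' @export
hill_effect <- function(fit, concentration) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$direction == "none")
    mh_stop(sprintf("chemical %s has no fitted curve (direction none)",
                    fit$chemical), "mixhill_input_error")
  if (any(concentration < 0))
    mh_stop("concentration must be >= 0", "mixhill_input_error")
  100 + (fit$top - 100) * concentration / (fit$ec50 + concentration)
}

#' Invert a fitted Hill curve
#'
#' Returns the concentration at which the chemical on its own produces a
#' given effect. Defined only for effects strictly between the control level
#' (100%) and the chemical's plateau; requests beyond the plateau raise a
#' domain error naming the chemical — this is what truncates CA predictions
#' for partial-efficacy components.
#'
#' @param fit a `hill_fit`.
#' @param effect effect level(s) in % of control.
#' @return concentration(s) in uM.
#' @export
inverse_hill <- function(fit, effect) {
  stopifnot(inherits(fit, "hill_fit"))
  if (fit$direction == "none")
    mh_stop(sprintf("chemical %s has no fitted curve (direction none)",
                    fit$chemical), "mixhill_input_error")
  lo <- min(100, fit$top)
  hi <- max(100, fit$top)
  bad <- effect <= lo | effect >= hi
  if (any(bad))
    mh_stop(
      sprintf("effect %s out of the predictable range (%g, %g) for chemical %s",
              paste(signif(effect[bad], 6), collapse = ", "),
              lo, hi, fit$chemical),
      "mixhill_domain_error"
    )
  fit$ec50 * (effect - 100) / (fit$top - effect)
}

# Vectorized inverse that returns NA outside the open effect domain.
inverse_hill_safe <- function(fit, effect) {
  lo <- min(100, fit$top)
  hi <- max(100, fit$top)
  out <- rep(NA_real_, length(effect))
  ok <- effect > lo & effect < hi
  out[ok] <- fit$ec50 * (effect[ok] - 100) / (fit$top - effect[ok])
  out
}

#' Pointwise confidence band around a fitted Hill curve
#'
#' Default method is a parametric residual bootstrap: residuals from the fit
#' are resampled onto the fitted values, the constrained fit is repeated, and
#' pointwise quantiles over the refits form the band. A faster delta-method
#' (normal-approximation) band is available. The band always contains the
#' fitted curve pointwise.
#'
#' @param fit a `hill_fit` produced by [fit_hill()] (it must carry its data).
#' @param data optional response dataset; defaults to the data stored in
#'   `fit`.
#' @param grid concentrations (uM) at which to evaluate the band.
#' @param level coverage level, default 0.95.
#' @param method "bootstrap" (default) or "delta".
#' @param nboot bootstrap resamples (default 1000).
#' @param seed optional RNG seed for the bootstrap.
#' @return a tibble of class `confidence_band` with columns
#'   `concentration_uM`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, data = NULL, grid, level = 0.95,
                            method = c("bootstrap", "delta"),
                            nboot = 1000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "hill_fit"), level > 0, level < 1)
  data <- data %||% fit$data
  if (is.null(data))
    mh_stop("confidence_band needs the dataset the fit was derived from",
            "mixhill_input_error")
  center <- hill_effect(fit, grid)
  fitted_vals <- hill_effect(fit, data$concentration_uM)
  resid <- data$response_pct - fitted_vals

  if (method == "delta") {
    if (is.null(fit$pars) || is.null(fit$vcov))
      mh_stop("delta bands need a data-derived fit (from fit_hill)",
              "mixhill_input_error")
    cf <- fit$pars
    eps <- 1e-6
    J <- vapply(seq_along(cf), function(j) {
      cfp <- cf; cfp[j] <- cfp[j] + eps
      fp <- fit
      fp$ec50 <- 10^cfp[["lec"]]
      if ("top" %in% names(cfp)) fp$top <- cfp[["top"]]
      (hill_effect(fp, grid) - center) / eps
    }, numeric(length(grid)))
    J <- matrix(J, nrow = length(grid))
    se <- sqrt(pmax(rowSums((J %*% fit$vcov) * J), 0))
    half <- stats::qnorm(1 - (1 - level) / 2) * se
    lower <- center - half
    upper <- center + half
  } else {
    if (!is.null(seed)) set.seed(seed)
    n <- length(resid)
    curves <- matrix(NA_real_, nrow = nboot, ncol = length(grid))
    failures <- 0L
    for (b in seq_len(nboot)) {
      y <- fitted_vals + sample(resid, n, replace = TRUE)
      refit <- try({
        d <- data
        d$response_pct <- y
        means <- concentration_means(d)
        tc <- if (fit$direction == "inhibitory") min(means$mean_response)
              else max(means$mean_response)
        fit_hill_core(d$concentration_uM, y, fit$direction, tc)
      }, silent = TRUE)
      if (inherits(refit, "try-error")) {
        failures <- failures + 1L
        next
      }
      curves[b, ] <- 100 + (refit$top - 100) * grid / (refit$ec50 + grid)
    }
    if (failures > 0.2 * nboot)
      mh_stop(sprintf("bootstrap refits failed for %d/%d resamples",
                      failures, nboot), "mixhill_fit_error")
    qs <- apply(curves, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                na.rm = TRUE)
    lower <- qs[1, ]
    upper <- qs[2, ]
  }
  out <- tibble::tibble(
    concentration_uM = grid,
    fit = center,
    lower = pmin(lower, center),
    upper = pmax(upper, center)
  )
  structure(out, level = level, band_method = method,
            class = c("confidence_band", class(out)))
}
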