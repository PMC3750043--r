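# Calculated contribution of a single chemical to a fixed-ratio mixture and
# band-location comparison of curves against experimental mixture data.

#' Contribution of one chemical on the mixture-concentration axis
#'
#' Re-expresses a single chemical's fitted curve as a function of TOTAL
#' mixture concentration: a component present at fraction p of the mixture
#' sees dose `p * X`, so its contribution at mixture concentration X is
#' `hill_effect(fit, p * X)`. On a log axis this is the single-chemical
#' curve shifted right by a factor 1/p.
#'
#' @param fit a significant `hill_fit`.
#' @param fraction the chemical's fraction of the total mixture
#'   concentration, in (0, 1].
#' @param grid total mixture concentrations (uM).
#' @return a `contribution_curve` tibble with `concentration_uM` and
#'   `effect_pct`.
#' @export
contribution_curve <- function(fit, fraction, grid) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    mh_stop("fraction must be in (0, 1]", "mixhill_input_error")
  if (!isTRUE(fit$significant) || fit$direction == "none")
    mh_stop(sprintf("chemical %s has no significant fitted curve",
                    fit$chemical), "mixhill_input_error")
  out <- tibble::tibble(
    chemical = fit$chemical,
    concentration_uM = grid,
    effect_pct = hill_effect(fit, fraction * grid)
  )
  structure(out, fraction = fraction,
            class = c("contribution_curve", class(out)))
}

#' Locate a curve relative to an experimental confidence band
#'
#' Classifies each overlapping grid point of a contribution or prediction
#' curve as inside the band, left of it (the curve reaches a given effect at
#' lower concentration than the band does) or right of it. Containment is
#' judged horizontally — at the point's effect level, does its concentration
#' fall between the concentrations at which the two band edges pass that
#' level? — wherever the effect level is invertible on the band edges, and
#' vertically (effect at matched concentration) otherwise; either
#' containment counts as inside, mirroring the visual judgment of a curve
#' lying within a confidence belt. The aggregate verdict is "inside" when at
#' least 95% of evaluable points fall within the band; otherwise the side
#' holding at least 90% of the outside points wins, and "mixed" when neither
#' does.
#'
#' @param curve a `contribution_curve` or `prediction_curve`.
#' @param band a `confidence_band` of the experimental mixture data.
#' @return a `band_comparison` list with per-point counts, the inside
#'   fraction and the verdict.
#' @export
compare_to_band <- function(curve, band) {
  stopifnot(inherits(band, "confidence_band"))
  check_columns(curve, c("concentration_uM", "effect_pct"), "curve")
  rng <- range(band$concentration_uM)
  ok <- curve$concentration_uM >= rng[1] & curve$concentration_uM <= rng[2]
  if (sum(ok) < 10)
    mh_stop("curve and band grids overlap on fewer than 10 points",
            "mixhill_input_error")
  x <- curve$concentration_uM[ok]
  e <- curve$effect_pct[ok]
  # interpolate band edges on the log-concentration axis
  lx <- log10(pmax(x, .Machine$double.xmin))
  bx <- log10(pmax(band$concentration_uM, .Machine$double.xmin))
  lower <- stats::approx(bx, band$lower, xout = lx, rule = 2)$y
  upper <- stats::approx(bx, band$upper, xout = lx, rule = 2)$y
  decreasing <- utils::tail(band$fit, 1) <= band$fit[1]
  eps <- 1e-9
  # vertical containment at matched concentration
  inside_v <- e >= lower - eps & e <= upper + eps
  # horizontal containment at matched effect level: invert each monotone
  # band edge (effect -> log-concentration) where the level is reachable
  invert_edge <- function(edge_y, level) {
    ord <- order(edge_y)
    yo <- edge_y[ord]
    xo <- bx[ord]
    out <- rep(NA_real_, length(level))
    reach <- level >= min(yo) & level <= max(yo)
    if (any(reach))
      out[reach] <- stats::approx(yo, xo, xout = level[reach],
                                  ties = "ordered")$y
    out
  }
  x_lo_edge <- invert_edge(band$lower, e)
  x_up_edge <- invert_edge(band$upper, e)
  # for a decreasing band the lower (deeper) edge passes a level first
  x_first <- if (decreasing) x_lo_edge else x_up_edge
  x_last <- if (decreasing) x_up_edge else x_lo_edge
  inside_h <- !is.na(x_first) & !is.na(x_last) &
    lx >= x_first - eps & lx <= x_last + eps
  # a level beyond one edge's range leaves the interval open on that side
  inside_h <- inside_h |
    (is.na(x_first) & !is.na(x_last) & lx <= x_last + eps) |
    (is.na(x_last) & !is.na(x_first) & lx >= x_first - eps)
  inside <- inside_v | inside_h
  # left = reaches the effect at lower concentration / responds more
  # strongly at the same concentration
  stronger <- !inside & if (decreasing) e < lower else e > upper
  stronger <- stronger | (!inside & !is.na(x_first) & lx < x_first)
  weaker <- !inside & !stronger
  n <- length(e)
  n_left <- sum(stronger)
  n_right <- sum(weaker)
  frac_inside <- mean(inside)
  verdict <- if (frac_inside >= 0.95) "inside"
  else {
    out_left <- n_left / (n_left + n_right)
    if (out_left >= 0.9) "left_of_band"
    else if (out_left <= 0.1) "right_of_band"
    else "mixed"
  }
  structure(
    list(
      curve_id = if ("chemical" %in% names(curve)) curve$chemical[1]
                 else attr(curve, "model") %||% "curve",
      n_points = n,
      frac_inside = frac_inside,
      n_left = n_left,
      n_right = n_right,
      verdict = verdict
    ),
    class = "band_comparison"
  )
}

#' @export
print.band_comparison <- function(x, ...) {
  cat(sprintf(
    "<band_comparison> %s: %s (%.0f%% of %d points inside; %d left, %d right)\n",
    x$curve_id, x$verdict, 100 * x$frac_inside, x$n_points, x$n_left,
    x$n_right))
  invisible(x)
}
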