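# Significance gating, constrained Hill fitting, forward/inverse evaluation
# and confidence bands.

test_that("significance gate matches a permutation oracle and handles degenerate input", {
  # no separation: every replicate identical to control
  flat <- exact_hill_data(top = 100 - 1e-12, ec50 = 1)
  flat$response_pct <- 100
  g <- significance_gate(flat)
  expect_false(g$significant)

  # clearly responding synthetic data: rank test agrees with a
  # permutation-based recomputation of the same statistic
  tr <- tibble::tibble(chemical = "X", endpoint = "testosterone",
                       direction = "inhibitory", ec50_uM = 1, top_pct = 10)
  d <- generate_single(tr, noise_sd = 5, seed = 7)
  g <- significance_gate(d)
  expect_true(g$significant)
  p_perm <- kw_permutation_p(d$response_pct, d$concentration_uM)
  expect_lt(abs(g$p_value - p_perm), 0.02)

  # single concentration group is refused
  one <- tibble::tibble(concentration_uM = rep(1, 6),
                        response_pct = rnorm(6, 100, 5))
  expect_error(significance_gate(one), class = "mixhill_input_error")
  # single replicate per group is refused
  single_rep <- tibble::tibble(concentration_uM = c(0, 1, 10),
                               response_pct = c(100, 80, 50))
  expect_error(significance_gate(single_rep), class = "mixhill_input_error")
})

test_that("significance gate is invariant under monotone response transformations", {
  tr <- tibble::tibble(chemical = "X", endpoint = "t",
                       direction = "inhibitory", ec50_uM = 1, top_pct = 40)
  d <- generate_single(tr, noise_sd = 8, seed = 11)
  p0 <- significance_gate(d)$p_value
  for (f in list(function(x) x^2, function(x) log(x),
                 function(x) 5 * x + 3)) {
    d2 <- d
    d2$response_pct <- f(d$response_pct)
    expect_equal(significance_gate(d2)$p_value, p0)
  }
})

test_that("fit recovers generating parameters exactly on noise-free data", {
  # a design whose top concentration resolves the plateau: with the
  # inhibitory top pinned to the strongest mean response, exact recovery
  # requires the plateau to actually be observed
  d <- exact_hill_data(top = 9, ec50 = 0.04,
                       concentrations = c(lseq(0.04, 30, 7), 1e4))
  fit <- fit_hill(d)
  expect_equal(fit$direction, "inhibitory")
  expect_equal(fit$ec50, 0.04, tolerance = 1e-4)
  means <- tapply(d$response_pct[d$concentration_uM > 0],
                  d$concentration_uM[d$concentration_uM > 0], mean)
  expect_equal(fit$top, unname(min(means)))

  # under the standard assay design the plateau is extrapolated, so the
  # pinned top sits just above the true plateau and the EC50 estimate
  # carries a small deterministic bias in compensation
  d_std <- exact_hill_data(top = 9, ec50 = 0.04)
  fit_std <- fit_hill(d_std)
  expect_gt(fit_std$top, 9)
  expect_lt(fit_std$top, 9.2)
  expect_equal(fit_std$ec50, 0.04, tolerance = 0.01)
  expect_equal(fit$bottom, 100)
  expect_equal(fit$hill_slope, 1)

  # stimulatory: top is estimated, bounded by the max mean response
  d2 <- exact_hill_data(top = 230, ec50 = 2)
  fit2 <- fit_hill(d2)
  expect_equal(fit2$direction, "stimulatory")
  expect_lte(fit2$top, max(d2$response_pct) + 1e-8)
})

test_that("inhibitory plateau equals the minimum per-concentration mean", {
  tr <- tibble::tibble(chemical = "X", endpoint = "t",
                       direction = "inhibitory", ec50_uM = 0.5, top_pct = 30)
  for (seed in c(3, 17, 41)) {
    d <- generate_single(tr, noise_sd = 8, seed = seed)
    fit <- fit_hill(d)
    means <- tapply(d$response_pct[d$concentration_uM > 0],
                    d$concentration_uM[d$concentration_uM > 0], mean)
    expect_equal(fit$top, unname(min(means)))
  }
})

test_that("non-significant or direction-ambiguous data are refused", {
  # pure noise around control level: overwhelmingly non-significant
  set.seed(5)
  noise <- exact_hill_data(top = 100 - 1e-9, ec50 = 1)
  noise$response_pct <- rnorm(nrow(noise), 100, 5)
  g <- significance_gate(noise)
  if (!g$significant)
    expect_error(fit_hill(noise), class = "mixhill_not_significant")

  # strong deviations on both sides of 100 with no dominant trend
  straddle <- exact_hill_data(top = 50, ec50 = 1)
  conc <- straddle$concentration_uM
  straddle$response_pct <- ifelse(conc > 3, 160, ifelse(conc > 0, 45, 100))
  expect_error(fit_hill(straddle, gate = FALSE),
               class = "mixhill_direction_error")
})

test_that("median EC50 recovery stays within 50% over repeated noisy assays", {
  # prochloraz-on-testosterone scenario: truth EC50 0.04 uM, plateau 9%
  tr <- truth_registry()
  pro <- tr[tr$chemical == "prochloraz" & tr$endpoint == "testosterone" &
              tr$context == "mixture1", ]
  ec50s <- vapply(1:100, function(s) {
    d <- generate_single(pro, noise_sd = 5, seed = s)
    if (!significance_gate(d)$significant) return(NA_real_)
    fit_hill(d, gate = FALSE)$ec50
  }, numeric(1))
  med <- median(ec50s, na.rm = TRUE)
  expect_gt(med, 0.02)
  expect_lt(med, 0.06)
})

test_that("forward evaluation honours the Hill identities", {
  f <- hill_fit("prochloraz", top = 9, ec50 = 0.04)
  expect_equal(hill_effect(f, 0), 100)
  expect_equal(hill_effect(f, 0.04), 54.5)
  expect_equal(hill_effect(f, 1e9), 9, tolerance = 1e-6)
  g <- hill_fit("prochloraz", top = 2200, ec50 = 0.30,
                endpoint = "progesterone")
  expect_equal(hill_effect(g, 0.30), 1150)
  expect_error(hill_effect(f, -1), class = "mixhill_input_error")
})

test_that("inverse evaluation is the exact inverse on its domain and refuses beyond it", {
  f <- hill_fit("prochloraz", top = 9, ec50 = 0.04)
  expect_equal(inverse_hill(f, 54.5), 0.04)
  # closed form, checked by forward evaluation
  c30 <- inverse_hill(f, 30)
  expect_equal(hill_effect(f, c30), 30, tolerance = 1e-12)
  expect_equal(c30, 0.04 * (30 - 100) / (9 - 30))

  # round trip across the whole open effect range
  effects <- seq(9 + 1e-3, 100 - 1e-3, length.out = 50)
  expect_equal(hill_effect(f, inverse_hill(f, effects)), effects,
               tolerance = 1e-8)
  conc <- lseq(1e-4, 1e4, 50)
  expect_equal(inverse_hill(f, hill_effect(f, conc)), conc,
               tolerance = 1e-8)

  # beyond the plateau: domain error naming the chemical
  omc <- hill_fit("OMC", top = 60, ec50 = 3.4)
  err <- expect_error(inverse_hill(omc, 55), class = "mixhill_domain_error")
  expect_match(conditionMessage(err), "OMC")
  expect_error(inverse_hill(f, 9), class = "mixhill_domain_error")
  expect_error(inverse_hill(f, 100), class = "mixhill_domain_error")
})

test_that("confidence bands degenerate on exact data and contain the fitted curve", {
  grid <- lseq(0.04, 30, 25)
  # with the top pinned to the minimum mean, noise-free data leave a tiny
  # deterministic residual (the plateau is only approached, never attained),
  # so the band collapses to the residual scale rather than to zero exactly
  d <- exact_hill_data(top = 20, ec50 = 1,
                       concentrations = c(lseq(0.04, 30, 7), 1e4))
  fit <- fit_hill(d)
  resid_scale <- max(abs(d$response_pct -
    ifelse(d$concentration_uM == 0, 100,
           hill_effect(fit, d$concentration_uM))))
  expect_lt(resid_scale, 0.01)
  band <- confidence_band(fit, grid = grid, nboot = 50, seed = 1)
  expect_true(all(band$upper - band$lower <= 4 * resid_scale))

  tr <- tibble::tibble(chemical = "X", endpoint = "t",
                       direction = "inhibitory", ec50_uM = 1, top_pct = 20)
  d2 <- generate_single(tr, noise_sd = 10, seed = 2)
  fit2 <- fit_hill(d2)
  for (method in c("bootstrap", "delta")) {
    b <- confidence_band(fit2, grid = grid, method = method, nboot = 200,
                         seed = 3)
    expect_true(all(b$lower <= b$fit + 1e-12))
    expect_true(all(b$upper >= b$fit - 1e-12))
  }
})

test_that("bootstrap bands cover the generating curve at the EC50", {
  tr <- tibble::tibble(chemical = "X", endpoint = "t",
                       direction = "inhibitory", ec50_uM = 1, top_pct = 20)
  truth_at_ec50 <- 60  # (100 + 20) / 2
  hits <- vapply(1:200, function(s) {
    d <- generate_single(tr, noise_sd = 8, seed = s)
    fit <- fit_hill(d, gate = FALSE)
    b <- confidence_band(fit, grid = 1, nboot = 199, seed = s)
    b$lower[1] <= truth_at_ec50 && truth_at_ec50 <= b$upper[1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
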