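# CA, IA and GCA predictors, predictable ranges and the applicability rule.

test_that("effective component selection keeps only significant fits", {
  fits <- registry_fits("testosterone", "mixture1")
  eff <- effective_components(fits, mix1())
  expect_setequal(names(eff),
                  c("BPA", "epoxiconazole", "linuron", "OMC", "prochloraz"))

  # all-none mixture: empty effective set
  none_fits <- lapply(mix2()$chemical, function(ch)
    hill_fit(ch, direction = "none"))
  names(none_fits) <- mix2()$chemical
  expect_length(effective_components(none_fits, mix2()), 0)

  # a component without any fit record is an error
  expect_error(effective_components(fits[-1], mix1()),
               class = "mixhill_input_error")
})

test_that("applicability verdicts follow component directions", {
  # Mixture 1 testosterone: five inhibitory components, everything allowed
  rep1 <- check_applicability(mix1_testo_fits(), "testosterone")
  expect_equal(rep1$verdict, "all_inhibitory")
  expect_setequal(rep1$models_allowed, c("CA", "IA", "GCA"))

  # Mixture 2 estradiol: three inhibitory + two stimulatory -> opposing,
  # nothing may run
  f_e2 <- effective_components(registry_fits("estradiol", "mixture2"),
                               mix2())
  rep2 <- check_applicability(f_e2, "estradiol")
  expect_equal(rep2$verdict, "opposing")
  expect_length(rep2$models_allowed, 0)
  expect_error(ca_predict(f_e2, mix2()),
               class = "mixhill_applicability_error")
  expect_error(ia_predict(f_e2, mix2()),
               class = "mixhill_applicability_error")
  expect_error(gca_predict(f_e2, mix2()),
               class = "mixhill_applicability_error")

  # no effective components
  expect_equal(check_applicability(list())$verdict, "none_effective")
  # stimulatory-only mixtures get CA and GCA but not IA
  stim <- list(A = hill_fit("A", 300, 1), B = hill_fit("B", 200, 2))
  rep3 <- check_applicability(stim)
  expect_equal(rep3$verdict, "all_stimulatory")
  expect_setequal(rep3$models_allowed, c("CA", "GCA"))
  expect_error(ia_predict(stim, mixture_definition(
    tibble::tibble(chemical = c("A", "B"), mass_fraction = c(0.5, 0.5)))),
    class = "mixhill_applicability_error")
})

test_that("the CA effect floor is the component plateau closest to control", {
  expect_equal(ca_effect_floor(mix1_testo_fits()), 60)
  expect_equal(ca_effect_floor(mix2_testo_fits()), 44)
  solo <- list(X = hill_fit("X", 35, 1))
  expect_equal(ca_effect_floor(solo), 35)
  stim <- list(A = hill_fit("A", 300, 1), B = hill_fit("B", 200, 2))
  expect_equal(ca_effect_floor(stim), 200)
})

test_that("CA reduces to the single chemical and is sham-combination invariant", {
  f <- hill_fit("X", 20, 1.5)
  solo_mix <- mixture_definition(
    tibble::tibble(chemical = "X", mass_fraction = 1))
  grid <- seq(25, 99, length.out = 40)
  ca1 <- ca_predict(list(X = f), solo_mix, grid)
  expect_equal(ca1$concentration_uM, inverse_hill(f, ca1$effect_pct),
               tolerance = 1e-10)

  # n copies of the same chemical in arbitrary fractions
  copies <- list(X1 = hill_fit("X1", 20, 1.5), X2 = hill_fit("X2", 20, 1.5),
                 X3 = hill_fit("X3", 20, 1.5))
  sham <- mixture_definition(tibble::tibble(
    chemical = c("X1", "X2", "X3"), mass_fraction = c(0.6, 0.3, 0.1)))
  ca3 <- ca_predict(copies, sham, grid)
  expect_equal(ca3$concentration_uM, inverse_hill(f, ca3$effect_pct),
               tolerance = 1e-8)
  gca3 <- gca_predict(copies, sham, conc_grid = lseq(1e-3, 1e3, 60))
  expect_equal(gca3$effect_pct,
               hill_effect(f, gca3$concentration_uM), tolerance = 1e-8)
})

test_that("CA agrees with a brute-force root scan on the study mixture", {
  fits <- mix1_testo_fits()
  m <- mix1()
  p <- setNames(m$mass_fraction, m$chemical)
  for (e in c(80, 70, 65)) {
    curve <- ca_predict(fits, m, effect_grid = e)
    oracle <- ca_root_scan(fits, p, e)
    expect_equal(curve$concentration_uM, oracle, tolerance = 1e-3)
  }
  x80 <- ca_predict(fits, m, effect_grid = 80)$concentration_uM
  expect_true(is.finite(x80) && x80 > 0)
})

test_that("CA truncates at partial-efficacy plateaus", {
  fits <- mix1_testo_fits()  # floor at 60% of control
  curve <- ca_predict(fits, mix1(), effect_grid = seq(30, 99, by = 1))
  expect_true(attr(curve, "truncated"))
  expect_true(all(curve$effect_pct > 60))
  # default grid keeps inside the predictable range
  full <- ca_predict(fits, mix1())
  expect_false(attr(full, "truncated"))
  expect_true(all(full$effect_pct > 60 & full$effect_pct < 100))
  expect_error(ca_predict(fits, mix1(), effect_grid = c(10, 50)),
               class = "mixhill_domain_error")
})

test_that("IA is the Bliss product of surviving fractions", {
  # two components each at 50% of control at some concentration -> 25%
  fits <- list(A = hill_fit("A", 10, 1), B = hill_fit("B", 10, 1))
  m <- mixture_definition(tibble::tibble(chemical = c("A", "B"),
                                         mass_fraction = c(0.5, 0.5)))
  # each component at p*X = 1 uM needs total X = 2; e_i(1) = 55 each
  ia <- ia_predict(fits, m, conc_grid = 2)
  expect_equal(ia$effect_pct, 100 * 0.55 * 0.55)

  # single component: IA curve equals the component curve
  solo <- mixture_definition(tibble::tibble(chemical = "A",
                                            mass_fraction = 1))
  grid <- lseq(1e-2, 1e2, 30)
  ia1 <- ia_predict(fits["A"], solo, grid)
  expect_equal(ia1$effect_pct, hill_effect(fits$A, grid))

  # study mixture: term-by-term product oracle at 1 uM
  sfits <- mix1_testo_fits()
  sm <- mix1()
  p <- setNames(sm$mass_fraction, sm$chemical)
  ia_m <- ia_predict(sfits, sm, conc_grid = 1)
  oracle <- 100
  for (ch in names(sfits)) {
    f <- sfits[[ch]]
    oracle <- oracle * (100 + (f$top - 100) * p[ch] /
                          (f$ec50 + p[ch])) / 100
  }
  expect_equal(ia_m$effect_pct, unname(oracle), tolerance = 1e-12)
  expect_equal(attr(ia_m, "effect_floor"),
               100 * prod(vapply(sfits, function(f) f$top, 1) / 100))
})

test_that("GCA obeys midpoint, sham and asymptote identities", {
  f <- hill_fit("X", 9, 0.04)
  solo <- mixture_definition(tibble::tibble(chemical = "X",
                                            mass_fraction = 1))
  gca <- gca_predict(list(X = f), solo, conc_grid = 0.04)
  expect_equal(gca$effect_pct, (100 + 9) / 2)
  expect_equal(gca_asymptote(list(X = f), solo), 9)

  # equal fractions, equal potency, tops 0 and 100 -> asymptote 50
  pair <- list(A = hill_fit("A", 1e-9, 1), B = hill_fit("B", 99.9999999, 1))
  m2 <- mixture_definition(tibble::tibble(chemical = c("A", "B"),
                                          mass_fraction = c(0.5, 0.5)))
  expect_equal(gca_asymptote(pair, m2), 50, tolerance = 1e-6)

  # study mixture: closed form at 30 uM is between asymptote and floor 20
  fits <- mix1_testo_fits()
  gca30 <- gca_predict(fits, mix1(), conc_grid = 30)$effect_pct
  asym <- gca_asymptote(fits, mix1())
  expect_lte(gca30, 20)
  expect_gte(gca30, asym)
  expect_equal(asym, 14.96, tolerance = 1e-3)
})

test_that("CA and GCA coincide when all components have equal efficacy", {
  fits <- list(A = hill_fit("A", 30, 0.5), B = hill_fit("B", 30, 5))
  m <- mixture_definition(tibble::tibble(chemical = c("A", "B"),
                                         mass_fraction = c(0.3, 0.7)))
  e_grid <- seq(31, 99, length.out = 60)
  ca <- ca_predict(fits, m, e_grid)
  gca_at_ca <- gca_predict(fits, m, conc_grid = ca$concentration_uM)
  expect_equal(gca_at_ca$effect_pct, ca$effect_pct, tolerance = 1e-6)
})

test_that("all three prediction curves are monotone and GCA passes the CA floor", {
  fits <- mix1_testo_fits()
  m <- mix1()
  grid <- lseq(1e-3, 1e3, 150)
  ca <- ca_predict(fits, m)
  ia <- ia_predict(fits, m, grid)
  gca <- gca_predict(fits, m, grid)
  expect_true(all(diff(ca$effect_pct[order(ca$concentration_uM)]) <= 1e-9))
  expect_true(all(diff(ia$effect_pct) <= 1e-9))
  expect_true(all(diff(gca$effect_pct) <= 1e-9))
  # component tops differ, so GCA reaches strictly below the CA floor
  expect_lt(min(gca$effect_pct), ca_effect_floor(fits))
  expect_gt(min(ca$effect_pct), ca_effect_floor(fits))
})

test_that("mass-to-molar conversion renormalizes by molecular weight", {
  m <- mixture_definition(tibble::tibble(
    chemical = c("A", "B"), mass_fraction = c(0.5, 0.5),
    molecular_weight = c(100, 200)))
  mol <- mass_to_molar(m)
  expect_equal(mol$mass_fraction, c(2 / 3, 1 / 3))
  expect_equal(sum(mol$mass_fraction), 1)
  expect_equal(attr(mol, "fraction_type"), "molar")

  eq <- mixture_definition(tibble::tibble(
    chemical = c("A", "B"), mass_fraction = c(0.5, 0.5),
    molecular_weight = c(150, 150)))
  expect_equal(mass_to_molar(eq)$mass_fraction, c(0.5, 0.5))

  no_mw <- mixture_definition(tibble::tibble(chemical = "A",
                                             mass_fraction = 1))
  expect_error(mass_to_molar(no_mw), class = "mixhill_input_error")
})

test_that("mixture definitions validate fractions and uniqueness", {
  expect_error(mixture_definition(tibble::tibble(
    chemical = c("A", "A"), mass_fraction = c(0.5, 0.5))),
    class = "mixhill_input_error")
  expect_error(mixture_definition(tibble::tibble(
    chemical = "A", mass_fraction = -1)), class = "mixhill_input_error")
  expect_error(mixture_definition(tibble::tibble(
    chemical = c("A", "B"), mass_fraction = c(0.2, 0.2))),
    class = "mixhill_input_error")
})
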