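# Shared fixtures and independent oracles for the test suite.

# Noise-free responses on an exact Hill truth (slope 1, bottom 100).
exact_hill_data <- function(top, ec50, concentrations = lseq(0.04, 30, 7),
                            n_rep = 3, chemical = "X",
                            endpoint = "testosterone") {
  conc <- rep(c(0, concentrations), each = n_rep)
  eff <- 100 + (top - 100) * conc / (ec50 + conc)
  tibble::tibble(
    chemical = chemical, endpoint = endpoint, concentration_uM = conc,
    replicate = rep(seq_len(n_rep), length(concentrations) + 1),
    response_pct = eff
  )
}

# Permutation oracle for the Kruskal-Wallis gate: recompute the KW statistic
# by hand and estimate its null distribution by label permutation.
kw_permutation_p <- function(response, group, n_perm = 4000, seed = 99) {
  group <- factor(group)
  kw_stat <- function(y) {
    r <- rank(y)
    n <- length(y)
    num <- sum(tapply(r, group, function(ri) length(ri) *
                        (mean(ri) - (n + 1) / 2)^2))
    # tie correction
    ties <- table(y)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    (12 / (n * (n + 1))) * num / corr
  }
  obs <- kw_stat(response)
  set.seed(seed)
  perm <- replicate(n_perm, kw_stat(sample(response)))
  mean(perm >= obs - 1e-12)
}

# Brute-force CA oracle: scan a dense concentration grid for the total
# mixture concentration where sum_i p_i * X / x_i(e) = 1.
ca_root_scan <- function(fits, fractions, effect, n_grid = 1e5) {
  xs <- lseq(1e-6, 1e4, n_grid)
  inv <- vapply(names(fits), function(ch) {
    f <- fits[[ch]]
    f$ec50 * (effect - 100) / (f$top - effect)
  }, numeric(1))
  g <- vapply(xs, function(X) sum(fractions[names(fits)] * X / inv),
              numeric(1))
  i <- which.min(abs(g - 1))
  xs[i]
}

# Printed-parameter fits and compositions used across tests.
mix1 <- function() suppressWarnings(read_mixture_table(mixhill_example("mixture1")))
mix2 <- function() read_mixture_table(mixhill_example("mixture2"))

mix1_testo_fits <- function() {
  effective_components(registry_fits("testosterone", "mixture1"), mix1())
}
mix2_testo_fits <- function() {
  effective_components(registry_fits("testosterone", "mixture2"), mix2())
}
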