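# Independent oracles used across test files.

# Quadratic-root oracle for the NRH gross rate: solve
# theta*A^2 - (phi*q + amax)*A + phi*q*amax = 0 with stats::polyroot-free
# explicit formula and take the smaller root.
oracle_nrh_gross <- function(q, a_max, phi, theta) {
  vapply(q, function(qi) {
    if (theta == 0) return(phi * qi * a_max / (phi * qi + a_max))
    b <- phi * qi + a_max
    (b - sqrt(b^2 - 4 * theta * phi * qi * a_max)) / (2 * theta)
  }, numeric(1))
}

# Direct-formula SMA slope oracle: sign(s_xy) * sqrt(s_yy / s_xx).
oracle_sma_slope <- function(x, y) {
  sxy <- stats::cov(x, y)
  s <- if (sxy == 0) 1 else sign(sxy)
  s * sqrt(stats::var(y) / stats::var(x))
}

# Permutation oracle for the common-slope test: permute group labels and
# recompute the LR statistic.
oracle_perm_common_slope_p <- function(x, y, g, n_perm = 199, seed = 1) {
  stat_of <- function(g) {
    fits <- lapply(split(data.frame(x, y), g), function(d)
      leafecon::sma_fit(d$x, d$y))
    b <- leafecon:::sma_common_slope(fits)
    -leafecon:::sma_common_slope_objective(fits, b)
  }
  obs <- stat_of(g)
  set.seed(seed)
  perm <- replicate(n_perm, stat_of(sample(g)))
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

# Small noiseless curve fixture on the standard 12-step sequence.
make_curve <- function(params, noise_sd = 0, seed = NULL,
                       q = c(800, 1000, 1300, 1000, 800, 500, 300, 200,
                             100, 50, 20, 0)) {
  if (!is.null(seed)) set.seed(seed)
  a <- leafecon::nrh_predict(params, q)
  if (noise_sd > 0) a <- a + rnorm(length(q), 0, noise_sd)
  data.frame(ppfd = q, a_net = a)
}

tiny_species_meta <- function(panel) {
  panel[, c("species_code", "nativity", "leaf_habit")]
}
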