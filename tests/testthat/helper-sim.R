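# Shared fixtures, built in code and cached for the duration of the run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small two-environment population: 50 pollinators in 5 subfamilies,
# 70 hybrids, 200 markers, 120-point wavelength grid.
small_config <- function(seed = 7, ...) {
  defaults <- list(n_markers = 200, n_wavelengths = 120, n_qtl = 50,
                   family_sizes = rep(10, 5), n_both = 20,
                   n_t1_only = 10, n_t2_only = 10,
                   environments = data.frame(location = c("LOC1", "LOC2"),
                                             year = 2020L),
                   seed = seed)
  extra <- list(...)
  defaults[names(extra)] <- extra
  do.call(sim_config, defaults)
}

small_population <- function() {
  cached("small_pop", simulate_population(small_config()))
}

# HWE panel (non-inbred): dosages ~ Binomial(2, p) per marker.
hwe_panel <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  M <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  dimnames(M) <- list(paste0("i", seq_len(n)), paste0("mk", seq_len(m)))
  M
}

# Dense-loop Gram oracle for relationship matrices.
gram_loop <- function(A, denom) {
  n <- nrow(A)
  G <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      G[i, j] <- sum(A[i, ] * A[j, ]) / denom
  G
}

# Balanced one-way ANOVA estimators of (sigma2_group, sigma2_resid).
anova_oneway <- function(y, group) {
  r <- as.integer(table(group)[1])
  means <- tapply(y, group, mean)
  msw <- sum((y - means[group])^2) / (length(y) - length(means))
  msb <- r * var(as.numeric(means))
  c(group = (msb - msw) / r, residual = msw)
}
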