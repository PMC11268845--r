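# Smooth random curve over the wavelength grid: a sum of Gaussian bumps
# with random centres and widths, scaled to unit maximum absolute value.
smooth_profile <- function(wl, n_bumps = 3) {
  span <- diff(range(wl))
  y <- numeric(length(wl))
  for (b in seq_len(n_bumps)) {
    centre <- stats::runif(1, min(wl), max(wl))
    width <- stats::runif(1, 0.05, 0.25) * span
    y <- y + stats::rnorm(1) * exp(-0.5 * ((wl - centre) / width)^2)
  }
  m <- max(abs(y))
  if (m > 0) y / m else y
}

#' Simulate plot-level seed NIR reflectance spectra
#'
#' Each spectrum is the sum of a fixed smooth baseline, a genotype-driven
#' signal (a rank-\code{spectral_loading_rank} loading of genetic factors
#' onto smooth Gaussian-bump wavelength profiles), an optional component
#' proportional to the standardised genotypic value of the first trait, an
#' environment-specific smooth effect, a per-scan additive baseline drift
#' that increases with wavelength, and independent measurement noise. Two
#' technical replicates are produced per plot; they differ only by their
#' drift and noise draws.
#'
#' @param genotypes individuals x markers dosage matrix covering every
#'   non-check genotype in \code{plots}.
#' @param plots plot table from \code{\link{simulate_field_trial}}.
#' @param config a \code{\link{sim_config}}.
#' @param genetic_values optional named vector of genotypic values used
#'   for the trait-linked spectral component (omit for a purely
#'   genotype-factor signal).
#' @param n_tech_reps technical replicates per plot (default 2).
#' @return a \code{\link{spectra}} object with one row per plot and
#'   technical replicate.
#' @export
simulate_nirs <- function(genotypes, plots, config, genetic_values = NULL,
                          n_tech_reps = 2) {
  r <- config$spectral_loading_rank
  if (r > config$n_wavelengths)
    stop("spectral_loading_rank exceeds the wavelength count")
  wl <- wavelength_grid(config)
  L <- length(wl)
  stage_seed(config, "nirs")

  # fixed instrument baseline: gentle upward trend plus broad features
  base <- 0.4 + 0.2 * (wl - wl[1]) / max(1, diff(range(wl))) +
    0.05 * smooth_profile(wl, 4)

  # genotype factors: random projections of centred dosages, standardised
  Mc <- sweep(genotypes, 2, colMeans(genotypes))
  P <- matrix(stats::rnorm(ncol(genotypes) * r), ncol = r)
  FX <- Mc %*% P
  FX <- scale(FX)
  FX[is.nan(FX)] <- 0
  rownames(FX) <- rownames(genotypes)

  # loading matrix: one smooth profile per factor
  B <- t(vapply(seq_len(r), function(k) smooth_profile(wl),
                numeric(L))) * config$nirs_geno_sd / sqrt(r)

  # trait-linked component
  trait_prof <- smooth_profile(wl)
  gstd <- if (!is.null(genetic_values) && stats::sd(genetic_values) > 0)
    (genetic_values - mean(genetic_values)) / stats::sd(genetic_values)
  else NULL

  # check genotypes get their own factor draws
  checks <- setdiff(unique(plots$genotype), rownames(FX))
  if (length(checks)) {
    FC <- matrix(stats::rnorm(length(checks) * r), nrow = length(checks),
                 dimnames = list(checks, NULL))
    FX <- rbind(FX, FC)
    if (!is.null(gstd))
      gstd <- c(gstd, stats::setNames(stats::rnorm(length(checks)), checks))
  }

  envs <- unique(plots$environment)
  env_eff <- t(vapply(envs, function(e) smooth_profile(wl) *
                        config$nirs_env_sd * abs(stats::rnorm(1, 1, 0.3)),
                      numeric(L)))
  rownames(env_eff) <- envs

  ramp <- (wl - wl[1]) / max(1, diff(range(wl)))
  n_plot <- nrow(plots)
  n_samp <- n_plot * n_tech_reps
  V <- matrix(0, nrow = n_samp, ncol = L)
  info <- data.frame(
    sample_id = character(n_samp), plot_id = character(n_samp),
    replicate = integer(n_samp), genotype = character(n_samp),
    environment = character(n_samp), is_check = logical(n_samp),
    stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(n_plot)) {
    geno <- plots$genotype[i]
    sig <- base + drop(FX[geno, , drop = FALSE] %*% B) +
      env_eff[plots$environment[i], ]
    if (!is.null(gstd))
      sig <- sig + gstd[[geno]] * trait_prof * config$nirs_trait_sd
    for (tr in seq_len(n_tech_reps)) {
      k <- k + 1L
      drift <- config$baseline_drift_amplitude *
        stats::runif(1, 0.5, 1.5) * ramp
      noise <- stats::rnorm(L, 0, config$nirs_noise_sd)
      V[k, ] <- sig + drift + noise
      info$sample_id[k] <- paste0(plots$plot_id[i], "_r", tr)
      info$plot_id[k] <- plots$plot_id[i]
      info$replicate[k] <- tr
      info$genotype[k] <- geno
      info$environment[k] <- plots$environment[i]
      info$is_check[k] <- plots$is_check[i]
    }
  }
  rownames(V) <- info$sample_id
  spectra(V, wl, info)
}

#' Simulate the full population in one call
#'
#' Convenience wrapper chaining parent simulation, pollinator derivation,
#' the crossing design, hybrid genotypes, trait architectures, the field
#' trial and plot-level NIR spectra.
#'
#' @param config a \code{\link{sim_config}}.
#' @param nirs logical; also simulate spectra (default TRUE).
#' @return list with \code{parents}, \code{pollinators}, \code{families},
#'   \code{pedigree}, \code{hybrids} (dosage matrix), \code{architectures}
#'   (per trait), \code{genetic_values} (per trait), \code{plots} and
#'   \code{nirs}.
#' @export
simulate_population <- function(config, nirs = TRUE) {
  parents <- simulate_parent_genomes(config)
  pol <- derive_pollinators(parents, config)
  ped <- make_crossing_design(rownames(pol$genotypes), config,
                              families = pol$families)
  hyb <- synthesize_hybrid_genotypes(pol$genotypes, parents, ped)
  arch <- lapply(names(config$h2_targets), function(tr)
    simulate_trait_architecture(hyb, config, tr))
  names(arch) <- names(config$h2_targets)
  gv <- lapply(arch, `[[`, "values")
  plots <- simulate_field_trial(gv, config)
  sp <- if (nirs) simulate_nirs(hyb, plots, config,
                                genetic_values = gv[[1]]) else NULL
  list(parents = parents, pollinators = pol$genotypes,
       families = pol$families, pedigree = ped, hybrids = hyb,
       architectures = arch, genetic_values = gv, plots = plots,
       nirs = sp)
}
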