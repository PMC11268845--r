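#' Simulation configuration for a structured test-hybrid population
#'
#' Builds the parameter object consumed by every generator in the package.
#' Defaults emulate a winter oilseed rape test-hybrid programme: five
#' founder-by-elite subfamilies of fully inbred pollinators (251 in total),
#' two male-sterile testers, 410 test hybrids, multi-environment partially
#' replicated field trials (1.2 replicates plus replicated check varieties),
#' and seed NIR reflectance spectra measured in two technical replicates.
#'
#' @param n_markers number of biallelic SNP markers.
#' @param n_wavelengths number of points on the NIR wavelength grid.
#' @param wavelength_start,wavelength_step wavelength grid origin and step
#'   in nm (default 680 nm, 1 nm; 1,820 points reproduce the full-range
#'   instrument profile).
#' @param n_founders number of founder lines crossed to the common elite
#'   line.
#' @param family_sizes integer vector, pollinators per subfamily; must have
#'   length \code{n_founders}.
#' @param n_both,n_t1_only,n_t2_only pollinators crossed with both testers
#'   or with only one of them. Defaults 159/46/46 give 410 hybrids.
#' @param environments data.frame with columns \code{location} and
#'   \code{year}; one row per trial environment.
#' @param replicate_fraction fraction of test genotypes grown twice within
#'   an environment (p-rep design; 0.2 gives 1.2 replicates).
#' @param n_checks,check_reps number of check varieties and their
#'   replicates per environment.
#' @param h2_targets named numeric vector of entry-mean heritability
#'   targets per trait, each in (0, 1].
#' @param var_env,var_year,var_loc,var_gxe,var_row,var_col,var_resid
#'   variance components of the field-trial model (environment, year,
#'   location, genotype-by-environment, row and column within environment,
#'   plot residual), shared across traits.
#' @param n_qtl number of additive QTL per trait.
#' @param n_blocks recombination blocks on the abstract linear genome used
#'   when deriving inbred pollinators.
#' @param founder_freq_range range of per-marker reference allele
#'   frequencies among parents (bounded away from 0/1 so the
#'   expected-heterozygosity marker filter is non-degenerate).
#' @param spectral_loading_rank rank of the genotype-to-spectrum loading
#'   (smooth Gaussian-bump wavelength profiles).
#' @param baseline_drift_amplitude amplitude (reflectance units) of the
#'   per-scan additive baseline drift that increases with wavelength.
#' @param nirs_geno_sd,nirs_env_sd,nirs_trait_sd,nirs_noise_sd standard
#'   deviations (reflectance units) of the genotype-driven spectral
#'   signal, the environment-specific smooth effect, the component
#'   proportional to the (standardised) genotypic value of the first
#'   trait, and the independent measurement noise.
#' @param plot_drop_fraction fraction of plots of one random environment
#'   dropped after simulation (waterlogging-style exclusion; default off).
#' @param seed integer master seed; every generator derives its stream
#'   from it.
#' @return object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_markers = 200, n_wavelengths = 120)
#' cfg$n_both + cfg$n_t1_only + cfg$n_t2_only
#' @export
sim_config <- function(n_markers = 600,
                       n_wavelengths = 200,
                       wavelength_start = 680,
                       wavelength_step = 1,
                       n_founders = 5,
                       family_sizes = c(53, 50, 51, 45, 52),
                       n_both = 159,
                       n_t1_only = 46,
                       n_t2_only = 46,
                       environments = default_environments(),
                       replicate_fraction = 0.2,
                       n_checks = 3,
                       check_reps = 10,
                       h2_targets = c(yield = 0.55, height = 0.7,
                                      flowering = 0.85),
                       var_env = 1,
                       var_year = 0.25,
                       var_loc = 0.25,
                       var_gxe = 0.5,
                       var_row = 0.1,
                       var_col = 0.1,
                       var_resid = 1,
                       n_qtl = 100,
                       n_blocks = 20,
                       founder_freq_range = c(0.1, 0.9),
                       spectral_loading_rank = 10,
                       baseline_drift_amplitude = 0.05,
                       nirs_geno_sd = 0.02,
                       nirs_env_sd = 0.02,
                       nirs_trait_sd = 0.02,
                       nirs_noise_sd = 0.005,
                       plot_drop_fraction = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  markers: %d, wavelengths: %d (%g-%g nm)\n", x$n_markers,
              x$n_wavelengths, x$wavelength_start,
              x$wavelength_start + (x$n_wavelengths - 1) * x$wavelength_step))
  cat(sprintf("  pollinators: %d in %d subfamilies; hybrids: %d\n",
              sum(x$family_sizes), x$n_founders,
              2L * x$n_both + x$n_t1_only + x$n_t2_only))
  cat(sprintf("  environments: %d; replicate fraction %.2f; %d checks x %d\n",
              nrow(x$environments), x$replicate_fraction, x$n_checks,
              x$check_reps))
  cat(sprintf("  traits: %s\n",
              paste(sprintf("%s (h2=%.2f)", names(x$h2_targets),
                            x$h2_targets), collapse = ", ")))
  invisible(x)
}

default_environments <- function(n_locations = 5, years = c(2020L, 2021L)) {
  expand.grid(location = paste0("LOC", seq_len(n_locations)),
              year = years, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_markers >= 1, cfg$n_wavelengths >= 1,
            cfg$wavelength_step > 0)
  if (length(cfg$family_sizes) != cfg$n_founders)
    stop("family_sizes must have one entry per founder")
  if (any(cfg$family_sizes < 1))
    stop("family_sizes must be positive")
  if (cfg$n_both + cfg$n_t1_only + cfg$n_t2_only > sum(cfg$family_sizes))
    stop("crossing-design counts exceed the number of pollinators")
  if (!all(c("location", "year") %in% names(cfg$environments)) ||
      nrow(cfg$environments) < 1)
    stop("environments must be a data.frame with location and year")
  if (cfg$replicate_fraction < 0 || cfg$replicate_fraction > 1)
    stop("replicate_fraction must lie in [0, 1]")
  vars <- c("var_env", "var_year", "var_loc", "var_gxe", "var_row",
            "var_col", "var_resid")
  if (any(unlist(cfg[vars]) < 0)) stop("variance components must be >= 0")
  if (is.null(names(cfg$h2_targets)) || any(names(cfg$h2_targets) == ""))
    stop("h2_targets must be a named vector")
  if (any(cfg$h2_targets <= 0 | cfg$h2_targets > 1))
    stop("h2_targets must lie in (0, 1]")
  if (cfg$founder_freq_range[1] <= 0 || cfg$founder_freq_range[2] >= 1 ||
      diff(cfg$founder_freq_range) < 0)
    stop("founder_freq_range must be within (0, 1)")
  if (cfg$spectral_loading_rank > cfg$n_wavelengths)
    stop("spectral_loading_rank cannot exceed the wavelength count")
  if (cfg$plot_drop_fraction < 0 || cfg$plot_drop_fraction >= 1)
    stop("plot_drop_fraction must lie in [0, 1)")
  invisible(cfg)
}

#' Wavelength grid of a configuration
#' @param config a \code{sim_config}.
#' @return numeric vector of wavelengths (nm), strictly increasing.
#' @export
wavelength_grid <- function(config) {
  config$wavelength_start +
    (seq_len(config$n_wavelengths) - 1) * config$wavelength_step
}

# Derive a reproducible per-stage RNG state from the master seed, so that
# each generator is bit-reproducible on its own and stages do not share a
# stream. Offsets are fixed constants per stage name.
stage_seed <- function(config, stage) {
  offsets <- c(parents = 11L, pollinators = 23L, crossing = 37L,
               architecture = 53L, trial = 71L, nirs = 89L,
               checks = 101L, drop = 113L)
  off <- offsets[[stage]]
  set.seed((as.integer(config$seed) %% 1000000L) * 1009L + off)
  invisible(NULL)
}
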