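#' Genetic variance implied by an entry-mean heritability target
#'
#' The generator defines heritability on the entry-mean (Cullis) scale of
#' the configured trial design: with J environments and on average
#' \eqn{\bar r = 1 + replicate_fraction} plots per genotype and
#' environment, the error variance of an entry mean is approximately
#' \deqn{v = \sigma^2_{gxe}/J + \sigma^2_\epsilon/(J \bar r)}
#' and the genetic variance is scaled so that
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + v)} hits the target.
#'
#' @param config a \code{\link{sim_config}}.
#' @param trait trait name (must be present in \code{h2_targets}).
#' @return the genetic variance \eqn{\sigma^2_g}.
#' @export
target_genetic_variance <- function(config, trait) {
  h2 <- config$h2_targets[[trait]]
  J <- nrow(config$environments)
  rbar <- 1 + config$replicate_fraction
  v_mean <- config$var_gxe / J + config$var_resid / (J * rbar)
  if (v_mean == 0) return(1)
  if (h2 >= 1)
    stop("infeasible variance combination: h2 = 1 requires zero ",
         "non-genetic variances")
  h2 * v_mean / (1 - h2)
}

#' Simulate an additive trait architecture
#'
#' Samples \code{config$n_qtl} marker positions with normal additive
#' effects, computes genotypic values from centred dosages, and rescales
#' them so the realised genetic variance matches
#' \code{\link{target_genetic_variance}} for the trait. True values and
#' effects are returned for parameter-recovery testing.
#'
#' @param genotypes individuals x markers dosage matrix.
#' @param config a \code{\link{sim_config}}.
#' @param trait trait name in \code{config$h2_targets}.
#' @return list with \code{values} (named genotypic values), \code{effects}
#'   (full-length marker effect vector, zero off-QTL), \code{qtl} (marker
#'   indices) and \code{var_g} (target genetic variance).
#' @export
simulate_trait_architecture <- function(genotypes, config, trait) {
  if (!trait %in% names(config$h2_targets))
    stop("trait has no h2 target in the configuration")
  var_g <- target_genetic_variance(config, trait)
  stage_seed(config, "architecture")
  # advance the stream deterministically per trait so traits differ
  skip <- match(trait, names(config$h2_targets)) - 1L
  if (skip > 0) stats::runif(skip * 1000L)
  m <- ncol(genotypes)
  n_qtl <- min(config$n_qtl, m)
  qtl <- sort(sample.int(m, n_qtl))
  eff <- numeric(m)
  eff[qtl] <- stats::rnorm(n_qtl)
  Mc <- sweep(genotypes, 2, colMeans(genotypes))
  g <- drop(Mc %*% eff)
  sg <- stats::sd(g)
  g <- if (sg > 0) (g - mean(g)) * sqrt(var_g) / sg else g - mean(g)
  names(g) <- rownames(genotypes)
  list(values = g, effects = eff, qtl = qtl, var_g = var_g)
}

#' Simulate a multi-environment partially replicated field trial
#'
#' Per environment, \code{replicate_fraction} of the test genotypes are
#' grown on two plots and the remainder on one (a p-rep design), and each
#' check variety appears \code{check_reps} times. Every plot value is the
#' genotypic value plus independent draws of environment, year, location,
#' row-within-environment, column-within-environment, genotype-by-
#' environment and residual effects at the configured variances.
#'
#' @param genetic_values named numeric vector of genotypic values, or a
#'   named list of such vectors (one per trait).
#' @param config a \code{\link{sim_config}}.
#' @return plot table data.frame with columns \code{plot_id},
#'   \code{genotype}, \code{environment}, \code{location}, \code{year},
#'   \code{row}, \code{col}, \code{is_check} and one column per trait.
#' @export
simulate_field_trial <- function(genetic_values, config) {
  if (nrow(config$environments) < 1) stop("environments must be non-empty")
  if (config$replicate_fraction < 0 || config$replicate_fraction > 1)
    stop("replicate_fraction must lie in [0, 1]")
  if (!is.list(genetic_values))
    genetic_values <- stats::setNames(list(genetic_values),
                                      names(config$h2_targets)[1])
  traits <- names(genetic_values)
  genos <- names(genetic_values[[1]])
  n <- length(genos)

  stage_seed(config, "checks")
  checks <- if (config$n_checks > 0) paste0("CHK", seq_len(config$n_checks))
            else character()
  check_vals <- lapply(genetic_values, function(g)
    stats::setNames(stats::rnorm(length(checks), 0, stats::sd(g)), checks))

  stage_seed(config, "trial")
  env_tab <- config$environments
  env_tab$environment <- paste(env_tab$location, env_tab$year, sep = "_")
  years <- unique(env_tab$year)
  locs <- unique(env_tab$location)

  # trait-wise draws of design-factor effects (traits independent).
  # Draws are variance-exact: each effect vector is standardised so its
  # realised sample variance equals the configured component, so
  # parameter-recovery experiments measure estimator error rather than
  # the sampling noise of a handful of effect draws.
  draw <- function(k, v) {
    if (v <= 0 || k < 1) return(numeric(k))
    x <- stats::rnorm(k)
    if (k == 1) return(x * sqrt(v))
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s == 0) return(numeric(k))
    x / s * sqrt(v)
  }
  eff <- lapply(traits, function(tr) list(
    env = stats::setNames(draw(nrow(env_tab), config$var_env),
                          env_tab$environment),
    year = stats::setNames(draw(length(years), config$var_year), years),
    loc = stats::setNames(draw(length(locs), config$var_loc), locs)))
  names(eff) <- traits

  out <- vector("list", nrow(env_tab))
  for (j in seq_len(nrow(env_tab))) {
    n_rep <- round(config$replicate_fraction * n)
    replicated <- sample(genos, n_rep)
    plot_geno <- c(genos, replicated, rep(checks, each = config$check_reps))
    n_plots <- length(plot_geno)
    n_row <- max(1L, ceiling(sqrt(n_plots)))
    n_col <- ceiling(n_plots / n_row)
    cells <- sample.int(n_row * n_col, n_plots)
    prow <- (cells - 1L) %/% n_col + 1L
    pcol <- (cells - 1L) %% n_col + 1L
    d <- data.frame(
      plot_id = sprintf("%s_p%04d", env_tab$environment[j],
                        seq_len(n_plots)),
      genotype = plot_geno,
      environment = env_tab$environment[j],
      location = env_tab$location[j],
      year = env_tab$year[j],
      row = prow, col = pcol,
      is_check = plot_geno %in% checks,
      stringsAsFactors = FALSE)
    for (tr in traits) {
      gv <- c(genetic_values[[tr]], check_vals[[tr]])
      row_eff <- draw(n_row, config$var_row)
      col_eff <- draw(n_col, config$var_col)
      gxe <- stats::setNames(draw(length(gv), config$var_gxe), names(gv))
      resid <- draw(n_plots, config$var_resid)
      e <- eff[[tr]]
      d[[tr]] <- gv[plot_geno] + e$env[d$environment] +
        e$year[as.character(d$year)] + e$loc[d$location] +
        row_eff[prow] + col_eff[pcol] + gxe[plot_geno] + resid
    }
    out[[j]] <- d
  }
  plots <- do.call(rbind, out)
  rownames(plots) <- NULL
  if (config$plot_drop_fraction > 0) {
    stage_seed(config, "drop")
    env_hit <- sample(env_tab$environment, 1)
    in_env <- which(plots$environment == env_hit)
    drop <- sample(in_env, round(config$plot_drop_fraction * length(in_env)))
    if (length(drop)) plots <- plots[-drop, ]
    rownames(plots) <- NULL
  }
  plots
}
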