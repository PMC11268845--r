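#' Run the full simulation-to-evaluation pipeline
#'
#' Chains simulation, entry-mean adjustment of trait and spectra,
#' spectral preprocessing, kinship construction, cross-validated
#' prediction and selection-accuracy evaluation for one scenario, writing
#' every intermediate artefact plus a provenance log to \code{out_dir}.
#'
#' Scenarios: \describe{
#'   \item{within-generation}{hybrid spectra adjusted across all
#'     environments with the full model; random cross-validation.}
#'   \item{single-location}{hybrid spectra from one location only,
#'     adjusted with the reduced model (no environment/location terms);
#'     random cross-validation. Traits are still adjusted across all
#'     environments.}
#'   \item{familywise}{as within-generation but with leave-one-subfamily-
#'     out cross-validation.}
#'   \item{across-generation}{spectra simulated on the pollinators grown
#'     in a single location, adjusted with the reduced model and linked
#'     to the hybrids through the pedigree.}
#' }
#'
#' @param config a \code{\link{sim_config}}; its seed drives every
#'   stochastic stage.
#' @param scenario one of the four scenario tags above.
#' @param out_dir output directory (created if needed); NULL skips
#'   writing.
#' @param trait trait to predict (default: first configured trait).
#' @param models,predictor_sets forwarded to \code{\link{run_cv}}.
#' @param n_runs random cross-validation runs.
#' @param nirs_location location whose spectra are used in the
#'   single-location scenario (default: first configured location).
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param selection_k selection sizes for the Czekanowski evaluation
#'   (entries larger than the population are dropped).
#' @param chain chain settings for Bayesian models.
#' @return list with the simulated population, adjusted means,
#'   heritability, W, cross-validation result, selection accuracies and
#'   the provenance record.
#' @export
run_pipeline <- function(config = sim_config(),
                         scenario = c("within-generation",
                                      "single-location", "familywise",
                                      "across-generation"),
                         out_dir = NULL,
                         trait = names(config$h2_targets)[1],
                         models = "gblup",
                         predictor_sets = c("snp", "nirs"),
                         n_runs = 25,
                         nirs_location = NULL,
                         sg_window = 37, sg_polyorder = 2,
                         selection_k = c(80, 40),
                         chain = list(niter = 3000, burnin = 1000,
                                      thin = 5)) {
  scenario <- match.arg(scenario)
  sim <- simulate_population(config, nirs = scenario != "across-generation")

  # trait adjustment across all environments (all scenarios)
  adj <- adjust_trait(sim$plots, trait, model_spec())
  h2 <- heritability(sim$plots, trait, model_spec())
  y <- stats::setNames(adj$means$value, adj$means$genotype)

  # spectra per scenario
  if (scenario == "across-generation") {
    pol_cfg <- config
    pol_cfg$environments <- config$environments[
      config$environments$location == config$environments$location[1], ,
      drop = FALSE]
    pol_cfg$replicate_fraction <- 0
    validate_sim_config(pol_cfg)
    pol_gv <- stats::setNames(
      drop(sweep(sim$pollinators, 2, colMeans(sim$pollinators)) %*%
             sim$architectures[[trait]]$effects),
      rownames(sim$pollinators))
    pol_plots <- simulate_field_trial(pol_gv, pol_cfg)
    pol_nirs <- simulate_nirs(sim$pollinators, pol_plots, pol_cfg,
                              genetic_values = pol_gv)
    plot_sp <- average_technical_replicates(pol_nirs)
    adj_sp <- adjust_spectra(plot_sp, pol_plots,
                             model_spec(reduced = TRUE))
    used_model <- model_spec(reduced = TRUE)
    src_plots <- pol_plots
  } else if (scenario == "single-location") {
    loc <- nirs_location %||% config$environments$location[1]
    keep <- sim$plots$location == loc
    src_plots <- sim$plots[keep, , drop = FALSE]
    sp_keep <- sim$nirs$info$plot_id %in% src_plots$plot_id
    plot_sp <- average_technical_replicates(sim$nirs[sp_keep])
    used_model <- model_spec(reduced = TRUE)
    adj_sp <- adjust_spectra(plot_sp, src_plots, used_model)
  } else {
    src_plots <- sim$plots
    plot_sp <- average_technical_replicates(sim$nirs)
    used_model <- model_spec()
    adj_sp <- adjust_spectra(plot_sp, src_plots, used_model)
  }
  W <- preprocess_spectra(adj_sp, window = sg_window,
                          polyorder = sg_polyorder)
  if (scenario == "across-generation") {
    # link pollinator profiles to their hybrids through the pedigree
    ped <- sim$pedigree
    ok <- ped$pollinator_id %in% rownames(W)
    Wh <- W[ped$pollinator_id[ok], , drop = FALSE]
    rownames(Wh) <- ped$hybrid_id[ok]
    W <- Wh
  }
  ids <- intersect(names(y), rownames(W))
  y <- y[ids]

  fam <- stats::setNames(sim$pedigree$family, sim$pedigree$hybrid_id)
  tester <- stats::setNames(sim$pedigree$tester_id, sim$pedigree$hybrid_id)
  fixed <- stats::model.matrix(~ tester, data.frame(tester = tester[ids]))
  rownames(fixed) <- ids

  scheme <- if (scenario == "familywise")
    cv_scheme("familywise", families = fam[ids], seed = config$seed)
  else cv_scheme("random", n_runs = n_runs, seed = config$seed)

  cv <- run_cv(y, models = models, predictor_sets = predictor_sets,
               geno = filter_markers(sim$hybrids[ids, , drop = FALSE]),
               W = W[ids, , drop = FALSE], fixed = fixed,
               scheme = scheme, chain = chain)
  ks <- selection_k[selection_k <= length(y)]
  sel <- if (length(ks)) cv_selection_accuracy(cv, ks) else NULL

  provenance <- list(
    package_version = as.character(utils::packageVersion("phenopred")),
    timestamp = format(Sys.time(), tz = "UTC"),
    scenario = scenario, seed = config$seed, trait = trait,
    models = models, predictor_sets = predictor_sets,
    spectra_model_terms = used_model$random,
    sg_window = sg_window, sg_polyorder = sg_polyorder,
    n_hybrids = length(y), n_markers = ncol(sim$hybrids),
    n_wavelengths = ncol(W), cv = unclass(scheme)[c("kind", "n_runs",
                                                    "train_fraction")])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_genotypes(sim$hybrids, p("hybrid_genotypes.tsv"))
    write_pedigree(sim$pedigree, p("pedigree.csv"))
    write_plots(sim$plots, p("plots.csv"))
    write_spectra(plot_sp, p("plot_spectra.csv"))
    write_spectra(adj_sp, p("adjusted_spectra.csv"))
    utils::write.csv(adj$means, p("adjusted_means.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(term = names(h2$varcomp),
                                variance = as.numeric(h2$varcomp)),
                     p("variance_components.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(cv$results, p("cv_results.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(sel))
      utils::write.csv(sel, p("selection_accuracy.csv"),
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(provenance, p("provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(population = sim, adjusted = adj, heritability = h2, W = W,
       cv = cv, selection = sel, provenance = provenance)
}
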