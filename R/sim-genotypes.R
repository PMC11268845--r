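#' Simulate fully homozygous parental genomes
#'
#' Draws per-marker reference (B) allele frequencies from
#' Uniform(\code{founder_freq_range}) and samples one homozygous dosage
#' (0 or 2) per parent and marker. Parents are the founder lines, the
#' common elite line, and the two male-sterile testers.
#'
#' @param config a \code{\link{sim_config}}.
#' @return numeric dosage matrix (rows = parents, columns = markers) with
#'   attribute \code{allele_freq} holding the generative frequencies.
#' @export
simulate_parent_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_markers < 1) stop("n_markers must be positive")
  stage_seed(config, "parents")
  m <- config$n_markers
  p <- stats::runif(m, config$founder_freq_range[1],
                    config$founder_freq_range[2])
  ids <- c(paste0("P", seq_len(config$n_founders)), "L1", "M1", "M2")
  G <- matrix(0, nrow = length(ids), ncol = m,
              dimnames = list(ids, paste0("mk", seq_len(m))))
  for (i in seq_along(ids))
    G[i, ] <- 2 * stats::rbinom(m, 1L, p)
  attr(G, "allele_freq") <- p
  G
}

#' Derive inbred pollinators from founder-by-elite crosses
#'
#' Each pollinator is a fully inbred (doubled-haploid-like) offspring of
#' one founder and the common elite line: the abstract linear genome is cut
#' into \code{config$n_blocks} contiguous marker blocks and every block is
#' inherited intact from one of the two homozygous parents with equal
#' probability. Subfamily label = founder of origin.
#'
#' @param parents parental dosage matrix from
#'   \code{\link{simulate_parent_genomes}}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes} (pollinators x markers dosage
#'   matrix, all entries 0/2) and \code{families} (factor of subfamily
#'   labels, one per pollinator).
#' @export
derive_pollinators <- function(parents, config) {
  stopifnot(inherits(config, "sim_config"))
  founders <- paste0("P", seq_len(config$n_founders))
  if (!all(c(founders, "L1") %in% rownames(parents)))
    stop("parents must contain all founders and the elite line")
  if (length(config$family_sizes) != config$n_founders)
    stop("family_sizes inconsistent with the founder count")
  stage_seed(config, "pollinators")
  m <- ncol(parents)
  n_blocks <- max(1L, min(config$n_blocks, m))
  block <- sort(rep_len(seq_len(n_blocks), m))
  elite <- parents["L1", ]
  n_pol <- sum(config$family_sizes)
  G <- matrix(0, nrow = n_pol, ncol = m,
              dimnames = list(NULL, colnames(parents)))
  fam <- character(n_pol)
  ids <- character(n_pol)
  row <- 0L
  for (k in seq_len(config$n_founders)) {
    fk <- parents[founders[k], ]
    for (j in seq_len(config$family_sizes[k])) {
      row <- row + 1L
      from_founder <- stats::rbinom(n_blocks, 1L, 0.5)[block] == 1L
      G[row, ] <- ifelse(from_founder, fk, elite)
      fam[row] <- founders[k]
      ids[row] <- sprintf("%s_%03d", founders[k], j)
    }
  }
  rownames(G) <- ids
  list(genotypes = G, families = factor(fam, levels = founders))
}

#' Build the tester crossing design
#'
#' Randomly assigns pollinators to the three crossing classes: crossed
#' with both testers, with tester M1 only, or with tester M2 only. With
#' the default counts (159, 46, 46) the design yields 410 test hybrids.
#'
#' @param pollinators character vector of pollinator ids (or a dosage
#'   matrix whose rownames are used).
#' @param config a \code{\link{sim_config}}.
#' @param families optional factor of subfamily labels aligned with
#'   \code{pollinators}; carried into the pedigree when present.
#' @return pedigree data.frame with columns \code{hybrid_id},
#'   \code{pollinator_id}, \code{tester_id}, \code{family}.
#' @export
make_crossing_design <- function(pollinators, config, families = NULL) {
  if (is.matrix(pollinators)) {
    if (is.null(families))
      families <- attr(pollinators, "families")
    pollinators <- rownames(pollinators)
  }
  n <- length(pollinators)
  n_used <- config$n_both + config$n_t1_only + config$n_t2_only
  if (n_used > n)
    stop("crossing-design counts exceed the number of pollinators")
  stage_seed(config, "crossing")
  chosen <- sample(pollinators, n_used)
  both <- chosen[seq_len(config$n_both)]
  t1 <- chosen[config$n_both + seq_len(config$n_t1_only)]
  t2 <- chosen[config$n_both + config$n_t1_only +
                 seq_len(config$n_t2_only)]
  ped <- data.frame(
    pollinator_id = c(both, both, t1, t2),
    tester_id = rep(c("M1", "M2", "M1", "M2"),
                    c(length(both), length(both), length(t1),
                      length(t2))),
    stringsAsFactors = FALSE)
  if (nrow(ped) == 0) stop("crossing design produces no hybrids")
  ped$hybrid_id <- paste(ped$pollinator_id, ped$tester_id, sep = "_x_")
  if (!is.null(families)) {
    names(families) <- pollinators
    ped$family <- as.character(families[ped$pollinator_id])
  } else {
    ped$family <- NA_character_
  }
  ped <- ped[order(ped$hybrid_id),
             c("hybrid_id", "pollinator_id", "tester_id", "family")]
  rownames(ped) <- NULL
  stopifnot(!anyDuplicated(ped$hybrid_id))
  ped
}

#' Deterministic F1 hybrid genotypes from inbred parents
#'
#' Each hybrid dosage is the mean of the two homozygous parental dosages,
#' so hybrids are heterozygous (dosage 1) exactly where pollinator and
#' tester carry different alleles.
#'
#' @param pollinators pollinator dosage matrix (rows named by id).
#' @param testers tester dosage matrix (rows \code{M1}, \code{M2}); the
#'   parent matrix from \code{\link{simulate_parent_genomes}} works.
#' @param pedigree data.frame from \code{\link{make_crossing_design}}.
#' @return hybrids x markers dosage matrix in {0, 1, 2}.
#' @export
synthesize_hybrid_genotypes <- function(pollinators, testers, pedigree) {
  need_p <- unique(pedigree$pollinator_id)
  need_t <- unique(pedigree$tester_id)
  if (!all(need_p %in% rownames(pollinators)))
    stop("pedigree references pollinators absent from the matrix")
  if (!all(need_t %in% rownames(testers)))
    stop("pedigree references testers absent from the matrix")
  if (any(pollinators == 1) || any(testers[need_t, , drop = FALSE] == 1))
    stop("heterozygous parent encountered; parents must be fully inbred")
  H <- (pollinators[pedigree$pollinator_id, , drop = FALSE] +
          testers[pedigree$tester_id, , drop = FALSE]) / 2
  rownames(H) <- pedigree$hybrid_id
  H
}
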