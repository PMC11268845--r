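#' Read a genotype dosage matrix
#'
#' Reads either a TSV dosage matrix (first column \code{id}, one column
#' per marker, \code{NA} for missing calls) or a VCF file (biallelic
#' records; dosage = alternate-allele count, missing calls flagged
#' \code{NA}; records with more than one alternate allele are skipped
#' with a reported count). Missing entries are flagged, never silently
#' imputed.
#'
#' @param path file path (\code{.vcf}/\code{.vcf.gz} triggers the VCF
#'   reader, which requires the vcfR package).
#' @return individuals x markers numeric matrix.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_genotypes_vcf(path))
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(d)[1] != "id") stop("malformed header: first column must be 'id'")
  M <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric dosage entries")
  rownames(M) <- d$id
  M
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    message(sum(multi), " non-biallelic VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  ids <- vcfR::getID(v)[!multi]
  dose <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]))
  }
  M <- t(apply(gt, 2, function(col) vapply(col, dose, numeric(1))))
  colnames(M) <- ids
  M
}

#' Write a genotype dosage matrix as TSV
#' @param genotypes individuals x markers matrix.
#' @param path output path.
#' @export
write_genotypes <- function(genotypes, path) {
  d <- data.frame(id = rownames(genotypes), genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Dosages (0/1/2, NA) become unphased diploid genotype calls on
#' synthetic marker coordinates (one abstract chromosome, consecutive
#' positions).
#'
#' @param genotypes individuals x markers dosage matrix.
#' @param path output path.
#' @export
write_vcf <- function(genotypes, path) {
  gt_of <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    calls <- ifelse(is.na(g), "./.", gt_of[round(g) + 1])
    writeLines(paste(c("1", j, colnames(genotypes)[j], "A", "B", ".",
                       "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a plot table
#'
#' CSV with columns \code{plot_id}, \code{genotype}, \code{environment},
#' \code{location}, \code{year}, \code{row}, \code{col},
#' \code{is_check} and one column per trait. Duplicate plot ids are an
#' error.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_plots <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "genotype", "environment", "location", "year",
            "row", "col", "is_check")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("plot table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$plot_id)) stop("duplicate plot ids")
  d$is_check <- as.logical(d$is_check)
  d
}

#' @rdname read_plots
#' @param plots plot table data.frame.
#' @export
write_plots <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write spectra
#'
#' CSV with metadata columns first (at least \code{sample_id}) followed
#' by one \code{wl_<nm>} column per wavelength. The wavelength header
#' must be strictly increasing and gap-free (a missing mid-grid column is
#' an error).
#'
#' @param path file path.
#' @return a \code{\link{spectra}} object.
#' @export
read_spectra <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE,
                       stringsAsFactors = FALSE)
  is_wl <- grepl("^wl_", names(d))
  wl <- as.numeric(sub("^wl_", "", names(d)[is_wl]))
  if (anyNA(wl) || any(diff(wl) <= 0))
    stop("non-monotone wavelength header")
  steps <- diff(wl)
  if (length(steps) > 1 && max(steps) > 1.5 * min(steps))
    stop("gap in the wavelength grid (missing mid-grid column)")
  info <- d[, !is_wl, drop = FALSE]
  if (!"sample_id" %in% names(info)) stop("spectra need a sample_id column")
  if (anyDuplicated(info$sample_id)) stop("duplicate sample ids")
  V <- as.matrix(d[, is_wl, drop = FALSE])
  rownames(V) <- info$sample_id
  spectra(V, wl, info)
}

#' @rdname read_spectra
#' @param x a \code{spectra} object.
#' @export
write_spectra <- function(x, path) {
  d <- cbind(x$info, as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a pedigree table
#' @param path file path.
#' @return data.frame with hybrid_id, pollinator_id, tester_id, family.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hybrid_id", "pollinator_id", "tester_id", "family")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("pedigree lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$hybrid_id)) stop("duplicate hybrid ids")
  d
}

#' @rdname read_pedigree
#' @param pedigree pedigree data.frame.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a kinship matrix as TSV
#' @param path file path.
#' @return symmetric matrix with id dimnames.
#' @export
read_kinship <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  K <- as.matrix(d[, -1, drop = FALSE])
  rownames(K) <- d$id
  K
}

#' @rdname read_kinship
#' @param K kinship matrix.
#' @export
write_kinship <- function(K, path) {
  d <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#' @param path file path.
#' @return a \code{\link{sim_config}}.
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$environments))
    lst$environments <- as.data.frame(lst$environments,
                                      stringsAsFactors = FALSE)
  if (!is.null(lst$h2_targets)) lst$h2_targets <- unlist(lst$h2_targets)
  do.call(sim_config, lst)
}

#' @rdname read_config
#' @param config a \code{sim_config}.
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$environments <- as.list(lst$environments)
  lst$h2_targets <- as.list(lst$h2_targets)
  yaml::write_yaml(lst, path)
  invisible(path)
}
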