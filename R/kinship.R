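#' Marker quality-control filter
#'
#' Removes markers with more than \code{max_missing} missing calls, with
#' dosages outside {0, 1, 2} (treated as non-biallelic), or with expected
#' heterozygosity \eqn{2p(1-p)} below \code{min_expected_het} (boundary
#' inclusive: a marker at exactly the threshold is retained). Remaining
#' missing entries are imputed by the marker mean.
#'
#' @param genotypes individuals x markers dosage matrix, \code{NA} for
#'   missing calls.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param min_expected_het minimum expected heterozygosity (default
#'   0.095).
#' @return filtered, imputed dosage matrix; attribute \code{filter_report}
#'   lists counts of markers removed per rule.
#' @export
filter_markers <- function(genotypes, max_missing = 0.10,
                           min_expected_het = 0.095) {
  M <- as.matrix(genotypes)
  miss_frac <- colMeans(is.na(M))
  bad_allele <- apply(M, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && any(!v %in% c(0, 1, 2))
  })
  p <- colMeans(M, na.rm = TRUE) / 2
  ehet <- 2 * p * (1 - p)
  rm_missing <- miss_frac > max_missing
  rm_het <- !rm_missing & !bad_allele &
    (is.na(ehet) | ehet < min_expected_het)
  keep <- !(rm_missing | bad_allele | rm_het)
  if (!any(keep)) stop("all markers removed by filtering")
  out <- M[, keep, drop = FALSE]
  # marker-mean imputation of remaining missing calls
  if (anyNA(out)) {
    mu <- colMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- mu[idx[, 2]]
  }
  attr(out, "filter_report") <- list(
    n_input = ncol(M), n_kept = ncol(out),
    removed_missing = sum(rm_missing),
    removed_non_biallelic = sum(bad_allele & !rm_missing),
    removed_low_het = sum(rm_het))
  out
}

#' VanRaden additive genomic relationship matrix
#'
#' \deqn{G_a = Z Z' / (2 \sum_i p_i (1 - p_i))}
#' where Z contains allele-frequency-centred dosages (entries
#' \eqn{-2p_i}, \eqn{1-2p_i}, \eqn{2-2p_i} for dosages 0/1/2) and
#' \eqn{p_i} is the B-allele frequency of marker i.
#'
#' @param genotypes individuals x markers dosage matrix (no missing
#'   values; post-imputation reals allowed).
#' @param allele_freqs optional vector of B-allele frequencies; by default
#'   computed from the supplied individuals (typically the union of
#'   training and test sets so a single G serves every split).
#' @return symmetric relationship matrix with a \code{kind} attribute.
#' @export
vanraden_grm <- function(genotypes, allele_freqs = NULL) {
  M <- as.matrix(genotypes)
  if (anyNA(M)) stop("missing dosages; run filter_markers first")
  p <- allele_freqs %||% (colMeans(M) / 2)
  if (any(p <= 0 | p >= 1))
    stop("allele frequencies at 0 or 1; filter monomorphic markers first")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "kind") <- "additive-genomic"
  G
}

#' NIRS-based relationship matrix
#'
#' \deqn{G_{NIRS} = W W' / l} for the centred and scaled spectral
#' predictor matrix W with l wavelength columns.
#'
#' @param W preprocessed spectra matrix (genotypes x wavelengths), e.g.
#'   from \code{\link{preprocess_spectra}}.
#' @return symmetric relationship matrix with a \code{kind} attribute.
#' @export
nirs_relationship <- function(W) {
  W <- as.matrix(W)
  if (ncol(W) == 0) stop("W has no wavelength columns")
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(rownames(W), rownames(W))
  attr(G, "kind") <- "nirs"
  G
}

#' Gaussian kernel matrices over a bandwidth grid
#'
#' Computes pairwise squared Euclidean distances between individuals,
#' normalises them by their mean off-diagonal value (so the bandwidth grid
#' is scale-free regardless of the feature dimension), and returns
#' \eqn{K_h = \exp(-h \cdot D^2_{norm})} for every bandwidth h. These are
#' the kernels averaged by the RKHS model.
#'
#' @param features individuals x features numeric matrix (dosages or
#'   preprocessed spectra).
#' @param bandwidths positive bandwidth values (default 0.1, 0.5, 2.5).
#' @param normalize divide D^2 by its mean off-diagonal value (default
#'   TRUE).
#' @return named list of kernel matrices (diagonal exactly 1).
#' @export
gaussian_kernels <- function(features, bandwidths = c(0.1, 0.5, 2.5),
                             normalize = TRUE) {
  X <- as.matrix(features)
  if (nrow(X) < 2) stop("kernels need at least two individuals")
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  D2 <- as.matrix(stats::dist(X))^2
  if (normalize) {
    q <- mean(D2[upper.tri(D2)])
    if (q > 0) D2 <- D2 / q
  }
  out <- lapply(bandwidths, function(h) {
    K <- exp(-h * D2)
    diag(K) <- 1
    dimnames(K) <- list(rownames(X), rownames(X))
    attr(K, "kind") <- "gaussian-kernel"
    attr(K, "bandwidth") <- h
    K
  })
  names(out) <- paste0("h", bandwidths)
  out
}

#' Repair a nearly positive semi-definite matrix
#'
#' Adds escalating jitter to the diagonal until the smallest eigenvalue is
#' no smaller than -1e-8.
#'
#' @param K symmetric matrix.
#' @param jitter initial diagonal jitter (multiplied by 10 per escalation,
#'   at most 6 times).
#' @return repaired matrix; attribute \code{jitter} records the total
#'   jitter applied (0 if none was needed).
#' @export
ensure_psd <- function(K, jitter = 1e-6) {
  if (max(abs(K - t(K))) > 1e-10) stop("matrix is not symmetric")
  applied <- 0
  j <- jitter
  for (step in 0:6) {
    ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min >= -1e-8) {
      attr(K, "jitter") <- applied
      return(K)
    }
    if (step == 6) break
    K <- K + diag(j, nrow(K))
    applied <- applied + j
    j <- j * 10
  }
  stop("matrix not positive semi-definite after 6 jitter escalations")
}
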