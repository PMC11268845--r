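#' Cross-validation scheme
#'
#' Random scheme: repeated 80/20 splits of the population (training size
#' = floor(fraction * n)). Familywise scheme: each subfamily serves as the
#' test set exactly once, with the remaining families as training set.
#'
#' @param kind \code{"random"} or \code{"familywise"}.
#' @param n_runs number of random splits (default 200).
#' @param train_fraction training fraction for random splits.
#' @param families named character/factor vector (id -> subfamily),
#'   required for the familywise scheme.
#' @param seed master seed; the split sequence is reproducible from it.
#' @return object of class \code{cv_scheme}.
#' @export
cv_scheme <- function(kind = c("random", "familywise"), n_runs = 200,
                      train_fraction = 0.8, families = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "familywise" && is.null(families))
    stop("familywise cross-validation needs family labels")
  structure(list(kind = kind, n_runs = n_runs,
                 train_fraction = train_fraction, families = families,
                 seed = seed), class = "cv_scheme")
}

cv_splits <- function(scheme, ids) {
  if (scheme$kind == "random") {
    set.seed(as.integer(scheme$seed))
    n_train <- floor(scheme$train_fraction * length(ids))
    lapply(seq_len(scheme$n_runs), function(r) {
      train <- sample(ids, n_train)
      list(label = as.character(r), train = train,
           test = setdiff(ids, train))
    })
  } else {
    fam <- scheme$families
    missing <- setdiff(ids, names(fam))
    if (length(missing))
      stop("family label missing for: ", paste(head(missing, 3),
                                               collapse = ", "))
    fam <- fam[ids]
    lapply(sort(unique(as.character(fam))), function(f) {
      list(label = f, train = ids[fam != f], test = ids[fam == f])
    })
  }
}

#' Pearson prediction accuracy
#'
#' Pearson correlation between observed and predicted values. Pairs with
#' undefined variance (a constant vector) yield \code{NA} with a warning
#' rather than zero.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return correlation coefficient r, or \code{NA}.
#' @export
pearson_accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(observed[ok]) == 0 || stats::sd(predicted[ok]) == 0) {
    warning("constant vector; accuracy undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(observed[ok], predicted[ok])
}

#' Select the top k individuals
#'
#' Ids of the k largest values; ties at the selection boundary are broken
#' deterministically by lexicographic id order.
#'
#' @param values named numeric vector.
#' @param k selection size (1 <= k <= length(values)).
#' @return character vector of k selected ids.
#' @export
select_top_k <- function(values, k) {
  if (k <= 0) stop("k must be positive")
  if (k > length(values)) stop("k exceeds the population size")
  ord <- order(-values, names(values), method = "radix")
  names(values)[ord][seq_len(k)]
}

#' Czekanowski coefficient of selection similarity
#'
#' \deqn{CZ = 2a / (2a + b + c)} where a is the number of correctly
#' selected, b of wrongly selected and c of wrongly discarded genotypes.
#'
#' @param a,b,c non-negative counts.
#' @return CZ in [0, 1].
#' @examples
#' czekanowski(28, 52, 52)  # 0.35
#' czekanowski(35, 45, 45)  # 0.4375
#' @export
czekanowski <- function(a, b, c) {
  if (a < 0 || b < 0 || c < 0) stop("counts must be non-negative")
  if (2 * a + b + c == 0) stop("CZ undefined for all-zero counts")
  2 * a / (2 * a + b + c)
}

#' Classify a fixed-size selection against the true top set
#'
#' Partitions the population into correctly selected (a), wrongly
#' selected (b), wrongly discarded (c) and correctly discarded (d)
#' genotypes and attaches the Czekanowski coefficient.
#'
#' @param predicted_top ids selected on predicted performance.
#' @param actual_top ids selected on observed performance (same size).
#' @param ids all population ids.
#' @return data.frame with k, a, b, c, d and CZ.
#' @export
classify_selection <- function(predicted_top, actual_top, ids) {
  if (length(predicted_top) != length(actual_top))
    stop("selection sets must have equal size")
  if (!all(predicted_top %in% ids) || !all(actual_top %in% ids))
    stop("selection sets must be subsets of the population ids")
  a <- length(intersect(predicted_top, actual_top))
  b <- length(setdiff(predicted_top, actual_top))
  c <- length(setdiff(actual_top, predicted_top))
  d <- length(ids) - a - b - c
  data.frame(k = length(predicted_top), a = a, b = b, c = c, d = d,
             CZ = czekanowski(a, b, c))
}

#' Selection accuracy of predicted values
#'
#' Convenience wrapper: selects the top k by observed and by predicted
#' values (predictions typically averaged over all cross-validation runs)
#' and classifies the outcome.
#'
#' @param observed,predicted named numeric vectors over the same ids.
#' @param k selection size (e.g. 80 and 40, about 20\% and 10\% of a
#'   399-hybrid population).
#' @return data.frame as in \code{\link{classify_selection}}.
#' @export
evaluate_selection <- function(observed, predicted, k) {
  ids <- names(observed)
  predicted <- predicted[ids]
  classify_selection(select_top_k(predicted, k),
                     select_top_k(observed, k), ids)
}

#' Principal components of population structure
#'
#' Column-centred PCA of genotype dosages or adjusted spectra; the first
#' three components are the standard visualisation of subfamily
#' structure.
#'
#' @param x individuals x features numeric matrix.
#' @param n_components number of components to return (default 3).
#' @return list with \code{scores} (individuals x components) and
#'   \code{explained} (non-increasing variance fractions).
#' @export
pca_structure <- function(x, n_components = 3) {
  x <- as.matrix(x)
  if (nrow(x) < n_components)
    stop("fewer individuals than requested components")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
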