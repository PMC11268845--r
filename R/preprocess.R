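#' Average technical replicates of plot spectra
#'
#' Arithmetic mean per plot and wavelength over the technical replicates.
#'
#' @param plot_spectra \code{\link{spectra}} with \code{plot_id} and
#'   \code{replicate} columns in its metadata.
#' @return \code{spectra} with one row per plot; the replicate count per
#'   plot is recorded in the metadata column \code{n_replicates}.
#' @export
average_technical_replicates <- function(plot_spectra) {
  info <- plot_spectra$info
  if (!"plot_id" %in% names(info))
    stop("spectra metadata must contain plot_id")
  f <- factor(info$plot_id, levels = unique(info$plot_id))
  counts <- table(f)
  if (any(counts == 0)) stop("plot with zero replicates")
  V <- rowsum(plot_spectra$values, f, reorder = FALSE) /
    as.integer(counts)
  first <- !duplicated(info$plot_id)
  meta <- info[first, setdiff(names(info), c("replicate", "sample_id")),
               drop = FALSE]
  meta$sample_id <- meta$plot_id
  meta$n_replicates <- as.integer(counts)
  rownames(V) <- meta$plot_id
  rownames(meta) <- NULL
  spectra(V, plot_spectra$wavelengths, meta)
}

#' Savitzky-Golay first derivative of spectra
#'
#' Computes, per sample, the first derivative by local least-squares
#' polynomial fitting over a sliding window (Savitzky-Golay). Only
#' interior points with a full window are returned: (window - 1)/2 points
#' are trimmed from each edge and the wavelength grid is trimmed
#' accordingly. The derivative is expressed per unit of wavelength (nm).
#'
#' @param x a \code{\link{spectra}} object.
#' @param window odd window size in points (default 37).
#' @param polyorder order of the local polynomial fit (default 2); the
#'   derivative is exact for polynomial profiles up to this degree.
#' @return trimmed derivative \code{spectra}.
#' @export
savitzky_golay_derivative <- function(x, window = 37, polyorder = 2) {
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("window must exceed the polynomial order")
  if (polyorder < 1) stop("a first derivative needs polyorder >= 1")
  L <- length(x$wavelengths)
  if (L < window) stop("window exceeds the wavelength count")
  step <- x$wavelengths[2] - x$wavelengths[1]
  if (max(abs(diff(x$wavelengths) - step)) > 1e-8 * step)
    stop("Savitzky-Golay requires a uniform wavelength grid")
  co <- signal::sgolay(p = polyorder, n = window, m = 1)
  central <- as.numeric(co[(window + 1) / 2, ])
  h <- (window - 1) / 2
  out_idx <- (h + 1):(L - h)
  # band matrix D so that derivative = values %*% D (per index step)
  D <- matrix(0, nrow = L, ncol = length(out_idx))
  for (j in seq_along(out_idx))
    D[(out_idx[j] - h):(out_idx[j] + h), j] <- central
  V <- (x$values %*% D) / step
  rownames(V) <- rownames(x$values)
  spectra(V, x$wavelengths[out_idx], x$info)
}

#' Centre and scale spectra columns
#'
#' Standardises every wavelength column to mean 0 and sample standard
#' deviation 1, yielding the predictor matrix W used by the NIRS
#' relationship matrix and the spectra-based prediction models. Constant
#' columns cannot be scaled; they are dropped with a warning and recorded
#' in the attribute \code{dropped_wavelengths}.
#'
#' @param x a \code{\link{spectra}} object with at least 2 rows.
#' @return standardised \code{spectra}; attribute
#'   \code{dropped_wavelengths} lists removed grid points (if any).
#' @export
center_scale <- function(x) {
  if (nrow(x$values) < 2) stop("centring and scaling needs >= 2 samples")
  sds <- apply(x$values, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant wavelength column(s) dropped")
  V <- scale(x$values[, !const, drop = FALSE])
  attr(V, "scaled:center") <- NULL
  attr(V, "scaled:scale") <- NULL
  out <- spectra(V, x$wavelengths[!const], x$info)
  attr(out, "dropped_wavelengths") <- x$wavelengths[const]
  out
}

#' Full spectral preprocessing chain
#'
#' Savitzky-Golay first derivative followed by centring and scaling,
#' applied to genotype-level adjusted spectra; returns the matrix W.
#'
#' @param adjusted_spectra genotype-level \code{\link{spectra}} from
#'   \code{\link{adjust_spectra}}.
#' @inheritParams savitzky_golay_derivative
#' @return numeric matrix W (genotypes x trimmed wavelengths) with the
#'   trimmed grid in attribute \code{wavelengths}.
#' @export
preprocess_spectra <- function(adjusted_spectra, window = 37,
                               polyorder = 2) {
  d <- savitzky_golay_derivative(adjusted_spectra, window, polyorder)
  s <- center_scale(d)
  W <- s$values
  rn <- if ("genotype" %in% names(s$info)) s$info$genotype
        else rownames(s$values)
  rownames(W) <- rn
  attr(W, "wavelengths") <- s$wavelengths
  W
}
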