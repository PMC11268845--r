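#' Spectra container
#'
#' Lightweight container pairing a samples x wavelengths value matrix with
#' its wavelength grid and per-sample metadata.
#'
#' @param values numeric matrix, one row per sample.
#' @param wavelengths strictly increasing numeric grid (nm), length equal
#'   to \code{ncol(values)}.
#' @param info data.frame of per-sample metadata (e.g. \code{sample_id},
#'   \code{plot_id}, \code{replicate}, \code{genotype},
#'   \code{environment}), one row per sample.
#' @return object of class \code{spectra}.
#' @export
spectra <- function(values, wavelengths, info = NULL) {
  values <- as.matrix(values)
  if (length(wavelengths) != ncol(values))
    stop("wavelength grid length must match the number of columns")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (is.null(info))
    info <- data.frame(sample_id = rownames(values) %||%
                         paste0("s", seq_len(nrow(values))))
  if (nrow(info) != nrow(values))
    stop("info must have one row per sample")
  colnames(values) <- paste0("wl_", format(wavelengths, trim = TRUE,
                                           scientific = FALSE))
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 info = info), class = "spectra")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("spectra: %d samples x %d wavelengths (%g-%g nm)\n",
              nrow(x$values), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat("info columns:", paste(names(x$info), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra <- function(x) dim(x$values)

#' Subset a spectra object by sample
#' @param x a \code{spectra} object.
#' @param i row (sample) index.
#' @param ... ignored.
#' @export
`[.spectra` <- function(x, i, ...) {
  spectra(x$values[i, , drop = FALSE], x$wavelengths,
          x$info[i, , drop = FALSE])
}
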