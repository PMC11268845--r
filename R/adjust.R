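#' Mixed-model specification for entry-mean adjustment
#'
#' The full adjustment model treats the overall mean and genotype as fixed
#' and environment, row-within-environment, column-within-environment,
#' year, location and genotype-by-environment as random, with an
#' independent residual. The reduced model (used for spectra from a single
#' location and for parental spectra) omits the environment, location and
#' interaction terms and nests rows and columns within year.
#'
#' @param random character vector of random terms, a subset of
#'   \code{c("environment", "row", "column", "year", "location", "gxe")}.
#' @param reduced logical; if TRUE use the reduced single-location model
#'   \code{c("year", "row", "column")}.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(random = c("environment", "row", "column", "year",
                                  "location", "gxe"),
                       reduced = FALSE) {
  if (reduced) random <- c("year", "row", "column")
  allowed <- c("environment", "row", "column", "year", "location", "gxe")
  bad <- setdiff(random, allowed)
  if (length(bad)) stop("unknown random terms: ", paste(bad, collapse = ", "))
  structure(list(random = random, reduced = reduced), class = "model_spec")
}

# Assemble the factors of the adjustment model from a plot table,
# dropping terms that are inestimable (fewer than 2 levels).
build_adjust_factors <- function(plots, spec) {
  terms <- spec$random
  nest <- if ("environment" %in% terms) factor(plots$environment)
          else if ("year" %in% terms) factor(plots$year)
          else NULL
  fac <- list()
  if ("environment" %in% terms) fac$env <- factor(plots$environment)
  if ("year" %in% terms) fac$year <- factor(plots$year)
  if ("location" %in% terms) fac$location <- factor(plots$location)
  if ("row" %in% terms)
    fac$row <- if (is.null(nest)) factor(plots$row)
               else interaction(nest, plots$row, drop = TRUE, lex.order = TRUE)
  if ("column" %in% terms)
    fac$column <- if (is.null(nest)) factor(plots$col)
                  else interaction(nest, plots$col, drop = TRUE,
                                   lex.order = TRUE)
  if ("gxe" %in% terms)
    fac$gxe <- interaction(factor(plots$genotype),
                           factor(plots$environment), drop = TRUE)
  # terms with fewer than 2 levels are inestimable; terms with one level
  # per observation are confounded with the residual
  n <- nrow(plots)
  keep <- vapply(fac, function(f) nlevels(f) >= 2 && nlevels(f) < n,
                 logical(1))
  fac[keep]
}

lmer_blue_control <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    calc.derivs = FALSE)
}

fit_blue_model <- function(y, genotype, factors) {
  # a saturated genotype model leaves no information for random terms
  if (nlevels(genotype) >= length(y)) factors <- list()
  dat <- data.frame(.y = y, genotype = genotype)
  for (nm in names(factors)) dat[[nm]] <- factors[[nm]]
  if (length(factors) > 0) {
    rhs <- paste(c("0 + genotype",
                   sprintf("(1 | %s)", names(factors))), collapse = " + ")
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(stats::as.formula(paste(".y ~", rhs)), data = dat,
                   REML = TRUE, control = lmer_blue_control()))),
      error = function(e) NULL)
    if (!is.null(fit)) return(list(fit = fit, kind = "lmer", data = dat))
  }
  list(fit = stats::lm(.y ~ 0 + genotype, data = dat),
       kind = "lm", data = dat)
}

blue_values <- function(fit, kind) {
  b <- if (kind == "lmer") lme4::fixef(fit) else stats::coef(fit)
  stats::setNames(as.numeric(b), sub("^genotype", "", names(b)))
}

blue_varcomp <- function(fit, kind) {
  if (kind == "lm") {
    s2 <- summary(fit)$sigma^2
    return(c(residual = if (is.finite(s2)) s2 else 0))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- stats::setNames(vc$vcov, vc$grp)
  names(out)[names(out) == "Residual"] <- "residual"
  out
}

# Mean variance of a pairwise difference of adjusted means from the
# fixed-effect covariance matrix C (restricted to the genotypes kept).
# Exact over all pairs for <= max_exact genotypes, else from sampled pairs.
vdblue_from_vcov <- function(C, max_exact = 1000, n_pairs = 10000) {
  g <- nrow(C)
  if (g < 2) return(0)
  if (g <= max_exact) {
    d <- diag(C)
    (2 * (g - 1) * sum(d) - 2 * (sum(C) - sum(d))) / (g * (g - 1))
  } else {
    i <- sample.int(g, n_pairs, replace = TRUE)
    j <- sample.int(g, n_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    mean(diag(C)[i] + diag(C)[j] - 2 * C[cbind(i, j)])
  }
}

#' Adjusted entry means (BLUEs) for a trait
#'
#' Fits the adjustment model with genotype fixed and returns one adjusted
#' value (overall mean + genotype effect) per non-check genotype. Check
#' varieties participate in the fit, stabilising the field-effect
#' estimates, but are dropped from the output.
#'
#' @param plots plot table (see \code{\link{simulate_field_trial}}); rows
#'   with a missing trait value are excluded.
#' @param trait name of the trait column.
#' @param spec a \code{\link{model_spec}}.
#' @return object of class \code{adjusted_means}: data.frame
#'   \code{means} (genotype, value, se), \code{vdblue} (mean variance of a
#'   pairwise BLUE difference), \code{varcomp}, \code{n_obs}.
#' @export
adjust_trait <- function(plots, trait, spec = model_spec()) {
  if (!trait %in% names(plots)) stop("trait column not found: ", trait)
  keep <- !is.na(plots[[trait]])
  plots <- plots[keep, , drop = FALSE]
  if (nrow(plots) == 0) stop("no observations for trait ", trait)
  genotype <- factor(plots$genotype)
  fac <- build_adjust_factors(plots, spec)
  m <- fit_blue_model(plots[[trait]], genotype, fac)
  vals <- blue_values(m$fit, m$kind)
  C <- as.matrix(stats::vcov(m$fit))
  rownames(C) <- colnames(C) <- sub("^genotype", "", rownames(C))
  is_check <- if ("is_check" %in% names(plots)) {
    chk <- unique(plots$genotype[plots$is_check])
    names(vals) %in% chk
  } else rep(FALSE, length(vals))
  keep_g <- names(vals)[!is_check]
  Ck <- C[keep_g, keep_g, drop = FALSE]
  out <- data.frame(genotype = keep_g, value = as.numeric(vals[keep_g]),
                    se = sqrt(pmax(diag(Ck), 0)), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(means = out, vdblue = vdblue_from_vcov(Ck),
                 varcomp = blue_varcomp(m$fit, m$kind),
                 vcov = Ck, n_obs = nrow(plots), trait = trait),
            class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat(sprintf("adjusted entry means for '%s': %d genotypes from %d plots\n",
              x$trait, nrow(x$means), x$n_obs))
  cat(sprintf("  mean variance of a BLUE difference: %.4g\n", x$vdblue))
  invisible(x)
}

#' Adjust NIR spectra to one profile per genotype
#'
#' Applies the trait-adjustment mixed model independently to every
#' wavelength of plot-level spectra (technical replicates must have been
#' averaged first, see \code{\link{average_technical_replicates}}) and
#' returns the adjusted value (overall mean + genotype effect) per
#' genotype and wavelength: one aggregated profile per genotype. The
#' model structure is factorised once and refitted across wavelengths.
#'
#' @param plot_spectra plot-level \code{\link{spectra}} (one row per plot).
#' @param plots plot table whose \code{plot_id} matches
#'   \code{plot_spectra$info$plot_id}.
#' @param spec a \code{\link{model_spec}}.
#' @param varcomp_mode \code{"per-wavelength"} re-estimates the variance
#'   components at every wavelength (the default); \code{"shared"}
#'   estimates them on \code{shared_n} evenly spaced wavelengths, averages
#'   them, and solves the mixed-model equations for all wavelengths at the
#'   shared estimates.
#' @param shared_n number of calibration wavelengths in shared mode.
#' @return genotype-level \code{spectra} (non-check genotypes only).
#' @export
adjust_spectra <- function(plot_spectra, plots, spec = model_spec(),
                           varcomp_mode = c("per-wavelength", "shared"),
                           shared_n = 50) {
  varcomp_mode <- match.arg(varcomp_mode)
  info <- plot_spectra$info
  if (!"plot_id" %in% names(info))
    stop("plot-level spectra must carry a plot_id column")
  if (anyDuplicated(info$plot_id))
    stop("multiple rows per plot; average technical replicates first")
  idx <- match(info$plot_id, plots$plot_id)
  if (anyNA(idx)) stop("spectra reference plots absent from the plot table")
  pl <- plots[idx, , drop = FALSE]
  genotype <- factor(pl$genotype)
  fac <- build_adjust_factors(pl, spec)
  Y <- plot_spectra$values
  L <- ncol(Y)
  const <- apply(Y, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    warning(sum(const), " constant wavelength column(s) returned as-is")
  glev <- levels(genotype)

  B <- matrix(NA_real_, nrow = length(glev), ncol = L,
              dimnames = list(glev, colnames(Y)))
  todo <- which(!const)
  if (length(todo)) {
    if (length(fac) == 0) {
      # no estimable random term: ordinary least squares, one shared QR
      Xg <- stats::model.matrix(~ 0 + genotype)
      colnames(Xg) <- levels(genotype)
      cf <- stats::lm.fit(Xg, Y[, todo, drop = FALSE])$coefficients
      B[, todo] <- as.matrix(cf)[glev, , drop = FALSE]
    } else if (varcomp_mode == "per-wavelength") {
      first <- todo[1]
      m <- fit_blue_model(Y[, first], genotype, fac)
      B[, first] <- blue_values(m$fit, m$kind)[glev]
      {
        for (j in todo[-1]) {
          fj <- tryCatch(
            suppressMessages(suppressWarnings(
              lme4::refit(m$fit, newresp = Y[, j]))),
            error = function(e) NULL)
          if (is.null(fj))
            fj <- fit_blue_model(Y[, j], genotype, fac)$fit
          B[, j] <- blue_values(fj, "lmer")[glev]
        }
      }
    } else {
      calib <- todo[unique(round(seq(1, length(todo),
                                     length.out = min(shared_n,
                                                      length(todo)))))]
      m <- fit_blue_model(Y[, calib[1]], genotype, fac)
      vcs <- list(blue_varcomp(m$fit, m$kind))
      for (j in calib[-1]) {
        fj <- tryCatch(
          suppressMessages(suppressWarnings(
            lme4::refit(m$fit, newresp = Y[, j]))),
          error = function(e) NULL)
        if (!is.null(fj)) vcs <- c(vcs, list(blue_varcomp(fj, "lmer")))
      }
      vc_names <- names(vcs[[1]])
      vbar <- sapply(vc_names, function(nm)
        mean(vapply(vcs, function(v) v[[nm]], numeric(1))))
      B[, todo] <- mme_blues(Y[, todo, drop = FALSE], genotype, fac, vbar)
    }
  }
  if (any(const)) {
    for (j in which(const)) B[, j] <- Y[1, j]
  }
  chk <- unique(pl$genotype[pl$is_check %||% rep(FALSE, nrow(pl))])
  keep_g <- setdiff(glev, chk)
  spectra(B[keep_g, , drop = FALSE], plot_spectra$wavelengths,
          data.frame(genotype = keep_g, stringsAsFactors = FALSE))
}

# Solve Henderson's mixed-model equations at fixed variance components for
# a multi-column response; returns the genotype BLUEs (mu + g).
mme_blues <- function(Y, genotype, factors, varcomp) {
  X <- Matrix::sparse.model.matrix(~ 0 + genotype)
  colnames(X) <- levels(genotype)
  Zs <- lapply(factors, function(f) {
    Z <- Matrix::sparse.model.matrix(~ 0 + f)
    colnames(Z) <- levels(f)
    Z
  })
  s2e <- varcomp[["residual"]]
  lambdas <- unlist(lapply(names(Zs), function(nm)
    rep(s2e / max(varcomp[[nm]], 1e-10 * s2e), ncol(Zs[[nm]]))))
  Zall <- do.call(cbind, Zs)
  XtX <- Matrix::crossprod(X)
  XtZ <- Matrix::crossprod(X, Zall)
  ZtZ <- Matrix::crossprod(Zall) + Matrix::Diagonal(x = lambdas)
  C <- rbind(cbind(XtX, XtZ), cbind(Matrix::t(XtZ), ZtZ))
  rhs <- rbind(Matrix::crossprod(X, Y), Matrix::crossprod(Zall, Y))
  sol <- Matrix::solve(C + Matrix::Diagonal(nrow(C), 1e-10), rhs)
  as.matrix(sol[seq_len(ncol(X)), , drop = FALSE])
}

#' Cullis heritability from variance components
#'
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \bar v_{\Delta BLUE} / 2)}
#' where \eqn{\sigma^2_g} is the genotypic variance from the adjustment
#' model with genotype random and \eqn{\bar v_{\Delta BLUE}} the mean
#' variance of a difference between two adjusted genotype means.
#'
#' @param sigma2_g genotypic variance (>= 0).
#' @param vdblue mean variance of a pairwise BLUE difference (>= 0).
#' @return heritability in [0, 1].
#' @examples
#' estimate_heritability(15, 2)  # 0.9375
#' @export
estimate_heritability <- function(sigma2_g, vdblue) {
  if (sigma2_g < 0 || vdblue < 0) stop("arguments must be non-negative")
  if (sigma2_g == 0 && vdblue == 0)
    stop("heritability undefined when both arguments are zero")
  min(max(sigma2_g / (sigma2_g + vdblue / 2), 0), 1)
}

#' Estimate trait heritability from a plot table
#'
#' Convenience wrapper: fits the adjustment model once with genotype
#' random (for the genotypic variance) and once with genotype fixed (for
#' the mean variance of a BLUE difference), then applies
#' \code{\link{estimate_heritability}}.
#'
#' @inheritParams adjust_trait
#' @return list with \code{H2}, \code{sigma2_g}, \code{vdblue},
#'   \code{varcomp} (from the genotype-random fit).
#' @export
heritability <- function(plots, trait, spec = model_spec()) {
  keep <- !is.na(plots[[trait]])
  pl <- plots[keep, , drop = FALSE]
  fac <- build_adjust_factors(pl, spec)
  fac2 <- c(list(genotype = factor(pl$genotype)), fac)
  fit <- reml_fit(pl[[trait]], random = fac2)
  sigma2_g <- fit$varcomp[["genotype"]]
  adj <- adjust_trait(pl, trait, spec)
  list(H2 = estimate_heritability(sigma2_g, adj$vdblue),
       sigma2_g = sigma2_g, vdblue = adj$vdblue, varcomp = fit$varcomp)
}
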