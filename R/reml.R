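#' REML fit of a linear mixed model
#'
#' Unified restricted-maximum-likelihood interface used throughout the
#' package. Random terms with identity covariance (grouping factors) are
#' fitted with a sparse solver; terms with a supplied covariance
#' (relationship/kernel) matrix are fitted with a dense profile-REML
#' optimiser over variance ratios, which also backs
#' \code{\link{fit_blup}}.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (default: intercept only).
#' @param random named list of random terms. Each element is either a
#'   factor/character vector of length \code{length(y)} (identity
#'   covariance) or a list with elements \code{Z} (design matrix, n x q)
#'   and \code{K} (q x q covariance; \code{NULL} means identity).
#' @param max_iter,tol optimiser budget and convergence tolerance for the
#'   dense path.
#' @return object of class \code{reml_fit}: \code{varcomp} (named vector,
#'   includes \code{residual}), \code{beta}, \code{vcov_beta},
#'   \code{ranef} (named list of BLUPs), \code{loglik} (restricted),
#'   \code{converged}, \code{method}.
#' @examples
#' y <- c(4, 6, 8, 10, 12, 14)
#' f <- reml_fit(y, random = list(group = rep(1:3, each = 2)))
#' f$varcomp  # group 15, residual 2 (balanced ANOVA estimators)
#' @export
reml_fit <- function(y, X = NULL, random = list(), max_iter = 200,
                     tol = 1e-8) {
  if (!all(is.finite(y))) stop("response must be finite")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  if (length(random) && is.null(names(random)))
    stop("random terms must be named")
  is_grouping <- vapply(random, function(r) !is.list(r), logical(1))
  if (all(is_grouping) && length(random) > 0) {
    reml_sparse(y, X, lapply(random, function(f) factor(f)))
  } else if (length(random) == 0) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- n - fit$rank
    s2 <- if (df > 0) rss / df else 0
    XtXi <- chol2inv(chol(crossprod(X)))
    structure(list(varcomp = c(residual = s2), beta = fit$coefficients,
                   vcov_beta = s2 * XtXi, ranef = list(), loglik = NA_real_,
                   converged = TRUE, method = "ols"),
              class = "reml_fit")
  } else {
    terms <- lapply(random, function(r) {
      if (!is.list(r)) {
        f <- factor(r)
        Z <- stats::model.matrix(~ 0 + f)
        colnames(Z) <- levels(f)
        list(Z = Z, K = NULL)
      } else r
    })
    reml_dense(y, X, terms, max_iter = max_iter, tol = tol)
  }
}

# Sparse path: identity-covariance grouping factors via lme4.
reml_sparse <- function(y, X, factors) {
  dat <- data.frame(.y = y)
  dat$.X <- X
  for (nm in names(factors)) dat[[nm]] <- factors[[nm]]
  rhs <- paste(c("0 + .X",
                 sprintf("(1 | %s)", names(factors))), collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
    check.nobs.vs.nRE = "ignore", calc.derivs = FALSE)
  fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE,
                                     control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  names(varcomp)[names(varcomp) == "Residual"] <- "residual"
  varcomp <- varcomp[c(names(factors), "residual")]
  beta <- lme4::fixef(fit)
  names(beta) <- sub("^\\.X", "", names(beta))
  re <- lme4::ranef(fit, condVar = FALSE)
  ranef <- lapply(names(factors), function(nm)
    stats::setNames(re[[nm]][, 1], rownames(re[[nm]])))
  names(ranef) <- names(factors)
  vcb <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                  error = function(e) {
    p <- length(beta)
    matrix(NA_real_, p, p)
  })
  structure(list(varcomp = varcomp, beta = beta,
                 vcov_beta = vcb, ranef = ranef,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = TRUE, method = "sparse", lme4_fit = fit),
            class = "reml_fit")
}

# Dense path: profile restricted log-likelihood over variance ratios
# lambda_k = sigma2_k / sigma2_e, optimised on the log scale.
reml_dense <- function(y, X, terms, max_iter = 200, tol = 1e-8,
                       varcomp = NULL) {
  n <- length(y)
  p <- ncol(X)
  ZKZt <- lapply(terms, function(tm) {
    Z <- as.matrix(tm$Z)
    if (is.null(tm$K)) tcrossprod(Z) else Z %*% tm$K %*% t(Z)
  })
  k <- length(ZKZt)

  profile <- function(log_lambda) {
    H <- diag(n)
    for (j in seq_len(k)) H <- H + exp(log_lambda[j]) * ZKZt[[j]]
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = 1e10))
    Hi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtHiX <- crossprod(X, Hi_X)
    cx <- tryCatch(chol(XtHiX), error = function(e) NULL)
    if (is.null(cx)) return(list(nll = 1e10))
    beta <- backsolve(cx, forwardsolve(t(cx), crossprod(X, Hi_y)))
    r <- y - X %*% beta
    Hi_r <- backsolve(ch, forwardsolve(t(ch), r))
    quad <- drop(crossprod(r, Hi_r))
    s2 <- max(quad / (n - p), 1e-300)  # floor for degenerate responses
    nll <- 0.5 * ((n - p) * log(s2) + 2 * sum(log(diag(ch))) +
                    2 * sum(log(diag(cx))) + (n - p))
    if (!is.finite(nll)) return(list(nll = 1e10))
    list(nll = nll, s2 = s2, beta = drop(beta), ch = ch,
         XtHiX_chol = cx, Hi_r = Hi_r)
  }

  if (is.null(varcomp)) {
    start <- rep(0, k)
    opt <- stats::optim(start, function(ll) profile(ll)$nll,
                        method = if (k == 1) "Brent" else "Nelder-Mead",
                        lower = if (k == 1) -25 else -Inf,
                        upper = if (k == 1) 25 else Inf,
                        control = list(maxit = max_iter, reltol = tol))
    converged <- opt$convergence == 0
    if (!converged)
      warning("dense REML did not converge within max_iter iterations")
    log_lambda <- pmin(pmax(opt$par, -25), 25)
  } else {
    s2e <- varcomp[["residual"]]
    log_lambda <- log(pmax(varcomp[names(terms)] / s2e, 1e-12))
    converged <- TRUE
  }
  pr <- profile(log_lambda)
  s2e <- if (is.null(varcomp)) pr$s2 else varcomp[["residual"]]
  lambda <- exp(log_lambda)
  sig2 <- stats::setNames(lambda * s2e, names(terms))

  # BLUPs: u_k = lambda_k K_k Z_k' P y with P y = H^-1 (y - X beta)
  Hi_r <- pr$Hi_r
  ranef <- vector("list", k)
  for (j in seq_len(k)) {
    Z <- as.matrix(terms[[j]]$Z)
    ZtPy <- crossprod(Z, Hi_r)
    u <- if (is.null(terms[[j]]$K)) lambda[j] * ZtPy
         else lambda[j] * terms[[j]]$K %*% ZtPy
    ranef[[j]] <- stats::setNames(drop(u), colnames(Z))
  }
  names(ranef) <- names(terms)
  vcov_beta <- s2e * chol2inv(pr$XtHiX_chol)
  beta <- stats::setNames(pr$beta, colnames(X))
  structure(list(varcomp = c(sig2, residual = s2e), beta = beta,
                 vcov_beta = vcov_beta, ranef = ranef,
                 loglik = -pr$nll, converged = converged,
                 method = "dense", Hi_r = Hi_r, lambda = lambda),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit (", x$method, " path)\n", sep = "")
  cat("variance components:\n")
  print(round(x$varcomp, 6))
  cat("fixed effects:", length(x$beta), "; converged:", x$converged, "\n")
  invisible(x)
}
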