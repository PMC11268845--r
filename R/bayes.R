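# Inverse-Gaussian sampler (Michael, Schucany & Haas 1976); used for the
# 1/tau^2 updates of the Bayesian LASSO.
rinvgauss <- function(n, mean, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  z <- stats::runif(n)
  ifelse(z <= mean / (mean + x), x, mean^2 / x)
}

chain_settings <- function(niter = 12000, burnin = 2000, thin = 5) {
  if (niter <= burnin) stop("chain shorter than burn-in")
  list(niter = niter, burnin = burnin, thin = thin)
}

#' Bayesian LASSO regression on markers and/or spectra
#'
#' Gibbs sampler for \deqn{y = X\beta + Ma + Wi + e} with flat priors on
#' the fixed effects and double-exponential (Laplace) priors on the marker
#' effects a and wavelength effects i, implemented through the standard
#' scale-mixture-of-normals representation: \eqn{a_j \sim N(0, \sigma^2_e
#' \tau^2_j)} with exponential mixing on \eqn{\tau^2_j} and a Gamma
#' hyperprior on the squared regularisation parameter of each predictor
#' block (markers and spectra get their own parameter). Either M or W may
#' be omitted.
#'
#' @param y named numeric vector of training phenotypes.
#' @param M marker dosage matrix (0/1/2), rows covering at least the
#'   training ids; internally column-centred.
#' @param W preprocessed spectra matrix; internally column-centred.
#' @param fixed optional fixed-effect design over all individuals
#'   (rownames = ids); default intercept only.
#' @param niter,burnin,thin chain length, burn-in and thinning.
#' @param seed integer seed; identical settings give identical chains.
#' @param lambda2 optional named list/vector fixing the squared
#'   regularisation parameter per block (\code{M}, \code{W}); when NULL it
#'   is sampled.
#' @param sigma2e optional fixed residual variance; when NULL it is
#'   sampled.
#' @param hyper hyperparameters: \code{shape}, \code{rate} of the Gamma
#'   prior on each lambda^2 and \code{df_e}, \code{S_e} of the scaled
#'   inverse chi-squared prior on the residual variance (\code{S_e = NULL}
#'   scales to the response variance).
#' @param prior \code{"laplace"} (the LASSO's double-exponential prior,
#'   default) or \code{"gaussian"}, which freezes every \eqn{\tau^2_j} at
#'   \code{tau2_fixed} and thereby turns the sampler into Bayesian ridge
#'   regression (a sampler cross-check: it must collapse to the BLUP
#'   solution).
#' @param tau2_fixed fixed prior variance ratio for the gaussian prior.
#' @return object of class \code{bl_fit} with posterior means of the
#'   fixed effects and of the effect vectors, block centres for
#'   prediction, and chain diagnostics (posterior samples of the variance
#'   and regularisation parameters).
#' @export
fit_bayesian_lasso <- function(y, M = NULL, W = NULL, fixed = NULL,
                               niter = 12000, burnin = 2000, thin = 5,
                               seed = 1, lambda2 = NULL, sigma2e = NULL,
                               hyper = list(shape = 1.1, rate = 1e-5,
                                            df_e = 5, S_e = NULL),
                               prior = c("laplace", "gaussian"),
                               tau2_fixed = 1) {
  prior <- match.arg(prior)
  cs <- chain_settings(niter, burnin, thin)
  train <- names(y)
  if (is.null(train)) stop("y must be named by individual id")
  n <- length(y)
  blocks <- list()
  if (!is.null(M)) blocks$M <- as.matrix(M)[train, , drop = FALSE]
  if (!is.null(W)) blocks$W <- as.matrix(W)[train, , drop = FALSE]
  if (length(blocks) == 0) stop("supply at least one of M and W")
  centers <- lapply(blocks, colMeans)
  blocks <- Map(function(B, mu) sweep(B, 2, mu), blocks, centers)
  X <- if (is.null(fixed)) matrix(1, n, 1, dimnames = list(train, "mu"))
       else as.matrix(fixed)[train, , drop = FALSE]

  set.seed(as.integer(seed))
  p <- vapply(blocks, ncol, integer(1))
  xtx <- lapply(blocks, function(B) colSums(B^2))
  xtx_f <- colSums(X^2)
  a <- lapply(p, numeric)
  tau2 <- lapply(p, function(k) rep(tau2_fixed, k))
  lam2 <- lapply(p, function(k) max(k, 1))
  fix_lam <- !is.null(lambda2)
  if (fix_lam) {
    lambda2 <- as.list(lambda2)
    for (nm in names(blocks)) lam2[[nm]] <- lambda2[[nm]]
  }
  beta <- numeric(ncol(X))
  vy <- stats::var(y)
  S_e <- hyper$S_e %||% (vy * 0.5 * (hyper$df_e + 2))
  s2e <- sigma2e %||% (vy / 2)
  fix_s2e <- !is.null(sigma2e)
  e <- y - drop(X %*% beta)

  keep <- seq(burnin + 1, niter, by = thin)
  sum_a <- lapply(p, numeric)
  sum_beta <- numeric(ncol(X))
  n_keep <- 0L
  trace <- matrix(NA_real_, nrow = length(keep),
                  ncol = 1 + length(blocks),
                  dimnames = list(NULL, c("sigma2e",
                                          paste0("lambda2_",
                                                 names(blocks)))))
  a_samples <- if (sum(p) <= 50)
    matrix(NA_real_, nrow = length(keep), ncol = sum(p)) else NULL

  for (it in seq_len(niter)) {
    # fixed effects, flat prior
    .gibbs_effect_sweep(X, e, beta, xtx_f, rep(0, ncol(X)), s2e)
    # block effects with Laplace (scale-mixture) priors
    for (nm in names(blocks)) {
      .gibbs_effect_sweep(blocks[[nm]], e, a[[nm]], xtx[[nm]],
                          1 / tau2[[nm]], s2e)
      if (prior == "laplace") {
        aj2 <- pmax(a[[nm]]^2, 1e-12)
        mu_ig <- sqrt(lam2[[nm]] * s2e / aj2)
        tau2[[nm]] <- 1 / rinvgauss(p[[nm]], mu_ig, lam2[[nm]])
        tau2[[nm]] <- pmax(tau2[[nm]], 1e-12)
        if (!fix_lam)
          lam2[[nm]] <- stats::rgamma(1, shape = hyper$shape + p[[nm]],
                                      rate = hyper$rate +
                                        sum(tau2[[nm]]) / 2)
      }
    }
    if (!fix_s2e) {
      ss <- sum(e^2) +
        sum(unlist(Map(function(av, tv) sum(av^2 / tv), a, tau2))) + S_e
      s2e <- ss / stats::rchisq(1, df = n + sum(p) + hyper$df_e)
    }
    pos <- match(it, keep)
    if (!is.na(pos)) {
      n_keep <- n_keep + 1L
      for (nm in names(blocks)) sum_a[[nm]] <- sum_a[[nm]] + a[[nm]]
      sum_beta <- sum_beta + beta
      trace[pos, ] <- c(s2e, unlist(lam2))
      if (!is.null(a_samples)) a_samples[pos, ] <- unlist(a)
    }
  }
  post_a <- lapply(sum_a, function(s) s / n_keep)
  structure(list(beta = stats::setNames(sum_beta / n_keep, colnames(X)),
                 effects = post_a, centers = centers,
                 fixed = if (is.null(fixed)) NULL else as.matrix(fixed),
                 chain = c(cs, seed = seed), trace = trace,
                 a_samples = a_samples, train = train),
            class = "bl_fit")
}

#' Predict from a Bayesian LASSO fit
#'
#' @param object a \code{bl_fit}.
#' @param M,W predictor matrices for the individuals to predict (same
#'   columns as at fit time; whichever blocks the model was fitted with
#'   must be supplied).
#' @param ids individuals to predict; default the rownames of the first
#'   supplied block.
#' @param ... ignored.
#' @return named numeric vector of predictions.
#' @export
predict.bl_fit <- function(object, M = NULL, W = NULL, ids = NULL, ...) {
  blocks <- list()
  if ("M" %in% names(object$effects)) {
    if (is.null(M)) stop("model was fitted with markers; supply M")
    blocks$M <- as.matrix(M)
  }
  if ("W" %in% names(object$effects)) {
    if (is.null(W)) stop("model was fitted with spectra; supply W")
    blocks$W <- as.matrix(W)
  }
  ids <- ids %||% rownames(blocks[[1]])
  yhat <- numeric(length(ids))
  for (nm in names(blocks)) {
    B <- sweep(blocks[[nm]][ids, , drop = FALSE], 2, object$centers[[nm]])
    yhat <- yhat + drop(B %*% object$effects[[nm]])
  }
  Xn <- if (is.null(object$fixed)) matrix(1, length(ids), 1)
        else object$fixed[ids, , drop = FALSE]
  stats::setNames(yhat + drop(Xn %*% object$beta), ids)
}

#' RKHS regression with kernel averaging
#'
#' Bayesian multi-kernel model \deqn{y = X\beta + \sum_l u_l + e,\quad
#' u_l \sim N(0, K_l \sigma^2_l)} fitted by Gibbs sampling in the
#' eigenbasis of each kernel. Each kernel (typically Gaussian kernels at
#' bandwidths 0.1, 0.5 and 2.5 per predictor type) carries its own
#' variance component, so kernel averaging emerges from the relative
#' variance-component weights.
#'
#' @param y named numeric vector of training phenotypes.
#' @param kernels named list of PSD kernel matrices covering training and
#'   test individuals (e.g. from \code{\link{gaussian_kernels}}; combine
#'   the SNP and NIRS kernel lists for the combined model).
#' @param fixed optional fixed-effect design over all individuals.
#' @param niter,burnin,thin,seed chain settings.
#' @param varcomp optional named vector fixing all variance components
#'   (one per kernel plus \code{residual}); sampled when NULL.
#' @param hyper \code{df0} and R2 split used to scale the
#'   scaled-inverse-chi-squared priors on the variance components.
#' @return object of class \code{rkhs_fit}; includes posterior-mean
#'   random effects per kernel and the variance-component trace.
#' @export
fit_rkhs_ka <- function(y, kernels, fixed = NULL, niter = 12000,
                        burnin = 2000, thin = 5, seed = 1,
                        varcomp = NULL,
                        hyper = list(df0 = 5, R2 = 0.5)) {
  cs <- chain_settings(niter, burnin, thin)
  if (!length(kernels)) stop("empty kernel list")
  if (is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_along(kernels))
  train <- names(y)
  if (is.null(train)) stop("y must be named by individual id")
  n <- length(y)
  all_ids <- rownames(kernels[[1]])
  X <- if (is.null(fixed)) matrix(1, n, 1, dimnames = list(train, "mu"))
       else as.matrix(fixed)[train, , drop = FALSE]

  # eigendecompose each kernel's training block; drop null directions
  eig <- lapply(kernels, function(K) {
    if (!all(train %in% rownames(K)))
      stop("kernel does not cover all training individuals")
    E <- eigen(K[train, train], symmetric = TRUE)
    keep <- E$values > max(E$values) * 1e-8
    list(Phi = E$vectors[, keep, drop = FALSE],
         lam = E$values[keep])
  })
  L <- length(kernels)
  vy <- stats::var(y)
  df0 <- hyper$df0
  S0_u <- vapply(seq_len(L), function(l)
    vy * hyper$R2 / L * (df0 + 2) /
      mean(diag(kernels[[l]][train, train])), numeric(1))
  S0_e <- vy * (1 - hyper$R2) * (df0 + 2)

  set.seed(as.integer(seed))
  fix_vc <- !is.null(varcomp)
  s2u <- if (fix_vc) as.numeric(varcomp[names(kernels)])
         else rep(vy * hyper$R2 / L, L)
  s2e <- if (fix_vc) varcomp[["residual"]] else vy / 2
  delta <- lapply(eig, function(eg) numeric(length(eg$lam)))
  beta <- numeric(ncol(X))
  xtx_f <- colSums(X^2)
  e <- y - drop(X %*% beta)

  keep_it <- seq(burnin + 1, niter, by = thin)
  sum_delta <- lapply(delta, function(d) d * 0)
  sum_beta <- numeric(ncol(X))
  n_keep <- 0L
  trace <- matrix(NA_real_, nrow = length(keep_it), ncol = L + 1,
                  dimnames = list(NULL, c(names(kernels), "sigma2e")))

  for (it in seq_len(niter)) {
    .gibbs_effect_sweep(X, e, beta, xtx_f, rep(0, ncol(X)), s2e)
    for (l in seq_len(L)) {
      eg <- eig[[l]]
      ones <- rep(1, length(eg$lam))  # Phi columns are orthonormal
      .gibbs_effect_sweep(eg$Phi, e, delta[[l]], ones,
                          s2e / (s2u[l] * eg$lam), s2e)
      if (!fix_vc) {
        ss <- sum(delta[[l]]^2 / eg$lam) + S0_u[l]
        s2u[l] <- ss / stats::rchisq(1, df = length(eg$lam) + df0)
      }
    }
    if (!fix_vc)
      s2e <- (sum(e^2) + S0_e) / stats::rchisq(1, df = n + df0)
    pos <- match(it, keep_it)
    if (!is.na(pos)) {
      n_keep <- n_keep + 1L
      for (l in seq_len(L)) sum_delta[[l]] <- sum_delta[[l]] + delta[[l]]
      sum_beta <- sum_beta + beta
      trace[pos, ] <- c(s2u, s2e)
    }
  }
  post_delta <- lapply(sum_delta, function(s) s / n_keep)
  # u on training ids and the coefficients alpha = K_tt^+ u used for
  # out-of-sample prediction via the kernel cross-block
  u_train <- Map(function(eg, d) drop(eg$Phi %*% d), eig, post_delta)
  alpha <- Map(function(eg, d) drop(eg$Phi %*% (d / eg$lam)),
               eig, post_delta)
  structure(list(beta = stats::setNames(sum_beta / n_keep, colnames(X)),
                 u_train = u_train, alpha = alpha, kernels = kernels,
                 fixed = if (is.null(fixed)) NULL else as.matrix(fixed),
                 train = train, trace = trace, chain = c(cs, seed = seed)),
            class = "rkhs_fit")
}

#' Predict from an RKHS kernel-averaging fit
#'
#' Random effects of unobserved individuals are obtained from the kernel
#' cross-block: \eqn{u_{new} = K[new, train] K[train, train]^{+} u_{train}}.
#'
#' @param object an \code{rkhs_fit}.
#' @param ids individuals to predict (must be covered by the kernels).
#' @param ... ignored.
#' @return named numeric vector of predictions.
#' @export
predict.rkhs_fit <- function(object, ids = object$train, ...) {
  for (K in object$kernels)
    if (!all(ids %in% rownames(K))) stop("unknown individual id in ids")
  u <- numeric(length(ids))
  for (l in seq_along(object$kernels)) {
    Kc <- object$kernels[[l]][ids, object$train, drop = FALSE]
    u <- u + drop(Kc %*% object$alpha[[l]])
  }
  Xn <- if (is.null(object$fixed)) matrix(1, length(ids), 1)
        else object$fixed[ids, , drop = FALSE]
  stats::setNames(u + drop(Xn %*% object$beta), ids)
}
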