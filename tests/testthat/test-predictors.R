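# ridge/GLS closed form used as the BLUP oracle
mixed_model_oracle <- function(y, X, V_g, s2e) {
  V <- V_g + diag(s2e, length(y))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(beta = drop(beta), resid_proj = Vi %*% (y - X %*% beta))
}

test_that("BLUP with identity kinship equals the ridge closed form", {
  y <- c(a = 1, b = 3)
  G <- diag(2); dimnames(G) <- list(c("a", "b"), c("a", "b"))
  fit <- fit_blup(y, list(g = G), varcomp = c(g = 1, residual = 1))
  # equal variances: u = (K + I)^-1 (y - mean), shrinkage by 1/2
  expect_equal(unname(fit$u[, 1]), c(-0.5, 0.5))
  expect_equal(unname(predict(fit, c("a", "b"))), c(1.5, 2.5))
})

test_that("constant phenotypes give zero genetic predictions", {
  set.seed(11)
  M <- hwe_panel(30, 60, seed = 11)
  G <- vanraden_grm(M)
  y <- setNames(rep(4.2, 30), rownames(M))
  fit <- fit_blup(y, list(g = ensure_psd(G)))
  expect_lt(max(abs(fit$u)), 1e-4)
  expect_equal(unname(fit$beta[1]), 4.2, tolerance = 1e-6)
})

test_that("GBLUP and RR-BLUP predictions coincide", {
  set.seed(12)
  M <- hwe_panel(50, 200, seed = 12)
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p)
  y <- setNames(drop(Z[, 1:30] %*% rnorm(30, 0, 0.15)) + rnorm(50),
                rownames(M))
  G <- vanraden_grm(M)
  vc <- c(g = 0.6, residual = 0.5)
  fit <- fit_blup(y, list(g = G), varcomp = vc)
  pred_g <- predict(fit, rownames(M))
  # marker-effect ridge with matching per-marker variance
  denom <- 2 * sum(p * (1 - p))
  lam <- vc["residual"] / (vc["g"] / denom)
  X <- matrix(1, 50, 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lam, ncol(Z))))
  sol <- solve(C, rbind(crossprod(X, y), crossprod(Z, y)))
  pred_rr <- drop(X %*% sol[1] + Z %*% sol[-1])
  expect_lt(max(abs(pred_g - pred_rr)), 1e-6)
})

test_that("combined BLUP with a null spectral variance reduces to GBLUP", {
  set.seed(13)
  M <- hwe_panel(40, 80, seed = 13)
  G <- ensure_psd(vanraden_grm(M))
  W <- scale(matrix(rnorm(40 * 30), 40, 30))
  rownames(W) <- rownames(M)
  Gn <- ensure_psd(nirs_relationship(W))
  y <- setNames(rnorm(40), rownames(M))
  vc2 <- c(snp = 0.7, nirs = 1e-12, residual = 0.4)
  both_fit <- fit_blup(y, list(snp = G, nirs = Gn), varcomp = vc2)
  one <- fit_blup(y, list(snp = G), varcomp = c(snp = 0.7, residual = 0.4))
  expect_equal(predict(both_fit, rownames(M)), predict(one, rownames(M)),
               tolerance = 1e-6)
})

test_that("predictions are equivariant and clone-consistent", {
  set.seed(14)
  M <- hwe_panel(30, 60, seed = 14)
  G <- ensure_psd(vanraden_grm(rbind(M, clone = M[1, ])))
  y <- setNames(rnorm(30), rownames(M))
  fit <- fit_blup(y, list(g = G))
  ids <- c("i3", "i1", "clone")
  expect_equal(predict(fit, ids), predict(fit, rev(ids))[ids])
  # a clone (identical kinship row) predicts like its training original
  expect_equal(unname(predict(fit, "clone")),
               unname(predict(fit, "i1")), tolerance = 1e-8)
  expect_error(predict(fit, "nobody"), "unknown individual")
  # shift invariance: adding a constant shifts predictions by it
  fit2 <- fit_blup(y + 100, list(g = G))
  expect_equal(predict(fit2, names(y)), predict(fit, names(y)) + 100,
               tolerance = 1e-4)
})

test_that("Bayesian LASSO posterior matches a quadrature oracle", {
  set.seed(15)
  n <- 40
  x <- rnorm(n)
  y <- setNames(0.8 * x + rnorm(n), paste0("s", 1:n))
  M <- matrix(x + 1, ncol = 1, dimnames = list(names(y), "mk1"))
  bl <- fit_bayesian_lasso(y, M = M, niter = 20000, burnin = 2000,
                           thin = 2, seed = 5, lambda2 = list(M = 0.01),
                           sigma2e = 1)
  # 1-D numerical integration of the exact conditional posterior
  xc <- drop(scale(x + 1, scale = FALSE))
  xtx <- sum(xc^2); cxy <- sum(xc * (y - mean(y)))
  lam <- sqrt(0.01)
  dens <- function(a) exp(-(xtx * a^2 - 2 * cxy * a) / 2 - lam * abs(a))
  gr <- seq(-3, 3, length.out = 20001)
  w <- dens(gr)
  post_mean <- sum(gr * w) / sum(w)
  samp <- bl$a_samples[, 1]
  se <- sd(tapply(samp, rep(1:30, length.out = length(samp)), mean)) /
    sqrt(30)
  expect_lt(abs(bl$effects$M - post_mean), 3 * max(se, 1e-4))
})

test_that("extreme shrinkage collapses the LASSO to the fixed-effect fit", {
  set.seed(16)
  M <- hwe_panel(35, 20, seed = 16)
  y <- setNames(rnorm(35, 5), rownames(M))
  bl <- fit_bayesian_lasso(y, M = M, niter = 3000, burnin = 500,
                           thin = 2, seed = 2,
                           lambda2 = list(M = 1e8), sigma2e = 1)
  expect_lt(max(abs(bl$effects$M)), 1e-2)
  expect_equal(unname(bl$beta[1]), mean(y), tolerance = 0.05)
})

test_that("chains are reproducible under a fixed seed", {
  set.seed(17)
  M <- hwe_panel(30, 15, seed = 17)
  y <- setNames(rnorm(30), rownames(M))
  b1 <- fit_bayesian_lasso(y, M = M, niter = 500, burnin = 100, seed = 9)
  b2 <- fit_bayesian_lasso(y, M = M, niter = 500, burnin = 100, seed = 9)
  expect_identical(b1$effects, b2$effects)
  expect_identical(b1$trace, b2$trace)
})

test_that("gaussian-prior sampling collapses to the BLUP solution", {
  set.seed(18)
  M <- hwe_panel(40, 30, seed = 18)
  y <- setNames(drop(scale(M[, 1:10]) %*% rnorm(10, 0, 0.3)) + rnorm(40),
                rownames(M))
  tau2 <- 0.05
  bl <- fit_bayesian_lasso(y, M = M, niter = 12000, burnin = 2000,
                           thin = 2, seed = 4, sigma2e = 0.8,
                           prior = "gaussian", tau2_fixed = tau2)
  # ridge closed form with prior variance sigma2e * tau2 per effect
  Mc <- scale(M, scale = FALSE)
  X <- matrix(1, 40, 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, Mc)),
             cbind(crossprod(Mc, X), crossprod(Mc) +
                     diag(1 / tau2, ncol(Mc))))
  sol <- solve(C, rbind(crossprod(X, y), crossprod(Mc, y)))
  expect_gt(cor(bl$effects$M, sol[-1]), 0.999)
  expect_lt(max(abs(bl$effects$M - sol[-1])), 0.02)
})

test_that("single-kernel RKHS matches the kernel-ridge closed form", {
  set.seed(19)
  M <- hwe_panel(50, 120, seed = 19)
  G <- vanraden_grm(M)
  K <- ensure_psd(G / mean(diag(G)))
  y <- setNames(rnorm(50) + K[, 5] * 2, rownames(M))
  vc <- c(K = 0.6, residual = 0.4)
  fit <- fit_rkhs_ka(y, list(K = K), niter = 6000, burnin = 1000,
                     thin = 2, seed = 3, varcomp = vc)
  pr <- predict(fit, rownames(M))
  X <- matrix(1, 50, 1)
  or <- mixed_model_oracle(y, X, 0.6 * K, 0.4)
  oracle <- drop(X %*% or$beta + 0.6 * K %*% or$resid_proj)
  expect_gt(cor(pr, oracle), 0.999)
  expect_lt(max(abs(pr - oracle)), 0.1)
})

test_that("identical kernels split variance without changing predictions", {
  set.seed(20)
  M <- hwe_panel(40, 80, seed = 20)
  K <- ensure_psd(gaussian_kernels(scale(M), 0.5)[[1]])
  y <- setNames(rnorm(40), rownames(M))
  f1 <- fit_rkhs_ka(y, list(K = K), niter = 5000, burnin = 1000,
                    seed = 6)
  f3 <- fit_rkhs_ka(y, list(K1 = K, K2 = K, K3 = K), niter = 5000,
                    burnin = 1000, seed = 6)
  expect_gt(cor(predict(f1, names(y)), predict(f3, names(y))), 0.99)
})

test_that("RKHS captures epistatic signal at least as well as GBLUP", {
  # purely epistatic trait: sums of pairwise products of standardised
  # dosages; the additive kinship carries no signal for it while the
  # Gaussian kernels can represent the interactions
  wins <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 150; m <- 40
    p <- runif(m, 0.2, 0.8)
    M <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
    dimnames(M) <- list(paste0("i", 1:n), paste0("mk", 1:m))
    Z <- scale(M)
    pairs <- matrix(sample(m, 40, replace = TRUE), ncol = 2)
    g <- rowSums(Z[, pairs[, 1]] * Z[, pairs[, 2]])
    y <- setNames(drop(scale(g)) + rnorm(n, 0, 0.3), rownames(M))
    train <- sample(rownames(M), 120)
    test <- setdiff(rownames(M), train)
    G <- ensure_psd(vanraden_grm(M))
    ks <- lapply(gaussian_kernels(Z), ensure_psd)
    r_g <- cor(y[test], predict(fit_blup(y[train], list(g = G)), test))
    r_k <- cor(y[test],
               predict(fit_rkhs_ka(y[train], ks, niter = 1500,
                                   burnin = 400, thin = 2,
                                   seed = s), test))
    r_k >= r_g
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("the tuning budget and bounds are honoured", {
  space <- ml_search_space("rf", 6300)
  expect_equal(space$mtry$lower, 100)
  expect_equal(space$mtry$upper, 2100)

  set.seed(21)
  X <- matrix(rnorm(60 * 30), 60, 30,
              dimnames = list(paste0("i", 1:60), NULL))
  y <- setNames(drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(60, 0, 0.2),
                rownames(X))
  fit <- tune_and_fit_ml(y, X, learner = "rf", seed = 1)
  expect_equal(nrow(fit$trace), 18)  # 12 initial + 6 sequential
  sp <- fit$space
  expect_true(all(fit$trace$mtry >= sp$mtry$lower &
                    fit$trace$mtry <= sp$mtry$upper))
  expect_true(all(fit$trace$min.node.size >= 3 &
                    fit$trace$min.node.size <= 15))
  expect_error(tune_and_fit_ml(y[1:10], X[1:10, ], "rf"), "at least 30")
})

test_that("tuned SVR recovers a noiseless linear trait", {
  set.seed(22)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("i", 1:n), NULL))
  y <- setNames(drop(X %*% c(1, 2, -1, 0.5, 1)), rownames(X))
  train <- sample(rownames(X), 320)
  test <- setdiff(rownames(X), train)
  fit <- tune_and_fit_ml(y[train], X[train, ], learner = "svm", seed = 2)
  expect_gt(cor(y[test], predict(fit, X[test, ])), 0.95)
  expect_true(all(fit$trace$C >= 1e-6 & fit$trace$C <= 2^10))
  expect_true(all(fit$trace$epsilon >= 0 & fit$trace$epsilon <= 0.5))
})
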