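#' Kinship-based BLUP (GBLUP / NIRS-BLUP / combined)
#'
#' Fits \deqn{y = X\beta + \sum_k u_k + e,\quad u_k \sim N(0, K_k
#' \sigma^2_k),\quad e \sim N(0, I\sigma^2_e)} by REML on the training
#' individuals and predicts the random effects of every individual covered
#' by the kinship matrices through the kinship cross-block. With the
#' VanRaden matrix this is GBLUP, with the NIRS relationship matrix
#' NIRS-BLUP, and with both the combined model.
#'
#' @param y named numeric vector of training phenotypes (adjusted means).
#' @param kinships one kinship matrix or a named list of up to two; the
#'   dimnames must cover the training ids and every individual to be
#'   predicted.
#' @param fixed optional fixed-effect design matrix over all individuals
#'   (rownames = ids), e.g. an intercept plus a one-hot tester indicator;
#'   default intercept only.
#' @param varcomp optional named variance components (one per kinship plus
#'   \code{residual}); when supplied, REML estimation is skipped and BLUP
#'   is computed at these values.
#' @return object of class \code{blup_fit} with \code{varcomp},
#'   \code{beta}, \code{u} (individuals x kinships matrix of random-effect
#'   predictions), \code{train} ids.
#' @seealso \code{\link{predict.blup_fit}}
#' @export
fit_blup <- function(y, kinships, fixed = NULL, varcomp = NULL) {
  if (is.matrix(kinships)) kinships <- list(K = kinships)
  if (length(kinships) < 1 || length(kinships) > 2)
    stop("supply one or two kinship matrices")
  if (is.null(names(kinships)))
    names(kinships) <- paste0("K", seq_along(kinships))
  train <- names(y)
  if (is.null(train)) stop("y must be named by individual id")
  all_ids <- rownames(kinships[[1]])
  for (K in kinships) {
    if (is.null(rownames(K)) || !all(train %in% rownames(K)))
      stop("kinship matrix does not cover all training individuals")
    if (!setequal(rownames(K), all_ids))
      stop("kinship matrices cover different individual sets")
  }
  if (is.null(fixed)) {
    fixed <- matrix(1, length(all_ids), 1,
                    dimnames = list(all_ids, "(Intercept)"))
  } else {
    fixed <- as.matrix(fixed)
    if (!all(all_ids %in% rownames(fixed)))
      stop("fixed design must cover every individual in the kinships")
  }
  Xt <- fixed[train, , drop = FALSE]
  terms <- lapply(kinships, function(K)
    list(Z = diag(length(train)), K = K[train, train]))
  fit <- reml_dense(y, Xt, terms, varcomp = varcomp)
  s2 <- fit$varcomp
  # random effects for every individual via the kinship cross-block:
  # u_k = sigma2_k K[., train] V^{-1} (y - X beta) = lambda_k K Hi_r
  U <- sapply(seq_along(kinships), function(k)
    drop(fit$lambda[k] * kinships[[k]][, train] %*% fit$Hi_r))
  if (is.null(dim(U))) U <- matrix(U, ncol = length(kinships))
  dimnames(U) <- list(all_ids, names(kinships))
  structure(list(varcomp = s2, beta = fit$beta, u = U, fixed = fixed,
                 train = train, converged = fit$converged,
                 loglik = fit$loglik),
            class = "blup_fit")
}

#' Predict phenotypic values from a fitted BLUP model
#'
#' @param object a \code{blup_fit}.
#' @param ids individuals to predict (must be covered by the kinships
#'   supplied at fit time).
#' @param ... ignored.
#' @return named numeric vector: fixed-effect part plus the summed
#'   random-effect predictions. Deterministic given the fitted model.
#' @export
predict.blup_fit <- function(object, ids = object$train, ...) {
  unknown <- setdiff(ids, rownames(object$u))
  if (length(unknown))
    stop("unknown individual id(s): ", paste(head(unknown, 3),
                                             collapse = ", "))
  fx <- drop(object$fixed[ids, , drop = FALSE] %*% object$beta)
  stats::setNames(fx + rowSums(object$u[ids, , drop = FALSE]), ids)
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("kinship BLUP fit:", paste(colnames(x$u), collapse = " + "), "\n")
  cat("variance components:\n")
  print(round(x$varcomp, 6))
  invisible(x)
}
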