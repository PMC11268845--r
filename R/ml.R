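#' Hyperparameter search space for the machine-learning models
#'
#' Random forest tunes \code{mtry} between 100 and one third of the
#' feature-column count (collapsed sensibly when the matrix is narrower)
#' and \code{min.node.size} in [3, 15], with 500 trees. Support vector
#' regression (RBF kernel) tunes \code{C} in (0, 2^10] and
#' \code{epsilon} in [0, 0.5]; the degenerate lower bound C = 0 is
#' implemented as 1e-6. C is searched on the log scale.
#'
#' @param learner \code{"rf"} or \code{"svm"}.
#' @param n_features number of columns of the feature matrix.
#' @return list of per-parameter bounds, transforms and integer flags.
#' @export
ml_search_space <- function(learner = c("rf", "svm"), n_features) {
  learner <- match.arg(learner)
  if (learner == "rf") {
    third <- max(1, floor(n_features / 3))
    lo <- min(100, third)
    list(mtry = list(lower = lo, upper = max(lo, third), integer = TRUE,
                     log = FALSE),
         min.node.size = list(lower = 3, upper = 15, integer = TRUE,
                              log = FALSE))
  } else {
    list(C = list(lower = 1e-6, upper = 2^10, integer = FALSE, log = TRUE),
         epsilon = list(lower = 0, upper = 0.5, integer = FALSE,
                        log = FALSE))
  }
}

space_decode <- function(u, space) {
  # u in [0,1]^d -> named parameter list respecting bounds/log/integer
  out <- list()
  for (d in seq_along(space)) {
    s <- space[[d]]
    v <- if (s$log) exp(log(s$lower) + u[d] * (log(s$upper) - log(s$lower)))
         else s$lower + u[d] * (s$upper - s$lower)
    if (s$integer) v <- as.integer(round(v))
    v <- min(max(v, s$lower), s$upper)
    out[[names(space)[d]]] <- v
  }
  out
}

# Minimal Gaussian-process surrogate on the unit cube with expected
# improvement, used for the sequential phase of the tuning budget.
gp_expected_improvement <- function(U, z, cand) {
  zs <- (z - mean(z)) / (stats::sd(z) + 1e-12)
  d2 <- as.matrix(stats::dist(U))^2
  theta2 <- stats::median(d2[upper.tri(d2)]) + 1e-6
  K <- exp(-d2 / theta2) + diag(1e-6, nrow(U))
  Ki <- tryCatch(chol2inv(chol(K)), error = function(e)
    solve(K + diag(1e-3, nrow(U))))
  # pairwise squared distances candidate-to-design
  cd2 <- outer(rowSums(cand^2), rep(1, nrow(U))) +
    outer(rep(1, nrow(cand)), rowSums(U^2)) - 2 * cand %*% t(U)
  kc <- exp(-pmax(cd2, 0) / theta2)
  mu <- drop(kc %*% (Ki %*% zs))
  s2 <- pmax(1 - rowSums((kc %*% Ki) * kc), 1e-12)
  s <- sqrt(s2)
  zbest <- min(zs)
  imp <- zbest - mu
  ei <- imp * stats::pnorm(imp / s) + s * stats::dnorm(imp / s)
  ei
}

#' Tune and fit a machine-learning prediction model
#'
#' Model-based hyperparameter optimisation with a budget of 12 initial
#' space-filling (Latin hypercube) evaluations followed by 6 sequential
#' evaluations guided by a Gaussian-process surrogate with expected
#' improvement (\code{tuner = "mbo"}), or 18 pure random evaluations
#' (\code{tuner = "random"}). The objective is the out-of-bag mean squared
#' error for the random forest and the 5-fold cross-validated mean squared
#' error for support vector regression. The best configuration is refitted
#' on all training data.
#'
#' @param y named numeric response (training individuals).
#' @param features numeric feature matrix over the training individuals
#'   (SNP dosages, preprocessed spectra, or their column-bound
#'   combination plus a tester indicator); columns are used as-is.
#' @param learner \code{"rf"} (ranger random forest, 500 trees) or
#'   \code{"svm"} (kernlab eps-regression, RBF kernel).
#' @param seed integer seed controlling the design, the surrogate
#'   candidates and the learner fits.
#' @param budget list with \code{init} (default 12) and \code{seq}
#'   (default 6) evaluation counts.
#' @param tuner surrogate-guided (\code{"mbo"}, default) or pure random
#'   search with the same total budget.
#' @return object of class \code{ml_fit}: fitted learner, \code{best}
#'   hyperparameters, \code{trace} data.frame of all evaluations.
#' @export
tune_and_fit_ml <- function(y, features, learner = c("rf", "svm"),
                            seed = 1, budget = list(init = 12, seq = 6),
                            tuner = c("mbo", "random")) {
  learner <- match.arg(learner)
  tuner <- match.arg(tuner)
  X <- as.matrix(features)
  if (!is.null(names(y)) && !is.null(rownames(X)))
    X <- X[names(y), , drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 30) stop("need at least 30 training observations")
  space <- ml_search_space(learner, ncol(X))
  d <- length(space)
  set.seed(as.integer(seed))

  objective <- function(par) {
    if (learner == "rf") {
      fit <- ranger::ranger(
        x = X, y = as.numeric(y), num.trees = 500,
        mtry = min(par$mtry, ncol(X)),
        min.node.size = par$min.node.size,
        seed = seed, num.threads = 1)
      fit$prediction.error  # OOB MSE
    } else {
      folds <- sample(rep_len(1:5, n))
      errs <- vapply(1:5, function(k) {
        tr <- folds != k
        fit <- kernlab::ksvm(X[tr, , drop = FALSE], as.numeric(y)[tr],
                             type = "eps-svr", kernel = "rbfdot",
                             C = par$C, epsilon = par$epsilon)
        mean((as.numeric(y)[!tr] -
                as.numeric(kernlab::predict(fit,
                                            X[!tr, , drop = FALSE])))^2)
      }, numeric(1))
      mean(errs)
    }
  }

  n_init <- budget$init
  n_seq <- budget$seq
  U <- if (tuner == "mbo") as.matrix(lhs::maximinLHS(n_init, d))
       else matrix(stats::runif((n_init + n_seq) * d), ncol = d)
  params <- apply(U, 1, space_decode, space = space)
  zvals <- vapply(params, objective, numeric(1))
  if (tuner == "mbo") {
    for (s in seq_len(n_seq)) {
      cand <- matrix(stats::runif(300 * d), ncol = d)
      ei <- gp_expected_improvement(U, zvals, cand)
      u_new <- cand[which.max(ei), , drop = FALSE]
      p_new <- space_decode(drop(u_new), space)
      U <- rbind(U, u_new)
      params <- c(params, list(p_new))
      zvals <- c(zvals, objective(p_new))
    }
  }
  best <- params[[which.min(zvals)]]
  model <- if (learner == "rf") {
    ranger::ranger(x = X, y = as.numeric(y), num.trees = 500,
                   mtry = min(best$mtry, ncol(X)),
                   min.node.size = best$min.node.size,
                   seed = seed, num.threads = 1)
  } else {
    kernlab::ksvm(X, as.numeric(y), type = "eps-svr", kernel = "rbfdot",
                  C = best$C, epsilon = best$epsilon)
  }
  trace <- cbind(do.call(rbind, lapply(params, as.data.frame)),
                 objective = zvals)
  structure(list(learner = learner, model = model, best = best,
                 trace = trace, space = space, seed = seed),
            class = "ml_fit")
}

#' Predict from a tuned machine-learning model
#'
#' @param object an \code{ml_fit}.
#' @param features feature matrix with the same columns as at fit time.
#' @param ... ignored.
#' @return named numeric vector of predictions.
#' @export
predict.ml_fit <- function(object, features, ...) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  out <- if (object$learner == "rf")
    ranger::predictions(stats::predict(object$model, data = X,
                                       num.threads = 1))
  else as.numeric(kernlab::predict(object$model, X))
  stats::setNames(out, rownames(X))
}
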