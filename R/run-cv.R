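#' Cross-validated evaluation of the prediction models
#'
#' Runs the requested models over the requested predictor sets under a
#' cross-validation scheme: per run the models are trained on the
#' training split (machine-learning hyperparameters are re-tuned inside
#' every split) and evaluated on the masked test split by Pearson
#' correlation. Relationship matrices and kernels are computed once on
#' the full population (allele frequencies from the union of training and
#' test individuals); per-run model fits only see the training
#' phenotypes.
#'
#' @param y named numeric vector of adjusted entry means.
#' @param models any of \code{"gblup"}, \code{"bl"}, \code{"rkhs"},
#'   \code{"rf"}, \code{"svm"}. \code{"gblup"} is the NIRS-BLUP when run
#'   on the \code{"nirs"} predictor set.
#' @param predictor_sets any of \code{"snp"}, \code{"nirs"},
#'   \code{"combined"}.
#' @param geno filtered, imputed dosage matrix over all ids (required for
#'   snp/combined sets).
#' @param W preprocessed spectra matrix over all ids (required for
#'   nirs/combined sets).
#' @param fixed optional fixed-effect design over all ids (intercept plus
#'   tester indicator); default intercept only.
#' @param scheme a \code{\link{cv_scheme}}.
#' @param chain chain settings for the Bayesian models.
#' @param budget tuning budget for the machine-learning models.
#' @param bandwidths Gaussian-kernel bandwidth grid for RKHS.
#' @return object of class \code{cv_result}: \code{results} (tidy
#'   data.frame run/model/predictors/r), \code{predictions} (per
#'   model-set, test-set predictions averaged over runs), \code{scheme}.
#' @export
run_cv <- function(y, models = "gblup",
                   predictor_sets = c("snp", "nirs"),
                   geno = NULL, W = NULL, fixed = NULL,
                   scheme = cv_scheme(),
                   chain = list(niter = 3000, burnin = 1000, thin = 5),
                   budget = list(init = 12, seq = 6),
                   bandwidths = c(0.1, 0.5, 2.5)) {
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by individual id")
  models <- match.arg(models, c("gblup", "bl", "rkhs", "rf", "svm"),
                      several.ok = TRUE)
  predictor_sets <- match.arg(predictor_sets,
                              c("snp", "nirs", "combined"),
                              several.ok = TRUE)
  need_snp <- any(predictor_sets %in% c("snp", "combined"))
  need_nirs <- any(predictor_sets %in% c("nirs", "combined"))
  if (need_snp && is.null(geno)) stop("snp predictors need geno")
  if (need_nirs && is.null(W)) stop("nirs predictors need W")
  if (need_snp && !all(ids %in% rownames(geno)))
    stop("geno must cover every individual in y")
  if (need_nirs && !all(ids %in% rownames(W)))
    stop("W must cover every individual in y")
  if (need_snp) geno <- geno[ids, , drop = FALSE]
  if (need_nirs) W <- as.matrix(W)[ids, , drop = FALSE]
  if (!is.null(fixed)) fixed <- as.matrix(fixed)[ids, , drop = FALSE]

  # shared precomputations
  pre <- list()
  if (need_snp) {
    pre$G <- ensure_psd(vanraden_grm(geno))
    if ("rkhs" %in% models)
      pre$kern_snp <- gaussian_kernels(scale(geno), bandwidths)
    if (any(c("rf", "svm") %in% models)) {
      Xs <- scale(geno)
      pre$feat_snp <- Xs[, apply(Xs, 2, function(v) !anyNA(v)),
                         drop = FALSE]
    }
  }
  if (need_nirs) {
    pre$Gn <- ensure_psd(nirs_relationship(W))
    if ("rkhs" %in% models)
      pre$kern_nirs <- gaussian_kernels(W, bandwidths)
  }
  tester_cols <- if (!is.null(fixed)) {
    keep <- apply(fixed, 2, function(v) stats::sd(v) > 0)
    fixed[, keep, drop = FALSE]
  } else NULL

  fit_predict <- function(model, set, train, test, run_seed) {
    ytr <- y[train]
    if (model == "gblup") {
      kin <- switch(set, snp = list(snp = pre$G),
                    nirs = list(nirs = pre$Gn),
                    combined = list(snp = pre$G, nirs = pre$Gn))
      fit <- fit_blup(ytr, kin, fixed = fixed)
      predict(fit, test)
    } else if (model == "bl") {
      fit <- fit_bayesian_lasso(
        ytr,
        M = if (set %in% c("snp", "combined")) geno else NULL,
        W = if (set %in% c("nirs", "combined")) W else NULL,
        fixed = fixed, niter = chain$niter, burnin = chain$burnin,
        thin = chain$thin, seed = run_seed)
      predict(fit,
              M = if (set %in% c("snp", "combined")) geno else NULL,
              W = if (set %in% c("nirs", "combined")) W else NULL,
              ids = test)
    } else if (model == "rkhs") {
      kern <- switch(set, snp = pre$kern_snp, nirs = pre$kern_nirs,
                     combined = c(stats::setNames(pre$kern_snp,
                                    paste0("snp_", names(pre$kern_snp))),
                                  stats::setNames(pre$kern_nirs,
                                    paste0("nirs_", names(pre$kern_nirs)))))
      fit <- fit_rkhs_ka(ytr, kern, fixed = fixed, niter = chain$niter,
                         burnin = chain$burnin, thin = chain$thin,
                         seed = run_seed)
      predict(fit, test)
    } else {
      feat <- switch(set, snp = pre$feat_snp, nirs = W,
                     combined = cbind(pre$feat_snp, W))
      if (!is.null(tester_cols)) feat <- cbind(feat, tester_cols)
      fit <- tune_and_fit_ml(ytr, feat[train, , drop = FALSE],
                             learner = model, seed = run_seed,
                             budget = budget)
      predict(fit, feat[test, , drop = FALSE])
    }
  }

  splits <- cv_splits(scheme, ids)
  combos <- expand.grid(model = models, predictors = predictor_sets,
                        stringsAsFactors = FALSE)
  res <- list()
  pred_sum <- pred_cnt <- list()
  for (ci in seq_len(nrow(combos))) {
    key <- paste(combos$model[ci], combos$predictors[ci], sep = "_")
    pred_sum[[key]] <- stats::setNames(numeric(length(ids)), ids)
    pred_cnt[[key]] <- stats::setNames(integer(length(ids)), ids)
  }
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    run_seed <- (as.integer(scheme$seed) * 1000L + s) %% .Machine$integer.max
    for (ci in seq_len(nrow(combos))) {
      mdl <- combos$model[ci]; set <- combos$predictors[ci]
      key <- paste(mdl, set, sep = "_")
      yhat <- fit_predict(mdl, set, sp$train, sp$test, run_seed)
      r <- suppressWarnings(pearson_accuracy(y[sp$test], yhat[sp$test]))
      res[[length(res) + 1L]] <- data.frame(
        run = sp$label, model = mdl, predictors = set, r = r,
        n_train = length(sp$train), n_test = length(sp$test),
        stringsAsFactors = FALSE)
      pred_sum[[key]][sp$test] <- pred_sum[[key]][sp$test] +
        yhat[sp$test]
      pred_cnt[[key]][sp$test] <- pred_cnt[[key]][sp$test] + 1L
    }
  }
  predictions <- Map(function(s, k) {
    out <- s / pmax(k, 1L)
    out[k == 0L] <- NA_real_
    out
  }, pred_sum, pred_cnt)
  structure(list(results = do.call(rbind, res),
                 predictions = predictions, scheme = scheme,
                 observed = y),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation (%s): %d evaluations\n", x$scheme$kind,
              nrow(x$results)))
  print(summary(x))
  invisible(x)
}

#' Median accuracies of a cross-validation result
#'
#' Accuracies are aggregated as medians across runs (full per-run
#' distributions remain in \code{$results}).
#'
#' @param object a \code{cv_result}.
#' @param ... ignored.
#' @return data.frame model/predictors/median_r/n_runs.
#' @export
summary.cv_result <- function(object, ...) {
  agg <- stats::aggregate(r ~ model + predictors, data = object$results,
                          FUN = function(v) stats::median(v, na.rm = TRUE))
  names(agg)[3] <- "median_r"
  agg$n_runs <- stats::aggregate(r ~ model + predictors,
                                 data = object$results,
                                 FUN = length)$r
  agg
}

#' Selection accuracy from averaged cross-validation predictions
#'
#' Follows the selection-accuracy protocol: predictions are averaged over
#' all cross-validation runs, the top k genotypes are selected on
#' observed and on predicted values, and the outcome is classified with
#' the Czekanowski coefficient.
#'
#' @param cv a \code{cv_result}.
#' @param k selection sizes (default c(80, 40)).
#' @return data.frame with model, predictors, k, a, b, c, d, CZ.
#' @export
cv_selection_accuracy <- function(cv, k = c(80, 40)) {
  out <- list()
  for (key in names(cv$predictions)) {
    pred <- cv$predictions[[key]]
    ok <- !is.na(pred)
    parts <- strsplit(key, "_")[[1]]
    for (kk in k) {
      row <- evaluate_selection(cv$observed[ok], pred[ok], kk)
      row$model <- parts[1]
      row$predictors <- paste(parts[-1], collapse = "_")
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
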