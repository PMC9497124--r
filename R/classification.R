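# SVM training, hyperparameter search, stratified cross-validation,
# ROC/AUC with bootstrap CIs, and the four-model multimodal comparison.

# Evaluate expr under its own seed, then restore the caller's RNG
# stream, so seeded helpers do not couple their callers.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' SVM configuration
#'
#' @param kernel `"linear"`, `"poly"`, `"rbf"` or `"sigmoid"`.
#' @param C soft-margin penalty (> 0).
#' @param gamma kernel coefficient for the non-linear kernels (> 0).
#' @param degree polynomial degree (poly kernel).
#' @return list of class `SVMConfig`. The default (RBF, C = 1.1,
#'   gamma = 0.001) is the configuration the grid search favours for
#'   this screening task.
#' @export
svmConfig <- function(kernel = "rbf", C = 1.1, gamma = 0.001, degree = 3L) {
  kernel <- match.arg(kernel, c("linear", "poly", "rbf", "sigmoid"))
  if (C <= 0) stop("C must be positive")
  if (kernel != "linear" && gamma <= 0) stop("gamma must be positive")
  structure(list(kernel = kernel, C = C, gamma = gamma, degree = degree),
            class = "SVMConfig")
}

#' Default hyperparameter grid
#'
#' Spans the four kernels with `C` in {0.1, 0.5, 1.1, 4, 17, 20} and
#' `gamma` in {0.001, 0.01, 0.02, 0.1} (gamma ignored for the linear
#' kernel): the default hyperparameter search space.
#'
#' @return data.frame with columns `kernel`, `C`, `gamma`.
#' @export
defaultSVMGrid <- function() {
  Cs <- c(0.1, 0.5, 1.1, 4, 17, 20)
  gs <- c(0.001, 0.01, 0.02, 0.1)
  rbind(data.frame(kernel = "linear", C = Cs, gamma = NA_real_),
        expand.grid(kernel = c("rbf", "poly", "sigmoid"), C = Cs,
                    gamma = gs, stringsAsFactors = FALSE))
}

#' Fit a soft-margin kernel SVM
#'
#' Solves the dual soft-margin problem (box constraint `0 <= alpha_i
#' <= C`) via libsvm. The decision function is oriented so that
#' positive scores point to the MCI (+1) class regardless of libsvm's
#' internal class ordering.
#'
#' @param x numeric matrix (subjects x features), finite values.
#' @param labels +1 (MCI) / -1 (NC) vector, both classes present.
#' @param config an [svmConfig()].
#' @return list of class `cogniSVM` with the fitted model and score
#'   orientation.
#' @export
fitSVM <- function(x, labels, config = svmConfig()) {
  if (length(unique(labels)) < 2L) stop("single-class training set")
  y <- factor(ifelse(labels > 0, "MCI", "NC"), levels = c("MCI", "NC"))
  kern <- switch(config$kernel, linear = "linear", poly = "polynomial",
                 rbf = "radial", sigmoid = "sigmoid")
  m <- e1071::svm(x, y, scale = FALSE, kernel = kern,
                  cost = config$C,
                  gamma = if (config$kernel == "linear") 1 else config$gamma,
                  degree = config$degree)
  dv <- attr(predict(m, x, decision.values = TRUE), "decision.values")[, 1]
  flip <- if (mean(dv[labels > 0]) < mean(dv[labels < 0])) -1 else 1
  structure(list(model = m, flip = flip, config = config,
                 features = colnames(x)), class = "cogniSVM")
}

#' @rdname fitSVM
#' @param fit a fitted `cogniSVM`.
#' @param newx matrix of new observations (same columns as training).
#' @return `predictSVM`: list with `scores` (signed margins, positive =
#'   MCI) and `labels` (+1/-1).
#' @export
predictSVM <- function(fit, newx) {
  newx <- newx[, fit$features, drop = FALSE]
  pr <- predict(fit$model, newx, decision.values = TRUE)
  scores <- fit$flip * attr(pr, "decision.values")[, 1]
  list(scores = unname(scores), labels = ifelse(pr == "MCI", 1, -1))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)` (MCI positive) and
#' specificity `TN/(TN+FP)`, all in percent. Empty denominators yield
#' `NA` (undefined).
#'
#' @param tp,fn,tn,fp confusion counts (>= 0, total > 0).
#' @return named numeric vector `accuracy`, `sensitivity`,
#'   `specificity` (percent).
#' @export
computeMetrics <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  if (n <= 0) stop("empty confusion table")
  c(accuracy = 100 * (tp + tn) / n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

metricsFromPredictions <- function(truth, pred) {
  computeMetrics(tp = sum(truth > 0 & pred > 0),
                 fn = sum(truth > 0 & pred < 0),
                 tn = sum(truth < 0 & pred < 0),
                 fp = sum(truth < 0 & pred > 0))
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) statistic — the probability that a
#' random positive outranks a random negative, with ties counted 1/2 —
#' which equals the trapezoidal area under the empirical ROC. The 95
#' percent CI is a stratified bootstrap percentile interval.
#'
#' @param scores continuous decision scores (higher = more MCI-like).
#' @param labels +1/-1 truth, both classes present.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param ci confidence level (default 0.95).
#' @return list: `auc`, `ciLower`, `ciUpper`, `roc` (data.frame `fpr`,
#'   `tpr` from (0,0) to (1,1)).
#' @export
rocAucCI <- function(scores, labels, nBoot = 2000L, seed = 1L, ci = 0.95) {
  pos <- labels > 0
  if (!any(pos) || all(pos)) stop("both classes required")
  aucOf <- function(s, p) {
    r <- rank(s)
    (sum(r[p]) - sum(p) * (sum(p) + 1) / 2) / (sum(p) * sum(!p))
  }
  auc <- aucOf(scores, pos)
  ip <- which(pos); im <- which(!pos)
  boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- c(sample(ip, length(ip), replace = TRUE),
             sample(im, length(im), replace = TRUE))
    aucOf(scores[idx], pos[idx])
  }, numeric(1)))
  qs <- quantile(boots, c((1 - ci) / 2, 1 - (1 - ci) / 2), names = FALSE)
  # empirical ROC swept over unique thresholds
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(pos[ord]) / sum(pos)
  fpr <- cumsum(!pos[ord]) / sum(!pos)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fpr[keep], 1), tpr = c(0, tpr[keep], 1))
  list(auc = auc, ciLower = qs[1], ciUpper = qs[2], roc = roc)
}

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per subject (a true partition, class-balanced).
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 1L) {
  if (min(table(labels)) < k) stop("too few subjects per class for k folds")
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
}

# Train-only preprocessing: median imputation, normalization, optional
# MRMR selection. Returns the fitted components and transformed data.
fitFoldPipeline <- function(xTrain, yTrain, selectK = NULL,
                            mrmrCriterion = "miq", nBins = 8L) {
  med <- apply(xTrain, 2, median, na.rm = TRUE)
  impute <- function(x) {
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
    x
  }
  xTrain <- impute(xTrain)
  params <- suppressWarnings(fitNormalization(xTrain))
  xn <- applyNormalization(xTrain, params)
  ranking <- NULL
  if (!is.null(selectK) && selectK < ncol(xn)) {
    ranking <- suppressWarnings(mrmrRank(xn, yTrain, k = selectK,
                                         criterion = mrmrCriterion,
                                         nBins = nBins))
    xn <- xn[, selectedFeatures(ranking), drop = FALSE]
  }
  list(medians = med, impute = impute, params = params, ranking = ranking,
       x = xn,
       transform = function(xNew) {
       xNew <- impute(xNew)
        xNew <- applyNormalization(xNew, params)
        if (!is.null(ranking))
          xNew <- xNew[, selectedFeatures(ranking), drop = FALSE]
        xNew
      })
}

#' Stratified k-fold cross-validation of the full fold pipeline
#'
#' Subject-level stratified partition; within each fold the entire
#' pipeline — median imputation, min-max + z normalization, optional
#' MRMR selection, SVM — is fitted on the training folds only and
#' evaluated on the held-out fold. Metrics are reported per fold with
#' mean and SD; the AUC is computed on the pooled out-of-fold decision
#' scores.
#'
#' @param ft a [FeatureTable-class], or a numeric matrix with `labels`.
#' @param config an [svmConfig()].
#' @param k folds (default 5).
#' @param seed RNG seed for the partition and bootstrap.
#' @param labels +1/-1 labels when `ft` is a matrix.
#' @param selectK optional number of MRMR-selected features per fold.
#' @param mrmrCriterion `"miq"` or `"mid"`.
#' @param nBoot bootstrap resamples for the pooled AUC CI.
#' @param keepFits keep per-fold fitted components (for leakage audits).
#' @return list: `folds` (per-fold metrics data.frame), `mean`, `sd`,
#'   `auc` (pooled, from [rocAucCI()]), `scores`, `truth`, `foldId`,
#'   optionally `fits`.
#' @export
crossValidate <- function(ft, config = svmConfig(), k = 5L, seed = 1L,
                          labels = NULL, selectK = NULL,
                          mrmrCriterion = "miq", nBoot = 2000L,
                          keepFits = FALSE) {
  if (is(ft, "FeatureTable")) {
    x <- featureMatrix(ft)
    labels <- unname(classLabels(ft))
  } else x <- ft
  fold <- stratifiedFolds(labels, k = k, seed = seed)
  scores <- numeric(length(labels))
  pred <- numeric(length(labels))
  fits <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    pipe <- fitFoldPipeline(x[tr, , drop = FALSE], labels[tr],
                            selectK = selectK,
                            mrmrCriterion = mrmrCriterion)
    fit <- fitSVM(pipe$x, labels[tr], config)
    pv <- predictSVM(fit, pipe$transform(x[!tr, , drop = FALSE]))
    scores[!tr] <- pv$scores
    pred[!tr] <- pv$labels
    rows[[f]] <- data.frame(fold = f,
                            t(metricsFromPredictions(labels[!tr], pv$labels)))
    if (keepFits) fits[[f]] <- list(pipe = pipe, fit = fit)
  }
  folds <- do.call(rbind, rows)
  mets <- c("accuracy", "sensitivity", "specificity")
  out <- list(folds = folds,
              mean = colMeans(folds[mets], na.rm = TRUE),
              sd = apply(folds[mets], 2, sd, na.rm = TRUE),
              auc = rocAucCI(scores, labels, nBoot = nBoot, seed = seed),
              scores = scores, truth = labels, foldId = fold)
  if (keepFits) out$fits <- fits
  out
}

#' Cross-validated hyperparameter grid search
#'
#' Evaluates every grid row by stratified `k`-fold CV and returns the
#' configuration maximizing mean accuracy. Ties are broken by smaller
#' `C`, then kernel order linear < rbf < poly < sigmoid.
#'
#' @param ft a [FeatureTable-class] or matrix (see [crossValidate()]).
#' @param grid data.frame `kernel`, `C`, `gamma` (default
#'   [defaultSVMGrid()]).
#' @inheritParams crossValidate
#' @return list: `best` ([svmConfig()]), `results` (per-config CV
#'   metrics).
#' @export
gridSearch <- function(ft, grid = defaultSVMGrid(), k = 5L, seed = 1L,
                       labels = NULL, selectK = NULL) {
  if (nrow(grid) == 0L) stop("empty grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- svmConfig(kernel = as.character(grid$kernel[i]), C = grid$C[i],
                     gamma = if (is.na(grid$gamma[i])) 1 else grid$gamma[i])
    cv <- crossValidate(ft, cfg, k = k, seed = seed, labels = labels,
                        selectK = selectK, nBoot = 200L)
    data.frame(kernel = cfg$kernel, C = cfg$C,
               gamma = if (cfg$kernel == "linear") NA_real_ else cfg$gamma,
               accuracy = cv$mean["accuracy"], accuracySd = cv$sd["accuracy"],
               sensitivity = cv$mean["sensitivity"],
               specificity = cv$mean["specificity"], auc = cv$auc$auc)
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  kernelOrder <- c(linear = 1, rbf = 2, poly = 3, sigmoid = 4)
  ord <- order(-results$accuracy, results$C, kernelOrder[results$kernel])
  bestRow <- results[ord[1], ]
  list(best = svmConfig(kernel = bestRow$kernel, C = bestRow$C,
                        gamma = if (is.na(bestRow$gamma)) 0.001
                                else bestRow$gamma),
       results = results)
}

#' Four-model multimodal comparison with an independent test cohort
#'
#' For each comparison view (clinical, NTB-only, physiological-only,
#' combined): stratified 5-fold cross-validation on cohort 1; then the
#' pipeline is refit once on all of cohort 1 and evaluated single-shot
#' on cohort 2 (no information flows back). Test-cohort metric
#' dispersion is reported as a bootstrap SD over cohort-2 resamples.
#'
#' @param tables1 modality tables for cohort 1 (list `clinical`, `ntb`,
#'   `eeg`, `et`, as from [cohortFeatureTables()]).
#' @param tables2 optional modality tables for the independent cohort 2.
#' @param config an [svmConfig()].
#' @param k CV folds.
#' @param seed RNG seed.
#' @param selectK optional MRMR selection size per fit.
#' @param nBoot bootstrap resamples for AUC CIs.
#' @param views comparison views to run.
#' @return An [EvaluationReport-class].
#' @export
compareModels <- function(tables1, tables2 = NULL, config = svmConfig(),
                          k = 5L, seed = 1L, selectK = NULL,
                          nBoot = 2000L,
                          views = c("clinical", "ntb_only", "physio_only",
                                    "all")) {
  cvRows <- list(); testRows <- list(); roc <- list(); folds <- list()
  for (v in views) {
    ft1 <- assembleFeatures(tables1$clinical, tables1$ntb, tables1$eeg,
                            tables1$et, view = v)
    cv <- crossValidate(ft1, config, k = k, seed = seed, selectK = selectK,
                        nBoot = nBoot)
    cvRows[[v]] <- data.frame(
      view = v, accuracy = cv$mean["accuracy"], accuracySd = cv$sd["accuracy"],
      sensitivity = cv$mean["sensitivity"],
      sensitivitySd = cv$sd["sensitivity"],
      specificity = cv$mean["specificity"],
      specificitySd = cv$sd["specificity"],
      auc = cv$auc$auc, aucLower = cv$auc$ciLower, aucUpper = cv$auc$ciUpper)
    roc[[paste0("cohort1_", v)]] <- cv$auc$roc
    folds[[v]] <- cv$folds

    if (!is.null(tables2)) {
      ft2 <- assembleFeatures(tables2$clinical, tables2$ntb, tables2$eeg,
                              tables2$et, view = v)
      x1 <- featureMatrix(ft1); y1 <- unname(classLabels(ft1))
      x2 <- featureMatrix(ft2); y2 <- unname(classLabels(ft2))
      common <- intersect(colnames(x1), colnames(x2))
      pipe <- fitFoldPipeline(x1[, common, drop = FALSE], y1,
                              selectK = selectK)
      fit <- fitSVM(pipe$x, y1, config)
      pv <- predictSVM(fit, pipe$transform(x2[, common, drop = FALSE]))
      met <- metricsFromPredictions(y2, pv$labels)
      aucT <- rocAucCI(pv$scores, y2, nBoot = nBoot, seed = seed)
      # bootstrap dispersion of the single-shot metrics over cohort-2 draws
      bootMet <- withSeed(derivedSeed(seed, paste0("testboot_", v)),
        t(vapply(seq_len(200L), function(b) {
          idx <- c(sample(which(y2 > 0), sum(y2 > 0), replace = TRUE),
                   sample(which(y2 < 0), sum(y2 < 0), replace = TRUE))
          metricsFromPredictions(y2[idx], pv$labels[idx])
        }, numeric(3))))
      testRows[[v]] <- data.frame(
        view = v, accuracy = met["accuracy"],
        accuracySd = sd(bootMet[, "accuracy"]),
        sensitivity = met["sensitivity"],
        sensitivitySd = sd(bootMet[, "sensitivity"]),
        specificity = met["specificity"],
        specificitySd = sd(bootMet[, "specificity"]),
        auc = aucT$auc, aucLower = aucT$ciLower, aucUpper = aucT$ciUpper)
      roc[[paste0("cohort2_", v)]] <- aucT$roc
    }
  }
  cvDf <- do.call(rbind, cvRows); rownames(cvDf) <- NULL
  testDf <- if (length(testRows)) do.call(rbind, testRows) else
    data.frame()
  rownames(testDf) <- NULL
  new("EvaluationReport", cv = cvDf, test = testDf, roc = roc,
      folds = folds,
      config = list(svm = unclass(config), k = k, seed = seed,
                    selectK = selectK))
}
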