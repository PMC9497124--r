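blobs <- function(n = 60, gap = 4, seed = 23) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  x <- cbind(f1 = y * gap / 2 + rnorm(n), f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("the SVM separates blobs and honours the label symmetry", {
  b <- blobs()
  fit <- fitSVM(b$x, b$y, svmConfig("linear", C = 1))
  pr <- predictSVM(fit, b$x)
  expect_identical(pr$labels, b$y)
  # flipping labels flips the oriented decision scores
  fit2 <- fitSVM(b$x, -b$y, svmConfig("linear", C = 1))
  pr2 <- predictSVM(fit2, b$x)
  expect_equal(pr2$scores, -pr$scores, tolerance = 1e-6)
  expect_error(fitSVM(b$x, rep(1, nrow(b$x))), "single-class")
  # the default RBF operating point is a valid config
  cfg <- svmConfig("rbf", C = 1.1, gamma = 0.001)
  expect_s3_class(fitSVM(b$x, b$y, cfg)$model, "svm")
  expect_error(svmConfig(C = -1), "positive")
})

test_that("metrics arithmetic and undefined denominators", {
  m <- computeMetrics(tp = 43, fn = 7, tn = 45, fp = 5)
  expect_equal(unname(m), c(88, 86, 90))
  expect_equal(unname(computeMetrics(50, 0, 50, 0)), c(100, 100, 100))
  m0 <- computeMetrics(tp = 0, fn = 0, tn = 10, fp = 2)
  expect_true(is.na(m0[["sensitivity"]]))
  expect_error(computeMetrics(0, 0, 0, 0), "empty")
})

test_that("AUC equals the Mann-Whitney pair statistic and is rank-invariant", {
  set.seed(24)
  y <- rep(c(1, -1), each = 30)
  s <- y * 2 + rnorm(60)
  a <- rocAucCI(s, y, nBoot = 200, seed = 1)
  expect_equal(a$auc, aucPairOracle(s, y), tolerance = 1e-12)
  # ties handled as half-wins
  st <- round(s)
  expect_equal(rocAucCI(st, y, nBoot = 50, seed = 1)$auc,
               aucPairOracle(st, y), tolerance = 1e-12)
  # invariant to strictly monotone transforms of the scores
  expect_equal(rocAucCI(exp(s), y, nBoot = 50, seed = 1)$auc, a$auc,
               tolerance = 1e-12)
  # perfect ranking
  expect_equal(rocAucCI(y * 10, y, nBoot = 50, seed = 1)$auc, 1.0)
  # agrees with an independent ROC implementation
  expect_equal(a$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
  expect_true(a$ciLower <= a$auc && a$auc <= a$ciUpper)
  # ROC points are monotone and span the unit square
  expect_true(all(diff(a$roc$fpr) >= 0) && all(diff(a$roc$tpr) >= 0))
  expect_equal(unlist(a$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(a$roc[nrow(a$roc), ]), c(fpr = 1, tpr = 1))
  expect_error(rocAucCI(s, rep(1, 60)), "both classes")
})

test_that("random scores give chance-level AUC", {
  set.seed(25)
  y <- rep(c(1, -1), each = 100)
  aucs <- replicate(10, rocAucCI(rnorm(200), y, nBoot = 10, seed = 1)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 3 * 0.5 / sqrt(100 * 10)) # ~3 SE
})

test_that("stratified folds partition subjects with balanced classes", {
  y <- rep(c(1, -1), c(60, 40))
  f <- stratifiedFolds(y, k = 5, seed = 2)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 20))
  expect_true(all(table(f[y == 1]) == 12))
  expect_error(stratifiedFolds(rep(c(1, -1), c(3, 50)), k = 5), "too few")
})

test_that("cross-validation partitions subjects and reports fold dispersion", {
  b <- blobs(n = 100, gap = 3)
  cv <- crossValidate(b$x, svmConfig("linear", C = 1), k = 5, seed = 3,
                      labels = b$y, nBoot = 100)
  expect_identical(nrow(cv$folds), 5L)
  expect_true(all(table(cv$foldId) == 20))
  expect_gt(cv$mean[["accuracy"]], 85)
  expect_true(is.finite(cv$sd[["accuracy"]]))
  expect_gt(cv$auc$auc, 0.9)
})

test_that("permuted labels drive CV accuracy to chance", {
  set.seed(26)
  accs <- vapply(1:5, function(s) {
    b <- blobs(n = 60, gap = 3, seed = 100 + s)
    yPerm <- sample(b$y)
    crossValidate(b$x, svmConfig("linear", C = 1), k = 5, seed = s,
                  labels = yPerm, nBoot = 10)$mean[["accuracy"]]
  }, numeric(1))
  se <- 100 * 0.5 / sqrt(60 * 5)
  expect_lt(abs(mean(accs) - 50), 4 * se)
})

test_that("grid search honours ties and degenerate grids", {
  b <- blobs(n = 80, gap = 6) # strongly separated: most configs perfect
  oneRow <- data.frame(kernel = "rbf", C = 1.1, gamma = 0.001)
  gs1 <- gridSearch(b$x, grid = oneRow, labels = b$y, seed = 4)
  expect_identical(gs1$best$kernel, "rbf")
  expect_equal(gs1$best$C, 1.1)
  smallGrid <- data.frame(kernel = c("linear", "rbf", "poly"),
                          C = c(4, 0.5, 4), gamma = c(NA, 0.1, 0.1))
  gs <- gridSearch(b$x, grid = smallGrid, labels = b$y, seed = 4)
  top <- max(gs$results$accuracy)
  winners <- gs$results[gs$results$accuracy == top, ]
  expect_equal(min(winners$C), gs$best$C) # smaller C wins the tie
  expect_error(gridSearch(b$x, grid = smallGrid[0, ], labels = b$y), "empty")
  # the default grid spans all four kernels and the printed C / gamma sets
  g <- defaultSVMGrid()
  expect_setequal(unique(g$kernel), c("linear", "poly", "rbf", "sigmoid"))
  expect_true(all(c(0.1, 0.5, 1.1, 4, 17, 20) %in% g$C))
  expect_true(all(c(0.001, 0.01, 0.02, 0.1) %in% g$gamma[!is.na(g$gamma)]))
})

test_that("fold pipelines are blind to the held-out fold", {
  set.seed(27)
  n <- 80
  y <- rep(c(1, -1), each = n / 2)
  x <- cbind(matrix(rnorm(n * 4), n), y + rnorm(n))
  colnames(x) <- c(paste0("ntb.s", 1:2), "eeg.a", "et.b", "eeg.c")
  cv1 <- crossValidate(x, svmConfig("linear", C = 1), k = 4, seed = 5,
                       labels = y, selectK = 3, nBoot = 10, keepFits = TRUE)
  # perturb exactly the subjects held out in fold 1
  x2 <- x
  hold <- cv1$foldId == 1
  x2[hold, ] <- x2[hold, ] + matrix(rnorm(sum(hold) * 5, 0, 5), sum(hold))
  cv2 <- crossValidate(x2, svmConfig("linear", C = 1), k = 4, seed = 5,
                       labels = y, selectK = 3, nBoot = 10, keepFits = TRUE)
  f1 <- cv1$fits[[1]]; f2 <- cv2$fits[[1]]
  expect_identical(f1$pipe$params, f2$pipe$params)        # normalization
  expect_identical(selectedFeatures(f1$pipe$ranking),
                   selectedFeatures(f2$pipe$ranking))     # MRMR
  expect_identical(f1$fit$model$coefs, f2$fit$model$coefs) # SVM dual coefs
})
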