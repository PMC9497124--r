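mkTables <- function(n = 8, seed = 21) {
  set.seed(seed)
  ids <- sprintf("s%02d", 1:n)
  group <- rep(c("NC", "MCI"), length.out = n)
  clinical <- data.frame(subject_id = ids, group = group,
                         age = rnorm(n, 70, 5),
                         gender = rep(c("M", "F"), length.out = n),
                         education = rpois(n, 9),
                         moca_b = rnorm(n, 26, 2), ace_r = rnorm(n, 70, 8))
  ntb <- data.frame(subject_id = ids,
                    sub01 = rnorm(n, 10, 3), sub02 = rnorm(n, 10, 3),
                    total = rnorm(n, 200, 20), response_time = rnorm(n, 300, 30))
  eeg <- data.frame(subject_id = ids, eeg.abs_alpha = rnorm(n, 40, 5),
                    eeg.apen = rnorm(n, 0.7, 0.1))
  et <- data.frame(subject_id = ids, et.fixation_time = rnorm(n, 0.25, 0.05),
                   et.gaze_lzc = rnorm(n, 0.4, 0.05))
  list(clinical = clinical, ntb = ntb, eeg = eeg, et = et)
}

test_that("NTB cleaning drops out-of-range cells and sparse subjects", {
  ntb <- data.frame(subject_id = c("a", "b", "c"),
                    sub01 = c(10, 35, 12), sub02 = c(8, 9, NA),
                    total = c(180, 200, 150), response_time = c(300, 280, 320))
  res <- cleanNTB(ntb, ntbRanges(2))
  expect_true(is.na(res$table$sub01[res$table$subject_id == "b"]))
  expect_match(res$log, "out-of-range", all = FALSE)
  # subject missing > 50% of subtests is dropped
  ntb2 <- data.frame(subject_id = c("a", "b"),
                     sub01 = c(10, NA), sub02 = c(9, NA), sub03 = c(8, NA),
                     sub04 = c(7, 12))
  res2 <- cleanNTB(ntb2, ntbRanges(4))
  expect_identical(res2$table$subject_id, "a")
  # an all-valid table passes through unchanged
  good <- data.frame(subject_id = "a", sub01 = 10, sub02 = 9, total = 19,
                     response_time = 250)
  expect_identical(cleanNTB(good, ntbRanges(2))$table, good)
  expect_error(cleanNTB(good, NULL), "ranges")
})

test_that("normalization composes min-max then z using training parameters", {
  x <- cbind(ntb.a = c(10, 20, 30), other = c(1, 2, 4))
  params <- fitNormalization(x)
  # min-max step: (20 - 10) / (30 - 10) = 0.5 before the z step
  mmMid <- (20 - params$minmax$ntb.a["min"]) /
    (params$minmax$ntb.a["max"] - params$minmax$ntb.a["min"])
  expect_equal(unname(mmMid), 0.5)
  z <- applyNormalization(x, params)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-9)
  # held-out data keeps the training transform: means need not be 0
  held <- cbind(ntb.a = c(40, 50, 55), other = c(9, 9, 10))
  zh <- applyNormalization(held, params)
  expect_gt(abs(mean(zh[, "ntb.a"])), 0.5)
  expect_warning(fitNormalization(cbind(k = c(1, 1, 1))), "constant")
  expect_error(fitNormalization(x[0, , drop = FALSE]), "empty")
})

test_that("views select exactly their modality blocks and nest in 'all'", {
  tabs <- mkTables()
  ftAll <- assembleFeatures(tabs$clinical, tabs$ntb, tabs$eeg, tabs$et, "all")
  ftPhys <- assembleFeatures(tabs$clinical, tabs$ntb, tabs$eeg, tabs$et,
                             "physio_only")
  expect_setequal(rownames(ftPhys),
                  c("eeg.abs_alpha", "eeg.apen", "et.fixation_time",
                    "et.gaze_lzc"))
  for (v in c("clinical", "ntb_only", "physio_only")) {
    ft <- assembleFeatures(tabs$clinical, tabs$ntb, tabs$eeg, tabs$et, v)
    expect_true(all(rownames(ft) %in% rownames(ftAll)))
  }
  ftClin <- assembleFeatures(tabs$clinical, tabs$ntb, tabs$eeg, tabs$et,
                             "clinical")
  expect_true("clinical.gender_m" %in% rownames(ftClin)) # one-hot encoded
  expect_identical(ncol(ftAll), 8L)
  expect_true(all(classLabels(ftAll) %in% c(1, -1)))
  # column count of 'all' is the sum of the modality blocks
  nPer <- vapply(c("clinical", "ntb_only", "physio_only"), function(v)
    nrow(assembleFeatures(tabs$clinical, tabs$ntb, tabs$eeg, tabs$et, v)),
    integer(1))
  expect_identical(nrow(ftAll), sum(nPer))
})

test_that("the join is inner and rejects duplicate subjects", {
  tabs <- mkTables()
  tabs$et <- tabs$et[-3, ] # subject s03 has no ET data
  ft <- assembleFeatures(tabs$clinical, tabs$ntb, tabs$eeg, tabs$et, "all")
  expect_false("s03" %in% colnames(ft))
  expect_identical(ncol(ft), 7L)
  tabs2 <- mkTables()
  tabs2$eeg <- rbind(tabs2$eeg, tabs2$eeg[1, ])
  expect_error(assembleFeatures(tabs2$clinical, tabs2$ntb, tabs2$eeg,
                                tabs2$et, "all"), "duplicated")
})

test_that("group statistics run the declared test per variable", {
  set.seed(22)
  demo <- data.frame(subject_id = sprintf("s%02d", 1:40),
                     group = rep(c("NC", "MCI"), each = 20),
                     age = rnorm(40, 70, 5),
                     gender = sample(c("M", "F"), 40, TRUE),
                     education = rpois(40, 9),
                     moca_b = rnorm(40, 26, 2), ace_r = rnorm(40, 70, 8))
  st <- groupStatistics(demo)
  expect_setequal(st$variable, c("age", "gender", "education", "moca_b",
                                 "ace_r"))
  expect_identical(st$test[st$variable == "gender"], "chi-square")
  expect_identical(st$test[st$variable == "education"], "Wilcoxon rank-sum")
  # identical groups: t statistic exactly 0
  demo2 <- demo
  demo2$age <- rep(demo$age[1:20], 2)
  st2 <- groupStatistics(demo2)
  expect_equal(st2$statistic[st2$variable == "age"], 0, tolerance = 1e-12)
  # chi-square agrees with the direct Pearson formula
  tab <- table(demo$group, demo$gender)
  expect_equal(st$statistic[st$variable == "gender"], chisqOracle(tab),
               tolerance = 1e-9)
  expect_error(groupStatistics(demo[c(1, 21), ]), "at least 2")
})

test_that("reported statistics match hand computation on fixed tables", {
  # gender split [[30,18],[28,16]] by direct Pearson formula
  demo <- data.frame(
    subject_id = sprintf("s%03d", 1:92),
    group = rep(c("NC", "MCI"), c(48, 44)),
    age = rep(c(68, 72), 46),             # equal group means, nonzero SD
    gender = c(rep("M", 30), rep("F", 18), rep("M", 28), rep("F", 16)),
    education = rep(c(6, 9, 12, 16), 23), # same distribution in both groups
    moca_b = rep(c(25, 27), 46), ace_r = rep(c(69, 71), 46))
  st <- groupStatistics(demo)
  tab <- matrix(c(30, 28, 18, 16), nrow = 2)
  expect_equal(st$statistic[st$variable == "gender"], chisqOracle(tab),
               tolerance = 1e-12)
  # education identical in both groups: rank-sum statistic at its null
  # mean n1*n2/2 and t statistic for age exactly 0
  expect_equal(st$statistic[st$variable == "education"], 48 * 44 / 2,
               tolerance = 1e-9)
  expect_equal(st$statistic[st$variable == "age"], 0, tolerance = 1e-12)
})
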