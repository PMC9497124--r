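# Joining modalities into the subjects x features table, NTB cleaning,
# train-only normalization, and the group-comparison statistics.

#' FeatureTable: subjects x features with modality tags
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' `features` (features in rows, subjects in columns), a `modality` tag
#' (clinical / ntb / eeg / et) per feature in `rowData`, and `group` /
#' `label` (MCI = +1, NC = -1) per subject in `colData`.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"modality" %in% names(rowData(object)))
    return("rowData must carry a 'modality' tag per feature")
  if (!all(c("group", "label") %in% names(colData(object))))
    return("colData must carry 'group' and 'label'")
  if (!all(object$label %in% c(1, -1)))
    return("labels must be +1 (MCI) or -1 (NC)")
  TRUE
})

#' Construct a FeatureTable from a joined feature data.frame
#'
#' @param df data.frame with `subject_id`, `group` (`NC`/`MCI`) and
#'   numeric feature columns named `<modality>.<feature>`.
#' @return A [FeatureTable-class].
#' @export
featureTable <- function(df) {
  if (anyDuplicated(df$subject_id)) stop("duplicated subject_id")
  featCols <- setdiff(names(df), c("subject_id", "group"))
  modality <- sub("\\..*$", "", featCols)
  mat <- t(as.matrix(df[, featCols, drop = FALSE]))
  colnames(mat) <- df$subject_id
  se <- SummarizedExperiment(
    assays = list(features = mat),
    rowData = DataFrame(modality = modality, row.names = featCols),
    colData = DataFrame(group = df$group,
                        label = ifelse(df$group == "MCI", 1, -1),
                        row.names = df$subject_id))
  new("FeatureTable", se)
}

#' @rdname featureTable
#' @param ft a `FeatureTable`
#' @return `featureMatrix`: subjects x features numeric matrix.
#' @export
featureMatrix <- function(ft) t(assay(ft, "features"))

#' @rdname featureTable
#' @return `classLabels`: named +1/-1 vector (MCI positive).
#' @export
classLabels <- function(ft) setNames(ft$label, colnames(ft))

#' @rdname featureTable
#' @param view one of `"clinical"`, `"ntb_only"`, `"physio_only"`,
#'   `"all"` — the four comparison models.
#' @return `selectView`: the `FeatureTable` restricted to the view's
#'   modalities.
#' @export
selectView <- function(ft, view = c("all", "clinical", "ntb_only",
                                    "physio_only")) {
  view <- match.arg(view)
  mods <- switch(view,
                 clinical = "clinical",
                 ntb_only = "ntb",
                 physio_only = c("eeg", "et"),
                 all = c("clinical", "ntb", "eeg", "et"))
  keep <- rowData(ft)$modality %in% mods
  if (!any(keep)) stop("view '", view, "' selects no features")
  ft[keep, ]
}

#' Declared valid ranges for the neuropsychological battery
#'
#' @param nSubtests number of subtests (default 20, each scored 0-20).
#' @return data.frame `column`, `lo`, `hi`.
#' @export
ntbRanges <- function(nSubtests = 20L) {
  data.frame(column = c(sprintf("sub%02d", seq_len(nSubtests)), "total",
                        "response_time"),
             lo = c(rep(0, nSubtests), 0, 0),
             hi = c(rep(20, nSubtests), 20 * nSubtests, 3600))
}

#' Clean the neuropsychological battery table
#'
#' Cells outside their declared valid range are set missing and logged;
#' subjects missing more than half of the subtests are dropped.
#'
#' @param ntb data.frame with `subject_id` and score columns.
#' @param ranges data.frame as from [ntbRanges()].
#' @return list: `table` (cleaned), `log` (character vector of actions).
#' @export
cleanNTB <- function(ntb, ranges = ntbRanges()) {
  if (is.null(ranges) || !nrow(ranges)) stop("no declared ranges")
  log <- character()
  for (k in seq_len(nrow(ranges))) {
    cl <- ranges$column[k]
    if (!cl %in% names(ntb)) next
    bad <- which(!is.na(ntb[[cl]]) &
                 (ntb[[cl]] < ranges$lo[k] | ntb[[cl]] > ranges$hi[k]))
    if (length(bad)) {
      log <- c(log, sprintf("%s: out-of-range value %g for %s set missing",
                            cl, ntb[[cl]][bad], ntb$subject_id[bad]))
      ntb[[cl]][bad] <- NA
    }
  }
  subCols <- grep("^sub[0-9]+$", names(ntb), value = TRUE)
  if (length(subCols)) {
    missFrac <- rowMeans(is.na(ntb[, subCols, drop = FALSE]))
    drop <- missFrac > 0.5
    if (any(drop)) {
      log <- c(log, sprintf("subject %s dropped: %.0f%% of subtests missing",
                            ntb$subject_id[drop], 100 * missFrac[drop]))
      ntb <- ntb[!drop, , drop = FALSE]
    }
  }
  list(table = ntb, log = log)
}

#' Fit / apply train-only feature normalization
#'
#' NTB raw scores are min-max scaled into `[0, 1]` using training
#' min/max; all features are then z-transformed using training mean/SD.
#' Columns constant in training are dropped with a warning. Parameters
#' are fit on training data only — applying them to held-out data leaks
#' nothing.
#'
#' @param x numeric matrix (subjects x features), training data.
#' @param minmaxCols columns (names) to min-max scale first; default all
#'   `ntb.*` columns.
#' @return `fitNormalization`: list of class `NormalizationParams`.
#' @export
fitNormalization <- function(x, minmaxCols = grep("^ntb\\.", colnames(x),
                                                  value = TRUE)) {
  if (nrow(x) == 0L) stop("empty training set")
  minmaxCols <- intersect(minmaxCols, colnames(x))
  mm <- lapply(minmaxCols, function(cl) {
    r <- range(x[, cl], na.rm = TRUE)
    c(min = r[1], max = r[2])
  })
  names(mm) <- minmaxCols
  xs <- x
  for (cl in minmaxCols) {
    d <- mm[[cl]]["max"] - mm[[cl]]["min"]
    if (d > 0) xs[, cl] <- (xs[, cl] - mm[[cl]]["min"]) / d
  }
  mu <- colMeans(xs, na.rm = TRUE)
  sdv <- apply(xs, 2, stats::sd, na.rm = TRUE)
  dropped <- colnames(x)[is.na(sdv) | sdv == 0]
  if (length(dropped))
    warning("constant columns dropped: ", paste(dropped, collapse = ", "))
  structure(list(minmax = mm, mean = mu, sd = sdv, dropped = dropped),
            class = "NormalizationParams")
}

#' @rdname fitNormalization
#' @param params a `NormalizationParams` from `fitNormalization`.
#' @return `applyNormalization`: the transformed matrix (dropped columns
#'   removed).
#' @export
applyNormalization <- function(x, params) {
  keep <- setdiff(colnames(x), params$dropped)
  x <- x[, keep, drop = FALSE]
  for (cl in intersect(names(params$minmax), keep)) {
    d <- params$minmax[[cl]]["max"] - params$minmax[[cl]]["min"]
    if (d > 0) x[, cl] <- (x[, cl] - params$minmax[[cl]]["min"]) / d
  }
  sweep(sweep(x, 2, params$mean[keep], "-"), 2, params$sd[keep], "/")
}

#' Assemble modalities into one FeatureTable
#'
#' Inner-joins the clinical, NTB, EEG and ET per-subject tables on
#' `subject_id` (subjects absent from any modality are excluded), one-hot
#' encodes gender, prefixes columns with their modality, and restricts
#' to the requested comparison view.
#'
#' @param clinical data.frame: `subject_id`, `group`, `age`, `gender`,
#'   `education`, `moca_b`, `ace_r`.
#' @param ntb data.frame: `subject_id` + score columns.
#' @param eeg data.frame: `subject_id` + `eeg.*` columns.
#' @param et data.frame: `subject_id` + `et.*` columns.
#' @param view comparison model (see [selectView()]).
#' @return A [FeatureTable-class].
#' @export
assembleFeatures <- function(clinical, ntb, eeg, et, view = "all") {
  for (d in list(clinical, ntb, eeg, et))
    if (anyDuplicated(d$subject_id)) stop("duplicated subject_id")
  cl <- data.frame(subject_id = clinical$subject_id,
                   group = clinical$group,
                   clinical.age = clinical$age,
                   clinical.gender_m = as.numeric(clinical$gender == "M"),
                   clinical.education = clinical$education,
                   clinical.moca_b = clinical$moca_b,
                   clinical.ace_r = clinical$ace_r)
  nt <- ntb
  names(nt)[-1] <- paste0("ntb.", names(nt)[-1])
  j <- merge(cl, nt, by = "subject_id")
  j <- merge(j, eeg, by = "subject_id")
  j <- merge(j, et, by = "subject_id")
  if (nrow(j) == 0L) stop("empty join: no subject present in all modalities")
  j <- j[order(j$subject_id), , drop = FALSE]
  selectView(featureTable(j), view)
}

#' Group-comparison statistics for demographics and cognition
#'
#' Per variable: Welch two-sample t-test for continuous measures
#' (age, MoCA-B, ACE-R), Pearson chi-square without continuity
#' correction for gender, and the Wilcoxon rank-sum test for years of
#' education; reports group mean (or count) and SD plus the test
#' statistic and p value.
#'
#' @param demo demographics data.frame with `group`, `age`, `gender`,
#'   `education`, `moca_b`, `ace_r`.
#' @return data.frame, one row per variable.
#' @export
groupStatistics <- function(demo) {
  g <- demo$group
  if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
  cont <- function(v, test = c("t", "wilcoxon")) {
    test <- match.arg(test)
    x <- demo[[v]][g == "NC"]; y <- demo[[v]][g == "MCI"]
    res <- if (test == "t") t.test(x, y) else
      suppressWarnings(wilcox.test(x, y, exact = FALSE))
    data.frame(variable = v, test = if (test == "t") "two-sample t"
               else "Wilcoxon rank-sum",
               nc_mean = mean(x), nc_sd = stats::sd(x),
               mci_mean = mean(y), mci_sd = stats::sd(y),
               statistic = unname(res$statistic), p = res$p.value)
  }
  tab <- table(g, demo$gender)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  gender <- data.frame(variable = "gender", test = "chi-square",
                       nc_mean = mean(demo$gender[g == "NC"] == "M"),
                       nc_sd = NA, mci_mean = mean(demo$gender[g == "MCI"] == "M"),
                       mci_sd = NA, statistic = unname(chi$statistic),
                       p = chi$p.value)
  out <- rbind(cont("age"), gender, cont("education", "wilcoxon"),
               cont("moca_b"), cont("ace_r"))
  rownames(out) <- NULL
  out
}

#' Per-subject feature tables for a whole synthetic cohort
#'
#' Runs the full preprocessing + feature-extraction chain on every
#' subject: electrode-offset screening (invalid recordings excluded),
#' denoising, segmentation and EEG features; gaze preprocessing and ET
#' features; NTB cleaning. Returns the four modality tables
#' [assembleFeatures()] consumes.
#'
#' @param cohort list from [generateCohort()].
#' @param eegConfig list from [eegFeatureConfig()].
#' @param windowS,overlapFrac segmentation parameters.
#' @param passband,notch [denoiseEEG()] parameters.
#' @return list: `clinical`, `ntb`, `eeg`, `et` data.frames plus
#'   `excluded` (subject ids dropped at EEG validation).
#' @export
cohortFeatureTables <- function(cohort, eegConfig = eegFeatureConfig(),
                                windowS = 5, overlapFrac = 0.6,
                                passband = c(0.5, 30), notch = 50) {
  excluded <- character()
  eegRows <- list()
  for (id in names(cohort$recordings)) {
    rec <- detectElectrodeOffset(cohort$recordings[[id]])
    if (!isValidRecording(rec)) {
      excluded <- c(excluded, id)
      next
    }
    rec <- denoiseEEG(rec, passband = passband, notch = notch)
    segs <- segmentSignal(rec, windowS = windowS, overlapFrac = overlapFrac)
    eegRows[[id]] <- extractEEGFeatures(segs, eegConfig)
  }
  eeg <- data.frame(subject_id = names(eegRows),
                    do.call(rbind, eegRows), check.names = FALSE)
  etRows <- lapply(cohort$gaze, function(gs)
    extractETFeatures(preprocessGaze(gs)))
  et <- data.frame(subject_id = names(etRows),
                   do.call(rbind, etRows), check.names = FALSE)
  rownames(eeg) <- rownames(et) <- NULL
  ntb <- cleanNTB(cohort$ntb)$table
  list(clinical = cohort$demographics, ntb = ntb, eeg = eeg, et = et,
       excluded = excluded)
}
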