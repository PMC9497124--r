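#' EEGRecording: one subject's single-channel EEG trace
#'
#' Holds a single-channel EEG time series in microvolts together with its
#' sample rate, subject identifier, and a validity state set by
#' [detectElectrodeOffset()]. Invalid recordings are excluded from all
#' downstream feature tables rather than repaired.
#'
#' @slot samples numeric vector of samples (uV).
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot valid logical scalar; `FALSE` once the recording is flagged
#'   (electrode offset, saturation, flatline).
#' @slot reasons character vector of reasons the recording was flagged.
#' @export
setClass("EEGRecording",
  representation(samples = "numeric", fs = "numeric",
                 subjectId = "character", valid = "logical",
                 reasons = "character"),
  prototype(valid = TRUE, reasons = character()))

setValidity("EEGRecording", function(object) {
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (length(object@samples) < 1L)
    return("recording must contain at least one sample")
  if (length(object@valid) != 1L)
    return("valid must be a logical scalar")
  TRUE
})

#' Construct an EEGRecording
#'
#' @param samples numeric vector of EEG samples (uV).
#' @param fs sampling rate (Hz), > 0.
#' @param subjectId subject identifier string.
#' @return An [EEGRecording-class] object (valid by construction).
#' @examples
#' rec <- EEGRecording(sin(2 * pi * 10 * seq(0, 1, by = 1/256)), fs = 256)
#' @export
EEGRecording <- function(samples, fs, subjectId = "subject") {
  new("EEGRecording", samples = as.numeric(samples), fs = as.numeric(fs),
      subjectId = as.character(subjectId), valid = TRUE,
      reasons = character())
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d samples @ %g Hz (%.1f s), %s\n",
              object@subjectId, length(object@samples), object@fs,
              length(object@samples) / object@fs,
              if (object@valid) "valid"
              else paste0("INVALID [", paste(object@reasons, collapse = ", "), "]")))
})

#' @describeIn EEGRecording-class signal samples (uV)
#' @param x,object an `EEGRecording`
#' @export
setGeneric("eegSamples", function(x) standardGeneric("eegSamples"))
#' @rdname EEGRecording-class
#' @export
setMethod("eegSamples", "EEGRecording", function(x) x@samples)

#' @rdname EEGRecording-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname EEGRecording-class
#' @export
setMethod("sampleRate", "EEGRecording", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setGeneric("isValidRecording", function(x) standardGeneric("isValidRecording"))
#' @rdname EEGRecording-class
#' @export
setMethod("isValidRecording", "EEGRecording", function(x) x@valid)

#' SegmentSet: fixed-length overlapping windows cut from one recording
#'
#' @slot segments numeric matrix, one row per segment.
#' @slot fs sampling rate (Hz).
#' @slot windowS window length in seconds.
#' @slot overlapFrac fractional overlap in `[0, 1)`.
#' @slot subjectId subject identifier carried from the recording.
#' @export
setClass("SegmentSet",
  representation(segments = "matrix", fs = "numeric", windowS = "numeric",
                 overlapFrac = "numeric", subjectId = "character"))

setValidity("SegmentSet", function(object) {
  if (object@overlapFrac < 0 || object@overlapFrac >= 1)
    return("overlapFrac must lie in [0, 1)")
  if (ncol(object@segments) != round(object@windowS * object@fs))
    return("segment length inconsistent with windowS * fs")
  TRUE
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet '%s': %d segments x %d samples (%g s window, %d%% overlap)\n",
              object@subjectId, nrow(object@segments), ncol(object@segments),
              object@windowS, round(100 * object@overlapFrac)))
})

#' @rdname SegmentSet-class
#' @param x a `SegmentSet`
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname SegmentSet-class
#' @export
setMethod("nSegments", "SegmentSet", function(x) nrow(x@segments))

#' GazeStream: eye-tracking sample stream
#'
#' Raw or preprocessed gaze samples. After [preprocessGaze()] the x/y
#' coordinates of valid samples are display-normalized to `[0, 1]`;
#' invalid samples (blinks, tracking loss) carry a sentinel position.
#'
#' @slot t sample times (s), strictly increasing.
#' @slot x,y gaze coordinates (pixels raw; normalized after preprocessing).
#' @slot pupil pupil size (arbitrary units).
#' @slot valid logical per sample.
#' @slot fs nominal sampling rate (Hz).
#' @slot normalized has `preprocessGaze` run?
#' @slot subjectId subject identifier.
#' @export
setClass("GazeStream",
  representation(t = "numeric", x = "numeric", y = "numeric",
                 pupil = "numeric", valid = "logical", fs = "numeric",
                 normalized = "logical", subjectId = "character"),
  prototype(normalized = FALSE))

setValidity("GazeStream", function(object) {
  n <- length(object@t)
  if (any(lengths(list(object@x, object@y, object@pupil, object@valid)) != n))
    return("t, x, y, pupil, valid must have equal length")
  if (n >= 2 && any(diff(object@t) <= 0))
    return("sample times must be strictly increasing")
  TRUE
})

#' Construct a GazeStream
#'
#' @param t,x,y,pupil,valid per-sample vectors (see [GazeStream-class]).
#' @param fs nominal sampling rate (Hz).
#' @param subjectId subject identifier.
#' @param normalized whether x/y are already display-normalized.
#' @return A [GazeStream-class] object.
#' @export
GazeStream <- function(t, x, y, pupil = rep(NA_real_, length(t)),
                       valid = rep(TRUE, length(t)), fs,
                       subjectId = "subject", normalized = FALSE) {
  new("GazeStream", t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      pupil = as.numeric(pupil), valid = as.logical(valid),
      fs = as.numeric(fs), subjectId = as.character(subjectId),
      normalized = normalized)
}

setMethod("show", "GazeStream", function(object) {
  cat(sprintf("GazeStream '%s': %d samples @ %g Hz (%.1f s), %.1f%% valid, %s\n",
              object@subjectId, length(object@t), object@fs,
              diff(range(object@t)), 100 * mean(object@valid),
              if (object@normalized) "normalized" else "raw"))
})

#' MRMRRanking: greedy MRMR selection trace
#'
#' Ordered features selected by minimum-redundancy-maximum-relevance,
#' with the relevance (Theta), redundancy (Delta) and criterion score
#' recorded at each greedy step.
#'
#' @slot ranking data.frame with columns `rank`, `feature`, `theta`,
#'   `delta`, `score`.
#' @slot criterion `"miq"` (quotient) or `"mid"` (difference).
#' @slot nBins number of equal-frequency bins used for the MI estimates.
#' @export
setClass("MRMRRanking",
  representation(ranking = "data.frame", criterion = "character",
                 nBins = "integer"))

setValidity("MRMRRanking", function(object) {
  need <- c("rank", "feature", "theta", "delta", "score")
  if (!all(need %in% names(object@ranking)))
    return("ranking must have columns rank, feature, theta, delta, score")
  if (anyDuplicated(object@ranking$feature))
    return("selected features must be unique")
  TRUE
})

setMethod("show", "MRMRRanking", function(object) {
  cat(sprintf("MRMRRanking: %d features (%s criterion, %d bins)\n",
              nrow(object@ranking), object@criterion, object@nBins))
  print(head(object@ranking, 10))
  if (nrow(object@ranking) > 10) cat("...\n")
})

#' @rdname MRMRRanking-class
#' @param x an `MRMRRanking`
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname MRMRRanking-class
#' @export
setMethod("selectedFeatures", "MRMRRanking", function(x) x@ranking$feature)

#' EvaluationReport: cross-validated multimodal model comparison
#'
#' @slot cv data.frame: per model view, fold-mean and SD of accuracy,
#'   sensitivity, specificity (percent) plus pooled out-of-fold AUC with
#'   95 percent bootstrap CI.
#' @slot test data.frame: same metrics for the single-shot evaluation on
#'   the independent test cohort (empty if no test cohort supplied).
#' @slot roc named list of per-view ROC point data.frames (fpr, tpr).
#' @slot folds named list of per-view per-fold metric data.frames.
#' @slot config the evaluation configuration used.
#' @export
setClass("EvaluationReport",
  representation(cv = "data.frame", test = "data.frame", roc = "list",
                 folds = "list", config = "list"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (5-fold CV, metrics in %):\n")
  print(object@cv, digits = 3)
  if (nrow(object@test)) {
    cat("Independent test cohort:\n")
    print(object@test, digits = 3)
  }
})
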