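# EEG validation, denoising and segmentation for the single-channel
# wearable recordings the screening pipeline consumes.

#' Flag recordings with an offset or saturated electrode
#'
#' A recording is invalid when the electrode has come off or the
#' amplifier has railed: any run of samples pinned at the rail
#' (`|x| >= railFrac * railUv`) lasting at least `flatRunS` seconds, or
#' any flat (constant) run of that duration. Shorter bursts are treated
#' as transient artifacts and left to the band filters.
#'
#' @param rec an [EEGRecording-class].
#' @param flatRunS minimum run duration (s) for a flag (default 1).
#' @param railFrac fraction of the amplifier range that counts as the
#'   rail (default 0.95).
#' @param railUv amplifier full-scale amplitude (uV, default 200).
#' @return The recording with `valid`/`reasons` slots updated.
#' @export
detectElectrodeOffset <- function(rec, flatRunS = 1, railFrac = 0.95,
                                  railUv = 200) {
  stopifnot(is(rec, "EEGRecording"))
  x <- rec@samples
  if (length(x) == 0L) stop("empty recording")
  minRun <- ceiling(flatRunS * rec@fs)
  reasons <- character()

  runLen <- function(flag) {
    if (!any(flag)) return(0L)
    r <- rle(flag)
    max(r$lengths[r$values])
  }
  if (runLen(abs(x) >= railFrac * railUv) >= minRun)
    reasons <- c(reasons, "saturation")
  # flatline: consecutive identical samples (diff exactly 0)
  if (length(x) > 1 && runLen(c(diff(x) == 0, FALSE)) >= minRun - 1L)
    reasons <- c(reasons, "flatline")

  rec@valid <- length(reasons) == 0L
  rec@reasons <- reasons
  rec
}

#' Band-pass and notch filtering of an EEG recording
#'
#' Second-order Butterworth band-pass (default 0.5-30 Hz) plus a
#' second-order Butterworth band-stop around the power-line frequency
#' (default 50 +/- 2 Hz), both applied forward-backward (zero-phase) so
#' event timing is preserved for segment alignment.
#'
#' @param rec an [EEGRecording-class].
#' @param passband length-2 numeric `(low, high)` in Hz; both inside
#'   `(0, fs/2)`.
#' @param notch center of the band-stop (Hz); `NA` disables it. Skipped
#'   automatically when it lies outside the Nyquist range.
#' @param notchHalfWidth half width of the stop band (Hz, default 2).
#' @param order Butterworth order (default 2).
#' @return Filtered [EEGRecording-class], same length as input.
#' @export
denoiseEEG <- function(rec, passband = c(0.5, 30), notch = 50,
                       notchHalfWidth = 2, order = 2L) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  nyq <- fs / 2
  if (length(passband) != 2L || passband[1] <= 0 || passband[2] <= passband[1])
    stop("passband must be (low, high) with 0 < low < high")
  if (passband[2] >= nyq)
    stop("passband upper edge must lie below the Nyquist frequency")
  x <- rec@samples
  if (!is.na(notch) && notch + notchHalfWidth < nyq) {
    bs <- signal::butter(order, c(notch - notchHalfWidth,
                                  notch + notchHalfWidth) / nyq, type = "stop")
    x <- signal::filtfilt(bs, x)
  }
  bp <- signal::butter(order, passband / nyq, type = "pass")
  x <- signal::filtfilt(bp, x)
  rec@samples <- as.numeric(x)
  rec
}

#' Cut a recording into fixed-length overlapping segments
#'
#' Moving window of `windowS` seconds advancing by
#' `windowS * (1 - overlapFrac)`; a trailing partial window is
#' discarded. With the defaults (5 s window, 60 percent overlap) a 33 s
#' recording yields 15 segments.
#'
#' @param rec an [EEGRecording-class].
#' @param windowS window length in seconds (default 5).
#' @param overlapFrac fractional overlap in `[0, 1)` (default 0.6).
#' @return A [SegmentSet-class].
#' @export
segmentSignal <- function(rec, windowS = 5, overlapFrac = 0.6) {
  stopifnot(is(rec, "EEGRecording"))
  if (overlapFrac < 0 || overlapFrac >= 1)
    stop("overlapFrac must lie in [0, 1)")
  fs <- rec@fs
  wlen <- round(windowS * fs)
  n <- length(rec@samples)
  if (n < wlen) stop("recording shorter than window")
  step <- round(windowS * (1 - overlapFrac) * fs)
  if (step < 1L) stop("window step below one sample")
  starts <- seq(1L, n - wlen + 1L, by = step)
  segs <- t(vapply(starts, function(s) rec@samples[s:(s + wlen - 1L)],
                   numeric(wlen)))
  new("SegmentSet", segments = segs, fs = fs, windowS = windowS,
      overlapFrac = overlapFrac, subjectId = rec@subjectId)
}

#' Read / write the EEG CSV dialect
#'
#' One header line `# fs=<Hz>` followed by one sample (uV) per line.
#'
#' @param path file path.
#' @param subjectId identifier to attach (default: file's directory name).
#' @return [EEGRecording-class] for the reader; invisibly `path` for the
#'   writer.
#' @export
readEEGCsv <- function(path, subjectId = basename(dirname(path))) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*fs=([0-9.]+)", header))[[1]]
  if (length(m) < 2L) stop("EEG CSV must start with a '# fs=<Hz>' header: ", path)
  fs <- as.numeric(m[2])
  x <- scan(path, skip = 1L, quiet = TRUE)
  EEGRecording(x, fs = fs, subjectId = subjectId)
}

#' @rdname readEEGCsv
#' @param rec recording to write.
#' @export
writeEEGCsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec@fs), con)
  writeLines(formatC(rec@samples, format = "g", digits = 10), con)
  invisible(path)
}
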