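# Gaze-stream preprocessing, oculomotor event detection (blinks, I-VT
# fixations/saccades) and the visual-scan metrics used for screening.

#' Normalize and low-pass filter a gaze stream
#'
#' Converts pixel coordinates to display-normalized `[0, 1]` units and
#' applies a zero-phase second-order Butterworth low pass (default 5 Hz)
#' to each contiguous run of valid samples; invalid samples keep a
#' sentinel position and are never interpolated here.
#'
#' @param stream a raw [GazeStream-class] (pixel coordinates).
#' @param displayPx display size `(width, height)` in pixels.
#' @param cutoffHz low-pass cutoff (Hz, default 5).
#' @param order Butterworth order (default 2).
#' @return The normalized, filtered [GazeStream-class].
#' @export
preprocessGaze <- function(stream, displayPx = c(1920, 1080),
                           cutoffHz = 5, order = 2L) {
  stopifnot(is(stream, "GazeStream"))
  if (any(displayPx <= 0)) stop("display size must be positive")
  n <- length(stream@t)
  if (n < 2L) stop("gaze stream too short")
  if (!any(stream@valid)) stop("no valid gaze samples")
  x <- stream@x / displayPx[1]
  y <- stream@y / displayPx[2]
  x[!stream@valid] <- -1
  y[!stream@valid] <- -1

  nyq <- stream@fs / 2
  if (cutoffHz < nyq) {
    lp <- signal::butter(order, cutoffHz / nyq, type = "low")
    runs <- rle(stream@valid)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    minLen <- 3L * (order + 1L) * 3L # filtfilt needs padding room
    for (k in which(runs$values)) {
      idx <- starts[k]:ends[k]
      if (length(idx) >= minLen) {
        x[idx] <- signal::filtfilt(lp, x[idx])
        y[idx] <- signal::filtfilt(lp, y[idx])
      }
    }
  }
  stream@x <- pmin(pmax(x, ifelse(stream@valid, 0, -1)), 1)
  stream@y <- pmin(pmax(y, ifelse(stream@valid, 0, -1)), 1)
  stream@normalized <- TRUE
  stream
}

#' Detect blinks as bounded validity gaps
#'
#' Maximal runs of invalid samples with duration inside
#' `[minGapMs, maxGapMs]` are blinks. Shorter gaps are tracker noise and
#' are linearly interpolated and re-flagged valid; longer gaps are
#' signal loss and stay excluded.
#'
#' @param stream a preprocessed [GazeStream-class].
#' @param minGapMs,maxGapMs physiological blink duration bounds
#'   (defaults 70 and 500 ms).
#' @return list: `events` data.frame (`kind`, `tStart`, `tEnd`,
#'   `duration`), `stream` (with short gaps repaired), `lost` seconds of
#'   long-gap signal loss.
#' @export
detectBlinks <- function(stream, minGapMs = 70, maxGapMs = 500) {
  stopifnot(is(stream, "GazeStream"))
  v <- stream@valid
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dt <- 1 / stream@fs
  gaps <- which(!runs$values)
  durs <- runs$lengths[gaps] * dt
  # noise gaps: interpolate across where both neighbours exist
  for (k in gaps[durs * 1000 < minGapMs]) {
    i1 <- starts[k]; i2 <- ends[k]
    lo <- i1 - 1L; hi <- i2 + 1L
    if (lo >= 1L && hi <= length(v)) {
      w <- (seq(i1, i2) - lo) / (hi - lo)
      stream@x[i1:i2] <- stream@x[lo] * (1 - w) + stream@x[hi] * w
      stream@y[i1:i2] <- stream@y[lo] * (1 - w) + stream@y[hi] * w
      stream@valid[i1:i2] <- TRUE
    }
  }
  isBlink <- durs * 1000 >= minGapMs & durs * 1000 <= maxGapMs
  bk <- gaps[isBlink]
  events <- data.frame(kind = rep("blink", length(bk)),
                       tStart = stream@t[starts[bk]],
                       tEnd = stream@t[ends[bk]] + dt,
                       duration = durs[isBlink])
  list(events = events, stream = stream,
       lost = sum(durs[durs * 1000 > maxGapMs]))
}

#' I-VT fixation and saccade detection
#'
#' Sample-wise speed in normalized display units per second (central
#' difference); samples at or above `velocityThreshold` are saccade
#' samples, the rest fixation samples. Contiguous runs are merged into
#' events; invalid samples break runs; fixations shorter than
#' `minFixMs` are discarded.
#'
#' @param stream a preprocessed [GazeStream-class].
#' @param velocityThreshold I-VT threshold (normalized units/s,
#'   default 0.5).
#' @param minFixMs minimum fixation duration (ms, default 60).
#' @return data.frame of events: `kind` (fixation/saccade), `tStart`,
#'   `tEnd`, `duration`, centroid `cx`, `cy` (fixations), `peakVelocity`
#'   (saccades).
#' @export
detectFixationsSaccades <- function(stream, velocityThreshold = 0.5,
                                    minFixMs = 60) {
  stopifnot(is(stream, "GazeStream"))
  n <- length(stream@t)
  if (n < 3L) stop("stream shorter than 3 samples")
  t <- stream@t; x <- stream@x; y <- stream@y; v <- stream@valid
  vx <- c(NA, (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
  vy <- c(NA, (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
  speed <- sqrt(vx^2 + vy^2)
  speed[c(1, n)] <- speed[c(2, n - 1)]
  # neighbours of invalid samples have meaningless velocity
  badNb <- !v | c(FALSE, !v[-n]) | c(!v[-1], FALSE)
  state <- ifelse(speed >= velocityThreshold, "saccade", "fixation")
  state[badNb | !v] <- "invalid"

  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dt <- 1 / stream@fs
  keep <- runs$values != "invalid" &
    !(runs$values == "fixation" & runs$lengths * dt * 1000 < minFixMs)
  ks <- which(keep)
  if (!length(ks))
    return(data.frame(kind = character(), tStart = numeric(),
                      tEnd = numeric(), duration = numeric(),
                      cx = numeric(), cy = numeric(),
                      peakVelocity = numeric()))
  kind <- runs$values[ks]
  grpStat <- function(v, f) vapply(ks, function(k)
    f(v[starts[k]:ends[k]]), numeric(1))
  data.frame(kind = kind,
             tStart = t[starts[ks]],
             tEnd = t[ends[ks]] + dt,
             duration = runs$lengths[ks] * dt,
             cx = ifelse(kind == "fixation", grpStat(x, mean), NA_real_),
             cy = ifelse(kind == "fixation", grpStat(y, mean), NA_real_),
             peakVelocity = ifelse(kind == "saccade", grpStat(speed, max),
                                   NA_real_))
}

#' Visual-scan metrics from detected ocular events
#'
#' Blink frequency (blinks per minute), mean blink time (s), mean
#' fixation time (s), and sustained attention duration: the time span of
#' the longest unbroken run of consecutive fixations whose centroids lie
#' inside the area of interest (a blink or an out-of-AOI fixation breaks
#' the run). Empty event classes yield 0 for the frequency and `NA` for
#' the means.
#'
#' @param events data.frame combining blink and fixation/saccade events.
#' @param durationS stream duration in seconds (> 0).
#' @param aoi area-of-interest rectangle
#'   `c(xmin, xmax, ymin, ymax)` in normalized units; default the
#'   central half of the display.
#' @return named numeric vector: `blink_frequency`, `blink_time`,
#'   `fixation_time`, `sustained_attention`.
#' @export
computeETMetrics <- function(events, durationS,
                             aoi = c(0.25, 0.75, 0.25, 0.75)) {
  if (durationS <= 0) stop("stream duration must be positive")
  blinks <- events[events$kind == "blink", , drop = FALSE]
  fix <- events[events$kind == "fixation", , drop = FALSE]
  blinkFreq <- nrow(blinks) / durationS * 60
  blinkTime <- if (nrow(blinks)) mean(blinks$duration) else NA_real_
  fixTime <- if (nrow(fix)) mean(fix$duration) else NA_real_

  sustained <- 0
  if (nrow(fix)) {
    fix <- fix[order(fix$tStart), , drop = FALSE]
    inAoi <- fix$cx >= aoi[1] & fix$cx <= aoi[2] &
             fix$cy >= aoi[3] & fix$cy <= aoi[4]
    # a blink between two fixations breaks the attention run
    broken <- rep(FALSE, nrow(fix))
    if (nrow(blinks) && nrow(fix) > 1L) {
      for (i in 2:nrow(fix))
        broken[i] <- any(blinks$tStart >= fix$tEnd[i - 1L] &
                         blinks$tEnd <= fix$tStart[i])
    }
    runStart <- NA_integer_
    for (i in seq_len(nrow(fix))) {
      if (!inAoi[i]) {
        runStart <- NA_integer_
        next
      }
      if (is.na(runStart) || broken[i]) runStart <- i
      sustained <- max(sustained, fix$tEnd[i] - fix$tStart[runStart])
    }
  }
  c(blink_frequency = blinkFreq, blink_time = blinkTime,
    fixation_time = fixTime, sustained_attention = sustained)
}

#' Scan-path complexity of a gaze stream
#'
#' Lempel-Ziv complexity of the scan-path speed series of valid samples,
#' binarized at its median — the same LZ76 kernel used for EEG, applied
#' to the oculomotor signal.
#'
#' @param stream a preprocessed [GazeStream-class].
#' @return normalized LZ76 complexity (scalar).
#' @export
gazeComplexity <- function(stream) {
  stopifnot(is(stream, "GazeStream"))
  keep <- stream@valid
  if (sum(keep) < 3L) stop("too few valid samples")
  t <- stream@t[keep]; x <- stream@x[keep]; y <- stream@y[keep]
  speed <- sqrt(diff(x)^2 + diff(y)^2) / diff(t)
  lempelZivComplexity(speed, binarize = "median")$complexity
}

#' Subject-level eye-tracking feature vector
#'
#' Runs blink detection, I-VT event detection and the scan metrics on a
#' preprocessed stream and returns the named feature vector.
#'
#' @param stream a preprocessed [GazeStream-class].
#' @param velocityThreshold,minFixMs passed to
#'   [detectFixationsSaccades()].
#' @param aoi passed to [computeETMetrics()].
#' @return named numeric vector, names prefixed `et.`.
#' @export
extractETFeatures <- function(stream, velocityThreshold = 0.5,
                              minFixMs = 60,
                              aoi = c(0.25, 0.75, 0.25, 0.75)) {
  bl <- detectBlinks(stream)
  ev <- detectFixationsSaccades(bl$stream,
                                velocityThreshold = velocityThreshold,
                                minFixMs = minFixMs)
  allEv <- rbind(ev[, c("kind", "tStart", "tEnd", "duration")],
                 bl$events[, c("kind", "tStart", "tEnd", "duration")])
  allEv$cx <- c(ev$cx, rep(NA_real_, nrow(bl$events)))
  allEv$cy <- c(ev$cy, rep(NA_real_, nrow(bl$events)))
  met <- computeETMetrics(allEv, durationS = diff(range(stream@t)), aoi = aoi)
  lzc <- gazeComplexity(bl$stream)
  setNames(c(met, lzc), paste0("et.", c(names(met), "gaze_lzc")))
}

#' Read / write the eye-tracking CSV dialect
#'
#' Columns `t,x,y,pupil,valid`; a comment header line `# fs=<Hz>` carries
#' the nominal sampling rate.
#'
#' @param path file path.
#' @param subjectId identifier to attach.
#' @return [GazeStream-class] for the reader; invisibly `path` for the
#'   writer.
#' @export
readETCsv <- function(path, subjectId = basename(dirname(path))) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*fs=([0-9.]+)", header))[[1]]
  if (length(m) < 2L) stop("ET CSV must start with a '# fs=<Hz>' header: ", path)
  d <- read.csv(path, skip = 1L)
  GazeStream(d$t, d$x, d$y, d$pupil, as.logical(d$valid),
             fs = as.numeric(m[2]), subjectId = subjectId)
}

#' @rdname readETCsv
#' @param stream stream to write.
#' @export
writeETCsv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", stream@fs), con)
  d <- data.frame(t = stream@t, x = stream@x, y = stream@y,
                  pupil = stream@pupil, valid = as.integer(stream@valid))
  write.csv(format(d, digits = 10, trim = TRUE), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
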