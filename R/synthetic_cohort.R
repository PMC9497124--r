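# Synthetic NC/MCI cohort generator. Emulates the multimodal screening
# data (single-channel EEG, eye tracking, neuropsychological battery,
# demographics) with configurable standardized group effects so every
# downstream stage is testable without clinical data.

#' Derive a stage/subject seed from the master seed
#'
#' Stable integer hashing keeps every stream reproducible from one
#' master seed while decoupling stages from each other.
#'
#' @param seed master integer seed.
#' @param tag character stream tag.
#' @return integer seed in `[1, 2^31)`.
#' @export
derivedSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 20117) %% 2147483629 + 1)
}

#' Cohort specification for the synthetic generator
#'
#' The `effects` entries are standardized shifts applied to the MCI
#' group's per-subject latent trait for each feature family (in SD units
#' of the between-subject variation); `noiseSd` scales that
#' between-subject variation relative to the family baseline. Defaults
#' emulate MCI-typical alterations: reduced alpha and elevated theta
#' power, reduced signal complexity, longer fixations, more blinks, and
#' lower cognitive scores.
#'
#' @param nNc,nMci group sizes (each >= 2).
#' @param eegFs,eegDurationS EEG sampling rate (Hz) and duration (s).
#'   The 33 s default yields the canonical 15 overlapping 5 s segments.
#' @param etFs,etDurationS eye-tracking rate (Hz) and duration (s).
#' @param effects named list of standardized MCI shifts:
#'   `alpha_power`, `theta_power`, `complexity`, `fixation_time`,
#'   `blink_rate`, `ntb_scores`, `moca`, `ace`.
#' @param noiseSd named list of per-family between-subject coefficients
#'   of variation.
#' @param baseBlinkPerMin NC mean blink rate (blinks/min, default 15;
#'   0 disables blinks entirely).
#' @param baseFixationS NC mean fixation duration (s, default 0.25).
#' @param lineAmp 50 Hz line-noise amplitude (uV, 0 disables).
#' @param artifactRate saturation-artifact bursts per minute (default 0).
#' @param seed master integer seed; fixed seed gives bit-identical
#'   cohorts.
#' @return list of class `CohortSpec`.
#' @export
cohortSpec <- function(nNc = 184L, nMci = 152L,
                       eegFs = 256, eegDurationS = 33,
                       etFs = 60, etDurationS = 60,
                       effects = list(), noiseSd = list(),
                       baseBlinkPerMin = 15, baseFixationS = 0.25,
                       lineAmp = 2, artifactRate = 0, seed = 1L) {
  if (nNc < 2L || nMci < 2L) stop("each group needs at least 2 subjects")
  if (eegDurationS <= 5) stop("EEG duration must exceed the analysis window")
  if (etDurationS <= 0 || eegFs <= 0 || etFs <= 0)
    stop("durations and sampling rates must be positive")
  eff <- modifyList(list(alpha_power = -0.8, theta_power = 0.8,
                         complexity = -0.6, fixation_time = 0.8,
                         blink_rate = 0.5, ntb_scores = -1.0,
                         moca = -0.5, ace = -0.4), effects)
  ns <- modifyList(list(alpha_power = 0.15, theta_power = 0.15,
                        complexity = 0.15, fixation_time = 0.2,
                        blink_rate = 0.3, ntb_scores = 1.0),
                   noiseSd)
  structure(list(nNc = as.integer(nNc), nMci = as.integer(nMci),
                 eegFs = eegFs, eegDurationS = eegDurationS,
                 etFs = etFs, etDurationS = etDurationS,
                 effects = eff, noiseSd = ns,
                 baseBlinkPerMin = baseBlinkPerMin,
                 baseFixationS = baseFixationS, lineAmp = lineAmp,
                 artifactRate = artifactRate, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Set every group effect in a spec to zero
#'
#' Convenience for null-cohort simulations: the two groups become
#' statistically indistinguishable in every modality.
#'
#' @param spec a [cohortSpec()].
#' @return the spec with all effects 0.
#' @export
nullEffects <- function(spec) {
  spec$effects[] <- lapply(spec$effects, function(x) 0)
  spec
}

# White noise spectrally shaped to 1/f (power ~ 1/f), unit variance.
#' 1/f (pink) noise
#'
#' @param n number of samples.
#' @return numeric vector, unit variance.
#' @export
pinkNoise <- function(n) {
  m <- 2L * n
  X <- stats::fft(rnorm(m))
  f <- c(1, seq_len(m - 1L))            # guard DC
  f <- pmin(f, m - f + 1)               # fold to two-sided frequencies
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  as.numeric(scale(x))
}

# Band-limited Gaussian noise with target RMS, via order-2 Butterworth.
bandNoise <- function(n, fs, lo, hi, rms) {
  b <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(b, rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]             # drop filter edges
  x / stats::sd(x) * rms
}

# Latent per-subject family trait: N(effect, 1) for MCI, N(0, 1) for NC,
# mapped to a positive multiplicative factor 1 + cv * z.
familyFactor <- function(group, effect, cv) {
  z <- rnorm(1, mean = if (group == "MCI") effect else 0, sd = 1)
  max(1 + cv * z, 0.05)
}

#' Generate one subject's synthetic EEG recording
#'
#' Sum of band-limited oscillations (delta/theta/alpha/beta) with
#' group-dependent amplitudes, a 1/f pink-noise floor whose amplitude
#' carries the complexity effect, optional 50 Hz line noise, and
#' optional saturation bursts. MCI subjects draw lower alpha and higher
#' theta amplitudes and a lower broadband (complexity) level than NC by
#' the spec's standardized effects.
#'
#' @param group `"NC"` or `"MCI"`.
#' @param spec a [cohortSpec()].
#' @param subjectId identifier; also salts the per-subject seed.
#' @return An [EEGRecording-class].
#' @export
generateEEGRecording <- function(group, spec, subjectId = "s1") {
  group <- match.arg(group, c("NC", "MCI"))
  set.seed(derivedSeed(spec$seed, paste0("eeg_", subjectId)))
  fs <- spec$eegFs
  n <- round(spec$eegDurationS * fs)
  eff <- spec$effects; cv <- spec$noiseSd
  # baseline band RMS amplitudes (uV), resting-state-like alpha dominance
  amp <- c(delta = 6, theta = 5, alpha = 10, beta = 3)
  amp["alpha"] <- amp["alpha"] * familyFactor(group, eff$alpha_power, cv$alpha_power)
  amp["theta"] <- amp["theta"] * familyFactor(group, eff$theta_power, cv$theta_power)
  bands <- eegBands()
  x <- numeric(n)
  for (k in seq_len(nrow(bands)))
    x <- x + bandNoise(n, fs, bands$lo[k], bands$hi[k], amp[[bands$name[k]]])
  # broadband 1/f floor: lower amplitude = more regular = lower complexity
  x <- x + 5 * familyFactor(group, eff$complexity, cv$complexity) * pinkNoise(n)
  if (spec$lineAmp > 0 && 50 < fs / 2)
    x <- x + spec$lineAmp * sin(2 * pi * 50 * seq_len(n) / fs + runif(1, 0, 2 * pi))
  if (spec$artifactRate > 0) {
    nBurst <- rpois(1, spec$artifactRate * spec$eegDurationS / 60)
    for (b in seq_len(nBurst)) {
      i0 <- sample.int(n - round(0.2 * fs), 1)
      x[i0:(i0 + round(0.2 * fs))] <- 200
    }
  }
  EEGRecording(x, fs = fs, subjectId = subjectId)
}

#' Generate one subject's synthetic gaze stream
#'
#' Piecewise-stationary scan path: fixations (lognormal durations,
#' group-shifted mean) mostly at jittered positions inside a central
#' area of interest, ballistic saccades between them, and blinks as
#' validity gaps at a group-shifted Poisson rate. Coordinates are in
#' display pixels (1920 x 1080); [preprocessGaze()] normalizes them.
#'
#' @inheritParams generateEEGRecording
#' @return A raw (pixel-coordinate) [GazeStream-class].
#' @export
generateGazeStream <- function(group, spec, subjectId = "s1") {
  group <- match.arg(group, c("NC", "MCI"))
  set.seed(derivedSeed(spec$seed, paste0("et_", subjectId)))
  fs <- spec$etFs
  dur <- spec$etDurationS
  if (dur <= 0) stop("duration must be positive")
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  eff <- spec$effects; cv <- spec$noiseSd
  meanFix <- spec$baseFixationS *
    familyFactor(group, eff$fixation_time, cv$fixation_time)
  blinkPerMin <- spec$baseBlinkPerMin *
    familyFactor(group, eff$blink_rate, cv$blink_rate)

  x <- numeric(n); y <- numeric(n)
  pos <- c(0.5, 0.5)
  i <- 1L
  while (i <= n) {
    # next fixation target: 80% inside the central AOI, else periphery
    pos <- if (runif(1) < 0.8)
      c(runif(1, 0.3, 0.7), runif(1, 0.3, 0.7))
    else
      c(sample(c(runif(1, 0.02, 0.2), runif(1, 0.8, 0.98)), 1),
        runif(1, 0.02, 0.98))
    nFix <- max(2L, round(rlnorm(1, log(meanFix), 0.4) * fs))
    i2 <- min(n, i + nFix - 1L)
    x[i:i2] <- pos[1]; y[i:i2] <- pos[2]
    i <- i2 + 1L
    nSac <- max(1L, round(0.03 * fs))      # ~30 ms ballistic saccade
    if (i <= n) {
      i2 <- min(n, i + nSac - 1L)
      x[i:i2] <- pos[1]; y[i:i2] <- pos[2] # overwritten by next target via filter
      i <- i2 + 1L
    }
  }
  # tracker jitter (~2 px RMS on a 1920 px display)
  x <- x + rnorm(n, 0, 2 / 1920)
  y <- y + rnorm(n, 0, 2 / 1080)

  valid <- rep(TRUE, n)
  nBlink <- rpois(1, blinkPerMin * dur / 60)
  if (nBlink > 0) {
    starts <- sort(runif(nBlink, 0, dur - 0.4))
    for (b in seq_len(nBlink)) {
      durB <- runif(1, 0.1, 0.3)
      idx <- which(t >= starts[b] & t < starts[b] + durB)
      valid[idx] <- FALSE
    }
  }
  px <- x * 1920; py <- y * 1080
  px[!valid] <- -1; py[!valid] <- -1     # sentinel during validity gaps
  pupil <- 3 + rnorm(n, 0, 0.1)
  pupil[!valid] <- 0
  GazeStream(t, px, py, pupil, valid, fs = fs, subjectId = subjectId)
}

#' Generate a full synthetic cohort
#'
#' Produces per-subject EEG recordings and gaze streams plus the
#' neuropsychological battery (20 subtests, total score, response time)
#' and demographics tables (age, gender, education, MoCA-B, ACE-R,
#' group). MoCA-B and ACE-R are sampled with an MCI < NC shift; age,
#' gender and education are group-balanced. With `dir` given, writes the
#' on-disk layout `dir/<subject>/eeg.csv`, `dir/<subject>/et.csv`,
#' `dir/ntb.csv`, `dir/demographics.csv`.
#'
#' @param spec a [cohortSpec()].
#' @param dir optional output directory.
#' @return (invisibly when writing) list with `recordings` (named list
#'   of [EEGRecording-class]), `gaze` (named list of
#'   [GazeStream-class]), `ntb` and `demographics` data.frames.
#' @export
generateCohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  ids <- c(sprintf("nc_%03d", seq_len(spec$nNc)),
           sprintf("mci_%03d", seq_len(spec$nMci)))
  groups <- rep(c("NC", "MCI"), c(spec$nNc, spec$nMci))

  recordings <- setNames(
    mapply(function(g, id) generateEEGRecording(g, spec, id),
           groups, ids, SIMPLIFY = FALSE), ids)
  gaze <- setNames(
    mapply(function(g, id) generateGazeStream(g, spec, id),
           groups, ids, SIMPLIFY = FALSE), ids)

  set.seed(derivedSeed(spec$seed, "ntb"))
  effN <- spec$effects$ntb_scores
  cvN <- spec$noiseSd$ntb_scores
  nSub <- 20L
  ntb <- t(vapply(groups, function(g) {
    shared <- rnorm(1, if (g == "MCI") effN else 0, 0.7) * cvN
    scores <- pmax(0, pmin(20, 10 + 3 * (shared + rnorm(nSub, 0, 0.7))))
    rt <- max(60, 300 * (1 - 0.15 * shared) + rnorm(1, 0, 30))
    c(scores, sum(scores), rt)
  }, numeric(nSub + 2L)))
  ntb <- as.data.frame(ntb)
  names(ntb) <- c(sprintf("sub%02d", seq_len(nSub)), "total", "response_time")
  ntb <- cbind(subject_id = ids, ntb)
  rownames(ntb) <- NULL

  set.seed(derivedSeed(spec$seed, "demographics"))
  mci <- groups == "MCI"
  # NC marginals follow the screening literature for community elders;
  # MCI means shift by the standardized moca/ace effects
  mocaSd <- c(NC = 2.0, MCI = 3.4)
  aceSd <- c(NC = 7.8, MCI = 8.5)
  demo <- data.frame(
    subject_id = ids,
    group = groups,
    age = round(rnorm(length(ids), 71.6, 4.4), 1),
    gender = sample(c("M", "F"), length(ids), replace = TRUE),
    education = pmax(0, round(rnorm(length(ids), 9, 3.5))),
    moca_b = round(pmin(30, pmax(0,
      rnorm(length(ids), 26.5 + ifelse(mci, spec$effects$moca, 0) * 2.7,
            mocaSd[groups]))), 0),
    ace_r = round(pmin(100, pmax(0,
      rnorm(length(ids), 70 + ifelse(mci, spec$effects$ace, 0) * 8.2,
            aceSd[groups]))), 0))
  rownames(demo) <- NULL

  out <- list(recordings = recordings, gaze = gaze, ntb = ntb,
              demographics = demo)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
    for (id in ids) {
      sd <- file.path(dir, id)
      dir.create(sd, showWarnings = FALSE)
      writeEEGCsv(recordings[[id]], file.path(sd, "eeg.csv"))
      writeETCsv(gaze[[id]], file.path(sd, "et.csv"))
    }
    write.csv(ntb, file.path(dir, "ntb.csv"), row.names = FALSE, quote = FALSE)
    write.csv(demo, file.path(dir, "demographics.csv"), row.names = FALSE,
              quote = FALSE)
    return(invisible(out))
  }
  out
}
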