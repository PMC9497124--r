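mkStream <- function(x, y, fs = 60, valid = NULL, pupil = NULL) {
  n <- length(x)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(pupil)) pupil <- rep(3, n)
  GazeStream(t = (seq_len(n) - 1) / fs, x = x, y = y, pupil = pupil,
             valid = valid, fs = fs)
}

test_that("gaze preprocessing normalizes pixels and rejects empty streams", {
  s <- mkStream(rep(960, 120), rep(540, 120))
  p <- preprocessGaze(s, displayPx = c(1920, 1080))
  # away from the filter edges the normalized position is exact
  expect_equal(p@x[40:80], rep(0.5, 41), tolerance = 1e-6)
  expect_equal(p@y[40:80], rep(0.5, 41), tolerance = 1e-6)
  expect_true(p@normalized)
  expect_error(preprocessGaze(mkStream(1, 1)), "too short")
  allBad <- mkStream(rep(-1, 50), rep(-1, 50), valid = rep(FALSE, 50))
  expect_error(preprocessGaze(allBad), "no valid gaze samples")
  expect_error(preprocessGaze(s, displayPx = c(0, 1080)), "positive")
})

test_that("the 5 Hz low pass attenuates 20 Hz positional jitter by 20 dB", {
  fs <- 120
  n <- 10 * fs
  jitter <- 50 * sin(2 * pi * 20 * (seq_len(n) - 1) / fs)
  s <- mkStream(960 + jitter, rep(540, n), fs = fs)
  p <- preprocessGaze(s, displayPx = c(1920, 1080))
  mid <- (2 * fs):(n - 2 * fs)
  ampIn <- sd(jitter[mid] / 1920)
  ampOut <- sd(p@x[mid] - mean(p@x[mid]))
  expect_gt(20 * log10(ampIn / ampOut), 20)
})

test_that("blink detection applies the duration window", {
  fs <- 100
  mkGap <- function(gapMs) {
    n <- 200
    valid <- rep(TRUE, n)
    gap <- seq(100, length.out = round(gapMs / 1000 * fs))
    valid[gap] <- FALSE
    x <- rep(0.5, n); x[!valid] <- -1
    s <- mkStream(x * 1920, rep(540, n), fs = fs, valid = valid)
    detectBlinks(preprocessGaze(s))
  }
  one <- mkGap(150)
  expect_identical(nrow(one$events), 1L)
  expect_equal(one$events$duration, 0.15, tolerance = 1e-9)
  short <- mkGap(20)
  expect_identical(nrow(short$events), 0L)
  expect_true(all(short$stream@valid)) # noise gap interpolated
  long <- mkGap(800)
  expect_identical(nrow(long$events), 0L)
  expect_gt(long$lost, 0.7)
  clean <- detectBlinks(preprocessGaze(mkStream(rep(960, 100), rep(540, 100))))
  expect_identical(nrow(clean$events), 0L)
})

test_that("I-VT splits a jump trace into two fixations and one saccade", {
  fs <- 100
  n <- 60
  s <- GazeStream(t = (seq_len(n) - 1) / fs,
                  x = c(rep(0.3, 30), rep(0.7, 30)), y = rep(0.5, n),
                  pupil = rep(3, n), valid = rep(TRUE, n), fs = fs,
                  normalized = TRUE)
  ev <- detectFixationsSaccades(s, velocityThreshold = 0.5)
  expect_identical(sum(ev$kind == "fixation"), 2L)
  expect_identical(sum(ev$kind == "saccade"), 1L)
  expect_equal(ev$cx[ev$kind == "fixation"], c(0.3, 0.7), tolerance = 0.01)

  const <- detectFixationsSaccades(
    GazeStream(t = (seq_len(50) - 1) / fs, x = rep(0.5, 50),
               y = rep(0.5, 50), pupil = rep(3, 50),
               valid = rep(TRUE, 50), fs = fs, normalized = TRUE))
  expect_identical(nrow(const), 1L)
  expect_identical(const$kind, "fixation")

  # constant speed exactly at threshold classifies as saccade (>= rule)
  ramp <- (seq_len(50) - 1) / fs * 0.5 # 0.5 units/s in normalized x
  s <- GazeStream(t = (seq_len(50) - 1) / fs, x = ramp, y = rep(0.5, 50),
                  pupil = rep(3, 50), valid = rep(TRUE, 50), fs = fs,
                  normalized = TRUE)
  ev2 <- detectFixationsSaccades(s, velocityThreshold = 0.5)
  expect_true(all(ev2$kind == "saccade"))
  expect_error(detectFixationsSaccades(mkStream(c(1, 2), c(1, 2))), "3 samples")
})

test_that("scan metrics follow their defining arithmetic", {
  ev <- data.frame(kind = rep("blink", 6),
                   tStart = seq(10, 110, by = 20),
                   tEnd = seq(10.2, 110.2, by = 20),
                   duration = rep(0.2, 6), cx = NA, cy = NA)
  m <- computeETMetrics(ev, durationS = 120)
  expect_equal(m[["blink_frequency"]], 3.0)
  expect_equal(m[["blink_time"]], 0.2)
  expect_true(is.na(m[["fixation_time"]]))

  fx <- data.frame(kind = "fixation",
                   tStart = c(0, 1.5, 10, 14), tEnd = c(1.2, 2.0, 13.4, 15),
                   duration = c(1.2, 0.5, 3.4, 1.0),
                   cx = c(0.5, 0.9, 0.5, 0.9), cy = c(0.5, 0.5, 0.5, 0.5))
  m2 <- computeETMetrics(fx, durationS = 20)
  expect_equal(m2[["sustained_attention"]], 3.4)
  expect_equal(m2[["fixation_time"]], mean(c(1.2, 0.5, 3.4, 1.0)))
})

test_that("a blink between in-AOI fixations breaks the attention run", {
  fx <- data.frame(kind = "fixation",
                   tStart = c(0, 2), tEnd = c(1, 3.5),
                   duration = c(1, 1.5), cx = 0.5, cy = 0.5)
  bl <- data.frame(kind = "blink", tStart = 1.2, tEnd = 1.4, duration = 0.2,
                   cx = NA, cy = NA)
  m <- computeETMetrics(rbind(fx, bl), durationS = 5)
  expect_equal(m[["sustained_attention"]], 1.5)
  noBlink <- computeETMetrics(fx, durationS = 5)
  expect_equal(noBlink[["sustained_attention"]], 3.5)
})

test_that("gaze complexity shares the LZ76 kernel and orders regular vs shuffled", {
  set.seed(13)
  fs <- 60
  n <- 600
  xPeriodic <- 0.5 + 0.2 * sin(2 * pi * (seq_len(n) - 1) / 60)
  s <- GazeStream(t = (seq_len(n) - 1) / fs, x = xPeriodic, y = rep(0.5, n),
                  pupil = rep(3, n), valid = rep(TRUE, n), fs = fs,
                  normalized = TRUE)
  idx <- sample(n)
  sShuf <- GazeStream(t = (seq_len(n) - 1) / fs, x = xPeriodic[idx],
                      y = rep(0.5, n), pupil = rep(3, n),
                      valid = rep(TRUE, n), fs = fs, normalized = TRUE)
  expect_lt(gazeComplexity(s), gazeComplexity(sShuf))
  # identical binary sequence through either entry point
  speed <- sqrt(diff(s@x)^2 + diff(s@y)^2) / diff(s@t)
  expect_equal(gazeComplexity(s),
               lempelZivComplexity(speed, "median")$complexity)
})

test_that("ET feature vector has the declared schema and round-trips CSV", {
  spec <- cohortSpec(nNc = 2, nMci = 2, seed = 3)
  gs <- generateGazeStream("NC", spec, "s1")
  fv <- extractETFeatures(preprocessGaze(gs))
  expect_named(fv, c("et.blink_frequency", "et.blink_time",
                     "et.fixation_time", "et.sustained_attention",
                     "et.gaze_lzc"))
  expect_true(all(fv >= 0 | is.na(fv)))
  path <- file.path(withr::local_tempdir(), "et.csv")
  writeETCsv(gs, path)
  back <- readETCsv(path, subjectId = "s1")
  expect_equal(back@x, gs@x, tolerance = 1e-6)
  expect_identical(back@valid, gs@valid)
})
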