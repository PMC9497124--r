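# Linear (spectral) and nonlinear (entropy/complexity) EEG features,
# computed per segment and averaged to subject level.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz.
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
eegBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo = c(0.5, 4, 8, 13),
             hi = c(4, 8, 13, 30))
}

#' Power spectral density via the autocorrelation (Wiener-Khinchin) route
#'
#' Estimates the PSD as the discrete Fourier transform of the biased
#' sample autocorrelation over all lags, which coincides with the
#' periodogram of the zero-padded segment. Returned one-sided with a
#' power-conserving normalization: `sum(power) * df` equals the mean
#' square of the segment.
#'
#' @param x numeric segment (length >= 2).
#' @param fs sampling rate (Hz).
#' @return list with `freqs` (Hz, `0..fs/2`) and `power` (uV^2/Hz).
#' @export
psdAutocorrelation <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("segment too short")
  # FT of the biased autocorrelation over lags -(n-1)..(n-1) equals the
  # periodogram of x padded to 2n points
  X <- stats::fft(c(x, numeric(n)))
  p2 <- (Mod(X)^2) / (n * fs)         # two-sided density on a 2n grid
  nf <- n + 1L                        # bins 0..fs/2 inclusive
  power <- p2[seq_len(nf)]
  power[2:(nf - 1L)] <- 2 * power[2:(nf - 1L)]
  list(freqs = (seq_len(nf) - 1L) * fs / (2 * n), power = power)
}

#' Absolute and relative band powers and power ratios
#'
#' Integrates the PSD over each band `[lo, hi)`; relative powers are
#' normalized by the total power over 0.5-30 Hz. Ratios default to the
#' alpha/theta ratio; the (delta+theta)/(alpha+beta) slowing ratio is
#' available via `ratios`. With zero total power the relative powers and
#' ratios are undefined and returned as `NA`.
#'
#' @param psd a list from [psdAutocorrelation()].
#' @param bands band table as from [eegBands()].
#' @param ratios character vector of ratios `"a_b"` = band a over band b,
#'   or `"slowing"` for (delta+theta)/(alpha+beta).
#' @param totalRange frequency range (Hz) defining total power.
#' @return named numeric vector: `abs_<band>`, `rel_<band>`,
#'   `ratio_<name>`.
#' @export
bandPowers <- function(psd, bands = eegBands(),
                       ratios = "alpha_theta",
                       totalRange = c(0.5, 30)) {
  f <- psd$freqs
  p <- psd$power
  df <- f[2] - f[1]
  integ <- function(lo, hi) sum(p[f >= lo & f < hi]) * df
  absP <- setNames(mapply(integ, bands$lo, bands$hi),
                   paste0("abs_", bands$name))
  total <- integ(totalRange[1], totalRange[2])
  relP <- if (total > 0) setNames(unname(absP) / total, paste0("rel_", bands$name))
          else setNames(rep(NA_real_, nrow(bands)), paste0("rel_", bands$name))
  byName <- setNames(unname(absP), bands$name)
  ratioVals <- vapply(ratios, function(r) {
    if (identical(r, "slowing")) {
      num <- byName[["delta"]] + byName[["theta"]]
      den <- byName[["alpha"]] + byName[["beta"]]
    } else {
      parts <- strsplit(r, "_", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !all(parts %in% names(byName)))
        stop("unknown ratio spec: ", r)
      num <- byName[[parts[1]]]
      den <- byName[[parts[2]]]
    }
    if (is.na(den) || den <= 0) NA_real_ else num / den
  }, numeric(1))
  names(ratioVals) <- paste0("ratio_", ratios)
  c(absP, relP, ratioVals)
}

#' Default EEG feature configuration
#'
#' @param ratios power ratios to compute (see [bandPowers()]).
#' @param apenM,apenRFrac approximate-entropy embedding and tolerance.
#' @param msenMaxScale largest multiscale-entropy scale.
#' @param lzcBinarize binarization rule for Lempel-Ziv complexity.
#' @return list of settings consumed by [extractEEGFeatures()].
#' @export
eegFeatureConfig <- function(ratios = "alpha_theta", apenM = 2L,
                             apenRFrac = 0.15, msenMaxScale = 10L,
                             lzcBinarize = "median") {
  list(ratios = ratios, apenM = apenM, apenRFrac = apenRFrac,
       msenMaxScale = msenMaxScale, lzcBinarize = lzcBinarize)
}

#' Subject-level EEG feature vector from a segment set
#'
#' Computes, per segment: absolute and relative band powers, power
#' ratios, approximate entropy, the multiscale-entropy curve (plus its
#' mean over scales), and Lempel-Ziv complexity; then averages each
#' feature across segments. Segments where a feature is undefined (e.g.
#' a ratio with zero denominator) are excluded from that feature's mean.
#'
#' @param segs a [SegmentSet-class] with at least one segment.
#' @param config list from [eegFeatureConfig()].
#' @return named numeric vector, names prefixed `eeg.`.
#' @export
extractEEGFeatures <- function(segs, config = eegFeatureConfig()) {
  stopifnot(is(segs, "SegmentSet"))
  if (nrow(segs@segments) < 1L) stop("no valid segments")
  fs <- segs@fs
  perSeg <- apply(segs@segments, 1L, function(seg) {
    bp <- bandPowers(psdAutocorrelation(seg, fs), ratios = config$ratios)
    apen <- approximateEntropy(seg, m = config$apenM, rFrac = config$apenRFrac)
    msen <- suppressWarnings(
      multiscaleEntropy(seg, m = config$apenM, rFrac = config$apenRFrac,
                        maxScale = config$msenMaxScale))
    if (length(msen) < config$msenMaxScale) { # pad dropped scales as NA
      full <- setNames(rep(NA_real_, config$msenMaxScale),
                       paste0("scale", seq_len(config$msenMaxScale)))
      full[names(msen)] <- msen
      msen <- full
    }
    lzc <- lempelZivComplexity(seg, binarize = config$lzcBinarize)$complexity
    c(bp, apen = apen, setNames(msen, paste0("msen_", names(msen))),
      msen_mean = mean(msen, na.rm = TRUE), lzc = lzc)
  })
  out <- rowMeans(perSeg, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_ # feature undefined in every segment
  setNames(out, paste0("eeg.", names(out)))
}
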