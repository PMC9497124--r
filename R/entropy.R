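#' Approximate entropy of a time series
#'
#' Regularity statistic `ApEn(m, r)` of Pincus: the difference
#' `Phi_m(r) - Phi_{m+1}(r)` where `Phi_k` is the average natural log of
#' the self-inclusive fraction of length-`k` templates within Chebyshev
#' distance `r` of each template. Low values indicate a regular,
#' predictable signal; a constant series has ApEn exactly 0.
#'
#' The tolerance is data-relative by convention: `rFrac * sd(x)` unless
#' an absolute `r` is given, which makes the statistic invariant
#' to affine rescaling of the input.
#'
#' @param x numeric series.
#' @param m embedding dimension (default 2).
#' @param r absolute tolerance; if `NULL`, `rFrac * sd(x)` is used.
#' @param rFrac tolerance as a fraction of the series SD (default 0.15).
#' @return Non-negative scalar (nats).
#' @seealso [sampleEntropy()], [multiscaleEntropy()]
#' @examples
#' approximateEntropy(rep(1, 100))          # 0: perfectly regular
#' approximateEntropy(rnorm(500))           # high: irregular
#' @export
approximateEntropy <- function(x, m = 2L, r = NULL, rFrac = 0.15) {
  x <- as.numeric(x)
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) return(0) # constant series: all templates match at any r > 0
    r <- rFrac * s
  }
  if (r <= 0) stop("tolerance r must be positive")
  if (length(x) <= m + 1L) stop("series too short for embedding dimension m")
  apen_cpp(x, as.integer(m), r)
}

#' Sample entropy of a time series
#'
#' `SampEn(m, r) = -ln(A/B)` with `A`, `B` the numbers of template pairs
#' (self-matches excluded) within tolerance `r` at lengths `m + 1` and
#' `m`. Returns `NA` when no template pair matches (undefined).
#'
#' @inheritParams approximateEntropy
#' @return Non-negative scalar (nats), or `NA` if undefined.
#' @export
sampleEntropy <- function(x, m = 2L, r = NULL, rFrac = 0.15) {
  x <- as.numeric(x)
  if (is.null(r)) {
    s <- stats::sd(x)
    if (s == 0) return(0)
    r <- rFrac * s
  }
  if (r <= 0) stop("tolerance r must be positive")
  if (length(x) <= m + 1L) stop("series too short for embedding dimension m")
  sampen_cpp(x, as.integer(m), r)
}

#' Multiscale entropy curve
#'
#' Coarse-grains the series at scales `1..maxScale` (non-overlapping
#' block means of length tau) and computes the sample entropy of each
#' coarse-grained series. The tolerance `r` is fixed once from the SD of
#' the original series, so the curve reflects structure across scales
#' rather than the shrinking variance of the block means. White noise
#' shows a decreasing curve; 1/f (pink) noise stays approximately flat.
#'
#' Scales whose coarse-grained series would be shorter than
#' `minScaleLen` samples are dropped with a warning.
#'
#' @inheritParams approximateEntropy
#' @param maxScale largest coarse-graining factor (default 10).
#' @param minScaleLen minimum coarse-grained length to keep a scale.
#' @return Named numeric vector `scale1..scaleK` of sample entropies.
#' @export
multiscaleEntropy <- function(x, m = 2L, rFrac = 0.15, maxScale = 10L,
                              minScaleLen = 10L) {
  x <- as.numeric(x)
  n <- length(x)
  s <- stats::sd(x)
  scales <- seq_len(maxScale)
  keep <- (n %/% scales) >= max(minScaleLen, m + 2L)
  if (!any(keep)) stop("series too short for any requested scale")
  if (!all(keep))
    warning(sprintf("series of length %d supports scales 1-%d only; larger scales dropped",
                    n, max(which(keep))))
  scales <- scales[keep]
  r <- rFrac * s
  out <- vapply(scales, function(tau) {
    if (s == 0) return(0)
    nb <- n %/% tau
    cg <- if (tau == 1L) x else
      colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
    sampen_cpp(cg, as.integer(m), r)
  }, numeric(1))
  names(out) <- paste0("scale", scales)
  out
}

#' Lempel-Ziv complexity of a series
#'
#' Binarizes the series at its median (default) or mean, runs the LZ76
#' exhaustive-history parse, and normalizes the word count `c(n)` as
#' `C = c(n) * log2(n) / n`, so that i.i.d. random binary sequences
#' approach 1 while regular sequences score much lower.
#'
#' @param x numeric series (length >= 2), or a logical/0-1 integer
#'   vector taken as the binary sequence directly.
#' @param binarize threshold rule, `"median"` (robust to amplitude
#'   outliers; values strictly above the median map to 1) or `"mean"`.
#' @return list with `c` (raw LZ76 parse count) and `complexity`
#'   (normalized value).
#' @examples
#' lempelZivComplexity(rep(0, 100))$c        # 2: one repeated pattern
#' lempelZivComplexity(rnorm(1000))$complexity  # near 1
#' @export
lempelZivComplexity <- function(x, binarize = c("median", "mean")) {
  n <- length(x)
  if (n < 2L) stop("sequence too short")
  if (is.logical(x) || (is.integer(x) && all(x %in% c(0L, 1L)))) {
    b <- as.integer(x)
  } else {
    binarize <- match.arg(binarize)
    thr <- if (binarize == "median") stats::median(x) else mean(x)
    b <- as.integer(x > thr)
  }
  cc <- lz76_cpp(b)
  list(c = cc, complexity = cc * log2(n) / n)
}
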