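# Plug-in mutual information and the greedy minimum-redundancy-
# maximum-relevance (MRMR) feature ranking.

#' Equal-frequency discretization
#'
#' Rank-based binning: depends only on the ordering of the values, so
#' any strictly monotone transform of a feature yields the same bins.
#'
#' @param x numeric vector.
#' @param nBins number of bins (>= 2).
#' @return integer bin indices in `1..nBins`.
#' @export
equalFrequencyBins <- function(x, nBins = 8L) {
  if (nBins < 2L) stop("nBins must be at least 2")
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * nBins / n))
}

#' Plug-in mutual information (bits)
#'
#' `M(X,Y) = sum p(x,y) log2(p(x,y) / (p(x) p(y)))` from the joint
#' contingency table. Discrete inputs (factors, or numerics with few
#' distinct values) are tabulated directly; continuous inputs are
#' discretized by equal-frequency binning first. Symmetric in its
#' arguments; tiny negative values from floating-point noise are
#' clipped to 0.
#'
#' @param x,y equal-length vectors.
#' @param estimator `"auto"`, `"discrete"`, or `"binned"`.
#' @param nBins bins for continuous inputs (default 8).
#' @return list: `value` (bits), `estimator`, `nBins`.
#' @export
mutualInformation <- function(x, y, estimator = c("auto", "discrete",
                                                  "binned"), nBins = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  estimator <- match.arg(estimator)
  disc <- function(v) {
    if (is.factor(v) || is.character(v) || is.logical(v)) return(as.integer(factor(v)))
    if (estimator == "discrete" || (estimator == "auto" &&
                                    length(unique(v)) <= max(nBins, 12L)))
      return(as.integer(factor(v)))
    equalFrequencyBins(v, nBins)
  }
  xi <- disc(x); yi <- disc(y)
  tab <- table(xi, yi)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
  list(value = max(mi, 0), estimator = estimator, nBins = as.integer(nBins))
}

#' Relevance of a feature subset to the class labels
#'
#' Mean over the subset of the mutual information between each feature
#' and the class variable.
#'
#' @param x numeric matrix (subjects x features), the candidate subset.
#' @param labels class labels (+1/-1 or factor).
#' @param nBins bins for continuous features.
#' @return scalar Theta (bits).
#' @export
relevance <- function(x, labels, nBins = 8L) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (ncol(x) == 0L) stop("empty feature set")
  mean(apply(x, 2, function(f)
    mutualInformation(f, labels, nBins = nBins)$value))
}

#' Redundancy of a feature against a feature set
#'
#' `Delta = (1/|S|^2) * sum_{f_j in S, f_j != f_i} M(f_i, f_j)`, with
#' `S` the already-selected set in the greedy step. An empty (or
#' singleton-self) set has zero redundancy.
#'
#' @param fi numeric vector, the candidate feature.
#' @param selected numeric matrix of selected features (columns), may
#'   be empty.
#' @param fiName optional column name identifying `fi` inside
#'   `selected`, excluded from the sum.
#' @param nBins bins for continuous features.
#' @return scalar Delta (bits).
#' @export
redundancy <- function(fi, selected, fiName = NULL, nBins = 8L) {
  if (is.null(dim(selected))) selected <- matrix(selected, ncol = 1)
  cols <- seq_len(ncol(selected))
  if (!is.null(fiName) && !is.null(colnames(selected)))
    cols <- cols[colnames(selected) != fiName]
  m <- ncol(selected)
  if (m == 0L || length(cols) == 0L) return(0)
  s <- sum(vapply(cols, function(j)
    mutualInformation(fi, selected[, j], nBins = nBins)$value, numeric(1)))
  s / m^2
}

#' Greedy MRMR feature ranking
#'
#' Forward selection under the minimum-redundancy-maximum-relevance
#' principle: the first feature maximizes relevance to the labels; each
#' subsequent step maximizes the quotient criterion
#' `Theta / Delta` (`"miq"`, default) or the difference `Theta - Delta`
#' (`"mid"`), with `Delta` the mean mutual information against the
#' already-selected set (scaled by `1/|S|^2`). Ties are broken by column
#' order; constant columns are skipped with a warning; `k` beyond the
#' number of usable features truncates with a warning.
#'
#' All features are discretized once (equal-frequency, on the data given,
#' which in a leakage-safe harness is the training fold).
#'
#' @param x numeric matrix (subjects x features) with column names.
#' @param labels class labels.
#' @param k number of features to select (default 20).
#' @param criterion `"miq"` or `"mid"`.
#' @param nBins equal-frequency bins (default 8).
#' @return An [MRMRRanking-class].
#' @export
mrmrRank <- function(x, labels, k = 20L, criterion = c("miq", "mid"),
                     nBins = 8L) {
  criterion <- match.arg(criterion)
  if (k < 1L) stop("k must be at least 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  constant <- apply(x, 2, function(v) length(unique(v[!is.na(v)])) < 2L)
  if (any(constant)) {
    warning("constant feature columns skipped: ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
  }
  D <- ncol(x)
  if (D == 0L) stop("no usable features")
  if (k > D) {
    warning(sprintf("k = %d exceeds %d usable features; truncating", k, D))
    k <- D
  }
  # discretize once so every pairwise MI uses the same code book
  xb <- apply(x, 2, function(v) {
    if (length(unique(v)) <= max(nBins, 12L)) as.integer(factor(v))
    else equalFrequencyBins(v, nBins)
  })
  colnames(xb) <- colnames(x)

  theta <- vapply(seq_len(D), function(j)
    mutualInformation(xb[, j], labels, estimator = "discrete")$value,
    numeric(1))
  names(theta) <- colnames(x)

  selected <- character()
  rows <- vector("list", k)
  candidates <- colnames(x)
  for (step in seq_len(k)) {
    if (step == 1L) {
      scores <- theta[candidates]
      deltas <- setNames(numeric(length(candidates)), candidates)
    } else {
      deltas <- vapply(candidates, function(f) {
        s <- sum(vapply(selected, function(g)
          mutualInformation(xb[, f], xb[, g],
                            estimator = "discrete")$value, numeric(1)))
        s / length(selected)^2
      }, numeric(1))
      scores <- if (criterion == "miq")
        theta[candidates] / pmax(deltas, .Machine$double.eps)
      else theta[candidates] - deltas
    }
    best <- candidates[which.max(scores)] # which.max: first max = column order
    rows[[step]] <- data.frame(rank = step, feature = best,
                               theta = unname(theta[best]),
                               delta = unname(deltas[best]),
                               score = unname(scores[best]))
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  new("MRMRRanking", ranking = do.call(rbind, rows), criterion = criterion,
      nBins = as.integer(nBins))
}
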