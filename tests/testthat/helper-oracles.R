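# Independent brute-force oracles, written literally from the defining
# formulas. They share no code with the package kernels they check.

# ApEn: double loop over all template pairs, self-inclusive counts.
apenOracle <- function(x, m, r) {
  n <- length(x)
  phi <- numeric(2)
  for (s in 0:1) {
    mm <- m + s
    nt <- n - mm + 1
    acc <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt)
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1
      acc <- acc + log(cnt / nt)
    }
    phi[s + 1] <- acc / nt
  }
  phi[1] - phi[2]
}

# SampEn: pair counts at lengths m and m+1, self-matches excluded.
sampenOracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# MsEn: coarse-grain by block means, then the SampEn oracle with r from
# the original series.
msenOracle <- function(x, m, rFrac, maxScale) {
  r <- rFrac * sd(x)
  vapply(seq_len(maxScale), function(tau) {
    nb <- length(x) %/% tau
    cg <- if (tau == 1) x else colMeans(matrix(x[1:(nb * tau)], nrow = tau))
    sampenOracle(cg, m, r)
  }, numeric(1))
}

# LZ76 exhaustive parse from the definition: each word is extended while
# it is reproducible from the preceding string (history plus the word
# minus its last character); the final word counts even if reproducible.
lz76Oracle <- function(b) {
  s <- paste(b, collapse = "")
  n <- length(b)
  cc <- 0L
  pos <- 1
  while (pos <= n) {
    len <- 1
    repeat {
      if (pos + len - 1 >= n) break
      word <- substr(s, pos, pos + len - 1)
      hist <- substr(s, 1, pos + len - 2)
      if (!grepl(word, hist, fixed = TRUE)) break
      len <- len + 1
    }
    cc <- cc + 1L
    pos <- pos + len
  }
  cc
}

# Plug-in MI (bits) from a contingency table of two discrete vectors.
miOracle <- function(x, y) {
  p <- table(x, y) / length(x)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  as.numeric(s)
}

# Greedy MRMR trace re-evaluated step by step from the criterion
# definition, on an already-discretized matrix.
mrmrTraceOracle <- function(xb, labels, k, criterion = "miq") {
  theta <- vapply(seq_len(ncol(xb)), function(j) miOracle(xb[, j], labels),
                  numeric(1))
  names(theta) <- colnames(xb)
  sel <- character()
  cand <- colnames(xb)
  out <- character()
  for (step in seq_len(k)) {
    if (step == 1) {
      sc <- theta[cand]
    } else {
      delta <- vapply(cand, function(f)
        sum(vapply(sel, function(g) miOracle(xb[, f], xb[, g]),
                   numeric(1))) / length(sel)^2, numeric(1))
      sc <- if (criterion == "miq")
        theta[cand] / pmax(delta, .Machine$double.eps)
      else theta[cand] - delta
    }
    best <- cand[which.max(sc)]
    out <- c(out, best)
    sel <- c(sel, best)
    cand <- setdiff(cand, best)
  }
  out
}

# AUC as the Mann-Whitney pair statistic: fraction of (positive,
# negative) pairs ranked correctly, ties counting one half.
aucPairOracle <- function(scores, labels) {
  sp <- scores[labels > 0]; sn <- scores[labels < 0]
  s <- 0
  for (a in sp) for (b in sn)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(sp) * length(sn))
}

# Pearson chi-square statistic from the direct formula.
chisqOracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
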