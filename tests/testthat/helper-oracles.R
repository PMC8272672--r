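# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementation.

# direct 2-D convolution over an H x W x C array, kernel kh x kw x C x OC
naiveConv2d <- function(x, w, b = NULL, padTop = 0, padLeft = 0,
                        padBottom = 0, padRight = 0, stride = 1) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x); k <- dim(w)
  if (is.null(b)) b <- numeric(k[4])
  xp <- array(0, c(d[1] + padTop + padBottom, d[2] + padLeft + padRight, d[3]))
  xp[padTop + seq_len(d[1]), padLeft + seq_len(d[2]), ] <- x
  Ho <- (dim(xp)[1] - k[1]) %/% stride + 1
  Wo <- (dim(xp)[2] - k[2]) %/% stride + 1
  out <- array(0, c(Ho, Wo, k[4]))
  for (oc in seq_len(k[4]))
    for (oh in seq_len(Ho))
      for (ow in seq_len(Wo)) {
        acc <- b[oc]
        for (c in seq_len(d[3]))
          for (i in seq_len(k[1]))
            for (j in seq_len(k[2]))
              acc <- acc + xp[(oh - 1) * stride + i, (ow - 1) * stride + j, c] *
                w[i, j, c, oc]
        out[oh, ow, oc] <- acc
      }
  out
}

# sliding-window max pooling of a square matrix
naiveMaxPool <- function(m, kernel, stride) {
  Ho <- (nrow(m) - kernel) %/% stride + 1
  Wo <- (ncol(m) - kernel) %/% stride + 1
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho))
    for (j in seq_len(Wo))
      out[i, j] <- max(m[(i - 1) * stride + seq_len(kernel),
                         (j - 1) * stride + seq_len(kernel)])
  out
}

# nearest-neighbour 2x upsampling of an H x W x C array
naiveUpsample2x <- function(x) {
  d <- dim(x)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c in seq_len(d[3]))
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        out[2 * i - c(1, 0), 2 * j - c(1, 0), c] <- x[i, j, c]
  out
}

# AUC by exhaustive positive x negative pair counting
naivePairAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# confusion counting by explicit loop
naiveConfusion <- function(calls, labels) {
  tp <- fp <- tn <- fn <- 0
  for (k in seq_along(calls)) {
    if (calls[k] == 1 && labels[k] == 1) tp <- tp + 1
    if (calls[k] == 1 && labels[k] == 0) fp <- fp + 1
    if (calls[k] == 0 && labels[k] == 0) tn <- tn + 1
    if (calls[k] == 0 && labels[k] == 1) fn <- fn + 1
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# textbook Pearson chi-square
naiveChisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

# RBM energy by triple loop
naiveEnergy <- function(x, y, t, beta, W) {
  e <- 0
  for (i in seq_along(x)) e <- e - t[i] * x[i]
  for (j in seq_along(y)) e <- e - beta[j] * y[j]
  for (i in seq_along(x))
    for (j in seq_along(y))
      e <- e - x[i] * W[i, j] * y[j]
  e
}

# a small RBM with hand-settable parameters
setParams <- function(model, t = NULL, beta = NULL, W = NULL) {
  if (!is.null(t)) model@visibleBias <- t
  if (!is.null(beta)) model@hiddenBias <- beta
  if (!is.null(W)) model@weights <- W
  model
}

# single-channel weight list for a two-level toy pyramid (blocks 4 and 5)
toyFusionWeights <- function(lat4, lat5, smooth4, b = 0) {
  mk <- function(k) array(k, c(dim(k), 1L, 1L))
  list(lateral = list(block4 = list(w = mk(lat4), b = b),
                      block5 = list(w = mk(lat5), b = b)),
       smooth = list(block4 = list(w = mk(smooth4), b = b)))
}

toyPyramid <- function(raw4, raw5) {
  a4 <- raw4; dim(a4) <- c(dim(raw4), 1L)
  a5 <- raw5; dim(a5) <- c(dim(raw5), 1L)
  new("FeaturePyramid", rawMaps = list(block4 = a4, block5 = a5),
      fusedMaps = list(), upsampled = list(), blockRange = 4:5)
}
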