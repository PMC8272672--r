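# The handcrafted ("traditional") modality: 32 named intensity, texture
# and region-shape statistics. The set is a documented, replaceable
# default; ordering is fixed and part of the interface.

.DARK_THRESHOLD <- 0.35
.BRIGHT_THRESHOLD <- 0.75

.glcmFeatures <- function(px) {
  lv <- matrix(pmin(7, floor(px * 8)), nrow(px), ncol(px))
  a <- lv[, -ncol(lv)]; b <- lv[, -1L]
  tab <- table(factor(a, levels = 0:7), factor(b, levels = 0:7))
  P <- (tab + t(tab)) / (2 * length(a))   # symmetric co-occurrence
  P <- as.matrix(P)
  i <- row(P) - 1; j <- col(P) - 1
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (s_i > 0 && s_j > 0) sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j) else 0
  pnz <- P[P > 0]
  c(glcm_contrast = sum((i - j)^2 * P),
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_energy = sum(P^2),
    glcm_correlation = corr,
    glcm_entropy = if (length(pnz) > 1) -sum(pnz * log2(pnz)) else 0)
}

# ratio of the thinnest point of a dark-pixel profile to its typical
# thickness; a focal gap in a dark band drives this toward 0
.profileGapRatio <- function(cnt) {
  support <- which(cnt > 0)
  if (length(support) < 5L) return(1)
  inner <- cnt[seq(min(support), max(support))]
  med <- stats::median(inner)
  if (med <= 0) return(1)
  min(2, min(inner) / med)
}

#' Extract the traditional (handcrafted) feature vector
#'
#' Computes 32 named statistics in four families: intensity distribution
#' (moments, quantiles, histogram entropy/energy/mode over 32 bins),
#' finite-difference gradients, gray-level co-occurrence texture at 8
#' levels, and region-shape statistics of the dark (low-signal) region
#' below intensity 0.35 — including the thinnest-point ratio of its row
#' and column profiles, which responds to a focal bright gap in a dark
#' ligament band. For a constant image all dispersion, entropy and
#' texture features are 0 by convention. The interquartile-range feature
#' is invariant to adding a constant offset (as long as values stay in
#' range); the quantile features shift by exactly that offset.
#'
#' @param image a \linkS4class{LabeledImage} or numeric matrix in [0, 1].
#' @return named numeric vector of length 32, deterministic and finite.
#' @export
traditionalFeatures <- function(image) {
  px <- if (is(image, "LabeledImage")) image@pixels else image
  v <- as.numeric(px)
  m <- mean(v); s <- stats::sd(v)
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  if (s > 0) {
    z <- (v - m) / s
    skew <- mean(z^3); kurt <- mean(z^4) - 3
  } else skew <- kurt <- 0
  h <- tabulate(pmin(32L, floor(v * 32) + 1L), nbins = 32L) / length(v)
  hn <- h[h > 0]
  ent <- if (length(hn) > 1) -sum(hn * log2(hn)) else 0

  gr <- px[-1, ] - px[-nrow(px), ]   # row direction
  gc <- px[, -1] - px[, -ncol(px)]   # column direction
  n1 <- min(nrow(gr), nrow(gc)); n2 <- min(ncol(gr), ncol(gc))
  gm <- sqrt(gr[seq_len(n1), seq_len(n2)]^2 + gc[seq_len(n1), seq_len(n2)]^2)

  dark <- px < .DARK_THRESHOLD
  nd <- sum(dark)
  darkStats <- if (nd > 0) {
    dv <- px[dark]
    c(dark_mean = mean(dv), dark_sd = if (nd > 1) stats::sd(dv) else 0,
      dark_centroid_row = mean(row(px)[dark]) / nrow(px),
      dark_centroid_col = mean(col(px)[dark]) / ncol(px))
  } else c(dark_mean = 0, dark_sd = 0, dark_centroid_row = 0, dark_centroid_col = 0)

  out <- c(
    int_mean = m, int_sd = s, int_min = min(v), int_max = max(v),
    int_median = qs[2], int_q25 = qs[1], int_q75 = qs[3],
    int_iqr = qs[3] - qs[1], int_skewness = skew, int_kurtosis = kurt,
    hist_entropy = ent, hist_energy = sum(h^2),
    hist_mode = (which.max(h) - 0.5) / 32,
    grad_mean_abs_row = mean(abs(gr)), grad_mean_abs_col = mean(abs(gc)),
    grad_mag_mean = mean(gm), grad_mag_sd = if (length(gm) > 1) stats::sd(gm) else 0,
    grad_mag_max = max(gm), grad_mag_q90 = stats::quantile(gm, 0.9, names = FALSE),
    .glcmFeatures(px),
    dark_fraction = nd / length(v),
    bright_fraction = mean(v > .BRIGHT_THRESHOLD),
    darkStats,
    dark_row_gap = .profileGapRatio(rowSums(dark)),
    dark_col_gap = .profileGapRatio(colSums(dark)))
  stopifnot(length(out) == 32L, all(is.finite(out)))
  out
}

#' Fit / apply min-max feature scaling
#'
#' Scaling is fitted on the training set only and stored with the model;
#' constant features map to 0. Applied values are clipped to [0, 1] so
#' held-out samples outside the training range stay valid RBM inputs.
#'
#' @param x numeric matrix, rows = samples.
#' @return \code{fitScaling}: list with \code{min} and \code{range};
#'   \code{applyScaling}: matrix of the same shape with entries in [0, 1].
#' @export
fitScaling <- function(x) {
  mn <- apply(x, 2L, min)
  rg <- apply(x, 2L, max) - mn
  list(min = mn, range = rg)
}

#' @rdname fitScaling
#' @param scaling list returned by \code{fitScaling}.
#' @export
applyScaling <- function(x, scaling) {
  z <- sweep(x, 2L, scaling$min, "-")
  rg <- ifelse(scaling$range > 0, scaling$range, 1)
  z <- sweep(z, 2L, rg, "/")
  z[, scaling$range <= 0] <- 0
  clip01(z)
}
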