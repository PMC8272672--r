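#' Create an untrained energy-fusion model
#'
#' @param nVisible visible units = length of the fused feature vector
#'   m = (c, o) (traditional + deep, both scaled to [0, 1]).
#' @param nHidden hidden units; must be < nVisible.
#' @param seed seed for the small Gaussian weight initialization.
#' @return an \linkS4class{RBMModel} with zero biases and N(0, 0.01) weights.
#' @export
rbmModel <- function(nVisible, nHidden, seed = 1L) {
  with_seed(seed, new("RBMModel",
    visibleBias = numeric(nVisible), hiddenBias = numeric(nHidden),
    weights = matrix(rnorm(nVisible * nHidden, 0, 0.01), nVisible, nHidden),
    outWeights = numeric(nHidden), outBias = 0,
    trained = FALSE, scaling = list(), trainLog = data.frame()))
}

#' @describeIn RBMModel-class number of visible units.
#' @export
setMethod("nVisible", "RBMModel", function(object) length(object@visibleBias))

#' @describeIn RBMModel-class number of hidden units.
#' @export
setMethod("nHidden", "RBMModel", function(object) length(object@hiddenBias))

setMethod("show", "RBMModel", function(object) {
  cat(sprintf("RBMModel: %d visible -> %d hidden units, %s\n",
              nVisible(object), nHidden(object),
              if (object@trained) "trained" else "untrained"))
})

#' Hidden-layer forward pass
#'
#' p_e = sigmoid(sum_i m_i theta_ie + beta_e); outputs are strictly in
#' (0, 1). \code{variant = "printed"} reproduces the published variant in
#' which the visible bias is added to the input before the weight product
#' (sigmoid((m_i + t_i) theta_ie + beta_e)); it is kept for comparison
#' only, as it makes the visible bias act twice.
#'
#' @param m numeric vector (one sample) or matrix (rows = samples) of
#'   visible values in [0, 1].
#' @param model an \linkS4class{RBMModel}.
#' @param variant \code{"standard"} (default) or \code{"printed"}.
#' @return hidden probabilities, vector or matrix matching \code{m}.
#' @export
hiddenForward <- function(m, model, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, nrow = 1L)
  if (ncol(m) != nVisible(model))
    stop("sample length ", ncol(m), " != visible units ", nVisible(model))
  if (variant == "printed") m <- sweep(m, 2L, model@visibleBias, "+")
  p <- sigmoid(sweep(m %*% model@weights, 2L, model@hiddenBias, "+"))
  if (vec) drop(p) else p
}

#' RBM energy of a joint configuration
#'
#' Standard bilinear form E(x, y) = -sum_i t_i x_i - sum_e beta_e y_e
#' - sum_i sum_e x_i theta_ie y_e. \code{variant = "printed"} substitutes
#' the visible bias for the visible state inside the interaction term, as
#' printed in the source formulation (kept for comparison).
#'
#' @param x visible binary vector; @param y hidden binary vector.
#' @param model an \linkS4class{RBMModel}.
#' @param variant \code{"standard"} or \code{"printed"}.
#' @return scalar energy.
#' @export
rbmEnergy <- function(x, y, model, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  stopifnot(length(x) == nVisible(model), length(y) == nHidden(model))
  inter <- if (variant == "printed") model@visibleBias else x
  -sum(model@visibleBias * x) - sum(model@hiddenBias * y) -
    drop(inter %*% model@weights %*% y)
}

.enumBinary <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 1L, 0L))
  g <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(g) <- NULL
  g
}

#' Exact marginal distributions by enumeration
#'
#' Enumerates all joint binary configurations to compute the partition
#' function Z = sum exp(-E) and the marginals p(x) = (1/Z) sum_y exp(-E)
#' and p(y) = (1/Z) sum_x exp(-E). Refuses models with more than 20 total
#' units.
#'
#' @param model an \linkS4class{RBMModel}.
#' @return list with \code{visibleStates}, \code{pVisible},
#'   \code{hiddenStates}, \code{pHidden}, \code{logZ}.
#' @export
exactMarginals <- function(model) {
  nv <- nVisible(model); nh <- nHidden(model)
  if (nv + nh > 20L)
    stop("exact mode only supports <= 20 total units (got ", nv + nh, ")")
  X <- .enumBinary(nv); Y <- .enumBinary(nh)
  # E[a,b] for visible config a, hidden config b
  E <- -outer(drop(X %*% model@visibleBias), drop(Y %*% model@hiddenBias), "+") -
    X %*% model@weights %*% t(Y)
  mx <- max(-E)
  B <- exp(-E - mx)
  Z <- sum(B)
  list(visibleStates = X, pVisible = rowSums(B) / Z,
       hiddenStates = Y, pHidden = colSums(B) / Z,
       logZ = log(Z) + mx)
}

# log of the unnormalized marginal: t.x + sum_e softplus(beta_e + x.theta_e)
.freeEnergyNeg <- function(x, model) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  act <- sweep(x %*% model@weights, 2L, model@hiddenBias, "+")
  drop(x %*% model@visibleBias) + rowSums(log1p(exp(-abs(act))) + pmax(act, 0))
}

#' Exact log-likelihood of visible samples
#'
#' Sum over samples of log p(x | model), with the hidden layer summed out
#' analytically and log Z obtained by enumerating the binary visible
#' configurations (so the visible count must be <= 20). Rows may be
#' real-valued in [0, 1] (Bernoulli-expectation encoding). Natural log.
#'
#' @param x numeric matrix, rows = samples.
#' @param model an \linkS4class{RBMModel}.
#' @return scalar log-likelihood.
#' @export
exactLogLikelihood <- function(x, model) {
  nv <- nVisible(model)
  if (nv > 20L) stop("exact mode only supports <= 20 visible units")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  X <- .enumBinary(nv)
  fe <- .freeEnergyNeg(X, model)
  mx <- max(fe)
  logZ <- mx + log(sum(exp(fe - mx)))
  sum(.freeEnergyNeg(x, model)) - nrow(x) * logZ
}

#' Training configuration for the fusion model
#'
#' @param cdSteps contrastive-divergence steps k (default 1).
#' @param learningRate CD learning rate (default 0.05).
#' @param epochs unsupervised epochs (default 50).
#' @param batchSize minibatch size (default 16).
#' @param superviseEpochs iteration cap for the supervised logistic-head
#'   fit; 0 skips the supervised phase entirely.
#' @param seed training seed (hidden-unit sampling, shuffling).
#' @return validated list of settings.
#' @export
trainConfig <- function(cdSteps = 1L, learningRate = 0.05, epochs = 50L,
                        batchSize = 16L, superviseEpochs = 100L, seed = 1L) {
  stopifnot(cdSteps >= 1L, learningRate > 0, epochs >= 1L, batchSize >= 1L,
            superviseEpochs >= 0L)
  list(cdSteps = as.integer(cdSteps), learningRate = learningRate,
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       superviseEpochs = as.integer(superviseEpochs), seed = as.integer(seed))
}

#' Train the energy-fusion classifier
#'
#' Two phases. (1) Unsupervised contrastive-divergence ascent on the
#' marginal log-likelihood of the fused feature vectors: real-valued
#' visible units in [0, 1] are treated as Bernoulli expectations
#' (mean-field reconstruction), hidden units are sampled. Labels play no
#' role in this phase. When the visible layer is small enough to
#' enumerate (<= 15 units) the exact log-likelihood is recorded per epoch
#' in the training log. (2) The logistic output unit on the hidden
#' probabilities is fitted by cross-entropy gradient descent; this phase
#' requires both classes. Fully deterministic given the config seed.
#'
#' @param x numeric matrix of fused samples, rows in [0, 1].
#' @param labels binary vector (0/1), one per row; used in phase 2 only.
#' @param nHidden hidden units (< ncol(x)).
#' @param config a \code{\link{trainConfig}} list.
#' @param scaling optional scaling list to store with the model.
#' @return a trained \linkS4class{RBMModel}.
#' @export
trainFusionModel <- function(x, labels, nHidden, config = trainConfig(),
                             scaling = list()) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, length(labels) == nrow(x))
  if (min(x) < 0 || max(x) > 1) stop("fused samples must lie in [0, 1]")
  if (config$superviseEpochs > 0L && length(unique(labels)) < 2L)
    stop("supervised phase requires both classes in the training labels")
  model <- rbmModel(ncol(x), nHidden, seed = config$seed)
  nv <- ncol(x); n <- nrow(x)
  logRows <- list()
  with_seed(config$seed + 1L, {
    W <- model@weights; tb <- model@visibleBias; hb <- model@hiddenBias
    lr <- config$learningRate
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1L, n)]
        v0 <- x[idx, , drop = FALSE]
        h0p <- sigmoid(sweep(v0 %*% W, 2L, hb, "+"))
        hs <- matrix(runif(length(h0p)) < h0p, nrow(h0p), ncol(h0p)) * 1
        vk <- v0; hkp <- h0p
        for (k in seq_len(config$cdSteps)) {
          vk <- sigmoid(sweep(hs %*% t(W), 2L, tb, "+"))
          hkp <- sigmoid(sweep(vk %*% W, 2L, hb, "+"))
          if (k < config$cdSteps)
            hs <- matrix(runif(length(hkp)) < hkp, nrow(hkp), ncol(hkp)) * 1
        }
        q <- length(idx)
        W <- W + lr * (crossprod(v0, h0p) - crossprod(vk, hkp)) / q
        tb <- tb + lr * colMeans(v0 - vk)
        hb <- hb + lr * colMeans(h0p - hkp)
      }
      if (nv <= 15L) {
        model@weights <- W; model@visibleBias <- tb; model@hiddenBias <- hb
        logRows[[ep]] <- data.frame(epoch = ep,
                                    logLik = exactLogLikelihood(x, model))
      }
    }
    model@weights <- W; model@visibleBias <- tb; model@hiddenBias <- hb

    if (config$superviseEpochs > 0L) {
      # cross-entropy fit of the logistic output unit = binomial maximum
      # likelihood; solved by iteratively reweighted least squares
      H <- hiddenForward(x, model)
      fit <- suppressWarnings(stats::glm.fit(
        cbind(1, H), as.numeric(labels), family = stats::binomial(),
        control = list(maxit = config$superviseEpochs)))
      cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      model@outWeights <- cf[-1]; model@outBias <- cf[1]
      model@trained <- TRUE
    }
  })
  model@scaling <- scaling
  model@trainLog <- if (length(logRows)) do.call(rbind, logRows) else data.frame()
  validObject(model)
  model
}

#' Predict with the trained fusion model
#'
#' W = sigmoid of the affine output over the hidden probabilities; the
#' binary call is positive when W >= 0.5 (the boundary itself counts as
#' positive).
#'
#' @param m fused sample vector or matrix (rows = samples) in [0, 1].
#' @param model a trained \linkS4class{RBMModel}.
#' @return data.frame with columns \code{prob} and \code{call}.
#' @export
predictFusion <- function(m, model) {
  if (!model@trained)
    stop("model has no trained output head; run trainFusionModel first")
  H <- hiddenForward(m, model)
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  p <- sigmoid(drop(H %*% model@outWeights) + model@outBias)
  data.frame(prob = p, call = as.integer(p >= 0.5))
}

#' Sample binary visible configurations from a small RBM
#'
#' Exact sampling from the enumerated marginal p(x); used for
#' parameter-recovery studies on models small enough to enumerate.
#'
#' @param model an \linkS4class{RBMModel} with <= 20 total units.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return n x nVisible binary matrix.
#' @export
sampleVisible <- function(model, n, seed = 1L) {
  mg <- exactMarginals(model)
  with_seed(seed, {
    idx <- sample.int(length(mg$pVisible), n, replace = TRUE, prob = mg$pVisible)
    mg$visibleStates[idx, , drop = FALSE]
  })
}
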