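#' Create batch-normalization parameters
#'
#' @param nFeatures number of features (channels).
#' @param scale,shift initial per-feature affine parameters (recycled).
#' @param eps variance guard, must be > 0.
#' @param momentum weight of each new batch in the running-moment update.
#' @return a \linkS4class{BNParams}.
#' @export
bnParams <- function(nFeatures, scale = 1, shift = 0, eps = 1e-5,
                     momentum = 0.1) {
  new("BNParams", scale = rep_len(scale, nFeatures),
      shift = rep_len(shift, nFeatures), eps = eps,
      runningMean = numeric(nFeatures), runningVar = rep(1, nFeatures),
      momentum = momentum, initialized = FALSE)
}

#' Batch normalization
#'
#' Per feature n, output = scale_n * (x - q_n) / sqrt(v_n + eps) + shift_n,
#' where in train mode q_n and v_n are the batch mean and biased batch
#' variance (and the running estimates are updated), and in eval mode the
#' running estimates are used.
#'
#' @param x numeric matrix, rows = batch samples, columns = features; a
#'   plain vector is treated as a single feature's batch.
#' @param params a \linkS4class{BNParams}.
#' @param mode \code{"train"} or \code{"eval"}.
#' @return list with \code{values} (normalized batch, same shape as
#'   \code{x}) and \code{params} (updated in train mode).
#' @export
batchNormalize <- function(x, params, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (ncol(x) != length(params@scale))
    stop("x has ", ncol(x), " features but params expect ", length(params@scale))
  if (mode == "train") {
    if (nrow(x) < 1L) stop("train mode needs a batch of size >= 1")
    q <- colMeans(x)
    v <- colMeans(x^2) - q^2          # biased batch variance
    v <- pmax(v, 0)                   # guard tiny negative rounding
    m <- params@momentum
    if (params@initialized) {
      params@runningMean <- (1 - m) * params@runningMean + m * q
      params@runningVar <- (1 - m) * params@runningVar + m * v
    } else {
      params@runningMean <- q
      params@runningVar <- v
      params@initialized <- TRUE
    }
  } else {
    if (!params@initialized)
      stop("eval mode before any train-mode batch has been seen")
    q <- params@runningMean
    v <- params@runningVar
  }
  z <- sweep(x, 2L, q, "-")
  z <- sweep(z, 2L, sqrt(v + params@eps), "/")
  z <- sweep(z, 2L, params@scale, "*")
  z <- sweep(z, 2L, params@shift, "+")
  list(values = if (vec) drop(z) else z, params = params)
}

#' Rectified linear activation, elementwise max(0, x)
#'
#' @param x numeric vector, matrix or array.
#' @export
relu <- function(x) {
  x[] <- pmax(x, 0)
  x
}

#' Adaptive max pooling
#'
#' Pools an In x In (x channels) map to outSize x outSize using
#' stride = floor(In / Out) and kernel = In - (Out - 1) * stride, with no
#' padding, so the output side is exactly \code{outSize} for any input.
#'
#' @param map numeric matrix or height x width x channels array (square
#'   spatial extent).
#' @param outSize requested output side, <= input side.
#' @return pooled map of the same rank as the input.
#' @export
adaptiveMaxPool <- function(map, outSize) {
  wasMatrix <- is.matrix(map)
  if (wasMatrix) dim(map) <- c(dim(map), 1L)
  inSize <- dim(map)[1]
  if (dim(map)[2] != inSize) stop("adaptiveMaxPool expects a square map")
  outSize <- as.integer(outSize)
  if (outSize > inSize) stop("outSize ", outSize, " exceeds input side ", inSize)
  stride <- inSize %/% outSize
  kernel <- inSize - (outSize - 1L) * stride
  out <- maxpool_hwc(map, dim(map), kernel, stride)
  if (wasMatrix) out <- matrix(out, dim(out)[1], dim(out)[2])
  out
}

#' Draw a seeded random projection to the deep feature dimension
#'
#' @param inputLength flattened length of the pooled map.
#' @param outDim deep feature dimension; default 1026.
#' @param seed seed for the draws.
#' @return list with weight matrix \code{w} (inputLength x outDim) and
#'   bias \code{b}.
#' @export
randomProjection <- function(inputLength, outDim = 1026L, seed = 1L) {
  with_seed(seed, list(
    w = matrix(rnorm(inputLength * outDim, 0, sqrt(2 / inputLength)),
               inputLength, outDim),
    b = numeric(outDim)))
}

#' Project a pooled map to the deep feature vector
#'
#' Flattens the pooled map and applies the affine projection (the
#' full-size-convolution equivalent of a fully connected layer) followed
#' by ReLU. The default deep dimension is 1026.
#'
#' @param pooled pooled feature map (matrix or array) or a numeric vector.
#' @param projection output of \code{\link{randomProjection}}.
#' @return numeric vector of length \code{ncol(projection$w)}.
#' @export
projectDeepFeatures <- function(pooled, projection) {
  v <- as.numeric(pooled)
  if (length(v) != nrow(projection$w))
    stop("flattened length ", length(v), " does not match projection input ",
         nrow(projection$w))
  relu(drop(v %*% projection$w) + projection$b)
}
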