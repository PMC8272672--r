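#' Create a backbone configuration
#'
#' @param inputSize input image side; must be divisible by 16 (four
#'   halvings). Default 64, a desk-scale setting; 224 reproduces the
#'   classic transfer-learning geometry (block sides 112, 56, 28, 14).
#' @param blockRange contiguous block indices in 1..5; default \code{2:5}.
#' @param channels output channels of the five blocks.
#' @param fusedChannels channel width of the fused pyramid; default 64.
#' @param weightsMode \code{"seeded_random"} or \code{"checkpoint"}.
#' @param seed seed for the weight draws.
#' @return a \linkS4class{BackboneConfig}.
#' @export
backboneConfig <- function(inputSize = 64L, blockRange = 2:5,
                           channels = c(8L, 16L, 32L, 32L, 32L),
                           fusedChannels = 64L,
                           weightsMode = "seeded_random", seed = 1L) {
  new("BackboneConfig", weightsMode = weightsMode,
      blockRange = as.integer(blockRange), inputSize = as.integer(inputSize),
      channels = as.integer(channels), fusedChannels = as.integer(fusedChannels),
      seed = as.integer(seed))
}

conv2d <- function(x, w, b = NULL, pad = c(0L, 0L, 0L, 0L), stride = 1L) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.null(b)) b <- numeric(dim(w)[4])
  conv2d_hwc(x, dim(x), w, dim(w), b, pad[1], pad[2], pad[3], pad[4], stride)
}

heKernel <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

#' Draw frozen seeded-random backbone and fusion weights
#'
#' The backbone is never trained here: in \code{"seeded_random"} mode its
#' weights are deterministic He-scaled Gaussian draws with zero biases,
#' acting as a fixed random convolutional feature extractor (the same
#' frozen-backbone role a pretrained network plays, without requiring a
#' checkpoint). All downstream training leaves these untouched.
#'
#' @param config a \linkS4class{BackboneConfig}.
#' @return a list with per-block 3x3 kernels, per-level lateral 2x2 and
#'   smoothing 5x5 fusion kernels, and the config.
#' @export
randomBackboneWeights <- function(config) {
  validObject(config)
  with_seed(config@seed, {
    chan <- config@channels
    blocks <- lapply(1:5, function(g) {
      cin <- if (g == 1L) 1L else chan[g - 1L]
      list(w = heKernel(3L, 3L, cin, chan[g]), b = numeric(chan[g]))
    })
    fc <- config@fusedChannels
    lateral <- list(); smooth <- list()
    for (g in config@blockRange) {
      lateral[[paste0("block", g)]] <-
        list(w = heKernel(2L, 2L, chan[g], fc), b = numeric(fc))
      if (g < max(config@blockRange))
        smooth[[paste0("block", g)]] <-
          list(w = heKernel(5L, 5L, fc, fc), b = numeric(fc))
    }
    list(blocks = blocks, lateral = lateral, smooth = smooth, config = config)
  })
}

#' Extract the raw feature pyramid of one image
#'
#' Block 1 is a stride-1 3x3 convolution + ReLU at full resolution; each
#' later block convolves, applies ReLU and halves the spatial side with a
#' 2x2 max pool, so the block-g map has side inputSize / 2^(g-1). Maps
#' are collected for the configured block range only.
#'
#' @param image a \linkS4class{LabeledImage} or a numeric matrix in [0, 1].
#' @param weights output of \code{\link{randomBackboneWeights}} (or a
#'   loaded checkpoint of the same shape).
#' @return a \linkS4class{FeaturePyramid} with raw maps only.
#' @export
extractPyramid <- function(image, weights) {
  px <- if (is(image, "LabeledImage")) image@pixels else image
  config <- weights$config
  if (nrow(px) < 32L || ncol(px) < 32L)
    stop("image side must be at least 32 pixels")
  if (nrow(px) != config@inputSize)
    stop("image side ", nrow(px), " does not match configured inputSize ",
         config@inputSize)
  x <- px; dim(x) <- c(dim(px), 1L)
  raw <- list()
  for (g in 1:max(config@blockRange)) {
    bl <- weights$blocks[[g]]
    x <- conv2d(x, bl$w, bl$b, pad = c(1L, 1L, 1L, 1L))
    x[] <- pmax(x, 0)
    if (g > 1L) x <- maxpool_hwc(x, dim(x), 2L, 2L)
    if (g %in% config@blockRange) raw[[paste0("block", g)]] <- x
  }
  new("FeaturePyramid", rawMaps = raw, fusedMaps = list(), upsampled = list(),
      blockRange = config@blockRange)
}

upsample2x <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

# reconcile a <=1-pixel size mismatch between the upsampled map and the
# lateral target (odd sizes); larger disagreements are internal errors
.fitTo <- function(x, targetDim) {
  d <- dim(x)
  if (any(abs(d[1:2] - targetDim[1:2]) > 1L))
    stop("internal pyramid inconsistency: upsampled ", d[1], "x", d[2],
         " vs target ", targetDim[1], "x", targetDim[2])
  if (!all(d[1:2] == targetDim[1:2])) {
    message("pyramid: adjusting upsampled map by one pixel (",
            d[1], "x", d[2], " -> ", targetDim[1], "x", targetDim[2], ")")
    out <- array(0, c(targetDim[1:2], d[3]))
    h <- min(d[1], targetDim[1]); w <- min(d[2], targetDim[2])
    out[seq_len(h), seq_len(w), ] <- x[seq_len(h), seq_len(w), , drop = FALSE]
    x <- out
  }
  x
}

#' Top-down pyramid fusion
#'
#' The coarsest raw map is sent through its lateral 2x2 convolution to
#' become the top fused map. Walking down, each fused map is 2x
#' nearest-neighbour upsampled, summed pixelwise with the lateral 2x2
#' convolution of the raw map one level below, and the sum is smoothed by
#' a 5x5 convolution to remove upsampling aliasing. The 2x2 kernel uses
#' asymmetric zero padding (1 pixel right/bottom) and the 5x5 kernel
#' symmetric padding 2, so every map keeps its spatial size and the
#' pixelwise sum is well defined.
#'
#' @param pyramid a \linkS4class{FeaturePyramid} with raw maps.
#' @param weights backbone weight list carrying \code{lateral} and
#'   \code{smooth} kernels.
#' @return the pyramid with \code{fusedMaps} and \code{upsampled} populated.
#' @export
fusePyramid <- function(pyramid, weights) {
  br <- pyramid@blockRange
  if (!all(paste0("block", br) %in% names(pyramid@rawMaps)))
    stop("raw maps missing for the configured block range")
  fused <- list(); up <- list()
  top <- max(br)
  for (g in rev(br)) {
    key <- paste0("block", g)
    lat <- weights$lateral[[key]]
    lateralMap <- conv2d(pyramid@rawMaps[[key]], lat$w, lat$b,
                         pad = c(0L, 0L, 1L, 1L))
    if (g == top) {
      fused[[key]] <- lateralMap
    } else {
      k <- upsample2x(fused[[paste0("block", g + 1L)]])
      k <- .fitTo(k, dim(lateralMap))
      up[[key]] <- k
      sm <- weights$smooth[[key]]
      fused[[key]] <- conv2d(lateralMap + k, sm$w, sm$b, pad = c(2L, 2L, 2L, 2L))
    }
  }
  new("FeaturePyramid", rawMaps = pyramid@rawMaps, fusedMaps = fused,
      upsampled = up, blockRange = br)
}

#' @describeIn FeaturePyramid-class raw per-block maps.
#' @export
setMethod("rawMaps", "FeaturePyramid", function(object) object@rawMaps)

#' @describeIn FeaturePyramid-class fused maps (after \code{fusePyramid}).
#' @export
setMethod("fusedMaps", "FeaturePyramid", function(object) object@fusedMaps)

setMethod("show", "FeaturePyramid", function(object) {
  cat(sprintf("FeaturePyramid, blocks %s\n",
              paste(range(object@blockRange), collapse = "..")))
  for (nm in names(object@rawMaps)) {
    d <- dim(object@rawMaps[[nm]])
    cat(sprintf("  %s: raw %dx%dx%d%s\n", nm, d[1], d[2], d[3],
                if (nm %in% names(object@fusedMaps)) sprintf(
                  ", fused %s", paste(dim(object@fusedMaps[[nm]]), collapse = "x"))
                else ""))
  }
})

#' Save / load a weight checkpoint
#'
#' Checkpoints are single-file RDS archives holding the full weight list
#' (backbone kernels, fusion kernels, config and, for fitted models, any
#' attached scaling parameters).
#'
#' @param weights a weight list or fitted model object.
#' @param path file path.
#' @export
saveCheckpoint <- function(weights, path) {
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
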