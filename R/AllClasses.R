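#' @import methods
NULL

#' Configuration for the knee-MRI phantom generator
#'
#' Describes one synthetic dataset: image geometry, anatomical plane,
#' lesion prevalence, lesion contrast and additive noise. All intensities
#' live on a [0, 1] scale.
#'
#' @slot imageSize integer, pixels per side (>= 32).
#' @slot plane one of \code{"sagittal"}, \code{"coronal"}, \code{"transverse"}.
#' @slot aclTearProb probability in [0, 1] that an image carries an ACL tear.
#' @slot meniscusTearProb probability in [0, 1] of a meniscus tear.
#' @slot lesionContrast mean intensity increment of the lesion over the
#'   structure it interrupts, before noise (>= 0).
#' @slot noiseSd standard deviation of the additive noise (>= 0).
#' @slot noiseModel \code{"gaussian"} (default) or \code{"rician"}.
#' @slot nImages number of images to draw.
#' @slot seed integer RNG seed; identical config + seed gives bit-identical output.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(imageSize = "integer", plane = "character",
                 aclTearProb = "numeric", meniscusTearProb = "numeric",
                 lesionContrast = "numeric", noiseSd = "numeric",
                 noiseModel = "character", nImages = "integer",
                 seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@imageSize) != 1L || is.na(object@imageSize) || object@imageSize < 32L)
    msg <- c(msg, "imageSize must be a single integer >= 32")
  if (!object@plane %in% c("sagittal", "coronal", "transverse"))
    msg <- c(msg, "plane must be one of sagittal/coronal/transverse")
  for (p in c("aclTearProb", "meniscusTearProb")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", p))
  }
  if (object@lesionContrast < 0) msg <- c(msg, "lesionContrast must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "rician"))
    msg <- c(msg, "noiseModel must be gaussian or rician")
  if (object@nImages < 1L) msg <- c(msg, "nImages must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' A labeled synthetic knee-MRI slice
#'
#' One grayscale slice with its anatomical plane, the two binary task
#' labels, and the lesion region masks used when the image was drawn.
#' Masks are stored for negatives too (the region where the lesion
#' would have been), so lesion-region intensities can be compared
#' between positives and negatives.
#'
#' @slot pixels numeric matrix with values in [0, 1].
#' @slot plane anatomical plane tag.
#' @slot aclTear,meniscusTear binary labels (0/1).
#' @slot aclRegion,meniscusRegion logical matrices marking the lesion site.
#' @exportClass LabeledImage
setClass("LabeledImage",
  representation(pixels = "matrix", plane = "character",
                 aclTear = "integer", meniscusTear = "integer",
                 aclRegion = "matrix", meniscusRegion = "matrix"))

setValidity("LabeledImage", function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.numeric(px) || anyNA(px) || min(px) < 0 || max(px) > 1)
    msg <- c(msg, "pixels must be numeric in [0, 1] with no NA")
  if (!object@aclTear %in% c(0L, 1L)) msg <- c(msg, "aclTear must be 0 or 1")
  if (!object@meniscusTear %in% c(0L, 1L)) msg <- c(msg, "meniscusTear must be 0 or 1")
  if (!identical(dim(object@aclRegion), dim(px)) ||
      !identical(dim(object@meniscusRegion), dim(px)))
    msg <- c(msg, "region masks must match pixel dimensions")
  if (length(msg)) msg else TRUE
})

#' An ordered collection of labeled phantom slices
#'
#' @slot images list of \linkS4class{LabeledImage}.
#' @slot config the \linkS4class{PhantomConfig} that generated them (may be
#'   a zero-length placeholder for datasets read from disk).
#' @exportClass LabeledImageSet
setClass("LabeledImageSet",
  representation(images = "list", config = "ANY"))

setValidity("LabeledImageSet", function(object) {
  ok <- vapply(object@images, is, logical(1), class2 = "LabeledImage")
  if (!all(ok)) "all elements must be LabeledImage objects" else TRUE
})

#' Backbone configuration
#'
#' Five convolution blocks; block g halves the spatial side relative to
#' block g-1, so block g emits a map of side inputSize / 2^(g-1). The
#' feature maps of a contiguous block range (default 2..5, mirroring a
#' transfer-learning backbone whose earliest block is dropped) feed the
#' top-down pyramid fusion.
#'
#' @slot weightsMode \code{"seeded_random"} (deterministic He-scaled draws,
#'   zero biases; the default, no checkpoint needed) or \code{"checkpoint"}
#'   (weights loaded from file via \code{\link{loadCheckpoint}}).
#' @slot blockRange contiguous integers within 1..5.
#' @slot inputSize input image side in pixels; must be divisible by 2^4.
#' @slot channels integer vector of length 5: output channels per block.
#' @slot fusedChannels channel width all pyramid levels are mapped to by the
#'   lateral 2x2 convolution before summation.
#' @slot seed integer seed for the weight draws.
#' @exportClass BackboneConfig
setClass("BackboneConfig",
  representation(weightsMode = "character", blockRange = "integer",
                 inputSize = "integer", channels = "integer",
                 fusedChannels = "integer", seed = "integer"))

setValidity("BackboneConfig", function(object) {
  msg <- character()
  br <- object@blockRange
  if (length(br) < 1L || any(br < 1L) || any(br > 5L) ||
      !identical(br, seq(min(br), max(br))))
    msg <- c(msg, "blockRange must be contiguous integers within 1..5")
  if (!object@weightsMode %in% c("seeded_random", "checkpoint"))
    msg <- c(msg, "weightsMode must be seeded_random or checkpoint")
  if (length(object@channels) != 5L || any(object@channels < 1L))
    msg <- c(msg, "channels must be 5 positive integers")
  if (object@inputSize < 32L || object@inputSize %% 16L != 0L)
    msg <- c(msg, "inputSize must be >= 32 and divisible by 16")
  if (object@fusedChannels < 1L) msg <- c(msg, "fusedChannels must be positive")
  if (length(msg)) msg else TRUE
})

#' A multi-scale feature pyramid
#'
#' Raw per-block feature maps, and after \code{\link{fusePyramid}} the
#' top-down fused maps plus the intermediate 2x upsampled maps. Maps are
#' height x width x channels arrays; the entry for block g has spatial
#' side inputSize / 2^(g-1).
#'
#' @slot rawMaps,fusedMaps,upsampled named lists of 3-D arrays, names
#'   \code{"block<g>"}.
#' @slot blockRange the contiguous block indices covered.
#' @exportClass FeaturePyramid
setClass("FeaturePyramid",
  representation(rawMaps = "list", fusedMaps = "list",
                 upsampled = "list", blockRange = "integer"))

#' Batch-normalization parameters
#'
#' Per-feature affine parameters (scale, shift), the numerical guard
#' epsilon, and running first/second moments updated in train mode and
#' used in eval mode.
#'
#' @slot scale,shift numeric vectors, one entry per feature.
#' @slot eps small positive real added to the variance.
#' @slot runningMean,runningVar running estimates of the batch moments.
#' @slot momentum weight of the new batch in the running-estimate update.
#' @slot initialized has any train-mode batch been seen yet?
#' @exportClass BNParams
setClass("BNParams",
  representation(scale = "numeric", shift = "numeric", eps = "numeric",
                 runningMean = "numeric", runningVar = "numeric",
                 momentum = "numeric", initialized = "logical"))

setValidity("BNParams", function(object) {
  msg <- character()
  if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
  if (any(object@runningVar < 0)) msg <- c(msg, "variance estimates must be >= 0")
  n <- length(object@scale)
  if (length(object@shift) != n || length(object@runningMean) != n ||
      length(object@runningVar) != n)
    msg <- c(msg, "scale/shift/running moments must have equal length")
  if (length(msg)) msg else TRUE
})

#' Energy-based multimodal fusion model
#'
#' A restricted Boltzmann machine over the concatenated traditional + deep
#' feature vector (visible layer), with a logistic output unit on the
#' hidden probabilities. The hidden layer is narrower than the visible
#' layer by construction.
#'
#' @slot visibleBias numeric, one per visible unit (t).
#' @slot hiddenBias numeric, one per hidden unit (beta).
#' @slot weights visible x hidden numeric matrix (theta).
#' @slot outWeights,outBias parameters of the logistic output unit.
#' @slot trained has the supervised head been fitted?
#' @slot scaling list of per-feature min/max used to scale inputs to [0, 1].
#' @slot trainLog data.frame of per-epoch diagnostics (exact log-likelihood
#'   when the model is small enough to enumerate).
#' @exportClass RBMModel
setClass("RBMModel",
  representation(visibleBias = "numeric", hiddenBias = "numeric",
                 weights = "matrix", outWeights = "numeric",
                 outBias = "numeric", trained = "logical",
                 scaling = "list", trainLog = "data.frame"))

setValidity("RBMModel", function(object) {
  msg <- character()
  nv <- length(object@visibleBias); nh <- length(object@hiddenBias)
  if (!identical(dim(object@weights), c(nv, nh)))
    msg <- c(msg, "weights must be nVisible x nHidden")
  if (nh >= nv) msg <- c(msg, "hidden layer must be narrower than visible layer")
  if (!all(is.finite(object@visibleBias)) || !all(is.finite(object@hiddenBias)) ||
      !all(is.finite(object@weights)))
    msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Binary confusion counts
#'
#' @slot TP,FP,TN,FN nonnegative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(TP = "integer", FP = "integer", TN = "integer", FN = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be nonnegative integers")
  if (sum(v) < 1L) return("at least one observation required")
  TRUE
})

#' Injury-grade contingency table for two modalities
#'
#' Counts of knees per injury grade (0, I, II, III: normal, partial damage
#' under 50\%, damage of 50\% or more, complete rupture) for two diagnostic
#' modalities examining the same knees, so row sums must agree.
#'
#' @slot counts 2 x 4 integer matrix; rownames are the modalities, colnames
#'   \code{c("grade0","gradeI","gradeII","gradeIII")}.
#' @exportClass GradeTable
setClass("GradeTable", representation(counts = "matrix"))

setValidity("GradeTable", function(object) {
  m <- object@counts
  if (!identical(dim(m), c(2L, 4L))) return("counts must be 2 x 4")
  if (any(m < 0) || any(m != round(m))) return("counts must be nonnegative integers")
  if (sum(m[1, ]) != sum(m[2, ]))
    return("row sums must be equal (same knees examined by both modalities)")
  TRUE
})

#' One prediction task on one anatomical plane
#'
#' @slot task \code{"acl_tear"} or \code{"meniscus_tear"}.
#' @slot plane \code{"sagittal"}, \code{"coronal"} or \code{"transverse"}.
#' @exportClass TaskSpec
setClass("TaskSpec", representation(task = "character", plane = "character"))

setValidity("TaskSpec", function(object) {
  msg <- character()
  if (!object@task %in% c("acl_tear", "meniscus_tear"))
    msg <- c(msg, "task must be acl_tear or meniscus_tear")
  if (!object@plane %in% c("sagittal", "coronal", "transverse"))
    msg <- c(msg, "plane must be sagittal/coronal/transverse")
  if (length(msg)) msg else TRUE
})

#' Held-out evaluation of one task/plane experiment
#'
#' @slot task the \linkS4class{TaskSpec} evaluated.
#' @slot confusion the \linkS4class{ConfusionMatrix} at the 0.5 rule.
#' @slot accuracy,recall,auc scalar metrics in [0, 1].
#' @slot roc data.frame of (threshold, fpr, tpr) points.
#' @slot seed the experiment seed.
#' @slot configHash short hash of the effective configuration.
#' @slot model the trained \linkS4class{RBMModel} (carries the train-set
#'   scaling parameters).
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(task = "TaskSpec", confusion = "ConfusionMatrix",
                 accuracy = "numeric", recall = "numeric", auc = "numeric",
                 roc = "data.frame", seed = "integer", configHash = "character",
                 model = "ANY"))
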