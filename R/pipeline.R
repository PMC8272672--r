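#' Define a prediction task on one plane
#'
#' One independent model is trained per (task, plane) pair.
#'
#' @param task \code{"acl_tear"} or \code{"meniscus_tear"}.
#' @param plane \code{"sagittal"}, \code{"coronal"} or \code{"transverse"}.
#' @return a \linkS4class{TaskSpec}.
#' @export
taskSpec <- function(task = "acl_tear", plane = "sagittal") {
  new("TaskSpec", task = task, plane = plane)
}

#' Head configuration
#'
#' @param poolSize adaptive-max-pool target side before projection.
#' @param deepDim deep feature dimension; the full-scale default is 1026,
#'   desk-scale experiments typically use 128.
#' @param projectionSeed seed for the frozen projection draws.
#' @export
headConfig <- function(poolSize = 4L, deepDim = 1026L, projectionSeed = 1L) {
  stopifnot(poolSize >= 1L, deepDim >= 1L)
  list(poolSize = as.integer(poolSize), deepDim = as.integer(deepDim),
       projectionSeed = as.integer(projectionSeed))
}

#' Compute deep feature vectors for a batch of images
#'
#' Runs each image through the frozen backbone and pyramid fusion, takes
#' the finest fused map, batch-normalizes it per channel (statistics over
#' all images and spatial positions), applies ReLU, adaptive max pooling
#' and the frozen affine projection + ReLU. In train mode the batch-norm
#' moments are estimated from this batch and returned for later eval-mode
#' use.
#'
#' @param images a \linkS4class{LabeledImageSet} or list of images.
#' @param weights backbone weights (\code{\link{randomBackboneWeights}}).
#' @param head a \code{\link{headConfig}} list.
#' @param bn \linkS4class{BNParams} (required in eval mode; created fresh
#'   in train mode when NULL).
#' @param projection projection list (created on first use when NULL).
#' @param mode \code{"train"} or \code{"eval"}.
#' @return list with \code{features} (n x deepDim matrix), \code{bn},
#'   \code{projection}.
#' @export
deepFeatureMatrix <- function(images, weights, head = headConfig(),
                              bn = NULL, projection = NULL,
                              mode = c("train", "eval")) {
  mode <- match.arg(mode)
  imgs <- if (is(images, "LabeledImageSet")) images@images else images
  bottomKey <- paste0("block", min(weights$config@blockRange))
  maps <- lapply(imgs, function(im)
    fusedMaps(fusePyramid(extractPyramid(im, weights), weights))[[bottomKey]])
  d <- dim(maps[[1]])                      # H x W x C
  nSpat <- d[1] * d[2]
  flat <- do.call(rbind, lapply(maps, function(m) matrix(m, nSpat, d[3])))
  if (is.null(bn)) {
    if (mode == "eval") stop("eval mode requires fitted BNParams")
    bn <- bnParams(d[3])
  }
  nb <- batchNormalize(flat, bn, mode = mode)
  if (mode == "train") bn <- nb$params
  if (is.null(projection))
    projection <- randomProjection(head$poolSize^2 * d[3], head$deepDim,
                                   seed = head$projectionSeed)
  feats <- t(vapply(seq_along(maps), function(k) {
    m <- array(nb$values[(k - 1L) * nSpat + seq_len(nSpat), ], dim = d)
    projectDeepFeatures(adaptiveMaxPool(relu(m), head$poolSize), projection)
  }, numeric(head$deepDim)))
  list(features = feats, bn = bn, projection = projection)
}

.taskLabels <- function(set, task) {
  lb <- imageLabels(set)
  if (task@task == "acl_tear") lb$acl_tear else lb$meniscus_tear
}

#' Stratified train/test split
#'
#' @param set a \linkS4class{LabeledImageSet}.
#' @param labels binary vector used for stratification.
#' @param trainFraction fraction assigned to training (default 0.8).
#' @param seed split seed.
#' @return list with \code{train} and \code{test} sets and index vectors.
#' @export
splitDataset <- function(set, labels, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  with_seed(seed, {
    idx <- unlist(lapply(unique(labels), function(cl) {
      i <- which(labels == cl)
      sample(i, round(length(i) * trainFraction))
    }))
  })
  idx <- sort(idx)
  list(train = set[idx], test = set[-idx],
       trainIdx = idx, testIdx = setdiff(seq_along(labels), idx))
}

#' Run one end-to-end experiment
#'
#' Extracts traditional and deep features on the training set, fits all
#' data-dependent parameters (batch-norm moments, min-max scaling) on the
#' training set only, trains the energy-fusion classifier, and evaluates
#' on the held-out test set: confusion counts at the 0.5 rule, accuracy,
#' recall and trapezoidal AUC.
#'
#' @param trainSet,testSet disjoint \linkS4class{LabeledImageSet}s.
#' @param task a \linkS4class{TaskSpec}.
#' @param backbone a \linkS4class{BackboneConfig}.
#' @param head a \code{\link{headConfig}} list.
#' @param fusion a \code{\link{trainConfig}} list.
#' @param nHidden hidden units of the fusion model.
#' @param seed experiment seed; substreams are derived per stage.
#' @param shuffleLabels permute the training labels (negative control).
#' @return an \linkS4class{EvaluationReport}.
#' @export
runExperiment <- function(trainSet, testSet, task = taskSpec(),
                          backbone = backboneConfig(),
                          head = headConfig(deepDim = 128L),
                          fusion = trainConfig(), nHidden = 32L,
                          seed = 1L, shuffleLabels = FALSE) {
  yTrain <- .taskLabels(trainSet, task)
  yTest <- .taskLabels(testSet, task)
  if (length(unique(yTrain)) < 2L)
    stop("training set must contain both classes for task ", task@task)
  if (shuffleLabels)
    yTrain <- with_seed(deriveSeed(seed, "shuffle"), sample(yTrain))

  backbone@seed <- deriveSeed(seed, "backbone")
  weights <- randomBackboneWeights(backbone)
  head$projectionSeed <- deriveSeed(seed, "projection")

  tradTrain <- t(vapply(trainSet@images, traditionalFeatures, numeric(32)))
  tradTest <- t(vapply(testSet@images, traditionalFeatures, numeric(32)))
  deepTrain <- deepFeatureMatrix(trainSet, weights, head, mode = "train")
  deepTest <- deepFeatureMatrix(testSet, weights, head, bn = deepTrain$bn,
                                projection = deepTrain$projection, mode = "eval")

  xTrain <- cbind(tradTrain, deepTrain$features)
  xTest <- cbind(tradTest, deepTest$features)
  scaling <- fitScaling(xTrain)            # train-set statistics only
  fusion$seed <- deriveSeed(seed, "fusion")
  model <- trainFusionModel(applyScaling(xTrain, scaling), yTrain, nHidden,
                            config = fusion, scaling = scaling)

  pred <- predictFusion(applyScaling(xTest, scaling), model)
  cm <- confusionCounts(pred$call, yTest)
  ra <- rocAuc(pred$prob, yTest)
  cfg <- list(task = task@task, plane = task@plane,
              backbone = backbone, head = head, fusion = fusion,
              nHidden = nHidden)
  new("EvaluationReport", task = task, confusion = cm,
      accuracy = accuracy(cm), recall = recall(cm), auc = ra$auc,
      roc = ra$roc, seed = as.integer(seed), configHash = objectHash(cfg),
      model = model)
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s / %s], seed %d, config %s\n",
              object@task@task, object@task@plane, object@seed,
              object@configHash))
  cat(sprintf("  accuracy %.4f  recall %.4f  AUC %.4f\n",
              object@accuracy, object@recall, object@auc))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", object@confusion@TP,
              object@confusion@FP, object@confusion@TN, object@confusion@FN))
})

#' Serialize an evaluation report to JSON
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path output path.
#' @export
writeEvaluationReport <- function(report, path) {
  jsonlite::write_json(list(
    task = report@task@task, plane = report@task@plane,
    accuracy = report@accuracy, recall = report@recall, auc = report@auc,
    confusion = list(TP = report@confusion@TP, FP = report@confusion@FP,
                     TN = report@confusion@TN, FN = report@confusion@FN),
    seed = report@seed, configHash = report@configHash),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
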