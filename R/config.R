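#' Documented default run configuration
#'
#' Nested sections \code{phantom}, \code{backbone}, \code{head},
#' \code{fusion}, \code{eval}, plus a global \code{seed} and
#' \code{outputDir}. The global seed derives deterministic per-module
#' substreams (\code{\link{deriveSeed}}), so one knob reproduces a full
#' run bit-identically.
#'
#' @return nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    phantom = list(imageSize = 64L, plane = "sagittal", aclTearProb = 0.5,
                   meniscusTearProb = 0.5, lesionContrast = 0.4,
                   noiseSd = 0.1, noiseModel = "gaussian", nImages = 100L),
    backbone = list(inputSize = 64L, blockRange = c(2L, 5L),
                    channels = c(8L, 16L, 32L, 32L, 32L),
                    fusedChannels = 64L, weightsMode = "seeded_random"),
    head = list(poolSize = 4L, deepDim = 1026L),
    fusion = list(nHidden = 32L, cdSteps = 1L, learningRate = 0.05,
                  epochs = 50L, batchSize = 16L, superviseEpochs = 100L),
    eval = list(trainFraction = 0.8),
    seed = 1L,
    outputDir = ".")
}

.mergeConfig <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    full <- if (prefix == "") key else paste0(prefix, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a section")
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.checkRange <- function(value, key, lo = -Inf, hi = Inf, choices = NULL) {
  if (!is.null(choices)) {
    if (!all(value %in% choices))
      stop("invalid value for ", key, ": must be one of ",
           paste(choices, collapse = ", "))
    return(invisible())
  }
  if (!is.numeric(value) || anyNA(value) || any(value < lo) || any(value > hi))
    stop("invalid value for ", key, ": must lie in [", lo, ", ", hi, "]")
  invisible()
}

.validateConfig <- function(cfg) {
  ph <- cfg$phantom
  .checkRange(ph$imageSize, "phantom.imageSize", 32)
  .checkRange(ph$aclTearProb, "phantom.aclTearProb", 0, 1)
  .checkRange(ph$meniscusTearProb, "phantom.meniscusTearProb", 0, 1)
  .checkRange(ph$lesionContrast, "phantom.lesionContrast", 0)
  .checkRange(ph$noiseSd, "phantom.noiseSd", 0)
  .checkRange(ph$nImages, "phantom.nImages", 1)
  .checkRange(ph$plane, "phantom.plane",
              choices = c("sagittal", "coronal", "transverse"))
  .checkRange(ph$noiseModel, "phantom.noiseModel",
              choices = c("gaussian", "rician"))
  bb <- cfg$backbone
  .checkRange(bb$blockRange, "backbone.blockRange", 1, 5)
  .checkRange(bb$inputSize, "backbone.inputSize", 32)
  .checkRange(bb$fusedChannels, "backbone.fusedChannels", 1)
  .checkRange(bb$weightsMode, "backbone.weightsMode",
              choices = c("seeded_random", "checkpoint"))
  if (length(bb$channels) != 5L) stop("invalid value for backbone.channels: need 5 entries")
  .checkRange(cfg$head$poolSize, "head.poolSize", 1)
  .checkRange(cfg$head$deepDim, "head.deepDim", 1)
  fu <- cfg$fusion
  .checkRange(fu$nHidden, "fusion.nHidden", 1)
  .checkRange(fu$cdSteps, "fusion.cdSteps", 1)
  .checkRange(fu$learningRate, "fusion.learningRate", 1e-12)
  .checkRange(fu$epochs, "fusion.epochs", 1)
  .checkRange(fu$batchSize, "fusion.batchSize", 1)
  .checkRange(fu$superviseEpochs, "fusion.superviseEpochs", 0)
  .checkRange(cfg$eval$trainFraction, "eval.trainFraction", 1e-6, 1 - 1e-6)
  .checkRange(cfg$seed, "seed")
  cfg
}

#' Load and validate a run configuration
#'
#' YAML or JSON (by extension); absent keys take the documented defaults,
#' unknown keys are rejected with the offending key named, and every
#' value is range-checked. An empty or NULL path yields the pure
#' defaults.
#'
#' @param path config file path, or NULL for defaults.
#' @return validated effective configuration list.
#' @export
loadConfig <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- .mergeConfig(defaultConfig(), user)
  for (sec in c("phantom", "backbone", "head", "fusion"))
    for (k in names(cfg[[sec]]))
      if (is.numeric(cfg[[sec]][[k]]) && is.integer(defaultConfig()[[sec]][[k]]))
        cfg[[sec]][[k]] <- as.integer(cfg[[sec]][[k]])
  cfg$seed <- as.integer(cfg$seed)
  .validateConfig(cfg)
}

#' Write the effective configuration (YAML)
#'
#' Together with the seed and package version this is sufficient to
#' reproduce a run bit-identically.
#'
#' @param cfg configuration list from \code{\link{loadConfig}}.
#' @param path output path.
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Materialize module objects from a configuration
#'
#' @param cfg validated configuration list.
#' @return list with \code{phantom} (\linkS4class{PhantomConfig}),
#'   \code{backbone} (\linkS4class{BackboneConfig}), \code{head} and
#'   \code{fusion} lists, ready for \code{\link{runExperiment}}.
#' @export
configObjects <- function(cfg) {
  ph <- cfg$phantom; bb <- cfg$backbone
  list(
    phantom = phantomConfig(ph$imageSize, ph$plane, ph$aclTearProb,
                            ph$meniscusTearProb, ph$lesionContrast, ph$noiseSd,
                            ph$noiseModel, ph$nImages,
                            seed = deriveSeed(cfg$seed, "phantom")),
    backbone = backboneConfig(bb$inputSize, seq(bb$blockRange[1], bb$blockRange[2]),
                              bb$channels, bb$fusedChannels, bb$weightsMode,
                              seed = deriveSeed(cfg$seed, "backbone")),
    head = headConfig(cfg$head$poolSize, cfg$head$deepDim,
                      projectionSeed = deriveSeed(cfg$seed, "projection")),
    fusion = trainConfig(cfg$fusion$cdSteps, cfg$fusion$learningRate,
                         cfg$fusion$epochs, cfg$fusion$batchSize,
                         cfg$fusion$superviseEpochs,
                         seed = deriveSeed(cfg$seed, "fusion")))
}
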