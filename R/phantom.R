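#' Create a phantom configuration
#'
#' The phantom emulates the qualitative appearance of T2-weighted knee
#' slices: soft tissue is mid-bright, the cruciate ligament is a dark
#' (low-signal) band, the meniscus a dark wedge, and a tear shows up as a
#' focal high-signal region interrupting the dark structure. Geometry is
#' plane-dependent: a diagonal ligament band on sagittal slices, a
#' vertical band on coronal slices, and on transverse slices no band but
#' a ligament cross-section disc plus a dominant C-shaped meniscus.
#'
#' @param imageSize pixels per side (>= 32); default 64.
#' @param plane \code{"sagittal"} (default), \code{"coronal"} or
#'   \code{"transverse"}.
#' @param aclTearProb,meniscusTearProb per-image tear probabilities.
#' @param lesionContrast mean intensity increment of a tear over the dark
#'   structure it interrupts, before noise; default 0.4.
#' @param noiseSd additive noise standard deviation; default 0.1.
#' @param noiseModel \code{"gaussian"} (additive, clipped to [0, 1]) or
#'   \code{"rician"} (magnitude of the complex-noise-corrupted signal).
#' @param nImages number of images; default 100.
#' @param seed RNG seed.
#' @return a \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(nImages = 5, seed = 1)
#' imgs <- generateDataset(cfg)
#' length(imgs)
#' @export
phantomConfig <- function(imageSize = 64L, plane = "sagittal",
                          aclTearProb = 0.5, meniscusTearProb = 0.5,
                          lesionContrast = 0.4, noiseSd = 0.1,
                          noiseModel = "gaussian", nImages = 100L, seed = 1L) {
  new("PhantomConfig", imageSize = as.integer(imageSize), plane = plane,
      aclTearProb = aclTearProb, meniscusTearProb = meniscusTearProb,
      lesionContrast = lesionContrast, noiseSd = noiseSd,
      noiseModel = noiseModel, nImages = as.integer(nImages),
      seed = as.integer(seed))
}

# intensities of the phantom tissue classes on the [0,1] scale
.PHANTOM_LEVELS <- list(background = 0.60, ligament = 0.15, meniscus = 0.20)

# Draw the plane-dependent geometry for one image. Jitter (band offset,
# lesion position) consumes RNG; masks are returned for negatives too.
.phantomGeometry <- function(S, plane) {
  r <- row(matrix(0, S, S)); cc <- col(matrix(0, S, S))
  base <- matrix(.PHANTOM_LEVELS$background, S, S)
  lv <- .PHANTOM_LEVELS

  if (plane %in% c("sagittal", "coronal")) {
    wBand <- max(2L, round(S / 16))
    # dark meniscus wedge near the tibial plateau, widening downward
    top <- round(0.72 * S)
    wedge <- r >= top & r <= round(0.92 * S) &
      abs(cc - S / 2) <= (r - top) * 1.2 + 2
    base[wedge] <- lv$meniscus
    if (plane == "sagittal") {
      off <- round(0.05 * S) + sample(-2:2, 1L)
      band <- abs(r - (0.8 * cc + off)) <= wBand & r <= round(0.7 * S)
      along <- cc  # lesion position measured along columns
    } else {
      off <- round(0.5 * S) + sample(-3:3, 1L)
      band <- abs(cc - off) <= wBand & r >= round(0.08 * S) & r <= round(0.7 * S)
      along <- r   # vertical band: position measured along rows
    }
    base[band] <- lv$ligament
    gapLen <- max(4L, round(S / 10))
    t0 <- sample(seq(round(0.35 * S), round(0.6 * S)), 1L)
    aclRegion <- band & along >= t0 & along < t0 + gapLen
    c0 <- round(S / 2) + sample(-round(S / 8):round(S / 8), 1L)
    meniscusRegion <- wedge & abs(cc - c0) <= 1
  } else {
    # transverse: ligament cross-section disc + C-shaped meniscus ring
    dcy <- round(0.35 * S) + sample(-2:2, 1L); dcx <- round(0.55 * S)
    disc <- (r - dcy)^2 + (cc - dcx)^2 <= (S / 10)^2
    cy <- round(0.55 * S); cx <- round(0.5 * S)
    rad <- sqrt((r - cy)^2 + (cc - cx)^2)
    ang <- atan2(r - cy, cc - cx)
    ring <- rad >= 0.26 * S & rad <= 0.36 * S & abs(ang) > 0.5
    base[ring] <- lv$meniscus
    base[disc] <- lv$ligament
    aclRegion <- disc & (r - dcy)^2 + (cc - dcx)^2 <= (S / 22)^2
    a0 <- runif(1L, 0.8, 2.6) * sample(c(-1, 1), 1L)
    meniscusRegion <- ring & abs(ang - a0) <= 0.14
  }
  list(base = base, aclRegion = aclRegion, meniscusRegion = meniscusRegion)
}

.addNoise <- function(px, sd, model) {
  if (sd == 0) return(px)
  n <- length(px)
  if (model == "gaussian") {
    out <- px + rnorm(n, 0, sd)
  } else {
    out <- sqrt((px + rnorm(n, 0, sd))^2 + rnorm(n, 0, sd)^2)
  }
  matrix(clip01(out), nrow(px), ncol(px))
}

#' Generate a synthetic labeled dataset
#'
#' Draws \code{nImages} slices. Tear labels are independent Bernoulli draws
#' at the configured probabilities; for a positive label the lesion region
#' is raised by \code{lesionContrast} before noise. Identical config and
#' seed give bit-identical output.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return a \linkS4class{LabeledImageSet}.
#' @export
generateDataset <- function(config) {
  validObject(config)
  with_seed(config@seed, {
    imgs <- vector("list", config@nImages)
    for (k in seq_len(config@nImages)) {
      acl <- rbinom(1L, 1L, config@aclTearProb)
      men <- rbinom(1L, 1L, config@meniscusTearProb)
      g <- .phantomGeometry(config@imageSize, config@plane)
      px <- g$base
      if (acl == 1L) px[g$aclRegion] <- px[g$aclRegion] + config@lesionContrast
      if (men == 1L) px[g$meniscusRegion] <- px[g$meniscusRegion] + config@lesionContrast
      px <- clip01(px)
      px <- .addNoise(px, config@noiseSd, config@noiseModel)
      imgs[[k]] <- new("LabeledImage", pixels = px, plane = config@plane,
                       aclTear = acl, meniscusTear = men,
                       aclRegion = g$aclRegion, meniscusRegion = g$meniscusRegion)
    }
    new("LabeledImageSet", images = imgs, config = config)
  })
}

#' @describeIn LabeledImage-class pixel matrix accessor.
#' @export
setMethod("pixels", "LabeledImage", function(object) object@pixels)

#' @describeIn LabeledImage-class anatomical plane accessor.
#' @export
setMethod("imagePlane", "LabeledImage", function(object) object@plane)

#' Task labels of a dataset
#'
#' @param x a \linkS4class{LabeledImageSet}.
#' @return data.frame with columns \code{plane}, \code{acl_tear},
#'   \code{meniscus_tear}, one row per image.
#' @export
imageLabels <- function(x) {
  stopifnot(is(x, "LabeledImageSet"))
  data.frame(
    plane = vapply(x@images, function(i) i@plane, character(1)),
    acl_tear = vapply(x@images, function(i) i@aclTear, integer(1)),
    meniscus_tear = vapply(x@images, function(i) i@meniscusTear, integer(1)))
}

#' @export
setMethod("length", "LabeledImageSet", function(x) length(x@images))

#' @export
setMethod("[[", "LabeledImageSet", function(x, i) x@images[[i]])

#' @param x,i a \linkS4class{LabeledImageSet} and an index vector.
#' @describeIn LabeledImageSet-class subset to a new set.
#' @export
setMethod("[", "LabeledImageSet", function(x, i) {
  new("LabeledImageSet", images = x@images[i], config = x@config)
})

setMethod("show", "LabeledImageSet", function(object) {
  lb <- if (length(object@images)) imageLabels(object) else
    data.frame(acl_tear = integer(), meniscus_tear = integer())
  cat(sprintf("LabeledImageSet with %d image(s)\n", length(object@images)))
  if (length(object@images)) {
    d <- dim(object@images[[1]]@pixels)
    cat(sprintf("  %d x %d pixels, plane(s): %s\n", d[1], d[2],
                paste(unique(lb$plane), collapse = ", ")))
    cat(sprintf("  ACL tears: %d  meniscus tears: %d\n",
                sum(lb$acl_tear), sum(lb$meniscus_tear)))
  }
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %d x %d %s, n=%d, P(acl)=%.2f, P(men)=%.2f, contrast=%.2f, noise=%.3f (%s), seed=%d\n",
    object@imageSize, object@imageSize, object@plane, object@nImages,
    object@aclTearProb, object@meniscusTearProb, object@lesionContrast,
    object@noiseSd, object@noiseModel, object@seed))
})
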