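#' Write a labeled dataset to a directory
#'
#' Images are stored one file per slice together with a CSV manifest
#' (columns \code{file}, \code{plane}, \code{acl_tear},
#' \code{meniscus_tear}). The default interchange format is 8-bit
#' grayscale PNG, which quantizes intensities to 1/255; the
#' \code{"nifti"} mode stores float64 NIfTI-1 volumes and round-trips
#' pixel values exactly. Lesion region masks are generation-time
#' metadata and are not serialized.
#'
#' @param x a \linkS4class{LabeledImageSet}.
#' @param dir output directory (created if needed).
#' @param format \code{"png"} (default) or \code{"nifti"}.
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(x, dir, format = c("png", "nifti")) {
  stopifnot(is(x, "LabeledImageSet"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "png") "png" else "nii"
  n <- length(x@images)
  files <- if (n) sprintf("img_%04d.%s", seq_len(n), ext) else character()
  for (k in seq_len(n)) {
    px <- x@images[[k]]@pixels
    path <- file.path(dir, files[k])
    if (format == "png") {
      png::writePNG(px, target = path)
    } else {
      RNifti::writeNifti(RNifti::asNifti(px, datatype = "double"), path,
                         datatype = "double")
    }
  }
  manifest <- cbind(data.frame(file = files),
                    if (n) imageLabels(x) else
                      data.frame(plane = character(),
                                 acl_tear = integer(), meniscus_tear = integer()))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a labeled dataset written by \code{\link{writeDataset}}
#'
#' @param dir directory containing \code{manifest.csv} and the image files.
#' @return a \linkS4class{LabeledImageSet} (with empty lesion masks).
#' @export
readDataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("file", "plane", "acl_tear", "meniscus_tear")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest$file))
    stop("duplicate manifest rows: ",
         paste(unique(manifest$file[duplicated(manifest$file)]), collapse = ", "))
  missing <- manifest$file[!file.exists(file.path(dir, manifest$file))]
  if (length(missing))
    stop("manifest rows without files: ", paste(missing, collapse = ", "))
  imgs <- lapply(seq_len(nrow(manifest)), function(k) {
    path <- file.path(dir, manifest$file[k])
    px <- if (grepl("\\.png$", path)) {
      p <- png::readPNG(path)
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # grayscale stored with channels
      p
    } else {
      m <- as.array(RNifti::readNifti(path))
      matrix(as.numeric(m), dim(m)[1], dim(m)[2])
    }
    empty <- matrix(FALSE, nrow(px), ncol(px))
    new("LabeledImage", pixels = px, plane = manifest$plane[k],
        aclTear = as.integer(manifest$acl_tear[k]),
        meniscusTear = as.integer(manifest$meniscus_tear[k]),
        aclRegion = empty, meniscusRegion = empty)
  })
  new("LabeledImageSet", images = imgs, config = NULL)
}
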