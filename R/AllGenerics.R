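#' @rdname LabeledImage-class
#' @param object,x an object.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname LabeledImage-class
#' @export
setGeneric("imagePlane", function(object) standardGeneric("imagePlane"))

#' @rdname FeaturePyramid-class
#' @export
setGeneric("rawMaps", function(object) standardGeneric("rawMaps"))

#' @rdname FeaturePyramid-class
#' @export
setGeneric("fusedMaps", function(object) standardGeneric("fusedMaps"))

#' @rdname GradeTable-class
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname RBMModel-class
#' @export
setGeneric("nVisible", function(object) standardGeneric("nVisible"))

#' @rdname RBMModel-class
#' @export
setGeneric("nHidden", function(object) standardGeneric("nHidden"))
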