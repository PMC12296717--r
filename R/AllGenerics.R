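#' @rdname FeatureBlock-class
#' @param x,object a \code{FeatureBlock}, \code{SpectrumSet} or
#'   \code{FusionStudy}.
#' @export
setGeneric("platformOf", function(x) standardGeneric("platformOf"))

#' @rdname FeatureBlock-class
#' @export
setGeneric("blockMatrix", function(x) standardGeneric("blockMatrix"))

#' @rdname FusionStudy-class
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname FusionStudy-class
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname FusionStudy-class
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname ModelReport-class
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname CharacteristicVariableSet-class
#' @export
setGeneric("variables", function(x) standardGeneric("variables"))

#' @rdname ProjectionReport-class
#' @export
setGeneric("separationIndexOf", function(x) standardGeneric("separationIndexOf"))
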