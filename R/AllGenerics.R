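#' @include AllClasses.R
NULL

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("operatorId", function(x) standardGeneric("operatorId"))

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("repetition", function(x) standardGeneric("repetition"))

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("svScore", function(x) standardGeneric("svScore"))

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("boundaryLines", function(x) standardGeneric("boundaryLines"))

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("wallAxis", function(x, wall) standardGeneric("wallAxis"))

#' @rdname AortaAnnotation-accessors
#' @export
setGeneric("calcifiedTracts", function(x, wall) standardGeneric("calcifiedTracts"))

#' @rdname qcNative
#' @export
setGeneric("qcNative", function(x) standardGeneric("qcNative"))

#' @rdname qcNative
#' @export
setGeneric("qcScore", function(x) standardGeneric("qcScore"))

#' @rdname scScore
#' @export
setGeneric("scScore", function(x) standardGeneric("scScore"))

#' @rdname segmentFractions
#' @export
setGeneric("segmentFractions", function(x) standardGeneric("segmentFractions"))

#' @rdname segmentFractions
#' @export
setGeneric("segmentTertiles", function(x) standardGeneric("segmentTertiles"))

#' @rdname scoreTriple
#' @export
setGeneric("scoreTriple", function(x) standardGeneric("scoreTriple"))
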