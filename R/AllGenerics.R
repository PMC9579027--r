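#' @rdname PointCloud-class
#' @param object,x an object.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PointCloud-class
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname PointCloud-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname PointCloud-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname PointCloud-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname PointCloud-class
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))

#' @rdname RigidTransform-class
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @rdname RegistrationResult-class
#' @export
setGeneric("fitness", function(x) standardGeneric("fitness"))

#' @rdname RegistrationResult-class
#' @export
setGeneric("inlierRMSE", function(x) standardGeneric("inlierRMSE"))

#' @rdname RegistrationResult-class
#' @export
setGeneric("inlierMAE", function(x) standardGeneric("inlierMAE"))

#' @rdname RegistrationResult-class
#' @export
setGeneric("correspondences", function(x) standardGeneric("correspondences"))

#' @rdname CorrespondenceMap-class
#' @export
setGeneric("corrPairs", function(x) standardGeneric("corrPairs"))

#' @rdname CorrespondenceMap-class
#' @export
setGeneric("unmappedTargets", function(x) standardGeneric("unmappedTargets"))

#' @rdname CorrespondenceMap-class
#' @export
setGeneric("multiplicity", function(x) standardGeneric("multiplicity"))

#' @rdname CompositeMap-class
#' @export
setGeneric("compositeTarget", function(x) standardGeneric("compositeTarget"))

#' @rdname CompositeMap-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Apply a rigid transform
#'
#' Applies a [RigidTransform-class] to a coordinate matrix or to the
#' coordinates of a [PointCloud-class] (channels are carried over unchanged).
#'
#' @param x a \code{PointCloud} or an N x 3 coordinate matrix.
#' @param transform a \code{RigidTransform}.
#' @return an object of the same class as \code{x}, transformed.
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))
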