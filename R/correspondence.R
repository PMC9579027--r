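#' Construct a CorrespondenceMap
#'
#' @param pairs two-column integer matrix (source index, target index), or a
#'   data.frame with columns \code{source}, \code{target}.
#' @param nSource,nTarget sizes of the source and target clouds.
#' @return a [CorrespondenceMap-class].
#' @export
correspondenceMap <- function(pairs, nSource, nTarget) {
  p <- as.matrix(pairs)
  if (!nrow(p)) p <- matrix(integer(0), 0, 2)
  storage.mode(p) <- "integer"
  colnames(p) <- c("source", "target")
  new("CorrespondenceMap", pairs = p, nSource = as.integer(nSource),
      nTarget = as.integer(nTarget))
}

#' @rdname CorrespondenceMap-class
#' @param x a \code{CorrespondenceMap}.
#' @export
setMethod("corrPairs", "CorrespondenceMap", function(x) x@pairs)

#' @rdname CorrespondenceMap-class
#' @export
setMethod("multiplicity", "CorrespondenceMap", function(x) {
  tabulate(x@pairs[, 2], nbins = x@nTarget)
})

#' @rdname CorrespondenceMap-class
#' @export
setMethod("unmappedTargets", "CorrespondenceMap", function(x) {
  which(multiplicity(x) == 0L)
})

setMethod("show", "CorrespondenceMap", function(object) {
  cat(sprintf("CorrespondenceMap: %d pairs, %d/%d targets unmapped\n",
              nrow(object@pairs), length(unmappedTargets(object)),
              object@nTarget))
})

#' @rdname RegistrationResult-class
#' @param x a \code{RegistrationResult}.
#' @export
setMethod("fitness", "RegistrationResult", function(x) x@fitness)

#' @rdname RegistrationResult-class
#' @export
setMethod("inlierRMSE", "RegistrationResult", function(x) x@inlierRMSE)

#' @rdname RegistrationResult-class
#' @export
setMethod("inlierMAE", "RegistrationResult", function(x) x@inlierMAE)

#' @rdname RegistrationResult-class
#' @export
setMethod("correspondences", "RegistrationResult",
          function(x) x@correspondences)

#' @rdname RegistrationResult-class
#' @export
setMethod("transformMatrix", "RegistrationResult",
          function(x) x@transform@matrix)

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf(
    "RegistrationResult [%s]: fitness %.3f, inlier RMSE %.4g%s\n",
    paste(object@method, collapse = "+"), object@fitness, object@inlierRMSE,
    if (is.na(object@inlierMAE)) ""
    else sprintf(", inlier MAE %.4g", object@inlierMAE)))
})

#' Retrieve the estimated transform of a registration
#'
#' @param result a [RegistrationResult-class].
#' @return the [RigidTransform-class].
#' @export
resultTransform <- function(result) result@transform
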