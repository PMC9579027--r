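#' @import methods
#' @importFrom stats median quantile cor mad sd var dist rnorm runif rnbinom
#'   pnorm isoreg wilcox.test
NULL

#' PointCloud: segmented nuclei as a 3D point set with expression channels
#'
#' A \code{PointCloud} holds the centroid coordinates (micrometres) of the
#' segmented nuclei of one imaged tailbud sample together with zero or more
#' named per-nucleus channel intensities (e.g. HCR stains for \code{sox2},
#' \code{tbxta}). It is the unit of registration: sources are aligned onto a
#' target cloud and their channels imputed across.
#'
#' @slot coords numeric matrix, N x 3, columns x/y/z, all finite, N >= 1.
#' @slot channels numeric matrix, N x C (C may be 0), named columns; raw
#'   intensities are arbitrary nonnegative units, normalized channels lie in
#'   [0, 1].
#' @slot sampleId single character identifier.
#' @slot stage optional stage label such as \code{"18ss"} (\code{NA} if unset).
#'
#' @seealso [pointCloud()], [readPointsTable()], [simulateTailbud()]
#' @export
setClass("PointCloud",
  representation(coords = "matrix", channels = "matrix",
                 sampleId = "character", stage = "character"))

setValidity("PointCloud", function(object) {
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be a numeric N x 3 matrix")
  if (nrow(object@coords) < 1)
    msg <- c(msg, "a PointCloud needs at least one point")
  if (any(!is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (ncol(object@channels) > 0) {
    if (nrow(object@channels) != nrow(object@coords))
      msg <- c(msg, "every channel must have exactly one value per point")
    if (is.null(colnames(object@channels)) ||
        anyDuplicated(colnames(object@channels)))
      msg <- c(msg, "channels must have unique names")
    if (any(!is.finite(object@channels)))
      msg <- c(msg, "channel intensities must be finite (no NA)")
    if (any(object@channels < 0))
      msg <- c(msg, "channel intensities must be nonnegative")
  }
  if (length(object@sampleId) != 1)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' RigidTransform: a proper rigid-body motion
#'
#' A 4 x 4 homogeneous transform whose rotation block is orthonormal with
#' determinant +1 (no shearing, stretching or reflection) and whose last row
#' is (0, 0, 0, 1). This is the only class of transform the registration
#' pipeline will ever return: tailbuds are aligned by rotation and translation
#' alone.
#'
#' @slot matrix numeric 4 x 4 homogeneous matrix.
#' @seealso [rigidTransform()], [applyTransform()]
#' @export
setClass("RigidTransform", representation(matrix = "matrix"))

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !all(dim(m) == c(4, 4)))
    return("matrix must be numeric 4 x 4")
  if (any(!is.finite(m))) return("matrix entries must be finite")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation block must be orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation block must have determinant +1 (no reflection)")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    return("last row must be (0, 0, 0, 1)")
  TRUE
})

#' CorrespondenceMap: matched point pairs from a registration
#'
#' Records which source points were matched to which target points after
#' alignment, plus the target points that received no match. Multiplicity per
#' target drives the imputation policy: unique targets copy, multi-mapped
#' targets aggregate, unmapped targets fall back to k-NN/null/complete.
#'
#' @slot pairs integer matrix with columns \code{source}, \code{target}.
#' @slot nSource,nTarget sizes of the two clouds.
#' @export
setClass("CorrespondenceMap",
  representation(pairs = "matrix", nSource = "integer", nTarget = "integer"))

setValidity("CorrespondenceMap", function(object) {
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must have two columns (source, target)")
  if (nrow(p)) {
    if (any(p[, 1] < 1 | p[, 1] > object@nSource))
      return("source indices out of range")
    if (any(p[, 2] < 1 | p[, 2] > object@nTarget))
      return("target indices out of range")
  }
  TRUE
})

#' RegistrationResult: transform, correspondences and quality metrics
#'
#' @slot transform the estimated [RigidTransform-class].
#' @slot correspondences a [CorrespondenceMap-class] extracted at the inlier
#'   distance threshold.
#' @slot fitness fraction of source points with an inlier correspondence.
#' @slot inlierRMSE root-mean-square geometric error over inlier pairs (um).
#' @slot inlierMAE mean absolute color error over inlier pairs on the common
#'   channel (normalized-intensity units); \code{NA} when no channel was used.
#' @slot method character log of the steps taken ("ransac", "icp", "cicp").
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform",
                 correspondences = "CorrespondenceMap",
                 fitness = "numeric", inlierRMSE = "numeric",
                 inlierMAE = "numeric", method = "character"))

setValidity("RegistrationResult", function(object) {
  if (object@fitness < 0 || object@fitness > 1)
    return("fitness must lie in [0, 1]")
  if (is.finite(object@inlierRMSE) && object@inlierRMSE < 0)
    return("inlierRMSE must be nonnegative")
  if (!is.na(object@inlierMAE) &&
      (object@inlierMAE < -1e-12 || object@inlierMAE > 1 + 1e-12))
    return("inlierMAE must lie in [0, 1] when present")
  TRUE
})

#' CompositeMap: a target cloud carrying imputed multi-gene channels
#'
#' The product of [buildComposite()]: the target \code{PointCloud} augmented
#' with the channels imputed from each registered source, plus per-channel
#' provenance (which sample contributed it, the registration metrics, and the
#' per-point imputation policy used: unique / multi / knn / null / complete).
#'
#' @slot target the augmented [PointCloud-class].
#' @slot provenance named list, one entry per imputed channel, each holding
#'   \code{sampleId}, \code{metrics} (named numeric) and \code{policy}
#'   (character vector, one label per target point).
#' @slot rejected character vector of source sample ids rejected for low
#'   registration fitness.
#' @export
setClass("CompositeMap",
  representation(target = "PointCloud", provenance = "list",
                 rejected = "character"))

setValidity("CompositeMap", function(object) {
  n <- nrow(object@target@coords)
  for (nm in names(object@provenance)) {
    pol <- object@provenance[[nm]]$policy
    if (!is.null(pol) && length(pol) != n)
      return(sprintf("provenance policy for '%s' must label every point", nm))
  }
  TRUE
})

#' ProbabilityMap: per-target-point NMp mapping counts
#'
#' Counts, for every target cell, how many source samples mapped one of their
#' segmented NMps onto it. Cells with a large count are assigned a high
#' probability of being an NMp; the display set keeps cells with at least
#' \code{minCount} hits (default 2).
#'
#' @slot counts integer vector, one count per target point, each between 0 and
#'   the number of sources.
#' @slot nSources number of contributing source samples.
#' @slot minCount display threshold.
#' @export
setClass("ProbabilityMap",
  representation(counts = "integer", nSources = "integer",
                 minCount = "integer"))

setValidity("ProbabilityMap", function(object) {
  if (any(object@counts < 0) || any(object@counts > object@nSources))
    return("counts must lie between 0 and nSources")
  TRUE
})
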