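#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1); or a full
#'   4 x 4 homogeneous matrix via \code{matrix4}.
#' @param translation length-3 translation vector.
#' @param matrix4 alternatively, the full 4 x 4 matrix.
#' @return a [RigidTransform-class].
#' @examples
#' identityTransform()
#' rigidTransform(rotationAboutAxis("z", pi / 12), c(10, 0, 0))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           matrix4 = NULL) {
  m <- if (!is.null(matrix4)) {
    as.matrix(matrix4)
  } else {
    rbind(cbind(rotation, translation), c(0, 0, 0, 1))
  }
  dimnames(m) <- NULL
  new("RigidTransform", matrix = m)
}

#' @rdname rigidTransform
#' @export
identityTransform <- function() rigidTransform()

#' Rotation about a coordinate axis
#'
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c0 <- cos(angle); s0 <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c0, -s0, 0, s0, c0), 3, 3, byrow = TRUE),
    y = matrix(c(c0, 0, s0, 0, 1, 0, -s0, 0, c0), 3, 3, byrow = TRUE),
    z = matrix(c(c0, -s0, 0, s0, c0, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

#' @rdname RigidTransform-class
#' @export
setMethod("transformMatrix", "RigidTransform", function(x) x@matrix)

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object)
  tr <- object@matrix[1:3, 4]
  cat(sprintf("RigidTransform: rotation %.3f rad, translation (%.2f, %.2f, %.2f)\n",
              ang, tr[1], tr[2], tr[3]))
})

#' Compose, invert and measure rigid transforms
#'
#' \code{composeTransforms(a, b)} returns the transform applying \code{b}
#' first, then \code{a}. \code{invertTransform} is the exact inverse.
#' \code{rotationAngle} returns the rotation angle (radians) and
#' \code{translationNorm} the Euclidean translation length, used to measure
#' how far a composed transform is from the identity.
#'
#' @param a,b,transform [RigidTransform-class] objects.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(matrix4 = a@matrix %*% b@matrix)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(transform) {
  R <- transform@matrix[1:3, 1:3]
  t0 <- transform@matrix[1:3, 4]
  rigidTransform(rotation = t(R), translation = -t(R) %*% t0)
}

#' @rdname composeTransforms
#' @export
rotationAngle <- function(transform) {
  tr <- sum(diag(transform@matrix[1:3, 1:3]))
  acos(.clamp((tr - 1) / 2, -1, 1))
}

#' @rdname composeTransforms
#' @export
translationNorm <- function(transform) {
  sqrt(sum(transform@matrix[1:3, 4]^2))
}

#' Serialize a transform to/from JSON (16 numbers, row-major)
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @export
writeTransformJSON <- function(transform, path) {
  jsonlite::write_json(as.numeric(t(transform@matrix)), path, digits = NA)
}

#' @rdname writeTransformJSON
#' @export
readTransformJSON <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(matrix4 = matrix(as.numeric(v), 4, 4, byrow = TRUE))
}

# Least-squares rigid transform (Kabsch/Umeyama without scaling) mapping
# rows of src onto rows of dst, optionally weighted.
.kabsch <- function(src, dst, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(src))
  w <- w / sum(w)
  cs <- colSums(src * w)
  cd <- colSums(dst * w)
  H <- crossprod(sweep(src, 2, cs) * w, sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigidTransform(rotation = R, translation = cd - R %*% cs)
}
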