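# Small-motion update used by the Gauss-Newton ICP steps: xi = (wx, wy, wz,
# tx, ty, tz) mapped to a proper rigid transform via Euler composition.
.xiToTransform <- function(xi) {
  R <- rotationAboutAxis("z", xi[3]) %*% rotationAboutAxis("y", xi[2]) %*%
       rotationAboutAxis("x", xi[1])
  rigidTransform(rotation = R, translation = xi[4:6])
}

#' Point-to-plane ICP refinement
#'
#' Iteratively re-matches nearest neighbours within \code{maxCorrDist} and
#' minimizes the point-to-plane residual \eqn{n_q \cdot (p - q)} by a
#' linearized Gauss-Newton step, starting from \code{init}. The point-to-plane
#' objective is preferred over point-to-point for its faster convergence on
#' smooth surfaces such as the tailbud wall. Target normals are estimated
#' from k = 30 nearest neighbours and oriented toward the cloud centroid.
#'
#' @param source,target [PointCloud-class] objects.
#' @param init initial [RigidTransform-class] (typically from
#'   [ransacCoarse()]).
#' @param maxCorrDist correspondence distance threshold; default 2x mean
#'   nearest-neighbour spacing of the target.
#' @param maxIter maximum iterations.
#' @param tol relative residual-change convergence threshold.
#' @return a [RegistrationResult-class] (method \code{"icp"}).
#' @export
refineICP <- function(source, target, init = identityTransform(),
                      maxCorrDist = NULL, maxIter = 50, tol = 1e-8) {
  .icpCore(source, target, init, maxCorrDist, maxIter, tol,
           commonChannel = NULL, colorWeight = 0)
}

#' Colored ICP refinement
#'
#' Joint geometric and photometric refinement for clouds sharing a common
#' normalized color channel: the objective adds, to the point-to-plane term, a
#' color residual comparing the source intensity against the target's local
#' color field linearized on the tangent plane (a first-order "virtual image"
#' of the channel around each target point). The photometric term
#' disambiguates alignments the geometry alone cannot (the common channel in
#' the tailbud maps is \code{sox2}).
#'
#' @inheritParams refineICP
#' @param commonChannel channel name present and normalized to [0, 1] in both
#'   clouds.
#' @param colorWeight photometric fraction of the joint objective in [0, 1];
#'   default 0.032 (geometric 0.968). \code{colorWeight = 0} reduces to
#'   [refineICP()].
#' @return a [RegistrationResult-class] (method \code{"cicp"}) with
#'   \code{inlierMAE} populated.
#' @export
refineColoredICP <- function(source, target, init = identityTransform(),
                             commonChannel, maxCorrDist = NULL,
                             colorWeight = 0.032, maxIter = 50, tol = 1e-8) {
  for (cl in list(source, target))
    if (!commonChannel %in% channelNames(cl))
      .stopf("channel mismatch: '%s' missing in sample '%s'",
             commonChannel, sampleId(cl))
  .icpCore(source, target, init, maxCorrDist, maxIter, tol,
           commonChannel = commonChannel, colorWeight = colorWeight)
}

.icpCore <- function(source, target, init, maxCorrDist, maxIter, tol,
                     commonChannel, colorWeight) {
  sp <- coords(source); tp <- coords(target)
  if (is.null(maxCorrDist)) maxCorrDist <- 2 * .meanNNSpacing(tp)
  if (maxCorrDist <= 0) .stopf("maxCorrDist must be positive")
  tN <- .estimateNormals(tp, k = min(30, nrow(tp)))

  useColor <- !is.null(commonChannel) && colorWeight > 0
  sC <- if (!is.null(commonChannel)) getChannel(source, commonChannel)
  tC <- if (!is.null(commonChannel)) getChannel(target, commonChannel)
  tG <- if (useColor) .colorGradients(tp, tN, tC, k = min(30, nrow(tp)))

  wG <- sqrt(1 - colorWeight); wC <- sqrt(colorWeight)
  tf <- init
  prev <- Inf
  for (iter in seq_len(maxIter)) {
    moved <- applyTransform(sp, tf)
    nn <- .nn1(moved, tp)
    sel <- which(nn$dist <= maxCorrDist)
    if (length(sel) < 6) break
    p <- moved[sel, , drop = FALSE]
    qi <- nn$idx[sel]
    q <- tp[qi, , drop = FALSE]
    n <- tN[qi, , drop = FALSE]
    rg <- rowSums(n * (p - q))
    # geometric rows: [ p x n | n ]
    Ag <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
                p[, 3] * n[, 1] - p[, 1] * n[, 3],
                p[, 1] * n[, 2] - p[, 2] * n[, 1],
                n)
    A <- wG * Ag; b <- wG * (-rg)
    if (useColor) {
      d <- tG[qi, , drop = FALSE]
      off <- p - q
      ndot <- rowSums(n * off)
      u <- p - n * ndot                      # projection on tangent plane
      rc <- (tC[qi] + rowSums(d * (u - q))) - sC[sel]
      # dC/dp = (I - n n^T) d, rows of the color Jacobian are [ p x g | g ]
      g <- d - n * rowSums(n * d)
      Ac <- cbind(p[, 2] * g[, 3] - p[, 3] * g[, 2],
                  p[, 3] * g[, 1] - p[, 1] * g[, 3],
                  p[, 1] * g[, 2] - p[, 2] * g[, 1],
                  g)
      A <- rbind(A, wC * Ac)
      b <- c(b, wC * (-rc))
    }
    xi <- tryCatch(qr.solve(A, b), error = function(e) rep(0, 6))
    tf <- composeTransforms(.xiToTransform(xi), tf)
    res <- sqrt(mean(rg^2))
    if (is.finite(prev) && abs(prev - res) <= tol * max(prev, 1e-30)) {
      prev <- res
      break
    }
    prev <- res
  }
  ev <- .evaluateAlignment(sp, tp, tf, maxCorrDist, srcColor = sC,
                           tgtColor = tC)
  .resultFromEval(ev, tf, nrow(sp), nrow(tp),
                  if (useColor) "cicp" else "icp")
}

# Per-target-point color gradient on the tangent plane: least-squares fit of
# C(q_j) ~ C(q) + d . (q_j - q) over the k-NN neighbourhood, with q_j first
# projected onto the tangent plane so that d is orthogonal to the normal.
.colorGradients <- function(pts, normals, colorVals, k = 30) {
  n <- nrow(pts)
  nn <- .knn(pts, pts, min(k, n))
  grad <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    js <- setdiff(nn$idx[i, ], i)
    if (length(js) < 3) next
    off <- pts[js, , drop = FALSE] -
      matrix(pts[i, ], length(js), 3, byrow = TRUE)
    nv <- normals[i, ]
    off <- off - outer(drop(off %*% nv), nv)   # tangent-plane projection
    y <- colorVals[js] - colorVals[i]
    AtA <- crossprod(off) + 1e-9 * diag(3)
    d <- solve(AtA, crossprod(off, y))
    grad[i, ] <- d - nv * sum(nv * d)
  }
  grad
}
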