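#' Coarse global alignment by RANSAC over feature correspondences
#'
#' Non-deterministic (but seeded) global registration providing the initial
#' coarse alignment for ICP refinement. Both clouds are voxel-downsampled,
#' local geometric descriptors (FPFH-style, descriptor radius 5x the voxel
#' size) are computed, and candidate correspondences are proposed by
#' nearest-neighbour matching in descriptor space. Each RANSAC iteration
#' samples three correspondences, prunes them by edge-length similarity,
#' estimates a rigid transform and scores it by inlier count among the
#' candidate set; the best transform is re-evaluated on the full clouds.
#'
#' @param source,target [PointCloud-class] objects.
#' @param maxCorrDist inlier distance threshold; default 2x the mean
#'   nearest-neighbour spacing of the target.
#' @param nIter number of RANSAC iterations.
#' @param seed integer seed (same seed, same result).
#' @param voxel downsampling voxel edge; default the mean nearest-neighbour
#'   spacing of the target.
#' @return a [RegistrationResult-class] (method \code{"ransac"}).
#' @export
ransacCoarse <- function(source, target, maxCorrDist = NULL, nIter = 1000,
                         seed = 1, voxel = NULL) {
  sp <- coords(source); tp <- coords(target)
  spacing <- .meanNNSpacing(tp)
  if (is.null(voxel)) voxel <- max(spacing, 1e-6)
  if (is.null(maxCorrDist)) maxCorrDist <- 2 * spacing
  if (maxCorrDist <= 0) .stopf("maxCorrDist must be positive")

  ds <- .voxelDownsample(sp, voxel)
  dt <- .voxelDownsample(tp, voxel)
  sPts <- ds$pts; tPts <- dt$pts
  if (nrow(sPts) < 4 || nrow(tPts) < 4)
    .stopf("too few points after downsampling for RANSAC")
  sN <- .estimateNormals(sPts, k = min(30, nrow(sPts)))
  tN <- .estimateNormals(tPts, k = min(30, nrow(tPts)))
  sF <- .fpfh(sPts, sN, radius = 5 * voxel)
  tF <- .fpfh(tPts, tN, radius = 5 * voxel)

  # candidate correspondences: nearest target descriptor per source point
  cand <- .nn1(sF, tF)$idx
  nC <- nrow(sPts)

  best <- NULL; bestScore <- -1; bestRMSE <- Inf
  .withSeed(seed, {
    for (pass in 1:2) {
      for (it in seq_len(nIter)) {
        pick <- sample.int(nC, 3)
        a <- sPts[pick, , drop = FALSE]
        b <- tPts[cand[pick], , drop = FALSE]
        # edge-length similarity pruning (cheap reject of bad triplets);
        # dropped in the rescue pass when nothing survives it
        if (pass == 1) {
          ea <- dist(a); eb <- dist(b)
          if (any(abs(ea - eb) > pmax(0.1 * ea, maxCorrDist))) next
        }
        tf <- .kabsch(a, b)
        moved <- applyTransform(sPts, tf)
        dd <- sqrt(rowSums((moved - tPts[cand, , drop = FALSE])^2))
        inl <- dd <= maxCorrDist
        score <- sum(inl)
        if (score > bestScore ||
            (score == bestScore && score > 0 &&
             sqrt(mean(dd[inl]^2)) < bestRMSE)) {
          bestScore <- score
          bestRMSE <- if (score > 0) sqrt(mean(dd[inl]^2)) else Inf
          best <- tf
        }
      }
      if (bestScore >= 3) break
    }
  })
  if (is.null(best) || bestScore < 3) {
    ev <- .evaluateAlignment(sp, tp, identityTransform(), maxCorrDist)
    .stopf(paste0("RANSAC found no consistent inlier set ",
                  "(best identity fitness %.3f)"), ev$fitness)
  }
  # polish on the downsampled inlier correspondences, then evaluate in full
  moved <- applyTransform(sPts, best)
  dd <- sqrt(rowSums((moved - tPts[cand, , drop = FALSE])^2))
  inl <- which(dd <= maxCorrDist)
  if (length(inl) >= 3)
    best <- .kabsch(sPts[inl, , drop = FALSE],
                    tPts[cand[inl], , drop = FALSE])
  ev <- .evaluateAlignment(sp, tp, best, maxCorrDist)
  .resultFromEval(ev, best, nrow(sp), nrow(tp), "ransac")
}
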