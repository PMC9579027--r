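#' Register a source cloud onto a target cloud
#'
#' Orchestrates the full alignment: coarse global alignment with
#' [ransacCoarse()], then fine refinement with point-to-plane ICP (no common
#' channel) or colored ICP (when \code{commonChannel} is given). The final
#' correspondence map is extracted at \code{maxCorrDist}.
#'
#' @param source,target [PointCloud-class] objects.
#' @param commonChannel optional name of a normalized channel shared by both
#'   clouds; switches the fine stage to colored ICP.
#' @param maxCorrDist inlier/correspondence distance threshold; default 2x
#'   mean nearest-neighbour spacing of the target.
#' @param nIter RANSAC iterations.
#' @param colorWeight photometric fraction for colored ICP.
#' @param maxIter,tol ICP iteration controls.
#' @param seed integer seed for the stochastic coarse stage.
#' @return a [RegistrationResult-class]; \code{@method} logs the path taken
#'   (\code{ransac+icp} or \code{ransac+cicp}).
#' @examples
#' pc <- simulateTailbud(nPoints = 200, seed = 1)
#' res <- registerClouds(pc, pc, seed = 1)
#' fitness(res)   # 1 on self-registration
#' @export
registerClouds <- function(source, target, commonChannel = NULL,
                           maxCorrDist = NULL, nIter = 1000,
                           colorWeight = 0.032, maxIter = 50, tol = 1e-8,
                           seed = 1) {
  if (is.null(maxCorrDist)) maxCorrDist <- 2 * .meanNNSpacing(coords(target))
  coarse <- ransacCoarse(source, target, maxCorrDist = maxCorrDist,
                         nIter = nIter, seed = seed)
  fine <- if (is.null(commonChannel)) {
    refineICP(source, target, init = resultTransform(coarse),
              maxCorrDist = maxCorrDist, maxIter = maxIter, tol = tol)
  } else {
    refineColoredICP(source, target, init = resultTransform(coarse),
                     commonChannel = commonChannel,
                     maxCorrDist = maxCorrDist, colorWeight = colorWeight,
                     maxIter = maxIter, tol = tol)
  }
  initialize(fine, method = c("ransac", fine@method))
}

#' Registration quality metrics, raw and fitness-scaled
#'
#' Returns fitness, inlier RMSE and (when a channel is given) inlier MAE,
#' together with their fitness-scaled versions. Inlier metrics are computed
#' over matched points only and therefore overestimate registration quality
#' when many points fall outside the threshold; dividing by the fitness
#' (scaled = inlier / fitness) inflates the error as the matched fraction
#' drops, correcting that bias. With fitness 0 the scaled metrics are
#' undefined and reported as \code{Inf}.
#'
#' @param result a [RegistrationResult-class].
#' @return named numeric vector: \code{fitness}, \code{inlierRMSE},
#'   \code{inlierMAE}, \code{scaledInlierRMSE}, \code{scaledInlierMAE}.
#' @export
registrationMetrics <- function(result) {
  f <- result@fitness
  sc <- function(x) {
    if (is.na(x)) NA_real_ else if (f == 0) Inf else x / f
  }
  c(fitness = f, inlierRMSE = result@inlierRMSE,
    inlierMAE = result@inlierMAE,
    scaledInlierRMSE = sc(result@inlierRMSE),
    scaledInlierMAE = sc(result@inlierMAE))
}
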