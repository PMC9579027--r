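#' Simulate a tailbud-shaped point cloud with co-expression fields
#'
#' Samples nuclei uniformly inside an ellipsoid (default half-axes 60 x 40 x
#' 40 um, ~900 points, the scale of a segmented tailbud) and attaches
#' spatially smooth channel fields: a sox2-like channel high toward the
#' anterior pole, a tbxta-like channel high toward the posterior pole, and a
#' smooth overlap zone around the equator where both exceed zero — emulating
#' the neural/mesodermal gradients with a co-expressing posterior-wall
#' population. Additional channels are generated as noisy affine functions of
#' an anchor with a requested Pearson correlation. All channels are min-max
#' normalized to [0, 1]; the generator is a pure function of its seed.
#'
#' @param nPoints number of nuclei.
#' @param halfAxes ellipsoid half-axes (um).
#' @param gradientScale length-scale of the anchor gradients as a fraction of
#'   the x half-axis.
#' @param channelNoiseSd additive Gaussian noise on the anchor fields before
#'   normalization.
#' @param genes named list of extra channels, each
#'   \code{list(anchor = "sox2"|"tbxta", correlation = r)}.
#' @param sampleId,stage metadata.
#' @param seed integer seed.
#' @return a [PointCloud-class].
#' @examples
#' pc <- simulateTailbud(nPoints = 500, seed = 1,
#'                       genes = list(cdh6 = list(anchor = "sox2",
#'                                                correlation = 0.8)))
#' @export
simulateTailbud <- function(nPoints = 900, halfAxes = c(60, 40, 40),
                            gradientScale = 0.35, channelNoiseSd = 0.3,
                            genes = list(), sampleId = "synthetic",
                            stage = NA_character_, seed = 1) {
  if (nPoints < 1) .stopf("nPoints must be >= 1")
  if (length(halfAxes) != 3 || any(halfAxes <= 0))
    .stopf("halfAxes must be three positive lengths")
  .withSeed(seed, {
    # uniform sampling in the unit ball, scaled to the ellipsoid
    g <- matrix(rnorm(3 * nPoints), nPoints, 3)
    g <- g / sqrt(rowSums(g^2))
    r <- runif(nPoints)^(1 / 3)
    pts <- g * r * matrix(halfAxes, nPoints, 3, byrow = TRUE)
    ax <- pts[, 1] / halfAxes[1]
    L <- gradientScale
    sox2 <- stats::plogis(-ax / L) + rnorm(nPoints, 0, channelNoiseSd)
    tbxta <- stats::plogis(ax / L) + rnorm(nPoints, 0, channelNoiseSd)
    chans <- list(sox2 = minMaxNormalize(sox2),
                  tbxta = minMaxNormalize(tbxta))
    for (nm in names(genes)) {
      sp <- genes[[nm]]
      rho <- sp$correlation
      if (abs(rho) > 1) .stopf("gene-anchor correlation must lie in [-1, 1]")
      av <- chans[[sp$anchor]]
      z <- (av - mean(av)) / stats::sd(av)
      chans[[nm]] <- minMaxNormalize(rho * z +
                                       sqrt(1 - rho^2) * rnorm(nPoints))
    }
    pointCloud(pts, channels = chans, sampleId = sampleId, stage = stage)
  })
}

#' Perturb a cloud by a rigid motion plus noise and dropout
#'
#' Applies \code{transform}, adds iid zero-mean Gaussian noise per coordinate
#' (SD \code{posSd}), adds Gaussian intensity noise clamped back to [0, 1]
#' (SD \code{channelSd}) and randomly deletes \code{floor(dropout * N)}
#' points. Used to build the noise-shifted replicates of the registration
#' calibration study.
#'
#' @param cloud a [PointCloud-class].
#' @param transform a [RigidTransform-class] (default identity).
#' @param posSd positional noise SD (coordinate units).
#' @param channelSd intensity noise SD.
#' @param dropout fraction of points to delete, in [0, 1).
#' @param seed integer seed.
#' @return the perturbed [PointCloud-class].
#' @export
perturbCloud <- function(cloud, transform = identityTransform(), posSd = 0,
                         channelSd = 0, dropout = 0, seed = 1) {
  if (posSd < 0 || channelSd < 0) .stopf("noise SDs must be nonnegative")
  if (dropout < 0 || dropout >= 1) .stopf("dropout must lie in [0, 1)")
  .withSeed(seed, {
    out <- applyTransform(cloud, transform)
    n <- nPoints(out)
    if (posSd > 0) {
      co <- coords(out) + matrix(rnorm(3 * n, 0, posSd), n, 3)
      colnames(co) <- c("x", "y", "z")
      out <- initialize(out, coords = co)
    }
    if (channelSd > 0 && ncol(channels(out))) {
      ch <- .clamp(channels(out) +
                     matrix(rnorm(length(channels(out)), 0, channelSd),
                            nrow = n))
      out <- initialize(out, channels = ch)
    }
    nDrop <- floor(dropout * n)
    if (nDrop > 0) out <- out[-sample.int(n, nDrop)]
    out
  })
}

#' Simulate a clustered expression count matrix
#'
#' Draws genes x cells counts from a negative-binomial model with
#' cluster-specific means and dispersions. Gene-module correlation is induced
#' by a shared latent factor per cell: module genes carry a loading equal to
#' \code{moduleCorrelation}, so coordinated modules (high loading) and noisy
#' cells (high dispersion or latent swing) can be dialed independently — the
#' two axes the criticality statistics measure. This is the minimal
#' generative model exhibiting the progenitor-versus-derivative contrast.
#'
#' @param clusterSpecs list of per-cluster specs:
#'   \code{list(name, nCells, meanExpr = 5, moduleCorrelation = 0,
#'   dispersion = 0.5)}.
#' @param nGenes total gene count; the first half belong to two latent
#'   modules (a quarter each).
#' @param seed integer seed.
#' @return a \code{SingleCellExperiment} with a \code{counts} assay,
#'   \code{colData()$cluster} labels and the module gene names in
#'   \code{metadata()$modules}.
#' @export
simulateExpression <- function(clusterSpecs, nGenes = 100, seed = 1) {
  if (!length(clusterSpecs)) .stopf("need at least one cluster spec")
  .withSeed(seed, {
    geneMeans <- exp(rnorm(nGenes, log(5), 0.4))
    mod1 <- seq_len(floor(nGenes / 4))
    mod2 <- seq_len(floor(nGenes / 4)) + floor(nGenes / 4)
    loadSign <- rep(0, nGenes)
    loadSign[mod1] <- 1
    loadSign[mod2] <- -1
    blocks <- lapply(clusterSpecs, function(sp) {
      nc <- sp$nCells
      mc <- if (is.null(sp$moduleCorrelation)) 0 else sp$moduleCorrelation
      if (abs(mc) > 1) .stopf("moduleCorrelation must lie in [-1, 1]")
      disp <- if (is.null(sp$dispersion)) 0.5 else sp$dispersion
      mu0 <- if (is.null(sp$meanExpr)) geneMeans
             else geneMeans * sp$meanExpr / mean(geneMeans)
      f <- rnorm(nc)                       # shared latent factor per cell
      lg <- loadSign * mc
      # log-mean shift lg * f, variance-centered so means stay comparable
      mu <- outer(mu0, rep(1, nc)) * exp(outer(lg, f) - outer(lg^2, rep(0.5, nc)))
      counts <- matrix(rnbinom(nGenes * nc, mu = mu, size = 1 / disp),
                       nGenes, nc)
      counts
    })
    counts <- do.call(cbind, blocks)
    labels <- unlist(lapply(clusterSpecs, function(sp)
      rep(sp$name, sp$nCells)))
    rownames(counts) <- paste0("gene", seq_len(nGenes))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
    sce <- expressionMatrix(counts, cluster = labels)
    S4Vectors::metadata(sce)$modules <- list(
      module1 = rownames(counts)[mod1], module2 = rownames(counts)[mod2])
    sce
  })
}

#' Simulate a staged transition series of NM index samples
#'
#' For each stage, draws per-cell NM index values from a two-component
#' mixture — neural-fated cells around +\code{nmCenter}, mesoderm-fated cells
#' around -\code{nmCenter} — with stage-specific dispersion, so a mid-series
#' stage generated with inflated dispersion carries the transient
#' heterogeneity peak as ground truth. Each cell also receives a fate-domain
#' label, a tcf level consistent with its NM state, and a matching tailbud
#' cloud position. A \code{rebelliousFraction} of the mesoderm-fated cells is
#' flipped to a neural NM state with a high (state-inconsistent) tcf level.
#'
#' @param stages list of per-stage specs:
#'   \code{list(label, nCells, nmDispersion)}.
#' @param nmCenter absolute center of the two NM mixture components.
#' @param rebelliousFraction fraction of mesoderm-fated cells injected as
#'   rebellious (neural state, high tcf).
#' @param tcfLevels length-2 vector: tcf means for (low, high) Wnt activity.
#' @param seed integer seed.
#' @return named list (one element per stage label), each with \code{table}
#'   (data.frame: NM, domain, tcf, truth), \code{cloud} (a
#'   [PointCloud-class]) and \code{spec}.
#' @export
simulateTransitionSeries <- function(stages, nmCenter = 0.3,
                                     rebelliousFraction = 0,
                                     tcfLevels = c(0.2, 0.8), seed = 1) {
  if (length(stages) < 2) .stopf("need at least two stages")
  out <- list()
  .withSeed(seed, {
    for (sp in stages) {
      nc <- sp$nCells
      sdv <- sp$nmDispersion
      domain <- rep(c("neural-fated", "mesoderm-fated"), length.out = nc)
      nm <- ifelse(domain == "neural-fated",
                   rnorm(nc, nmCenter, sdv), rnorm(nc, -nmCenter, sdv))
      # tcf consistent with the congruent state of each domain
      tcf <- .clamp(ifelse(domain == "neural-fated",
                           rnorm(nc, tcfLevels[1], 0.05),
                           rnorm(nc, tcfLevels[2], 0.05)))
      truth <- rep("Congruent", nc)
      meso <- which(domain == "mesoderm-fated")
      nReb <- floor(rebelliousFraction * length(meso))
      if (nReb > 0) {
        reb <- sample(meso, nReb)
        nm[reb] <- abs(rnorm(nReb, nmCenter, sdv / 2)) + 1e-6  # neural state
        tcf[reb] <- .clamp(rnorm(nReb, tcfLevels[2], 0.05))    # high Wnt
        truth[reb] <- "Rebellious"
      }
      cloud <- simulateTailbud(nPoints = nc, sampleId = sp$label,
                               stage = sp$label,
                               seed = sample.int(.Machine$integer.max, 1))
      cloud <- setChannel(cloud, "tcf", tcf)
      out[[sp$label]] <- list(
        table = data.frame(NM = nm, domain = domain, tcf = tcf,
                           truth = truth),
        cloud = cloud, spec = sp)
    }
  })
  out
}
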