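#' Impute one source channel onto a target cloud
#'
#' Transfers per-point intensities along a registration's correspondence map
#' under the three-outcome policy: (i) a target matched by exactly one source
#' point adopts that source intensity; (ii) a target matched by several source
#' points aggregates them by \code{multiPolicy} (default median); (iii) an
#' unmapped target is resolved by \code{unmappedPolicy} — \code{"null"} sets
#' it to 0, \code{"complete"} keeps the target's own existing value, and the
#' default \code{"knn"} takes the mean intensity of its k nearest target
#' points (default k = 5) among targets that already received a value under
#' outcomes (i) or (ii); ties in distance are broken by lower point index.
#'
#' @param correspondences a [CorrespondenceMap-class] (source onto target).
#' @param sourceValues per-source-point intensity vector.
#' @param target the target [PointCloud-class] (coordinates used for k-NN).
#' @param multiPolicy \code{"median"} (default) or \code{"mean"}.
#' @param unmappedPolicy \code{"knn"} (default), \code{"null"} or
#'   \code{"complete"}.
#' @param k neighbours for the knn policy.
#' @param existing required for \code{"complete"}: the target's own channel.
#' @return list with \code{values} (length-nTarget numeric) and \code{policy}
#'   (per-point labels: unique/multi/knn/null/complete).
#' @export
imputeChannel <- function(correspondences, sourceValues, target,
                          multiPolicy = c("median", "mean"),
                          unmappedPolicy = c("knn", "null", "complete"),
                          k = 5, existing = NULL) {
  multiPolicy <- match.arg(multiPolicy)
  unmappedPolicy <- match.arg(unmappedPolicy)
  if (k < 1) .stopf("k must be >= 1")
  if (length(sourceValues) != correspondences@nSource)
    .stopf("sourceValues length (%d) must match the source cloud size (%d)",
           length(sourceValues), correspondences@nSource)
  if (unmappedPolicy == "complete" && is.null(existing))
    .stopf("'complete' policy needs the target's existing channel values")
  nT <- correspondences@nTarget
  if (nT != nPoints(target))
    .stopf("correspondence map does not match the target cloud size")
  p <- corrPairs(correspondences)
  mult <- multiplicity(correspondences)
  values <- rep(NA_real_, nT)
  policy <- rep(NA_character_, nT)
  agg <- if (multiPolicy == "median") stats::median else mean
  if (nrow(p)) {
    byTarget <- split(sourceValues[p[, 1]], p[, 2])
    ti <- as.integer(names(byTarget))
    values[ti] <- vapply(byTarget, agg, numeric(1))
    policy[ti] <- ifelse(mult[ti] == 1L, "unique", "multi")
  }
  un <- which(is.na(values))
  if (length(un)) {
    if (unmappedPolicy == "null") {
      values[un] <- 0
      policy[un] <- "null"
    } else if (unmappedPolicy == "complete") {
      values[un] <- existing[un]
      policy[un] <- "complete"
    } else {
      assigned <- which(!is.na(values))
      if (!length(assigned))
        .stopf("knn imputation failed: no target point received a value")
      pts <- coords(target)
      for (t0 in un) {
        d <- sqrt(colSums((t(pts[assigned, , drop = FALSE]) - pts[t0, ])^2))
        o <- assigned[order(d, assigned)][seq_len(min(k, length(assigned)))]
        values[t0] <- mean(values[o])
      }
      policy[un] <- "knn"
    }
  }
  list(values = values, policy = policy)
}

#' Build a multi-gene composite map from several source samples
#'
#' Registers every source onto the target with [registerClouds()] (colored
#' ICP on \code{commonChannel}, default \code{sox2}) and imputes each source
#' channel that the target does not already carry. Sources whose registration
#' fitness falls below \code{fitnessThreshold} are rejected with a warning
#' and listed in the result. A channel contributed by several sources is
#' imputed from the first accepted source carrying it. With five sources
#' contributing six new genes onto a sox2+tbxta target this yields the
#' eight-channel composite map.
#'
#' @param target the target [PointCloud-class] (channels normalized).
#' @param sources list of source [PointCloud-class] objects.
#' @param commonChannel shared registration channel (default \code{"sox2"}).
#' @param multiPolicy,unmappedPolicy,k imputation controls, see
#'   [imputeChannel()].
#' @param fitnessThreshold minimum registration fitness to accept a source.
#' @param seed integer seed for the coarse registrations.
#' @param ... further arguments to [registerClouds()].
#' @return a [CompositeMap-class].
#' @export
buildComposite <- function(target, sources, commonChannel = "sox2",
                           multiPolicy = "median", unmappedPolicy = "knn",
                           k = 5, fitnessThreshold = 0.5, seed = 1, ...) {
  out <- target
  prov <- list()
  rejected <- character()
  for (si in seq_along(sources)) {
    src <- sources[[si]]
    res <- registerClouds(src, target, commonChannel = commonChannel,
                          seed = seed + si, ...)
    if (fitness(res) < fitnessThreshold) {
      .warnf("source '%s' rejected: fitness %.3f below threshold %.2f",
             sampleId(src), fitness(res), fitnessThreshold)
      rejected <- c(rejected, sampleId(src))
      next
    }
    newChans <- setdiff(channelNames(src),
                        c(commonChannel, channelNames(out)))
    for (nm in newChans) {
      imp <- imputeChannel(correspondences(res), getChannel(src, nm),
                           target, multiPolicy = multiPolicy,
                           unmappedPolicy = unmappedPolicy, k = k)
      out <- setChannel(out, nm, imp$values)
      prov[[nm]] <- list(sampleId = sampleId(src),
                         metrics = registrationMetrics(res),
                         policy = imp$policy)
    }
  }
  new("CompositeMap", target = out, provenance = prov, rejected = rejected)
}

#' @rdname CompositeMap-class
#' @param x a \code{CompositeMap}.
#' @export
setMethod("compositeTarget", "CompositeMap", function(x) x@target)

#' @rdname CompositeMap-class
#' @export
setMethod("provenance", "CompositeMap", function(x) x@provenance)

setMethod("show", "CompositeMap", function(object) {
  cat(sprintf("CompositeMap: %d points, %d channel(s) [%s], %d imputed, %d source(s) rejected\n",
              nPoints(object@target), ncol(channels(object@target)),
              paste(channelNames(object@target), collapse = ", "),
              length(object@provenance), length(object@rejected)))
})

#' Quantile-threshold and min-max rescale a channel
#'
#' Background suppression applied to every composite-map gene before NMp
#' calling: values strictly below the q-quantile (default 0.7, linearly
#' interpolated between order statistics) are set to 0, then the whole vector
#' is min-max rescaled to [0, 1]. After this step "positive" means strictly
#' greater than zero.
#'
#' @param values nonempty numeric vector.
#' @param q quantile threshold in [0, 1].
#' @return rescaled vector in [0, 1].
#' @export
thresholdRescale <- function(values, q = 0.7) {
  if (!length(values)) .stopf("thresholdRescale needs a nonempty vector")
  if (max(values) == min(values))
    .stopf("degenerate range: all values equal")
  thr <- stats::quantile(values, q, type = 7, names = FALSE)
  values[values < thr] <- 0
  minMaxNormalize(values)
}

#' Apply thresholdRescale to every channel of a composite map
#'
#' @param map a [CompositeMap-class].
#' @param q quantile threshold.
#' @return the map with all channels thresholded and rescaled.
#' @export
thresholdCompositeMap <- function(map, q = 0.7) {
  tgt <- map@target
  for (nm in channelNames(tgt))
    tgt <- setChannel(tgt, nm, thresholdRescale(getChannel(tgt, nm), q))
  initialize(map, target = tgt)
}

#' Identify in-silico NMps on a composite map
#'
#' NMps are the sox2+tbxta+ double-positive cells (strictly positive after
#' [thresholdRescale()]) that lie inside the user-supplied NMp spatial
#' region. Double-positives outside the region (hypochord and aberrant
#' cells) are excluded and reported separately.
#'
#' @param map a [CompositeMap-class] whose channels have been thresholded.
#' @param region per-point logical vector, or a list of axis-aligned boxes
#'   each of form \code{list(min = c(x,y,z), max = c(x,y,z))}.
#' @return list with integer vectors \code{nmps} and \code{excluded}.
#' @export
identifyNMps <- function(map, region) {
  tgt <- compositeTarget(map)
  for (nm in c("sox2", "tbxta"))
    if (!nm %in% channelNames(tgt))
      .stopf("channel error: composite map lacks '%s'", nm)
  inRegion <- .regionPredicate(region, coords(tgt))
  dp <- getChannel(tgt, "sox2") > 0 & getChannel(tgt, "tbxta") > 0
  list(nmps = which(dp & inRegion), excluded = which(dp & !inRegion))
}

.regionPredicate <- function(region, pts) {
  if (is.logical(region)) {
    if (length(region) != nrow(pts))
      .stopf("region label vector must cover every point")
    return(region)
  }
  if (is.function(region)) return(as.logical(region(pts)))
  inside <- rep(FALSE, nrow(pts))
  for (box in region) {
    hit <- rep(TRUE, nrow(pts))
    for (d in 1:3)
      hit <- hit & pts[, d] >= box$min[d] & pts[, d] <= box$max[d]
    inside <- inside | hit
  }
  inside
}

#' NMp probability map from repeated source mappings
#'
#' Counts, per target cell, how many source samples mapped one of their
#' segmented NMps onto it; cells hit often are assigned a high probability of
#' being an NMp. The display set keeps cells with at least \code{minCount}
#' hits (default 2).
#'
#' @param target the target [PointCloud-class].
#' @param nmpHits list of integer vectors, one per source, of target indices
#'   hit by that source's NMps.
#' @param minCount display threshold.
#' @return a [ProbabilityMap-class].
#' @export
probabilityMap <- function(target, nmpHits, minCount = 2) {
  n <- nPoints(target)
  counts <- integer(n)
  for (h in nmpHits) {
    h <- unique(as.integer(h))
    if (length(h) && (min(h) < 1 || max(h) > n))
      .stopf("NMp hit index out of target range")
    counts[h] <- counts[h] + 1L
  }
  new("ProbabilityMap", counts = counts, nSources = length(nmpHits),
      minCount = as.integer(minCount))
}

#' @rdname probabilityMap
#' @param map a [ProbabilityMap-class].
#' @return \code{displaySet}: indices with count >= minCount.
#' @export
displaySet <- function(map) which(map@counts >= map@minCount)

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf("ProbabilityMap: %d sources, %d/%d cells at count >= %d\n",
              object@nSources, sum(object@counts >= object@minCount),
              length(object@counts), object@minCount))
})
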