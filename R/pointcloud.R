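#' Construct a PointCloud
#'
#' @param coords numeric N x 3 matrix (or data.frame) of nucleus centroids in
#'   micrometres; columns are taken as x, y, z.
#' @param channels optional named list of length-N numeric vectors, or an
#'   N x C matrix with column names, holding per-nucleus intensities.
#' @param sampleId sample identifier string.
#' @param stage optional stage label (e.g. \code{"24ss"}).
#' @return a [PointCloud-class].
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), 10, 3),
#'                  channels = list(sox2 = runif(10)), sampleId = "s1")
#' nPoints(pc)
#' @export
pointCloud <- function(coords, channels = list(), sampleId = "sample",
                       stage = NA_character_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (is.list(channels)) {
    ch <- if (length(channels)) {
      do.call(cbind, lapply(channels, as.numeric))
    } else {
      matrix(numeric(0), nrow = nrow(coords), ncol = 0)
    }
    if (length(channels)) colnames(ch) <- names(channels)
  } else {
    ch <- as.matrix(channels)
    storage.mode(ch) <- "double"
  }
  new("PointCloud", coords = coords, channels = ch,
      sampleId = as.character(sampleId), stage = as.character(stage))
}

#' @rdname PointCloud-class
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' @rdname PointCloud-class
#' @export
setMethod("channels", "PointCloud", function(x) x@channels)

#' @rdname PointCloud-class
#' @export
setMethod("channelNames", "PointCloud", function(x) colnames(x@channels))

#' @rdname PointCloud-class
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

#' @rdname PointCloud-class
#' @export
setMethod("sampleId", "PointCloud", function(x) x@sampleId)

#' @rdname PointCloud-class
#' @export
setMethod("stageLabel", "PointCloud", function(x) x@stage)

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud '%s'%s: %d points, %d channel(s)%s\n",
              object@sampleId,
              if (is.na(object@stage)) "" else paste0(" [", object@stage, "]"),
              nrow(object@coords), ncol(object@channels),
              if (ncol(object@channels))
                paste0(" (", paste(colnames(object@channels), collapse = ", "),
                       ")") else ""))
})

#' Extract one channel of a PointCloud
#'
#' @param cloud a [PointCloud-class].
#' @param name channel name.
#' @return numeric vector of per-point intensities.
#' @export
getChannel <- function(cloud, name) {
  if (!name %in% colnames(cloud@channels))
    .stopf("channel '%s' not present in sample '%s'", name, cloud@sampleId)
  cloud@channels[, name]
}

#' Add or replace a channel of a PointCloud
#'
#' @param cloud a [PointCloud-class].
#' @param name channel name.
#' @param values length-N numeric vector.
#' @return the updated \code{PointCloud}.
#' @export
setChannel <- function(cloud, name, values) {
  if (length(values) != nrow(cloud@coords))
    .stopf("channel '%s' must have one value per point", name)
  ch <- cloud@channels
  if (name %in% colnames(ch)) {
    ch[, name] <- values
  } else {
    ch <- cbind(ch, values)
    colnames(ch)[ncol(ch)] <- name
  }
  initialize(cloud, channels = ch)
}

#' Subset a PointCloud by point index
#'
#' @param x a [PointCloud-class].
#' @param i integer or logical index over points.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(nrow(x@coords))[i]
  if (length(idx) < 1 || anyNA(idx))
    .stopf("subsetting would leave an empty or invalid PointCloud")
  initialize(x, coords = x@coords[idx, , drop = FALSE],
             channels = x@channels[idx, , drop = FALSE])
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform) {
  m <- transform@matrix
  t(m[1:3, 1:3] %*% t(x) + m[1:3, 4])
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "PointCloud", function(x, transform) {
  out <- applyTransform(x@coords, transform)
  colnames(out) <- c("x", "y", "z")
  initialize(x, coords = out)
})

#' Min-max normalization with clamping
#'
#' Rescales intensities to [0, 1] using user-chosen low/high thresholds,
#' clamping values outside the range to 0 or 1. Mirrors the per-sample
#' normalization applied to nuclear HCR intensities, where the extreme signal
#' values of each sample (after discarding mis-segmented outliers) define the
#' thresholds.
#'
#' @param values numeric vector of raw intensities.
#' @param lo,hi thresholds with \code{hi > lo}; defaults are the observed
#'   range of \code{values}.
#' @return numeric vector in [0, 1]: \code{clamp((values - lo)/(hi - lo))}.
#' @examples
#' minMaxNormalize(c(2, 5, 8), lo = 2, hi = 8)  # 0, 0.5, 1
#' @export
minMaxNormalize <- function(values, lo = min(values), hi = max(values)) {
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    .stopf("minMaxNormalize needs hi > lo (got lo = %g, hi = %g)", lo, hi)
  .clamp((values - lo) / (hi - lo))
}

#' Normalize every channel of a PointCloud to [0, 1]
#'
#' Applies [minMaxNormalize()] channel-wise with per-channel observed ranges
#' (or explicit thresholds).
#'
#' @param cloud a [PointCloud-class].
#' @param thresholds optional named list of \code{c(lo, hi)} per channel.
#' @return the normalized \code{PointCloud}.
#' @export
normalizeChannels <- function(cloud, thresholds = list()) {
  ch <- cloud@channels
  for (nm in colnames(ch)) {
    th <- thresholds[[nm]]
    ch[, nm] <- if (is.null(th)) minMaxNormalize(ch[, nm])
                else minMaxNormalize(ch[, nm], th[1], th[2])
  }
  initialize(cloud, channels = ch)
}

#' Crop a cloud to one side of an axis-aligned plane
#'
#' Used to keep a consistent field of view across samples: typically all
#' nuclei posterior to the tip of the developing notochord are retained before
#' registration.
#'
#' @param cloud a [PointCloud-class].
#' @param axis one of \code{"x"}, \code{"y"}, \code{"z"} (the user-named
#'   anterior-posterior axis; no axis convention is imposed).
#' @param cutoff plane coordinate.
#' @param keep \code{"greater"} or \code{"less"}: side of the plane to keep.
#' @return the cropped \code{PointCloud} (error if it would be empty).
#' @export
cropPosterior <- function(cloud, axis = c("x", "y", "z"), cutoff,
                          keep = c("greater", "less")) {
  axis <- match.arg(axis)
  keep <- match.arg(keep)
  v <- cloud@coords[, axis]
  sel <- if (keep == "greater") v > cutoff else v < cutoff
  if (!any(sel))
    .stopf("cropPosterior would remove every point (registration needs >= 1)")
  cloud[sel]
}
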