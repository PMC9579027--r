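#' Read a segmented-centroid table into a PointCloud
#'
#' Front end to centroid tables exported from nucleus segmentation: one row
#' per nucleus with coordinate columns and zero or more channel-intensity
#' columns. Comma- and tab-separated files are both accepted (dialect is
#' sniffed from the header line); a header row is required and the decimal
#' separator is ".".
#'
#' @param path CSV/TSV file path.
#' @param coordinateColumns names of the three coordinate columns.
#' @param channelColumns names of channel columns to attach; by default every
#'   numeric non-coordinate column.
#' @param sampleId,stage metadata passed to [pointCloud()]; \code{sampleId}
#'   defaults to the file name.
#' @return a [PointCloud-class] with one point per row, channels in file
#'   order.
#' @export
readPointsTable <- function(path, coordinateColumns = c("x", "y", "z"),
                            channelColumns = NULL, sampleId = NULL,
                            stage = NA_character_) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in coordinateColumns)
    if (!cc %in% names(df))
      .stopf("schema error: missing coordinate column '%s' in %s", cc, path)
  if (is.null(channelColumns)) {
    channelColumns <- setdiff(names(df), coordinateColumns)
    channelColumns <- channelColumns[vapply(df[channelColumns], is.numeric,
                                            logical(1))]
  } else {
    for (cc in channelColumns)
      if (!cc %in% names(df))
        .stopf("schema error: missing channel column '%s' in %s", cc, path)
  }
  xyz <- as.matrix(df[coordinateColumns])
  if (!is.numeric(xyz) || any(!is.finite(xyz))) {
    bad <- which(apply(xyz, 1, function(r) any(!is.finite(suppressWarnings(
      as.numeric(r))))))[1]
    .stopf("parse error: non-numeric coordinate at data row %d of %s",
           bad, path)
  }
  chans <- lapply(df[channelColumns], as.numeric)
  for (nm in names(chans))
    if (anyNA(chans[[nm]]))
      .stopf("parse error: missing value in channel '%s' at data row %d",
             nm, which(is.na(chans[[nm]]))[1])
  names(chans) <- channelColumns
  pointCloud(xyz, channels = chans,
             sampleId = if (is.null(sampleId)) basename(path) else sampleId,
             stage = stage)
}

#' Write a PointCloud to a CSV table
#'
#' Inverse of [readPointsTable()]: header \code{x,y,z} plus channel names,
#' one row per point. The round trip is lossless at full double precision.
#'
#' @param cloud a [PointCloud-class].
#' @param path output file path.
#' @export
writePointsTable <- function(cloud, path) {
  stopifnot(is(cloud, "PointCloud"))
  df <- as.data.frame(cloud@coords)
  if (ncol(cloud@channels))
    df <- cbind(df, as.data.frame(cloud@channels))
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stopf("I/O error: cannot write %s", path)
  invisible(path)
}

#' Export a PointCloud as ASCII PLY for external viewers
#'
#' Vertex positions plus one scalar property per channel.
#'
#' @param cloud a [PointCloud-class].
#' @param path output .ply path.
#' @export
writePLY <- function(cloud, path) {
  n <- nPoints(cloud)
  props <- c("x", "y", "z", channelNames(cloud))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           sprintf("property float %s", props),
           "end_header")
  body <- cbind(cloud@coords, cloud@channels)
  writeLines(c(hdr, apply(body, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Read a genes x cells count matrix
#'
#' Accepts MatrixMarket triplets (\code{matrix.mtx} + \code{genes.tsv} +
#' \code{barcodes.tsv}) or a dense TSV with gene ids in the first column.
#'
#' @param path path to a \code{.mtx} file or dense TSV.
#' @param genesPath,barcodesPath identifier files for the MTX route
#'   (defaults: \code{genes.tsv} / \code{barcodes.tsv} next to the matrix).
#' @param clusterPath optional TSV of per-cell cluster labels (one per line,
#'   or a two-column barcode/label table).
#' @return a \code{SingleCellExperiment} with a \code{counts} assay and, when
#'   given, \code{colData(x)$cluster}.
#' @export
readExpressionMatrix <- function(path, genesPath = NULL, barcodesPath = NULL,
                                 clusterPath = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    gp <- if (is.null(genesPath)) file.path(dirname(path), "genes.tsv")
          else genesPath
    bp <- if (is.null(barcodesPath)) file.path(dirname(path), "barcodes.tsv")
          else barcodesPath
    genes <- utils::read.table(gp, sep = "\t", stringsAsFactors = FALSE)[, 1]
    cells <- utils::read.table(bp, sep = "\t", stringsAsFactors = FALSE)[, 1]
    rownames(m) <- genes
    colnames(m) <- cells
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  cluster <- NULL
  if (!is.null(clusterPath)) {
    cl <- utils::read.table(clusterPath, sep = "\t", stringsAsFactors = FALSE)
    cluster <- cl[, ncol(cl)]
  }
  expressionMatrix(m, cluster = cluster)
}
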