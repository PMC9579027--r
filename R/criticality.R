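#' @importFrom SummarizedExperiment assay colData
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame
NULL

#' Construct a genes-by-cells expression container
#'
#' Wraps a nonnegative count matrix (dense or sparse) into a
#' \code{SingleCellExperiment} with a \code{counts} assay and an optional
#' per-cell \code{cluster} column, enforcing dimension/identifier
#' consistency.
#'
#' @param counts genes x cells nonnegative matrix.
#' @param geneIds,cellIds identifier vectors (default: existing dimnames or
#'   generated).
#' @param cluster optional per-cell cluster labels.
#' @return a \code{SingleCellExperiment}.
#' @export
expressionMatrix <- function(counts, geneIds = NULL, cellIds = NULL,
                             cluster = NULL) {
  if (min(counts) < 0) .stopf("counts must be nonnegative")
  if (is.null(geneIds))
    geneIds <- if (!is.null(rownames(counts))) rownames(counts)
               else paste0("gene", seq_len(nrow(counts)))
  if (is.null(cellIds))
    cellIds <- if (!is.null(colnames(counts))) colnames(counts)
               else paste0("cell", seq_len(ncol(counts)))
  if (length(geneIds) != nrow(counts) || length(cellIds) != ncol(counts))
    .stopf("identifier lists must match the matrix dimensions")
  rownames(counts) <- geneIds
  colnames(counts) <- cellIds
  cd <- if (is.null(cluster)) DataFrame(row.names = cellIds)
        else {
          if (length(cluster) != ncol(counts))
            .stopf("cluster labels must cover every cell")
          DataFrame(cluster = as.character(cluster), row.names = cellIds)
        }
  SingleCellExperiment(assays = list(counts = counts), colData = cd)
}

.counts <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
}

.clusters <- function(x, clusterLabels = NULL) {
  if (!is.null(clusterLabels)) return(as.character(clusterLabels))
  if (is(x, "SummarizedExperiment") && "cluster" %in% names(colData(x)))
    return(as.character(colData(x)$cluster))
  .stopf("no cluster labels available")
}

#' MAD-based quality control of a count matrix
#'
#' Removes outlier cells whose log-transformed library size (total counts) or
#' feature size (detected-gene count) deviates from the respective median by
#' more than \code{nMads} median absolute deviations (two-sided, standard
#' 1.4826 consistency constant), then removes genes with zero total count.
#' Cells are filtered before genes.
#'
#' @param x a \code{SingleCellExperiment} (from [expressionMatrix()]) or a
#'   genes x cells matrix.
#' @param nMads outlier threshold in MADs (default 3).
#' @return the filtered object, same class as the input.
#' @export
qcFilter <- function(x, nMads = 3) {
  m <- .counts(x)
  lib <- log(Matrix::colSums(m))
  nfeat <- log(Matrix::colSums(m > 0))
  keepCell <- abs(lib - stats::median(lib)) <= nMads * stats::mad(lib) &
              abs(nfeat - stats::median(nfeat)) <= nMads * stats::mad(nfeat)
  if (!any(keepCell)) .stopf("QC removed every cell")
  sub <- if (is(x, "SummarizedExperiment")) x[, keepCell]
         else x[, keepCell, drop = FALSE]
  keepGene <- Matrix::rowSums(.counts(sub)) > 0
  if (!any(keepGene)) .stopf("QC removed every gene")
  if (is(sub, "SummarizedExperiment")) sub[keepGene, ]
  else sub[keepGene, , drop = FALSE]
}

#' Critical transition index of a cells-by-genes submatrix
#'
#' The index is the ratio of two averaged absolute Pearson correlations: the
#' mean over all gene pairs of |r(gene_a, gene_b)| across cells, divided by
#' the mean over all cell pairs of |r(cell_a, cell_b)| across genes. As a
#' population nears a bifurcation, cells decorrelate from one another
#' (denominator falls) while gene modules move in concert (numerator rises),
#' so the index surges. Zero-variance genes or cells are dropped with a
#' warning before computing.
#'
#' @param submatrix cells x genes numeric matrix (typically the cluster's
#'   marker genes).
#' @return the index value (dimensionless, > 0).
#' @export
criticalIndex <- function(submatrix) {
  m <- as.matrix(submatrix)
  keepG <- apply(m, 2, stats::sd) > 0
  keepC <- apply(m, 1, stats::sd) > 0
  if (any(!keepG) || any(!keepC))
    .warnf("dropped %d zero-variance gene(s) and %d cell(s)",
           sum(!keepG), sum(!keepC))
  m <- m[keepC, keepG, drop = FALSE]
  # re-check: dropping cells can create constant genes (and vice versa)
  while (nrow(m) >= 2 && ncol(m) >= 2) {
    kg <- apply(m, 2, stats::sd) > 0
    kc <- apply(m, 1, stats::sd) > 0
    if (all(kg) && all(kc)) break
    m <- m[kc, kg, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2)
    .stopf("undefined index: fewer than 2 usable genes or cells")
  gg <- abs(stats::cor(m))          # gene-gene, across cells
  cc <- abs(stats::cor(t(m)))       # cell-cell, across genes
  num <- mean(gg[upper.tri(gg)])
  den <- mean(cc[upper.tri(cc)])
  num / den
}

#' Cluster-balanced bootstrap of the critical transition index
#'
#' To compare clusters of unequal size, \code{nCells} cells (default 200) are
#' drawn with replacement from each cluster and the index computed on the
#' cluster's marker-gene submatrix; the procedure is repeated \code{nBoot}
#' times (default 10000).
#'
#' @param x expression container or genes x cells matrix.
#' @param clusterLabels per-cell labels (taken from \code{colData(x)$cluster}
#'   when absent).
#' @param markerGenes named list: per-cluster character vectors of marker
#'   genes (a single unnamed vector is recycled for all clusters).
#' @param nCells resample size per replicate.
#' @param nBoot number of bootstrap replicates.
#' @param seed integer seed.
#' @return named list of per-cluster results, each with \code{ic} (median of
#'   the bootstrap distribution), \code{bootValues} and \code{cluster}.
#' @export
bootstrapCriticalIndex <- function(x, clusterLabels = NULL, markerGenes,
                                   nCells = 200, nBoot = 10000, seed = 1) {
  m <- .counts(x)
  cl <- .clusters(x, clusterLabels)
  cls <- unique(cl)
  if (!is.list(markerGenes))
    markerGenes <- stats::setNames(rep(list(markerGenes), length(cls)), cls)
  out <- list()
  .withSeed(seed, {
    for (cname in cls) {
      cells <- which(cl == cname)
      if (length(cells) < 2) {
        .warnf("cluster '%s' has fewer than 2 cells; skipped", cname)
        next
      }
      genes <- markerGenes[[cname]]
      if (is.null(genes)) .stopf("no marker genes for cluster '%s'", cname)
      if (!all(genes %in% rownames(m)))
        .stopf("marker gene '%s' absent from the matrix",
               setdiff(genes, rownames(m))[1])
      sub <- t(as.matrix(m[genes, cells, drop = FALSE]))  # cells x genes
      boot <- vapply(seq_len(nBoot), function(b) {
        rows <- sample.int(nrow(sub), nCells, replace = TRUE)
        tryCatch(suppressWarnings(criticalIndex(sub[rows, , drop = FALSE])),
                 error = function(e) NA_real_)
      }, numeric(1))
      out[[cname]] <- list(ic = stats::median(boot, na.rm = TRUE),
                           bootValues = boot, cluster = cname)
    }
  })
  out
}

# library-size normalization to the median depth, then log1p
.logNormalize <- function(m) {
  m <- as.matrix(m)
  libs <- colSums(m)
  libs[libs == 0] <- 1
  log1p(t(t(m) / libs * stats::median(libs)))
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p library-size-normalized
#' expression and returns the top \code{n} (default 2000; all genes when n
#' exceeds the gene count).
#'
#' @param x expression container or genes x cells matrix.
#' @param n number of genes to keep.
#' @return character vector of gene names.
#' @export
selectHVGs <- function(x, n = 2000) {
  m <- .counts(x)
  ln <- .logNormalize(m)
  v <- apply(ln, 1, stats::var)
  names(sort(v, decreasing = TRUE))[seq_len(min(n, length(v)))]
}

#' Transcriptional noise as pairwise cell-cell distances
#'
#' Computes all pairwise cell-cell Euclidean distances on the log-normalized
#' expression of a highly-variable-gene set (default: top 2000 per cluster
#' via [selectHVGs()]). A noisier population produces a distribution of
#' larger distances.
#'
#' @param x expression container or genes x cells matrix (>= 2 cells).
#' @param hvgSet gene names to use (must be present in the matrix).
#' @param metric distance metric (only \code{"euclidean"} is offered).
#' @return list with \code{distances} (numeric vector, one value per
#'   unordered cell pair) and \code{hvgSet}.
#' @export
transcriptionalNoise <- function(x, hvgSet = NULL,
                                 metric = "euclidean") {
  metric <- match.arg(metric, "euclidean")
  m <- .counts(x)
  if (ncol(m) < 2) .stopf("transcriptional noise needs >= 2 cells")
  if (is.null(hvgSet)) hvgSet <- selectHVGs(m)
  if (!all(hvgSet %in% rownames(m)))
    .stopf("HVG '%s' absent from the matrix",
           setdiff(hvgSet, rownames(m))[1])
  ln <- .logNormalize(m[hvgSet, , drop = FALSE])
  list(distances = as.numeric(stats::dist(t(ln), method = metric)),
       hvgSet = hvgSet)
}
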