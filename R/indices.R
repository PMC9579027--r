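#' Stage-wise anchor correlation statistics
#'
#' For every non-anchor gene, computes the Pearson correlation with the
#' anchor gene (\code{sox2} or \code{tbxta}) within each same-stage sample's
#' NMps, then summarizes across samples by the median \eqn{\tilde\rho_k} and
#' interquartile range \eqn{\epsilon_k}. The per-gene weight
#' \eqn{w_k = \tilde\rho_k (1 - \epsilon_k)} penalizes genes whose
#' correlation with the anchor varies strongly between samples. A sample in
#' which the gene or the anchor has zero variance contributes no correlation
#' and is dropped with a warning; \eqn{\epsilon_k} can exceed 1 for widely
#' spread correlations, making the weight negative — applied literally and
#' surfaced with a warning.
#'
#' @param samples list of per-sample channel tables (matrix or data.frame,
#'   cells in rows, named gene columns including the anchor), each with at
#'   least 3 cells.
#' @param genes non-anchor gene names to weight.
#' @param anchor \code{"sox2"} or \code{"tbxta"}.
#' @return data.frame with columns \code{gene}, \code{rhoMedian}, \code{iqr},
#'   \code{weight} and attribute \code{anchor}.
#' @export
anchorCorrelationStats <- function(samples, genes, anchor) {
  if (!length(samples)) .stopf("need at least one sample")
  stats <- lapply(genes, function(g) {
    rs <- vapply(samples, function(s) {
      s <- as.data.frame(s)
      if (!all(c(g, anchor) %in% names(s)))
        .stopf("sample table lacks gene '%s' or anchor '%s'", g, anchor)
      if (nrow(s) < 3) .stopf("each sample needs >= 3 cells")
      if (stats::sd(s[[g]]) == 0 || stats::sd(s[[anchor]]) == 0)
        return(NA_real_)
      stats::cor(s[[g]], s[[anchor]])
    }, numeric(1))
    if (anyNA(rs))
      .warnf("gene '%s': %d sample(s) with zero variance dropped from the %s stats",
             g, sum(is.na(rs)), anchor)
    rs <- rs[!is.na(rs)]
    if (!length(rs))
      .stopf("stats unavailable for gene '%s': all samples excluded", g)
    rho <- stats::median(rs)
    eps <- unname(stats::quantile(rs, 0.75) - stats::quantile(rs, 0.25))
    if (eps > 1)
      .warnf("gene '%s': correlation IQR %.2f exceeds 1; weight is negative-capable",
             g, eps)
    c(rhoMedian = rho, iqr = eps, weight = rho * (1 - eps))
  })
  out <- data.frame(gene = genes, do.call(rbind, stats))
  attr(out, "anchor") <- anchor
  out
}

# shared worker: anchor value + weighted sum of non-anchor gene values
.anchoredIndex <- function(cellChannels, stats, anchor) {
  m <- if (is.null(dim(cellChannels))) {
    matrix(cellChannels, nrow = 1, dimnames = list(NULL,
                                                   names(cellChannels)))
  } else as.matrix(as.data.frame(cellChannels))
  if (!anchor %in% colnames(m))
    .stopf("channel error: anchor '%s' missing", anchor)
  idx <- m[, anchor]
  if (nrow(stats)) {
    missing <- setdiff(stats$gene, colnames(m))
    if (length(missing))
      .stopf("coverage error: gene '%s' absent from the cell channels",
             missing[1])
    for (i in seq_len(nrow(stats)))
      idx <- idx + stats$weight[i] * m[, stats$gene[i]]
  }
  unname(idx)
}

#' Neural and mesodermal indices
#'
#' The neural index of cell j is
#' \eqn{N_j = sox2_j + \sum_k \tilde\rho_k (1 - \epsilon_k)\, Gene_{kj}}
#' summed over the G non-anchor genes, with weights from
#' [anchorCorrelationStats()] on the \code{sox2} anchor. The mesodermal index
#' \eqn{M_j} is defined symmetrically with \code{tbxta} as the anchor. All
#' channel values must be min-max normalized.
#'
#' @param cellChannels named per-cell channel vector, or a cells-by-channels
#'   matrix/data.frame.
#' @param statsSox2,statsTbxta anchor statistics tables (may have zero rows
#'   for the G = 0 reduction).
#' @return numeric vector of per-cell index values.
#' @export
neuralIndex <- function(cellChannels, statsSox2) {
  .anchoredIndex(cellChannels, statsSox2, "sox2")
}

#' @rdname neuralIndex
#' @export
mesodermalIndex <- function(cellChannels, statsTbxta) {
  .anchoredIndex(cellChannels, statsTbxta, "tbxta")
}

#' Per-cell NM index table
#'
#' Assembles the per-cell neural index N, mesodermal index M and the NM index
#' \eqn{NM_j = N_j - M_j}. Positive NM values indicate neural bias, negative
#' values mesodermal bias.
#'
#' @param cells cells-by-channels matrix/data.frame of thresholded,
#'   normalized intensities (identified NMps).
#' @param statsSox2,statsTbxta anchor statistics from
#'   [anchorCorrelationStats()].
#' @return data.frame with columns \code{N}, \code{M}, \code{NM}.
#' @export
nmIndexTable <- function(cells, statsSox2, statsTbxta) {
  N <- neuralIndex(cells, statsSox2)
  M <- mesodermalIndex(cells, statsTbxta)
  data.frame(N = N, M = M, NM = N - M)
}

#' Unweighted per-cell indices
#'
#' \code{naiveIndex} is the anchor difference \code{sox2 - tbxta} (the G = 0
#' reduction of the NM index). \code{categoricalIndex} groups genes into
#' fixed neural and mesodermal categories:
#' \code{(sox2 + cdh6) - (tbxta + tcf)}.
#'
#' @param cellChannels named per-cell channel vector or cells-by-channels
#'   matrix/data.frame.
#' @return numeric vector of per-cell values.
#' @export
naiveIndex <- function(cellChannels) {
  empty <- data.frame(gene = character(), rhoMedian = numeric(),
                      iqr = numeric(), weight = numeric())
  .anchoredIndex(cellChannels, empty, "sox2") -
    .anchoredIndex(cellChannels, empty, "tbxta")
}

#' @rdname naiveIndex
#' @export
categoricalIndex <- function(cellChannels) {
  m <- if (is.null(dim(cellChannels))) {
    matrix(cellChannels, nrow = 1,
           dimnames = list(NULL, names(cellChannels)))
  } else as.matrix(as.data.frame(cellChannels))
  for (nm in c("sox2", "cdh6", "tbxta", "tcf"))
    if (!nm %in% colnames(m))
      .stopf("channel error: '%s' missing", nm)
  unname((m[, "sox2"] + m[, "cdh6"]) - (m[, "tbxta"] + m[, "tcf"]))
}

#' Classify NMps as Congruent, Compliant or Rebellious
#'
#' Each cell's NM state (neural if NM > \code{nmBand}, mesodermal if
#' NM < -\code{nmBand}, indecisive otherwise) is compared with its fate-mapped
#' spatial domain. Cells whose state matches their domain are Congruent;
#' incongruent cells split by their canonical Wnt activity (\code{tcf}
#' level): Compliant when the tcf level is consistent with the NM state
#' (tcf at or above threshold for a mesodermal state, below threshold for a
#' neural state — canonical Wnt drives the mesodermal program), Rebellious
#' when inconsistent. Indecisive cells are left unassigned.
#'
#' @param table data.frame with an \code{NM} column (e.g. from
#'   [nmIndexTable()]).
#' @param domain per-cell fate labels: \code{"neural-fated"} or
#'   \code{"mesoderm-fated"}.
#' @param tcf per-cell normalized tcf level.
#' @param nmBand neutral half-width around NM = 0 (default 0: strict sign
#'   rule).
#' @param tcfThreshold tcf split point; default the median tcf of the cells.
#' @return the table with added columns \code{domain}, \code{state} and
#'   \code{congruence} (\code{"Congruent"}, \code{"Compliant"},
#'   \code{"Rebellious"} or \code{NA} for indecisive cells).
#' @export
classifyCongruence <- function(table, domain, tcf, nmBand = 0,
                               tcfThreshold = stats::median(tcf)) {
  if (nmBand < 0) .stopf("nmBand must be nonnegative")
  if (length(domain) != nrow(table) || anyNA(domain))
    .stopf("labeling error: every cell needs a fate domain label")
  if (!all(domain %in% c("neural-fated", "mesoderm-fated")))
    .stopf("labeling error: unknown domain label")
  nm <- table$NM
  state <- ifelse(nm > nmBand, "neural",
                  ifelse(nm < -nmBand, "mesodermal", "indecisive"))
  congruent <- (state == "neural" & domain == "neural-fated") |
               (state == "mesodermal" & domain == "mesoderm-fated")
  tcfConsistent <- ifelse(state == "mesodermal", tcf >= tcfThreshold,
                          tcf < tcfThreshold)
  congruence <- rep(NA_character_, nrow(table))
  decided <- state != "indecisive"
  congruence[decided & congruent] <- "Congruent"
  congruence[decided & !congruent & tcfConsistent] <- "Compliant"
  congruence[decided & !congruent & !tcfConsistent] <- "Rebellious"
  table$domain <- domain
  table$tcf <- tcf
  table$state <- state
  table$congruence <- congruence
  table
}
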