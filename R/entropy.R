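#' Histogram counts of a continuous index
#'
#' Bins sample values (typically per-cell NM index values) into counts using
#' explicit edges or the Freedman-Diaconis rule. Intervals follow the
#' right-closed convention \code{(a, b]} with the lowest edge included, so
#' values on an edge fall into the bin to their left.
#'
#' @param values nonempty numeric vector.
#' @param edges strictly increasing bin edges, or \code{"fd"} to compute
#'   Freedman-Diaconis edges from \code{values} (see [fdBinEdges()]).
#' @return integer vector of counts (sum = length(values)) with the edges as
#'   attribute \code{"edges"}.
#' @export
histogramCounts <- function(values, edges = "fd") {
  if (!length(values)) .stopf("histogramCounts needs a nonempty vector")
  if (is.character(edges)) edges <- fdBinEdges(values)
  if (any(diff(edges) <= 0)) .stopf("edges must be strictly increasing")
  if (any(values < edges[1] | values > edges[length(edges)]))
    .stopf("value outside the explicit bin edges")
  bin <- findInterval(values, edges, left.open = TRUE, rightmost.closed = FALSE)
  bin[bin == 0L] <- 1L  # lowest edge included
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  attr(counts, "edges") <- edges
  counts
}

#' Freedman-Diaconis bin edges
#'
#' Bin width \eqn{2\,IQR\, n^{-1/3}} over the range of the pooled data. When
#' comparing stages, compute the edges once on the pooled multi-stage values
#' and reuse them per stage so the entropies are comparable.
#'
#' @param values numeric vector.
#' @return numeric vector of edges.
#' @export
fdBinEdges <- function(values) {
  rng <- range(values)
  if (rng[2] == rng[1]) return(c(rng[1] - 0.5, rng[1] + 0.5))
  iqr <- stats::IQR(values)
  h <- 2 * iqr * length(values)^(-1 / 3)
  nb <- if (h <= 0) 1L else max(1L, ceiling((rng[2] - rng[1]) / h))
  seq(rng[1], rng[2], length.out = nb + 1L)
}

#' Discrete Shannon entropy estimators
#'
#' Five estimators of the Shannon entropy (in nats) of the distribution
#' underlying a vector of histogram counts:
#' \describe{
#'   \item{\code{entropyML}}{empirical (maximum-likelihood) plug-in,
#'     \eqn{-\sum \hat p \log \hat p}.}
#'   \item{\code{entropyMM}}{Miller-Madow bias correction,
#'     \eqn{H_{ML} + (\hat m - 1)/(2n)} with \eqn{\hat m} occupied bins.}
#'   \item{\code{entropyDirichlet}}{plug-in on Dirichlet-smoothed frequencies
#'     \eqn{(y_i + a)/(n + Ka)}; \code{a = 1/2} is Jeffreys' prior,
#'     \code{a = 1} Laplace's.}
#'   \item{\code{entropyShrink}}{plug-in on James-Stein-type frequencies
#'     shrunk toward the uniform target 1/K with data-driven intensity
#'     \eqn{\lambda^*} (variance-over-misfit ratio, clipped to [0, 1];
#'     \eqn{\lambda^* = 1} at n = 1).}
#' }
#'
#' @param counts nonnegative integer vector of bin counts (sum >= 1).
#' @param a pseudocount per bin for the Dirichlet estimator.
#' @return entropy estimate in nats.
#' @examples
#' entropyML(c(25, 25, 25, 25))  # log(4)
#' entropyMM(c(25, 25, 25, 25))  # log(4) + 3/200
#' @export
entropyML <- function(counts) {
  n <- sum(counts)
  if (n < 1) .stopf("entropy needs at least one observation")
  p <- counts / n
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @rdname entropyML
#' @export
entropyMM <- function(counts) {
  n <- sum(counts)
  m <- sum(counts > 0)
  entropyML(counts) + (m - 1) / (2 * n)
}

#' @rdname entropyML
#' @export
entropyDirichlet <- function(counts, a = 0.5) {
  if (a <= 0) .stopf("pseudocount a must be positive")
  n <- sum(counts)
  K <- length(counts)
  p <- (counts + a) / (n + K * a)
  -sum(p * log(p))
}

#' @rdname entropyML
#' @export
entropyShrink <- function(counts) {
  n <- sum(counts)
  K <- length(counts)
  if (K < 2) return(0)
  target <- 1 / K
  p <- counts / n
  lambda <- if (n <= 1) 1 else {
    num <- (1 - sum(p^2)) / (n - 1)
    den <- sum((target - p)^2)
    if (den == 0) 1 else .clamp(num / den, 0, 1)
  }
  ps <- lambda * target + (1 - lambda) * p
  ps <- ps[ps > 0]
  -sum(ps * log(ps))
}

#' All five entropy estimates of an index distribution
#'
#' Bins \code{values} with [histogramCounts()] and returns the ML,
#' Miller-Madow, Dirichlet-Jeffreys, Dirichlet-Laplace and shrinkage
#' estimates, optionally with jackknife standard errors (binning held fixed
#' across deletions).
#'
#' @param values numeric sample (e.g. NM index values of one stage).
#' @param edges bin edges or \code{"fd"}.
#' @param se logical: also compute jackknife standard errors.
#' @return list with \code{estimates} (named numeric, nats), \code{se}
#'   (named numeric or NULL), \code{n} and \code{edges}.
#' @export
entropyEstimates <- function(values, edges = "fd", se = FALSE) {
  counts <- histogramCounts(values, edges)
  edges <- attr(counts, "edges")
  fns <- list(ml = entropyML, mm = entropyMM,
              jeffrey = function(co) entropyDirichlet(co, 0.5),
              laplace = function(co) entropyDirichlet(co, 1),
              shrink = entropyShrink)
  est <- vapply(fns, function(f) f(counts), numeric(1))
  ses <- NULL
  if (se) {
    ses <- vapply(names(fns), function(nm) {
      jackknifeSE(values, function(v) fns[[nm]](histogramCounts(v, edges)))$se
    }, numeric(1))
  }
  list(estimates = est, se = ses, n = length(values), edges = edges)
}

#' Leave-one-out jackknife standard error
#'
#' Re-estimates the statistic with each data point removed in turn and
#' returns \eqn{se = \sqrt{(n-1)/n \sum_i (\hat\theta_{(i)} -
#' \bar\theta)^2}}. For entropy estimators pass a function that bins with
#' fixed edges so the binning does not change across deletions. With the
#' sample mean as the estimator the jackknife SE equals \eqn{s/\sqrt n}
#' exactly.
#'
#' @param values numeric sample, n >= 2.
#' @param estimator function mapping a numeric vector to a scalar.
#' @return list with \code{estimate} (on the full sample) and \code{se}.
#' @export
jackknifeSE <- function(values, estimator) {
  n <- length(values)
  if (n < 2) .stopf("jackknife needs n >= 2")
  loo <- vapply(seq_len(n), function(i) estimator(values[-i]), numeric(1))
  list(estimate = estimator(values),
       se = sqrt((n - 1) / n * sum((loo - mean(loo))^2)))
}
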