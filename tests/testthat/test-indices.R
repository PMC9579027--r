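# small helper: stats table with given weights
statsRow <- function(gene, rho, iqr) {
  data.frame(gene = gene, rhoMedian = rho, iqr = iqr,
             weight = rho * (1 - iqr))
}

test_that("anchor correlation stats summarize per-sample correlations", {
  # build three samples whose gene-anchor correlations are exactly 0.5/0.7/0.9
  mkSample <- function(r, n = 200, seed = 1) {
    set.seed(seed)
    a <- rnorm(n)
    g <- r * a + sqrt(1 - r^2) * rnorm(n)
    # force the empirical correlation to r exactly via regression residuals
    res <- residuals(lm(g ~ a))
    g <- r * scale(a)[, 1] + sqrt(1 - r^2) * scale(res)[, 1]
    data.frame(sox2 = a, gene1 = g)
  }
  samples <- list(mkSample(0.5, seed = 1), mkSample(0.7, seed = 2),
                  mkSample(0.9, seed = 3))
  st <- anchorCorrelationStats(samples, "gene1", "sox2")
  expect_equal(st$rhoMedian, 0.7, tolerance = 1e-10)
  expect_equal(st$iqr, 0.2, tolerance = 1e-10)
  expect_equal(st$weight, 0.7 * 0.8, tolerance = 1e-10)

  # single sample: iqr 0, weight = r
  st1 <- anchorCorrelationStats(samples[2], "gene1", "sox2")
  expect_equal(st1$iqr, 0)
  expect_equal(st1$weight, st1$rhoMedian)

  # gene identical to the anchor: rho 1, iqr 0, weight 1
  ident <- lapply(1:3, function(i) {
    set.seed(i); a <- rnorm(50); data.frame(sox2 = a, gene1 = a)
  })
  sti <- anchorCorrelationStats(ident, "gene1", "sox2")
  expect_equal(sti$weight, 1)

  # zero-variance samples are dropped with a warning
  flat <- c(samples[1:2], list(data.frame(sox2 = rep(1, 5),
                                          gene1 = rnorm(5))))
  expect_warning(anchorCorrelationStats(flat, "gene1", "sox2"),
                 "zero variance")
  allFlat <- list(data.frame(sox2 = rep(1, 5), gene1 = rnorm(5)))
  expect_error(suppressWarnings(
    anchorCorrelationStats(allFlat, "gene1", "sox2")), "unavailable")
})

test_that("neural and mesodermal indices follow the weighted-sum form", {
  empty <- statsRow(character(), numeric(), numeric())
  # G = 0: the index is the anchor value itself
  expect_equal(neuralIndex(c(sox2 = 0.8), empty), 0.8)
  expect_equal(mesodermalIndex(c(tbxta = 0.3), empty), 0.3)
  # worked weighted example
  st <- statsRow("geneA", 0.8, 0.1)
  expect_equal(neuralIndex(c(sox2 = 0.6, geneA = 0.5), st),
               0.6 + 0.8 * 0.9 * 0.5)
  stm <- statsRow("geneA", -0.4, 0.2)
  expect_equal(mesodermalIndex(c(tbxta = 0.2, geneA = 0.5), stm),
               0.2 + (-0.4) * 0.8 * 0.5)
  # all gene values zero: index reduces to the anchor
  expect_equal(neuralIndex(c(sox2 = 0.4, geneA = 0), st), 0.4)
  # anchor-swap symmetry maps N onto M exactly
  cells <- data.frame(sox2 = runif(10), tbxta = runif(10),
                      geneA = runif(10))
  swapped <- data.frame(sox2 = cells$tbxta, tbxta = cells$sox2,
                        geneA = cells$geneA)
  expect_equal(neuralIndex(cells, st),
               mesodermalIndex(swapped, st))
  expect_error(neuralIndex(c(sox2 = 1), st), "coverage error")
  expect_error(neuralIndex(c(tbxta = 1), empty), "anchor 'sox2' missing")
})

test_that("the NM index is exactly N minus M and reduces to the naive index", {
  set.seed(6)
  cells <- data.frame(sox2 = runif(50), tbxta = runif(50),
                      geneA = runif(50), geneB = runif(50))
  stN <- statsRow(c("geneA", "geneB"), c(0.8, -0.3), c(0.1, 0.4))
  stM <- statsRow(c("geneA", "geneB"), c(-0.5, 0.6), c(0.2, 0.1))
  tab <- nmIndexTable(cells, stN, stM)
  expect_equal(tab$NM, tab$N - tab$M)
  expect_equal(tab$NM[1],
               neuralIndex(cells[1, ], stN) - mesodermalIndex(cells[1, ], stM))
  # with zero weights the NM index equals sox2 - tbxta
  zero <- statsRow(c("geneA", "geneB"), c(0, 0), c(0, 0))
  expect_equal(nmIndexTable(cells, zero, zero)$NM, naiveIndex(cells))
})

test_that("naive and categorical indices behave as stated", {
  expect_equal(naiveIndex(c(sox2 = 0.8, tbxta = 0.3)), 0.5)
  expect_equal(naiveIndex(c(sox2 = 0.4, tbxta = 0.4)), 0)
  set.seed(2)
  v <- data.frame(sox2 = runif(100), tbxta = runif(100))
  expect_true(all(abs(naiveIndex(v)) <= 1))
  expect_equal(categoricalIndex(c(sox2 = 1, cdh6 = 1, tbxta = 0, tcf = 0)), 2)
  expect_equal(categoricalIndex(c(sox2 = .3, cdh6 = .3, tbxta = .3,
                                  tcf = .3)), 0)
  # antisymmetric under swapping the neural and mesodermal pairs
  a <- c(sox2 = .9, cdh6 = .7, tbxta = .2, tcf = .1)
  b <- c(sox2 = .2, cdh6 = .1, tbxta = .9, tcf = .7)
  expect_equal(categoricalIndex(a), -categoricalIndex(b))
  expect_error(categoricalIndex(c(sox2 = 1, tbxta = 0)), "missing")
})

test_that("congruence classification matches the full rule table", {
  # enumerate every (state, domain, tcf side) combination and check against
  # an independently coded rule table
  grid <- expand.grid(nm = c(0.4, -0.4, 0),
                      domain = c("neural-fated", "mesoderm-fated"),
                      tcfHigh = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tab <- data.frame(NM = grid$nm)
  out <- classifyCongruence(tab, grid$domain,
                            tcf = ifelse(grid$tcfHigh, 0.9, 0.1),
                            tcfThreshold = 0.5)
  oracle <- mapply(function(nm, domain, tcfHigh) {
    state <- if (nm > 0) "neural" else if (nm < 0) "mesodermal"
             else "indecisive"
    if (state == "indecisive") return(NA_character_)
    if ((state == "neural") == (domain == "neural-fated")) return("Congruent")
    consistent <- if (state == "mesodermal") tcfHigh else !tcfHigh
    if (consistent) "Compliant" else "Rebellious"
  }, grid$nm, grid$domain, grid$tcfHigh)
  expect_equal(out$congruence, unname(oracle))
  # spot checks from the rule table
  expect_equal(out$congruence[out$NM > 0 &
                                out$domain == "mesoderm-fated" &
                                out$tcf < 0.5][1], "Compliant")
  expect_equal(out$congruence[out$NM > 0 &
                                out$domain == "mesoderm-fated" &
                                out$tcf > 0.5][1], "Rebellious")
  # classification is exhaustive and exclusive
  decided <- !is.na(out$congruence)
  expect_true(all(out$congruence[decided] %in%
                    c("Congruent", "Compliant", "Rebellious")))
  expect_equal(sum(decided) + sum(out$state == "indecisive"), nrow(out))
  expect_error(classifyCongruence(tab, rep("elsewhere", nrow(tab)), 0.5),
               "unknown domain")
})

test_that("naive and full NM indices correlate strongly on synthetic NMps", {
  # three same-stage samples with anchor-correlated genes in the weight
  # ranges seen across stages; weights estimated then applied to a fourth
  genes <- list(cdh6 = list(anchor = "sox2", correlation = 0.6),
                tcf = list(anchor = "tbxta", correlation = 0.5),
                hes6 = list(anchor = "sox2", correlation = 0.4),
                sp5l = list(anchor = "tbxta", correlation = -0.3))
  mk <- function(seed) as.data.frame(channels(
    simulateTailbud(nPoints = 300, genes = genes, seed = seed)))
  samples <- lapply(1:3, mk)
  gn <- names(genes)
  stN <- anchorCorrelationStats(samples, gn, "sox2")
  stM <- anchorCorrelationStats(samples, gn, "tbxta")
  cells <- mk(99)
  tab <- nmIndexTable(cells, stN, stM)
  expect_gt(cor(tab$NM, naiveIndex(cells)), 0.7)
})
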