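test_that("tailbud generation is seed-reproducible and well-formed", {
  a <- simulateTailbud(nPoints = 500, seed = 42)
  b <- simulateTailbud(nPoints = 500, seed = 42)
  expect_identical(coords(a), coords(b))
  expect_identical(channels(a), channels(b))
  expect_equal(nPoints(a), 500)
  expect_true(all(channels(a) >= 0 & channels(a) <= 1))
  expect_true(validObject(a))
  # points stay inside the ellipsoid
  hx <- c(60, 40, 40)
  expect_true(all(rowSums(sweep(coords(a), 2, hx, "/")^2) <= 1 + 1e-9))
  # opposite anchor poles: sox2 falls along x, tbxta rises
  expect_lt(cor(coords(a)[, "x"], getChannel(a, "sox2")), -0.5)
  expect_gt(cor(coords(a)[, "x"], getChannel(a, "tbxta")), 0.5)
  expect_error(simulateTailbud(nPoints = 0), "nPoints")
  expect_error(simulateTailbud(halfAxes = c(1, -1, 1)), "halfAxes")
})

test_that("requested gene-anchor correlations are realized", {
  pc <- simulateTailbud(nPoints = 5000, seed = 3,
                        genes = list(g1 = list(anchor = "sox2",
                                               correlation = 0.8),
                                     g2 = list(anchor = "tbxta",
                                               correlation = -0.4)))
  expect_lt(abs(cor(getChannel(pc, "g1"), getChannel(pc, "sox2")) - 0.8),
            0.05)
  expect_lt(abs(cor(getChannel(pc, "g2"), getChannel(pc, "tbxta")) + 0.4),
            0.05)
  expect_error(simulateTailbud(genes = list(g = list(anchor = "sox2",
                                                     correlation = 1.5))),
               "correlation")
})

test_that("perturbation applies noise, transform and dropout as stated", {
  pc <- simulateTailbud(nPoints = 100, seed = 8)
  # no-op perturbation
  same <- perturbCloud(pc, seed = 1)
  expect_identical(coords(same), coords(pc))
  expect_identical(channels(same), channels(pc))
  # mean squared displacement approximates 3 sigma^2
  sig <- 2
  big <- simulateTailbud(nPoints = 4000, seed = 9)
  noisy <- perturbCloud(big, posSd = sig, seed = 2)
  msd <- mean(rowSums((coords(noisy) - coords(big))^2))
  expect_lt(abs(msd - 3 * sig^2) / (3 * sig^2), 0.1)
  # channel noise stays clamped in [0, 1]
  loud <- perturbCloud(pc, channelSd = 0.5, seed = 3)
  expect_true(all(channels(loud) >= 0 & channels(loud) <= 1))
  # dropout removes exactly floor(dropout * N) points
  half <- perturbCloud(pc, dropout = 0.5, seed = 4)
  expect_equal(nPoints(half), 50)
  expect_equal(nPoints(perturbCloud(pc, dropout = 0.999, seed = 5)), 1)
  expect_error(perturbCloud(pc, dropout = 1), "dropout")
  # known rigid motion is applied before the noise
  tf <- rigidTransform(translation = c(5, 0, 0))
  moved <- perturbCloud(pc, transform = tf, seed = 6)
  expect_equal(coords(moved), coords(applyTransform(pc, tf)))
})

test_that("expression simulation produces labeled NB counts with modules", {
  sce <- simulateExpression(list(list(name = "A", nCells = 100),
                                 list(name = "B", nCells = 100)),
                            nGenes = 40, seed = 2)
  expect_equal(dim(sce), c(40L, 200L))
  expect_equal(as.vector(table(SingleCellExperiment::colData(sce)$cluster)),
               c(100L, 100L))
  counts <- SummarizedExperiment::assay(sce)
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  # bit-reproducible
  sce2 <- simulateExpression(list(list(name = "A", nCells = 100),
                                  list(name = "B", nCells = 100)),
                             nGenes = 40, seed = 2)
  expect_identical(as.matrix(SummarizedExperiment::assay(sce2)), as.matrix(counts))

  # zero module correlation: mean off-diagonal |r| is small at n = 1000
  flat <- simulateExpression(list(list(name = "A", nCells = 1000,
                                       moduleCorrelation = 0)),
                             nGenes = 30, seed = 6)
  cm <- abs(cor(t(as.matrix(SummarizedExperiment::assay(flat)))))
  expect_lt(mean(cm[upper.tri(cm)]), 0.1)

  # doubling dispersion raises the median transcriptional noise
  twoD <- simulateExpression(list(
    list(name = "hi", nCells = 200, dispersion = 1.0),
    list(name = "lo", nCells = 200, dispersion = 0.5)), nGenes = 50,
    seed = 7)
  cts <- as.matrix(SummarizedExperiment::assay(twoD))
  cl <- SingleCellExperiment::colData(twoD)$cluster
  expect_gt(median(transcriptionalNoise(cts[, cl == "hi"])$distances),
            median(transcriptionalNoise(cts[, cl == "lo"])$distances))
  expect_error(simulateExpression(list(list(name = "A", nCells = 5,
                                            moduleCorrelation = 2))),
               "moduleCorrelation")
})

test_that("transition series carries the heterogeneity peak and rebels", {
  stages <- list(list(label = "18ss", nCells = 400, nmDispersion = 0.15),
                 list(label = "24ss", nCells = 400, nmDispersion = 0.35),
                 list(label = "28ss", nCells = 400, nmDispersion = 0.12))
  ser <- simulateTransitionSeries(stages, seed = 4)
  expect_named(ser, c("18ss", "24ss", "28ss"))
  # same spec and seed reproduce identical entropy estimates
  ser2 <- simulateTransitionSeries(stages, seed = 4)
  expect_identical(ser$`24ss`$table$NM, ser2$`24ss`$table$NM)
  # pooled-edge entropies rank the dispersed mid-stage highest (all five)
  pooled <- unlist(lapply(ser, function(s) s$table$NM))
  edges <- fdBinEdges(pooled)
  ests <- sapply(ser, function(s)
    entropyEstimates(s$table$NM, edges)$estimates)
  expect_true(all(apply(ests, 1, which.max) == 2))
  # rebellious fraction recovery at n = 1000
  ser3 <- simulateTransitionSeries(
    list(list(label = "a", nCells = 1000, nmDispersion = 0.15),
         list(label = "b", nCells = 1000, nmDispersion = 0.15)),
    rebelliousFraction = 0.2, seed = 5)
  tb <- ser3$a$table
  cls <- classifyCongruence(tb, tb$domain, tb$tcf, tcfThreshold = 0.5)
  meso <- cls[cls$domain == "mesoderm-fated", ]
  frac <- mean(meso$congruence == "Rebellious", na.rm = TRUE)
  expect_lt(abs(frac - 0.2), 0.05)
  # truth labels agree with the classifier on the injected cells
  agree <- cls$congruence[tb$truth == "Rebellious"] == "Rebellious"
  expect_gt(mean(agree, na.rm = TRUE), 0.95)
  expect_error(simulateTransitionSeries(stages[1]), "two stages")
})
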