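target5 <- pointCloud(cbind(c(0, 1, 2, 3, 10), 0, 0))

test_that("imputation follows the three-outcome policy", {
  # unique mapping copies the source value
  cm <- correspondenceMap(cbind(1, 1), 3, 5)
  imp <- imputeChannel(cm, c(0.42, 0.9, 0.1), target5,
                       unmappedPolicy = "null")
  expect_equal(imp$values[1], 0.42)
  expect_equal(imp$policy[1], "unique")
  expect_true(all(imp$values[2:5] == 0) && all(imp$policy[2:5] == "null"))

  # multi-mapping aggregates by median (default) or mean
  cm3 <- correspondenceMap(cbind(1:3, 1), 3, 5)
  med <- imputeChannel(cm3, c(0.2, 0.4, 0.9), target5, unmappedPolicy = "null")
  expect_equal(med$values[1], 0.4)
  expect_equal(med$policy[1], "multi")
  avg <- imputeChannel(cm3, c(0.2, 0.4, 0.9), target5,
                       multiPolicy = "mean", unmappedPolicy = "null")
  expect_equal(avg$values[1], 0.5)

  # 'complete' keeps the target's own channel on unmapped points
  comp <- imputeChannel(cm, c(0.42, 0, 0), target5,
                        unmappedPolicy = "complete",
                        existing = c(9, 8, 7, 6, 5))
  expect_equal(comp$values, c(0.42, 8, 7, 6, 5))
  expect_error(imputeChannel(cm, 1:3, target5, unmappedPolicy = "complete"),
               "existing")
  expect_error(imputeChannel(cm, 1:2, target5), "source cloud size")
  expect_error(imputeChannel(cm, 1:3, target5, k = 0), "k must be")
})

test_that("knn imputation averages the 5 nearest assigned targets", {
  # 6 targets: the first five assigned, the sixth takes their mean
  tgt <- pointCloud(rbind(cbind(c(0, 1, 2, 3, 4), 0, 0), c(2, 1, 0)))
  cm <- correspondenceMap(cbind(1:5, 1:5), 5, 6)
  imp <- imputeChannel(cm, c(0, 0.5, 1, 0.5, 0.5), tgt, k = 5)
  expect_equal(imp$values[6], 0.5)
  expect_equal(imp$policy[6], "knn")
  # ties in distance break toward the lower index
  tgt2 <- pointCloud(rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  cm2 <- correspondenceMap(cbind(1:2, 1:2), 2, 3)
  imp2 <- imputeChannel(cm2, c(0.2, 0.8), tgt2, k = 1)
  expect_equal(imp2$values[3], 0.2)
  # no assigned neighbour at all is an error
  empty <- correspondenceMap(matrix(0L, 0, 2), 2, 3)
  expect_error(imputeChannel(empty, c(1, 2), tgt2), "no target point")
})

test_that("imputed values stay within the contributing source range", {
  set.seed(4)
  for (rep in 1:10) {
    nS <- 30; nT <- 25
    tgt <- pointCloud(matrix(runif(3 * nT, 0, 50), nT, 3))
    pairs <- cbind(seq_len(nS), sample.int(nT, nS, replace = TRUE))
    vals <- runif(nS)
    cm <- correspondenceMap(pairs, nS, nT)
    imp <- imputeChannel(cm, vals, tgt)
    expect_true(all(imp$values >= min(vals) - 1e-12 &
                      imp$values <= max(vals) + 1e-12))
  }
})

test_that("a source copy of the target imputes its extra channel exactly", {
  tgt <- simulateTailbud(nPoints = 150, seed = 31)
  extra <- minMaxNormalize(coords(tgt)[, "y"],
                           min(coords(tgt)[, "y"]) - 1e-9,
                           max(coords(tgt)[, "y"]))
  src <- setChannel(tgt, "cdh6", extra)
  map <- buildComposite(tgt, list(src), commonChannel = "sox2", seed = 2)
  expect_equal(getChannel(compositeTarget(map), "cdh6"), extra,
               tolerance = 1e-9)
  expect_true(all(provenance(map)$cdh6$policy == "unique"))
  expect_equal(provenance(map)$cdh6$sampleId, sampleId(src))
})

test_that("five sources assemble the eight-channel composite map", {
  tgt <- simulateTailbud(nPoints = 150, seed = 41)
  groups <- list(STT = "tcf", STHC = c("hes6", "cdh6"),
                 STSC = c("sp5l", "cdh6"), STTC = c("tagln3b", "cdh6"),
                 STZC = c("znf703", "cdh6"))
  sources <- lapply(names(groups), function(g) {
    src <- initialize(tgt, sampleId = g)
    for (nm in groups[[g]])
      src <- setChannel(src, nm, minMaxNormalize(runif(nPoints(tgt))))
    src
  })
  map <- buildComposite(tgt, sources, commonChannel = "sox2", seed = 3)
  expect_setequal(channelNames(compositeTarget(map)),
                  c("sox2", "tbxta", "cdh6", "hes6", "sp5l", "tagln3b",
                    "tcf", "znf703"))
  expect_length(channelNames(compositeTarget(map)), 8)
  # cdh6 is credited to the first accepted source that carries it
  expect_equal(provenance(map)$cdh6$sampleId, "STHC")
  # zero sources: the map is the target unchanged
  empty <- buildComposite(tgt, list(), seed = 1)
  expect_equal(channels(compositeTarget(empty)), channels(tgt))
})

test_that("thresholdRescale zeroes below the quantile then rescales", {
  v <- seq(0, 0.9, by = 0.1)
  out <- thresholdRescale(v, q = 0.7)  # type-7 0.7-quantile = 0.63
  expect_equal(out[1:7], rep(0, 7))
  expect_equal(out[8:10], c(0.7, 0.8, 0.9) / 0.9)
  # q = 0 reduces to pure min-max rescale
  expect_equal(thresholdRescale(c(2, 5, 8), q = 0), c(0, 0.5, 1))
  # binary vectors are fixed points for q <= 0.5
  expect_equal(thresholdRescale(c(0, 1, 0, 1), q = 0.5), c(0, 1, 0, 1))
  # idempotent on its own output, min 0 / max 1
  out2 <- thresholdRescale(out, q = 0.7)
  expect_equal(thresholdRescale(out2, q = 0.7), out2)
  expect_equal(range(out), c(0, 1))
  expect_error(thresholdRescale(rep(0.3, 5)), "degenerate")
})

test_that("NMp calling needs double positivity inside the region", {
  tgt <- pointCloud(cbind(c(0, 1, 2, 3), 0, 0),
                    channels = list(sox2 = c(0.5, 0.5, 0, 0.5),
                                    tbxta = c(0.5, 0.5, 0.5, 0.5)))
  map <- new("CompositeMap", target = tgt, provenance = list(),
             rejected = character())
  region <- c(TRUE, FALSE, TRUE, TRUE)
  res <- identifyNMps(map, region)
  expect_equal(res$nmps, c(1L, 4L))       # double-positive and in region
  expect_equal(res$excluded, 2L)          # double-positive outside region
  # sox2 = 0 is never an NMp regardless of region
  expect_false(3L %in% res$nmps)
  # box regions work too
  res2 <- identifyNMps(map, list(list(min = c(-1, -1, -1),
                                      max = c(0.5, 1, 1))))
  expect_equal(res2$nmps, 1L)
  bare <- new("CompositeMap",
              target = pointCloud(cbind(1, 1, 1),
                                  channels = list(sox2 = 1)),
              provenance = list(), rejected = character())
  expect_error(identifyNMps(bare, TRUE), "tbxta")
})

test_that("probability maps count per-source hits with a display floor", {
  tgt <- pointCloud(matrix(runif(15), 5, 3))
  hits <- list(c(1, 2), c(1, 3), 1)
  pm <- probabilityMap(tgt, hits, minCount = 2)
  expect_equal(pm@counts, c(3L, 1L, 1L, 0L, 0L))
  expect_equal(displaySet(pm), 1L)
  expect_equal(sum(pm@counts), sum(lengths(hits)))
  # single source can never reach the default floor of 2
  expect_length(displaySet(probabilityMap(tgt, list(c(1, 2, 3)))), 0)
  # floor of 1 recovers the union
  expect_equal(displaySet(probabilityMap(tgt, hits, minCount = 1)),
               c(1L, 2L, 3L))
  expect_error(probabilityMap(tgt, list(99)), "out of target range")
})
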