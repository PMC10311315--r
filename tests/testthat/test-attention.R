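trainedToyRun <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gen <- generateClassificationDataset(
      syntheticSpec(n = 200, p = 60, kTrue = 6, M = 2, effectSize = 3,
                    withinBlockCorr = 0.4, seed = 71))
    ds <- gen$dataset
    sp <- stratifiedSplit(ds, seed = 1)
    std <- applyStandardizer(ds, fitStandardizer(ds, sp$train))
    m <- attOmicsModel(randomGrouping(60, 6, seed = 2), s = 8, h = 2,
                       nBlocks = 2, predictorWidths = 12,
                       classLevels = levels(classLabels(ds)), seed = 3)
    fit <- trainAttOmics(m, std[, sp$train], std[, sp$val],
                         trainConfig(learningRate = 1e-3, batchSize = 64,
                                     maxEpochs = 8, seed = 4))
    cache <<- list(model = fit$model, std = std, gen = gen)
    cache
  }
})

test_that("collected attention has the right shape and is deterministic", {
  tr <- trainedToyRun()
  rec <- collectAttention(tr$model, tr$std, batchSize = 64)
  expect_s3_class(rec, "attentionRecords")
  expect_equal(rec$nBlocks, 2L)
  expect_equal(rec$h, 2L)
  expect_equal(dim(rec$attention[[1]][[1]]), c(200L, 6L, 6L))

  # duplicated sample rows produce identical records
  X <- omicsMatrix(tr$std)[c(1, 1), ]
  r2 <- collectAttention(tr$model, X)
  expect_equal(r2$attention[[2]][[1]][1, , ], r2$attention[[2]][[1]][2, , ])

  # rows are probability distributions at every block/head
  for (b in 1:2) for (j in 1:2) {
    sums <- apply(rec$attention[[b]][[j]], c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-5))
  }
})

test_that("phenotype maps average the selected samples and stay row-stochastic", {
  tr <- trainedToyRun()
  rec <- collectAttention(tr$model, tr$std)
  labels <- classLabels(tr$std)
  mapA <- phenotypeAttentionMap(rec, phenotype = "class1")
  expect_s4_class(mapA, "AttentionMap")
  expect_equal(mapA@nSamples, sum(labels == "class1"))
  expect_equal(rowSums(mapA@map), rep(1, 6), tolerance = 1e-4,
               ignore_attr = TRUE)

  # single sample: the map is that sample's (head-averaged) matrix
  one <- which(labels == "class1")[1]
  sub <- collectAttention(tr$model,
                          omicsMatrix(tr$std)[one, , drop = FALSE])
  m1 <- phenotypeAttentionMap(sub, labels = "class1", phenotype = "class1")
  manual <- (sub$attention[[2]][[1]][1, , ] + sub$attention[[2]][[2]][1, , ]) / 2
  expect_equal(unname(m1@map), manual, tolerance = 1e-12)

  # two samples: elementwise mean
  two <- which(labels == "class1")[1:2]
  sub2 <- collectAttention(tr$model, omicsMatrix(tr$std)[two, , drop = FALSE])
  m2 <- phenotypeAttentionMap(sub2, labels = rep("class1", 2),
                              phenotype = "class1", headMode = 1)
  manual2 <- (sub2$attention[[2]][[1]][1, , ] + sub2$attention[[2]][[1]][2, , ]) / 2
  expect_equal(unname(m2@map), manual2, tolerance = 1e-12)

  # aggregation is linear over disjoint sample sets
  all1 <- which(labels == "class1")
  g1 <- all1[seq_len(floor(length(all1) / 2))]
  g2 <- setdiff(all1, g1)
  mAll <- phenotypeAttentionMap(rec, phenotype = "class1")@map
  mG1 <- phenotypeAttentionMap(rec, labels = replace(as.character(labels), g2, "x"),
                               phenotype = "class1")@map
  mG2 <- phenotypeAttentionMap(rec, labels = replace(as.character(labels), g1, "x"),
                               phenotype = "class1")@map
  wmean <- (length(g1) * mG1 + length(g2) * mG2) / length(all1)
  expect_equal(mAll, wmean, tolerance = 1e-12)

  expect_error(phenotypeAttentionMap(rec, phenotype = "nope"), "not present")
  expect_error(phenotypeAttentionMap(rec, phenotype = "class1", block = 9),
               "out of range")
})

test_that("phenotype maps differ between classes with class-specific signal", {
  tr <- trainedToyRun()
  rec <- collectAttention(tr$model, tr$std)
  m1 <- phenotypeAttentionMap(rec, phenotype = "class1")@map
  m2 <- phenotypeAttentionMap(rec, phenotype = "class2")@map
  expect_gt(norm(m1 - m2, "F"), 0)
})

test_that("top interactions rank cells with stable tie-breaking", {
  map <- methods::new("AttentionMap", phenotype = "x",
                      map = matrix(c(0.9, 0.4, 0.1, 0.6), 2, 2,
                                   dimnames = list(c("g1", "g2"), c("g1", "g2"))),
                      block = 1L, headMode = "mean", nSamples = 1L)
  top <- topInteractions(map, 1)
  expect_equal(top$group_i, "g2")
  expect_equal(top$group_j, "g1")
  expect_equal(top$weight, 0.4)

  # uniform map: all off-diagonal tied, order stable by index
  uni <- methods::new("AttentionMap", phenotype = "x",
                      map = matrix(1 / 3, 3, 3, dimnames = list(paste0("g", 1:3),
                                                                paste0("g", 1:3))),
                      block = 1L, headMode = "mean", nSamples = 1L)
  t6 <- topInteractions(uni, 6)
  expect_equal(t6$group_i, c("g1", "g1", "g2", "g2", "g3", "g3"))
  expect_warning(topInteractions(uni, 99), "truncating")
  # diagonal inclusion switch
  expect_equal(nrow(topInteractions(uni, 9, includeDiagonal = TRUE)), 9L)
})

test_that("attention maps export to TSV and round-trip", {
  tr <- trainedToyRun()
  rec <- collectAttention(tr$model, tr$std)
  map <- phenotypeAttentionMap(rec, phenotype = "class2")
  tf <- withr::local_tempfile(fileext = ".tsv")
  exportAttention(map, tf)
  back <- readAttentionMatrix(tf)
  expect_equal(back, map@map, tolerance = 1e-8)
  expect_equal(colnames(back), groupNames(tr$model@partition))
})
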