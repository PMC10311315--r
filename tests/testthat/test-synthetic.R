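test_that("generators are bit-reproducible under seed and balanced by class", {
  spec <- syntheticSpec(n = 101, p = 40, kTrue = 4, M = 3, effectSize = 2,
                        seed = 5)
  g1 <- generateClassificationDataset(spec)
  g2 <- generateClassificationDataset(spec)
  expect_identical(omicsMatrix(g1$dataset), omicsMatrix(g2$dataset))
  counts <- table(classLabels(g1$dataset))
  expect_lte(max(counts) - min(counts), 1)

  g3 <- generateClassificationDataset(syntheticSpec(n = 101, p = 40, kTrue = 4,
                                                    M = 3, seed = 6))
  expect_false(identical(omicsMatrix(g1$dataset), omicsMatrix(g3$dataset)))
})

test_that("planted within-block correlation matches the requested level", {
  spec <- syntheticSpec(n = 1500, p = 40, kTrue = 4, effectSize = 0,
                        withinBlockCorr = 0.5, seed = 8)
  gen <- generateClassificationDataset(spec)
  X <- omicsMatrix(gen$dataset)
  mb <- gen$truth$blockMembership
  cm <- cor(X)
  within <- cm[outer(mb, mb, "==") & upper.tri(cm)]
  between <- cm[outer(mb, mb, "!=") & upper.tri(cm)]
  expect_lt(abs(mean(within) - 0.5), 0.05)
  expect_lt(abs(mean(between)), 0.05)
})

test_that("class signal lives in the designated blocks", {
  spec <- syntheticSpec(n = 2000, p = 40, kTrue = 4, M = 2, effectSize = 1.5,
                        withinBlockCorr = 0.2, seed = 9)
  gen <- generateClassificationDataset(spec)
  X <- omicsMatrix(gen$dataset)
  y <- classLabels(gen$dataset)
  mb <- gen$truth$blockMembership
  shift <- colMeans(X[y == "class1", ]) - colMeans(X[y == "class2", ])
  b1 <- gen$truth$classBlocks[[1]]
  b2 <- gen$truth$classBlocks[[2]]
  expect_equal(mean(shift[mb %in% b1]), 1.5, tolerance = 0.15)
  expect_equal(mean(shift[mb %in% b2]), -1.5, tolerance = 0.15)
  neutral <- !(mb %in% c(b1, b2))
  expect_lt(max(abs(shift[neutral])), 0.3)
})

test_that("a linear oracle on block means separates strongly shifted classes", {
  spec <- syntheticSpec(n = 500, p = 100, kTrue = 5, M = 2, effectSize = 5,
                        withinBlockCorr = 0.5, seed = 10)
  gen <- generateClassificationDataset(spec)
  X <- omicsMatrix(gen$dataset)
  mb <- gen$truth$blockMembership
  bm <- vapply(1:5, function(b) rowMeans(X[, mb == b, drop = FALSE]),
               numeric(500))
  df <- data.frame(y = classLabels(gen$dataset), bm)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = binomial()))
  pred <- ifelse(stats::predict(fit, type = "response") > 0.5,
                 levels(df$y)[2], levels(df$y)[1])
  expect_lte(errorRate(pred, df$y), 0.02)
})

test_that("no-signal data leaves a held-out linear classifier at chance", {
  spec <- syntheticSpec(n = 1000, p = 30, kTrue = 3, M = 2, effectSize = 0,
                        seed = 12)
  gen <- generateClassificationDataset(spec)
  X <- omicsMatrix(gen$dataset)
  y <- classLabels(gen$dataset)
  mb <- gen$truth$blockMembership
  bm <- vapply(1:3, function(b) rowMeans(X[, mb == b, drop = FALSE]),
               numeric(1000))
  tr <- 1:500; te <- 501:1000
  fit <- suppressWarnings(stats::glm(y ~ ., family = binomial(),
                                     data = data.frame(y = y, bm)[tr, ]))
  pr <- stats::predict(fit, newdata = data.frame(bm)[te, ], type = "response")
  pred <- ifelse(pr > 0.5, levels(y)[2], levels(y)[1])
  expect_equal(errorRate(pred, y[te]), 0.5, tolerance = 0.1)  # (M-1)/M chance
})

test_that("survival generator plants a proportional-hazards signal with the
           requested censoring", {
  spec <- syntheticSpec(n = 1000, p = 50, kTrue = 5, withinBlockCorr = 0.5,
                        survival = list(beta = 5, baselineScale = 1,
                                        censorFraction = 0.3),
                        seed = 13)
  gen <- generateSurvivalDataset(spec)
  ds <- gen$dataset
  expect_equal(mean(survEvent(ds) == 0), 0.3, tolerance = 0.05)
  expect_true(all(survTime(ds) > 0))
  # oracle risk e^r ranks survival strongly
  expect_gte(concordanceIndex(exp(gen$truth$r), survTime(ds), survEvent(ds)), 0.9)

  # no signal: oracle concordance near 1/2
  g0 <- generateSurvivalDataset(syntheticSpec(n = 1000, p = 50, kTrue = 5,
    survival = list(beta = 0, baselineScale = 1, censorFraction = 0.2),
    seed = 14))
  r <- stats::rnorm(1000)
  expect_equal(concordanceIndex(exp(r), survTime(g0$dataset),
                                survEvent(g0$dataset)), 0.5, tolerance = 0.05)

  # censorFraction 0 observes every event
  gAll <- generateSurvivalDataset(syntheticSpec(n = 200, p = 20, kTrue = 2,
    survival = list(beta = 1, baselineScale = 1, censorFraction = 0),
    seed = 15))
  expect_true(all(survEvent(gAll$dataset) == 1))
})

test_that("spec validation guards parameter ranges", {
  expect_error(syntheticSpec(n = 10, p = 5, kTrue = 9), "kTrue")
  expect_error(syntheticSpec(n = 10, p = 5, kTrue = 2, effectSize = -1),
               "effectSize")
  expect_error(syntheticSpec(n = 10, p = 5, kTrue = 2, withinBlockCorr = 1),
               "withinBlockCorr")
  expect_warning(syntheticSpec(n = 10, p = 5, kTrue = 2,
                               survival = list(beta = 1, censorFraction = 0.95)),
                 "few events")
})
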