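test_that("early stopping needs strict improvement beyond the delta", {
  st <- earlyStoppingState(patience = 8, minDelta = 0.001, mode = "min")
  # monotone strong improvement never stops
  for (m in seq(1, 0.1, by = -0.1)) st <- earlyStoppingUpdate(st, m)
  expect_false(st$stop)

  # constant metric: first epoch is baseline, stop after 8 more
  st <- earlyStoppingState(patience = 8, minDelta = 0.001, mode = "min")
  stops <- c()
  for (e in 1:9) {
    st <- earlyStoppingUpdate(st, 0.5)
    stops <- c(stops, st$stop)
  }
  expect_equal(which(stops)[1], 9)

  # an improvement of exactly minDelta does not count (binary-exact values)
  st <- earlyStoppingState(patience = 1, minDelta = 0.125, mode = "min")
  st <- earlyStoppingUpdate(st, 0.5)
  st <- earlyStoppingUpdate(st, 0.375)
  expect_true(st$stop)
  # strictly more than minDelta resets the counter
  st <- earlyStoppingState(patience = 1, minDelta = 0.125, mode = "min")
  st <- earlyStoppingUpdate(st, 0.5)
  st <- earlyStoppingUpdate(st, 0.25)
  expect_false(st$stop)

  # higher-is-better orientation
  st <- earlyStoppingState(patience = 1, minDelta = 0.01, mode = "max")
  st <- earlyStoppingUpdate(st, 0.7)
  st <- earlyStoppingUpdate(st, 0.75)
  expect_false(st$stop)
})

test_that("whole-network gradients match finite differences", {
  set.seed(42)
  m <- tinyModel(p = 12, k = 3, s = 4, h = 2, nBlocks = 2)
  n <- 5
  X <- matrix(rnorm(n * 12), n, 12)
  y <- sample(1:2, n, replace = TRUE)
  lossOf <- function(model) {
    P <- attomics:::.softmaxRows(
      attomics:::.modelForward(model, X, training = TRUE)$logits)
    mean(-log(P[cbind(seq_len(n), y)]))
  }
  fw <- attomics:::.modelForward(m, X, training = TRUE, cache = TRUE)
  P <- attomics:::.softmaxRows(fw$logits)
  Y1 <- matrix(0, n, 2); Y1[cbind(seq_len(n), y)] <- 1
  grads <- attomics:::.modelBackward(m, fw$cache, (P - Y1) / n)

  eps <- 1e-6
  checks <- list(
    list(\(p) p$blocks[[1]]$gfcn[[2]][[1]]$W, \(p, v) { p$blocks[[1]]$gfcn[[2]][[1]]$W <- v; p }),
    list(\(p) p$blocks[[1]]$mhsa$Wq[[2]], \(p, v) { p$blocks[[1]]$mhsa$Wq[[2]] <- v; p }),
    list(\(p) p$blocks[[2]]$mhsa$Wo, \(p, v) { p$blocks[[2]]$mhsa$Wo <- v; p }),
    list(\(p) p$blocks[[2]]$norm$gain, \(p, v) { p$blocks[[2]]$norm$gain <- v; p }),
    list(\(p) p$pred$layers[[1]]$b, \(p, v) { p$pred$layers[[1]]$b <- v; p }),
    list(\(p) p$pred$out$W, \(p, v) { p$pred$out$W <- v; p })
  )
  for (chk in checks) {
    leaf <- chk[[1]](m@params); gleaf <- chk[[1]](grads)
    i <- sample(length(leaf), 1)
    mp <- m; vv <- leaf; vv[i] <- vv[i] + eps
    mp@params <- chk[[2]](m@params, vv)
    lp <- lossOf(mp)
    vv[i] <- leaf[i] - eps
    mp@params <- chk[[2]](m@params, vv)
    lm <- lossOf(mp)
    expect_equal(gleaf[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training is seeded, inert at zero learning rate, and improves a separable task", {
  gen <- generateClassificationDataset(
    syntheticSpec(n = 500, p = 200, kTrue = 10, M = 2, effectSize = 4,
                  withinBlockCorr = 0.3, seed = 51))
  ds <- gen$dataset
  sp <- stratifiedSplit(ds, seed = 1)
  std <- applyStandardizer(ds, fitStandardizer(ds, sp$train))
  part <- randomGrouping(200, 10, seed = 2)
  m <- attOmicsModel(part, s = 8, h = 2, predictorWidths = 16,
                     classLevels = levels(classLabels(ds)), seed = 3)

  # zero learning rate leaves every parameter untouched
  fit0 <- trainAttOmics(m, std[, sp$train], std[, sp$val],
                        trainConfig(learningRate = 0, batchSize = 128,
                                    maxEpochs = 2, seed = 4))
  expect_equal(fit0$model@params, m@params, tolerance = 1e-14)

  cfg <- trainConfig(learningRate = 1e-3, batchSize = 128, maxEpochs = 25,
                     seed = 4)
  fit <- trainAttOmics(m, std[, sp$train], std[, sp$val], cfg)
  expect_lte(min(fit$history$val_metric), 0.05)  # <= 5% validation error
  expect_true(all(c("epoch", "train_loss", "val_metric") %in% names(fit$history)))

  # same seed, same history
  fit2 <- trainAttOmics(m, std[, sp$train], std[, sp$val], cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model@params, fit2$model@params)
})

test_that("a survival head learns a planted proportional-hazards signal", {
  gen <- generateSurvivalDataset(
    syntheticSpec(n = 600, p = 100, kTrue = 5, withinBlockCorr = 0.5,
                  survival = list(beta = 4, baselineScale = 1,
                                  censorFraction = 0.2),
                  seed = 61))
  ds <- gen$dataset
  # the planted log-risk must itself rank survival strongly
  oracleC <- concordanceIndex(exp(gen$truth$r), survTime(ds), survEvent(ds))
  expect_gte(oracleC, 0.85)

  sp <- stratifiedSplit(ds, seed = 1)
  std <- applyStandardizer(ds, fitStandardizer(ds, sp$train))
  m <- attOmicsModel(randomGrouping(100, 5, seed = 2), s = 8, h = 1,
                     predictorWidths = 16, head = "survival", seed = 3)
  fit <- trainAttOmics(m, std[, sp$train], std[, sp$val],
                       trainConfig(learningRate = 1e-3, batchSize = 128,
                                   maxEpochs = 25, seed = 4))
  expect_gte(max(fit$history$val_metric), 0.75)  # validation C-index
})

test_that("training aborts with diagnostics when the loss turns non-finite", {
  ds <- tinyDataset(n = 30, p = 12)
  std <- applyStandardizer(ds, fitStandardizer(ds, 1:20))
  m <- tinyModel(p = 12, k = 3, s = 4, head = "survival")
  m@params$pred$out$W[1] <- Inf  # poisoned weight -> NaN/Inf log-risk
  dsS <- OmicsDataset(omicsMatrix(std), time = rexp(30) + 0.1,
                      event = rep(1, 30), featureIds = featureIds(std))
  expect_error(
    suppressMessages(trainAttOmics(m, dsS[, 1:20], dsS[, 21:30],
                                   trainConfig(batchSize = 20, maxEpochs = 2,
                                               seed = 1))),
    "non-finite|missing")
  expect_error(trainConfig(learningRate = -1), "learningRate")
})
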