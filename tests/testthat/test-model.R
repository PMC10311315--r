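test_that("fclForward applies affine map with ReLU clamp", {
  expect_equal(fclForward(c(1, 2), diag(2), c(0, 0)), c(1, 2))
  expect_equal(fclForward(c(-1, -2), diag(2), c(0, 0)), c(0, 0))
  expect_equal(fclForward(c(1, 1), matrix(c(1, 1), 1), -3), 0)
  expect_error(fclForward(c(1, 2, 3), diag(2), c(0, 0)), "shape")
})

test_that("group FCN depth schedules equalize the reduction ratio", {
  part <- .newPartitionForTest(c(1000, 10))
  sched <- planGroupFcn(part, s = 10, reductionRatio = 10)
  expect_equal(sched[[1]], c(1000L, 100L, 10L))  # depth 2
  expect_equal(sched[[2]], c(10L, 10L))          # depth 1, no reduction

  part2 <- .newPartitionForTest(c(64, 64))
  sched2 <- planGroupFcn(part2, s = 8, reductionRatio = 2)
  expect_equal(sched2[[1]], c(64L, 32L, 16L, 8L))  # depth 3 = log2(64/8)

  partEq <- .newPartitionForTest(c(6, 6, 6))
  expect_true(all(lengths(planGroupFcn(partEq, s = 6)) == 2L))  # all depth 1
})

test_that("gfcnForward embeds each group independently of the others", {
  m <- tinyModel(p = 12, k = 3, s = 4)
  X <- matrix(rnorm(5 * 12), 5, 12)
  E <- gfcnForward(X, m@partition, m@params$blocks[[1]]$gfcn)
  expect_equal(dim(E), c(5L, 3L, 4L))

  # perturbing a feature of group 1 leaves other groups' embeddings unchanged
  f1 <- featureGroups(m@partition)[[1]][1]
  X2 <- X; X2[, f1] <- X2[, f1] + 100
  E2 <- gfcnForward(X2, m@partition, m@params$blocks[[1]]$gfcn)
  expect_equal(E2[, 2:3, ], E[, 2:3, ])
  expect_false(isTRUE(all.equal(E2[, 1, ], E[, 1, ])))

  # zero weights give zero embeddings
  zeroPars <- lapply(m@params$blocks[[1]]$gfcn, function(g) {
    lapply(g, function(lyr) list(W = lyr$W * 0, b = lyr$b * 0))
  })
  expect_true(all(gfcnForward(X, m@partition, zeroPars) == 0))
  expect_error(gfcnForward(X * NA, m@partition, m@params$blocks[[1]]$gfcn), "missing")

  # against explicit matrix arithmetic on a hand-sized case
  part <- .newPartitionForTest(c(2, 2))
  W1 <- matrix(c(1, 0, 1, 1), 2, 2); b1 <- c(0.5, -0.5)
  W2 <- matrix(c(-1, 2, 0, 1), 2, 2); b2 <- c(0, 0)
  pars <- list(list(list(W = W1, b = b1)), list(list(W = W2, b = b2)))
  x <- c(1, -2, 3, 0.5)
  Eh <- gfcnForward(matrix(x, 1), part, pars)
  expect_equal(as.vector(Eh[1, 1, ]), pmax(as.vector(W1 %*% x[1:2]) + b1, 0))
  expect_equal(as.vector(Eh[1, 2, ]), pmax(as.vector(W2 %*% x[3:4]) + b2, 0))
})

test_that("MHSA matches a dense-algebra oracle and handles degenerate cases", {
  set.seed(8)
  for (cfg in list(list(k = 2, s = 2, h = 1), list(k = 5, s = 6, h = 3))) {
    k <- cfg$k; s <- cfg$s; h <- cfg$h; l <- s / h
    E <- matrix(rnorm(k * s), k, s)
    Wq <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
    Wk <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
    Wv <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
    Wo <- matrix(rnorm(s * s), s, s)
    got <- mhsaForward(E, Wq, Wk, Wv, Wo, scale = "s")
    want <- oracleMhsa(E, Wq, Wk, Wv, Wo, scaleval = s)
    expect_equal(got$U, want$U, tolerance = 1e-6)
    for (j in seq_len(h)) expect_equal(got$attention[[j]], want$A[[j]], tolerance = 1e-6)
  }

  # identical group embeddings give uniform attention rows
  s <- 4
  E <- matrix(rep(rnorm(s), each = 3), 3, s)
  Wq <- list(matrix(rnorm(s * s), s, s))
  got <- mhsaForward(E, Wq, Wq, Wq, diag(s), scale = "s")
  expect_equal(got$attention[[1]], matrix(1 / 3, 3, 3), tolerance = 1e-8)

  # sqrt_l scaling changes scores but rows stay stochastic
  E2 <- matrix(rnorm(3 * s), 3, s)
  g2 <- mhsaForward(E2, Wq, Wq, Wq, diag(s), scale = "sqrt_l")
  expect_equal(rowSums(g2$attention[[1]]), rep(1, 3), tolerance = 1e-5)
})

test_that("attention rows are probability distributions across random configs", {
  set.seed(123)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    h <- sample(c(1L, 2L), 1)
    s <- h * sample(1:4, 1)
    n <- sample(1:4, 1)
    l <- s / h
    E <- array(rnorm(n * k * s) * 10^sample(-1:2, 1), c(n, k, s))
    Wq <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
    Wk <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
    Wv <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
    got <- mhsaForward(E, Wq, Wk, Wv, matrix(rnorm(s * s), s, s))
    for (j in seq_len(h)) {
      A <- got$attention[[j]]
      expect_true(all(A >= 0))
      expect_true(all(abs(apply(A, c(1, 2), sum) - 1) < 1e-5))
    }
  }
})

test_that("MHSA is equivariant under permutation of the groups", {
  set.seed(4)
  k <- 5; s <- 6; h <- 2; l <- 3
  E <- matrix(rnorm(k * s), k, s)
  Wq <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
  Wk <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
  Wv <- replicate(h, matrix(rnorm(s * l), s, l), simplify = FALSE)
  Wo <- matrix(rnorm(s * s), s, s)
  base <- mhsaForward(E, Wq, Wk, Wv, Wo)
  perm <- c(3, 1, 5, 2, 4)
  permed <- mhsaForward(E[perm, ], Wq, Wk, Wv, Wo)
  expect_equal(permed$U, base$U[perm, ], tolerance = 1e-10)
  for (j in 1:h) {
    expect_equal(permed$attention[[j]], base$attention[[j]][perm, perm],
                 tolerance = 1e-10)
  }
})

test_that("encoder residual + layer norm behave as defined", {
  m <- tinyModel(p = 12, k = 3, s = 4, h = 1)
  X <- matrix(rnorm(4 * 12), 4, 12)
  # zero attention output projection => U = 0 => Z = LayerNorm(E)
  m0 <- m
  m0@params$blocks[[1]]$mhsa$Wo <- m0@params$blocks[[1]]$mhsa$Wo * 0
  blk <- attomics:::.encoderBlockForward(X, m0@params$blocks[[1]],
                                         m0@partition@groups, m0@config, 1L)
  # with U = 0 and the residual, Z must equal LayerNorm(E) exactly
  # (population variance; affine gain 1 / bias 0 at initialization)
  E <- gfcnForward(X, m0@partition, m0@params$blocks[[1]]$gfcn)
  manual <- apply(E, c(1, 2), function(v) {
    (v - mean(v)) / sqrt(mean(v^2) - mean(v)^2 + 1e-5)
  })                                   # dims: s x n x k
  expect_equal(blk$Z, aperm(manual, c(2, 3, 1)), tolerance = 1e-10)
  # normalized vectors are centered
  zmat <- matrix(blk$Z, 4 * 3, 4)
  expect_equal(rowMeans(zmat), rep(0, 12), tolerance = 1e-6)

  # toggling the residual changes the output when U != 0
  mR <- tinyModel(p = 12, k = 3, s = 4, h = 1)
  mN <- mR; mN@config$residual <- FALSE
  zR <- attomics:::.encoderBlockForward(X, mR@params$blocks[[1]],
                                        mR@partition@groups, mR@config, 1L)$Z
  zN <- attomics:::.encoderBlockForward(X, mN@params$blocks[[1]],
                                        mN@partition@groups, mN@config, 1L)$Z
  expect_false(isTRUE(all.equal(zR, zN)))
})

test_that("predictor softmax is stable and row-stochastic; survival head is linear", {
  m <- tinyModel(p = 12, k = 3, s = 4)
  Z <- matrix(rnorm(6 * 12), 6, 12)
  P <- predictorForward(m, Z)
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12)
  expect_equal(colnames(P), c("a", "b"))

  # softmax of extreme logits must not overflow
  sm <- attomics:::.softmaxRows(matrix(c(1000, 0), 1))
  expect_equal(as.vector(sm), c(1, 0), tolerance = 1e-12)

  ms <- tinyModel(p = 12, k = 3, s = 4, head = "survival")
  # zero all predictor weights: output equals the bias
  ms@params$pred$layers <- lapply(ms@params$pred$layers,
                                  function(l) list(W = l$W * 0, b = l$b * 0))
  ms@params$pred$out$W <- ms@params$pred$out$W * 0
  ms@params$pred$out$b <- 0.7
  out <- predictorForward(ms, Z)
  expect_equal(as.vector(out), rep(0.7, 6))
  expect_error(predictorForward(m, Z[, 1:5]), "k\\*s")
})

test_that("full forward is batch-consistent, deterministic, and checks shapes", {
  m <- tinyModel(p = 12, k = 3, s = 4, nBlocks = 2)
  X <- matrix(rnorm(5 * 12), 5, 12)
  full <- attOmicsForward(m, X)$output
  for (i in 1:5) {
    single <- attOmicsForward(m, X[i, , drop = FALSE])$output
    expect_equal(as.vector(single), unname(full[i, ]), tolerance = 1e-12)
  }
  expect_equal(rowSums(full), rep(1, 5), tolerance = 1e-12)
  expect_identical(attOmicsForward(m, X)$output, full)
  expect_error(attOmicsForward(m, X[, 1:10]), "feature count mismatch")

  # models built with the same seed are identical
  expect_identical(tinyModel(seed = 1)@params, tinyModel(seed = 1)@params)
})

test_that("embedding dimension must split evenly across heads", {
  part <- randomGrouping(12, 3, seed = 1)
  expect_error(attOmicsModel(part, s = 5, h = 2, classLevels = c("a", "b")),
               "divisible")
  m <- attOmicsModel(part, s = 6, h = 3, classLevels = c("a", "b"))
  expect_equal(m@config$l * m@config$h, m@config$s)
})

test_that("parameter counts match a symbolic oracle and beat the dense MLP", {
  part <- randomGrouping(1000, 10, seed = 1)
  m <- attOmicsModel(part, s = 20, h = 2, predictorWidths = 30,
                     classLevels = letters[1:4], seed = 1)
  expect_equal(countParameters(m),
               oracleParamCount(rep(100, 10), s = 20, h = 2,
                                predictorWidths = 30, nOut = 4))
  # grouped first projection needs far fewer parameters than a dense layer
  # to the same k*s dimension
  expect_lt(countParameters(m, "first_projection"), mlpParamCount(1000, 200))
  expect_equal(mlpParamCount(100, 50), 5050)
  expect_equal(mlpParamCount(10, 5), 55)
})

test_that("overlapping partitions copy shared features into each group", {
  part <- attomics:::.newPartition(list(c(1L, 2L), c(2L, 3L)), c("A", "B"),
                                   overlapping = TRUE, p = 3L)
  m <- attOmicsModel(part, s = 2, h = 1, classLevels = c("x", "y"), seed = 2)
  X <- matrix(c(1, 5, 2), 1, 3)
  E <- gfcnForward(X, part, m@params$blocks[[1]]$gfcn)
  # feature 2 feeds both groups: perturbing it changes both embeddings
  X2 <- X; X2[2] <- -4
  E2 <- gfcnForward(X2, part, m@params$blocks[[1]]$gfcn)
  expect_false(isTRUE(all.equal(E[, 1, ], E2[, 1, ])))
  expect_false(isTRUE(all.equal(E[, 2, ], E2[, 2, ])))
})
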