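#' Fully connected layer with ReLU
#'
#' The elementary layer of every FCN in the architecture:
#' \eqn{FCL(x) = ReLU(Wx + b) = \max(0, Wx + b)}.
#'
#' @param x numeric vector (length matching \code{ncol(W)}).
#' @param W weight matrix (out x in).
#' @param b bias vector (length \code{nrow(W)}).
#' @return numeric vector of length \code{nrow(W)}.
#' @examples
#' fclForward(c(-1, 2), diag(2), c(0, 0))
#' @export
fclForward <- function(x, W, b) {
  if (length(x) != ncol(W) || length(b) != nrow(W)) stop("shape mismatch in FCL")
  pmax(as.vector(W %*% x) + b, 0)
}

# Batched FCL stack: H (n x w0) through layers list(W (out x in), b).
# Returns output and per-layer caches (input, relu mask) for backprop.
.fcnForward <- function(H, layers, cache = FALSE) {
  caches <- if (cache) vector("list", length(layers)) else NULL
  for (d in seq_along(layers)) {
    Z <- tcrossprod(H, layers[[d]]$W)
    Z <- Z + rep(layers[[d]]$b, each = nrow(Z))
    out <- pmax(Z, 0)
    if (cache) caches[[d]] <- list(input = H, mask = Z > 0)
    H <- out
  }
  list(out = H, caches = caches)
}

#' Grouped FCN forward pass
#'
#' Embeds each feature group independently with its own FCN; a group's
#' embedding depends only on features inside that group. Overlapping
#' partitions copy shared features into every containing group.
#'
#' @param X numeric matrix, samples x features (p must match the partition).
#' @param partition a \linkS4class{GroupPartition}.
#' @param groupLayers list (one entry per group) of FCL parameter lists
#'   \code{list(W, b)}, e.g. \code{model@params$blocks[[1]]$gfcn}.
#' @return numeric array n x k x s of group embeddings.
#' @export
gfcnForward <- function(X, partition, groupLayers) {
  if (anyNA(X)) stop("input contains missing values")
  if (ncol(X) != partition@p) stop("feature count mismatch with partition")
  res <- .gfcnForwardRaw(X, partition@groups, groupLayers, cache = FALSE)
  res$E
}

.gfcnForwardRaw <- function(X, groups, groupLayers, cache = FALSE) {
  n <- nrow(X); k <- length(groups)
  s <- nrow(groupLayers[[1L]][[length(groupLayers[[1L]])]]$W)
  E <- array(0, c(n, k, s))
  caches <- if (cache) vector("list", k) else NULL
  for (i in seq_len(k)) {
    r <- .fcnForward(X[, groups[[i]], drop = FALSE], groupLayers[[i]], cache)
    E[, i, ] <- r$out
    if (cache) caches[[i]] <- r$caches
  }
  list(E = E, caches = caches)
}

# gFCN over embeddings (blocks >= 2): input n x k x s, one FCL per group.
.gfcnForwardEmb <- function(Z, groupLayers, cache = FALSE) {
  n <- dim(Z)[1L]; k <- dim(Z)[2L]; s <- dim(Z)[3L]
  E <- array(0, c(n, k, s))
  caches <- if (cache) vector("list", k) else NULL
  for (i in seq_len(k)) {
    r <- .fcnForward(matrix(Z[, i, ], n, s), groupLayers[[i]], cache)
    E[, i, ] <- r$out
    if (cache) caches[[i]] <- r$caches
  }
  list(E = E, caches = caches)
}

#' Multi-head self-attention over group embeddings
#'
#' For each head j, queries/keys/values are linear projections of the k group
#' embeddings to l = s/h dimensions; attention scores are scaled dot products
#' (divided by s, or by sqrt(l) when \code{scale = "sqrt_l"}), rows are
#' softmax-normalized, and head outputs are concatenated and projected by
#' \eqn{W^O}.
#'
#' @param E group embeddings: n x k x s array, or a k x s matrix for a single
#'   sample.
#' @param Wq,Wk,Wv lists (one per head) of s x l projection matrices.
#' @param Wo s x s output projection.
#' @param scale \code{"s"} or \code{"sqrt_l"}.
#' @return list with \code{U} (same shape as \code{E}) and \code{attention}, a
#'   list (one per head) of n x k x k arrays of row-stochastic attention
#'   weights (k x k matrices for single-sample input).
#' @export
mhsaForward <- function(E, Wq, Wk, Wv, Wo, scale = c("s", "sqrt_l")) {
  scale <- match.arg(scale)
  single <- is.matrix(E)
  if (single) E <- array(E, c(1L, nrow(E), ncol(E)))
  s <- dim(E)[3L]
  l <- ncol(Wq[[1L]])
  scaleval <- if (scale == "s") s else sqrt(l)
  r <- .mhsaForwardRaw(E, list(Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo),
                       scaleval, cache = FALSE)
  if (single) {
    r$U <- matrix(r$U[1L, , ], dim(r$U)[2L], dim(r$U)[3L])
    r$A <- lapply(r$A, function(a) matrix(a[1L, , ], dim(a)[2L], dim(a)[3L]))
  }
  list(U = r$U, attention = r$A)
}

.mhsaForwardRaw <- function(E, mhsa, scaleval, cache = FALSE) {
  n <- dim(E)[1L]; k <- dim(E)[2L]; s <- dim(E)[3L]
  h <- length(mhsa$Wq)
  l <- ncol(mhsa$Wq[[1L]])
  Emat <- matrix(E, n * k, s)
  Hcat <- array(0, c(n, k, s))
  A <- vector("list", h)
  hc <- if (cache) vector("list", h) else NULL
  for (j in seq_len(h)) {
    Q <- array(Emat %*% mhsa$Wq[[j]], c(n, k, l))
    K <- array(Emat %*% mhsa$Wk[[j]], c(n, k, l))
    V <- array(Emat %*% mhsa$Wv[[j]], c(n, k, l))
    S <- array(0, c(n, k, k))
    for (i in seq_len(k)) {
      Qi <- matrix(Q[, i, ], n, l)
      for (m in seq_len(k)) {
        S[, i, m] <- rowSums(Qi * matrix(K[, m, ], n, l))
      }
    }
    S <- S / scaleval
    Aj <- array(0, c(n, k, k))
    for (i in seq_len(k)) {
      Aj[, i, ] <- .softmaxRows(matrix(S[, i, ], n, k))
    }
    Uh <- array(0, c(n, k, l))
    for (i in seq_len(k)) {
      acc <- matrix(0, n, l)
      for (m in seq_len(k)) {
        acc <- acc + Aj[, i, m] * matrix(V[, m, ], n, l)
      }
      Uh[, i, ] <- acc
    }
    Hcat[, , (j - 1L) * l + seq_len(l)] <- Uh
    A[[j]] <- Aj
    if (cache) hc[[j]] <- list(Q = Q, K = K, V = V, A = Aj)
  }
  U <- array(matrix(Hcat, n * k, s) %*% mhsa$Wo, c(n, k, s))
  list(U = U, A = A,
       cache = if (cache) list(E = E, Emat = Emat, Hcat = Hcat, heads = hc,
                               scaleval = scaleval) else NULL)
}

# Layer normalization of each row of Xmat (rows x s) with population variance.
.layerNormForward <- function(Xmat, gain, bias, eps = 1e-5) {
  mu <- rowMeans(Xmat)
  v <- rowMeans(Xmat^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Xmat - mu) * invstd
  y <- xhat * rep(gain, each = nrow(Xmat)) + rep(bias, each = nrow(Xmat))
  list(y = y, xhat = xhat, invstd = invstd)
}

# Batch normalization over the batch, per column of Xmat (rows = samples).
.batchNormForward <- function(Xmat, gain, bias, runMean, runVar,
                              training, momentum = 0.1, eps = 1e-5) {
  g <- as.vector(gain); bta <- as.vector(bias)
  if (training) {
    mu <- colMeans(Xmat)
    v <- colMeans(Xmat^2) - mu^2
    newRun <- list(mean = (1 - momentum) * as.vector(runMean) + momentum * mu,
                   var = (1 - momentum) * as.vector(runVar) + momentum * v)
  } else {
    mu <- as.vector(runMean); v <- as.vector(runVar)
    newRun <- NULL
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(Xmat, 2L, mu, "-") * rep(invstd, each = nrow(Xmat))
  y <- xhat * rep(g, each = nrow(Xmat)) + rep(bta, each = nrow(Xmat))
  list(y = y, xhat = xhat, invstd = invstd, newRun = newRun)
}

# Normalization of an n x k x s tensor per the configured type.
.normForward <- function(R, normPar, type, training) {
  n <- dim(R)[1L]; k <- dim(R)[2L]; s <- dim(R)[3L]
  if (type == "layer") {
    r <- .layerNormForward(matrix(R, n * k, s), normPar$gain, normPar$bias)
    list(Z = array(r$y, c(n, k, s)), cache = r, newRun = NULL)
  } else {
    r <- .batchNormForward(matrix(R, n, k * s), normPar$gain, normPar$bias,
                           normPar$runMean, normPar$runVar, training)
    list(Z = array(r$y, c(n, k, s)), cache = r, newRun = r$newRun)
  }
}

# One encoder block. `input` is n x p (block 1) or n x k x s (later blocks).
.encoderBlockForward <- function(input, blockPar, groups, config, block,
                                 training = FALSE, cache = FALSE) {
  if (block == 1L) {
    g <- .gfcnForwardRaw(input, groups, blockPar$gfcn, cache)
  } else {
    g <- .gfcnForwardEmb(input, blockPar$gfcn, cache)
  }
  E <- g$E
  scaleval <- if (config$attentionScale == "s") config$s else sqrt(config$l)
  m <- .mhsaForwardRaw(E, blockPar$mhsa, scaleval, cache)
  R <- if (config$residual) E + m$U else m$U
  nr <- .normForward(R, blockPar$norm, config$norm, training)
  list(Z = nr$Z, A = m$A,
       cache = if (cache) list(gfcn = g$caches, E = E, mhsa = m$cache,
                               norm = nr$cache, R = R) else NULL,
       newRun = nr$newRun)
}

# Flatten n x k x s group-major: columns ordered (group 1's s dims, group 2's, ...).
.flattenZ <- function(Z) {
  n <- dim(Z)[1L]; k <- dim(Z)[2L]; s <- dim(Z)[3L]
  matrix(aperm(Z, c(1L, 3L, 2L)), n, k * s)
}

.unflattenZ <- function(Zflat, k, s) {
  n <- nrow(Zflat)
  aperm(array(Zflat, c(n, s, k)), c(1L, 3L, 2L))
}

# Prediction FCN: hidden FCLs each followed by the configured norm, then a
# linear output layer (never normalized).
.predictorForwardRaw <- function(Zflat, pred, config, training = FALSE,
                                 cache = FALSE) {
  H <- Zflat
  caches <- if (cache) vector("list", length(pred$layers)) else NULL
  newRuns <- vector("list", length(pred$layers))
  for (d in seq_along(pred$layers)) {
    f <- .fcnForward(H, pred$layers[d], cache)
    np <- pred$norms[[d]]
    if (config$norm == "layer") {
      nr <- .layerNormForward(f$out, np$gain, np$bias)
    } else {
      nr <- .batchNormForward(f$out, np$gain, np$bias, np$runMean, np$runVar,
                              training)
      newRuns[[d]] <- nr$newRun
    }
    if (cache) caches[[d]] <- list(fcl = f$caches[[1L]], norm = nr)
    H <- nr$y
  }
  out <- tcrossprod(H, pred$out$W) + rep(pred$out$b, each = nrow(H))
  list(out = out,
       cache = if (cache) list(layers = caches, lastH = H) else NULL,
       newRuns = newRuns)
}

#' Predictor head forward pass
#'
#' Maps the flattened encoder output \eqn{Z' \in R^{ks}} through the
#' prediction FCN. Classification returns a row-stochastic probability matrix
#' (stable softmax); survival returns the scalar log-risk \eqn{\hat{Y}} per
#' sample (the predicted risk is \eqn{\eta = e^{\hat{Y}}}).
#'
#' @param model an \linkS4class{AttOmicsModel}.
#' @param Zflat numeric matrix n x (k*s).
#' @return matrix of class probabilities (n x M) or a one-column matrix of
#'   log-risks.
#' @export
predictorForward <- function(model, Zflat) {
  cfg <- model@config
  if (ncol(Zflat) != nGroups(model@partition) * cfg$s) {
    stop("Zflat must have k*s columns")
  }
  r <- .predictorForwardRaw(Zflat, model@params$pred, cfg, training = FALSE)
  if (cfg$head == "classification") {
    P <- .softmaxRows(r$out)
    colnames(P) <- cfg$classLevels
    P
  } else {
    r$out
  }
}

#' Full model forward pass
#'
#' Runs grouping projection, the encoder stack (MHSA + residual +
#' normalization per block) and the predictor on a batch of samples, in
#' evaluation mode.
#'
#' @param model an \linkS4class{AttOmicsModel}.
#' @param X numeric matrix, samples x features, already standardized to the
#'   model's feature set.
#' @param collectAttention if TRUE, per-sample attention matrices for every
#'   block and head are returned.
#' @return list with \code{output} (probability matrix or log-risk column) and,
#'   when requested, \code{attention}: a list over blocks, each a list over
#'   heads of n x k x k arrays.
#' @examples
#' part <- randomGrouping(20, 4, seed = 1)
#' m <- attOmicsModel(part, s = 4, h = 2, classLevels = c("a", "b"), seed = 1)
#' out <- attOmicsForward(m, matrix(rnorm(100), 5, 20))
#' rowSums(out$output)
#' @export
attOmicsForward <- function(model, X, collectAttention = FALSE) {
  r <- .modelForward(model, X, training = FALSE, cache = FALSE,
                     collectAttention = collectAttention)
  out <- if (model@config$head == "classification") {
    P <- .softmaxRows(r$logits)
    colnames(P) <- model@config$classLevels
    P
  } else {
    r$logits
  }
  list(output = out, attention = r$attention)
}

.modelForward <- function(model, X, training = FALSE, cache = FALSE,
                          collectAttention = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("input contains missing values")
  cfg <- model@config
  groups <- model@partition@groups
  if (ncol(X) != model@partition@p) {
    stop("feature count mismatch: model expects ", model@partition@p,
         " features, got ", ncol(X))
  }
  k <- length(groups); s <- cfg$s
  input <- X
  blockCaches <- if (cache) vector("list", cfg$nBlocks) else NULL
  attention <- if (collectAttention || cache) vector("list", cfg$nBlocks) else NULL
  newRuns <- vector("list", cfg$nBlocks)
  for (b in seq_len(cfg$nBlocks)) {
    r <- .encoderBlockForward(input, model@params$blocks[[b]], groups, cfg,
                              block = b, training = training, cache = cache)
    if (!is.null(attention)) attention[[b]] <- r$A
    if (cache) blockCaches[[b]] <- c(r$cache, list(input = input))
    newRuns[[b]] <- r$newRun
    input <- r$Z
  }
  Zflat <- .flattenZ(input)
  pr <- .predictorForwardRaw(Zflat, model@params$pred, cfg,
                             training = training, cache = cache)
  list(logits = pr$out, attention = attention,
       cache = if (cache) list(blocks = blockCaches, Zflat = Zflat,
                               pred = pr$cache) else NULL,
       newRuns = list(blocks = newRuns, pred = pr$newRuns))
}
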