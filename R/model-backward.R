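# Reverse-mode gradients for every component of the network. Each backward
# function mirrors its forward counterpart in model-forward.R and consumes the
# cache that forward produced. Gradient trees are congruent with the
# parameter trees so the optimizer can walk them in parallel.

.fcnBackward <- function(dOut, layers, caches) {
  grads <- vector("list", length(layers))
  for (d in rev(seq_along(layers))) {
    dZ <- dOut * caches[[d]]$mask
    gW <- crossprod(dZ, caches[[d]]$input)
    dimnames(gW) <- NULL
    grads[[d]] <- list(W = gW, b = unname(colSums(dZ)))
    dOut <- dZ %*% layers[[d]]$W
  }
  list(grads = grads, dIn = dOut)
}

.layerNormBackward <- function(dY, cache, gain) {
  n <- nrow(dY)
  dgain <- colSums(dY * cache$xhat)
  dbias <- colSums(dY)
  dxhat <- dY * rep(gain, each = n)
  dX <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$invstd
  list(dX = dX, dgain = dgain, dbias = dbias)
}

.batchNormBackward <- function(dY, cache, gain) {
  n <- nrow(dY)
  g <- as.vector(gain)
  dgain <- colSums(dY * cache$xhat)
  dbias <- colSums(dY)
  dxhat <- dY * rep(g, each = n)
  dX <- (sweep(dxhat, 2L, colMeans(dxhat), "-") -
           cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
    rep(cache$invstd, each = n)
  list(dX = dX, dgain = dgain, dbias = dbias)
}

.normBackward <- function(dZ, normPar, type, cache) {
  d <- dim(dZ)
  n <- d[1L]; k <- d[2L]; s <- d[3L]
  if (type == "layer") {
    r <- .layerNormBackward(matrix(dZ, n * k, s), cache, normPar$gain)
    gshape <- function(x) x
  } else {
    r <- .batchNormBackward(matrix(dZ, n, k * s), cache, normPar$gain)
    gshape <- function(x) array(x, dim(normPar$gain))
  }
  list(dR = array(r$dX, c(n, k, s)),
       grads = list(gain = gshape(r$dgain), bias = gshape(r$dbias)))
}

.mhsaBackward <- function(dU, mhsa, cache) {
  E <- cache$E
  n <- dim(E)[1L]; k <- dim(E)[2L]; s <- dim(E)[3L]
  h <- length(mhsa$Wq); l <- ncol(mhsa$Wq[[1L]])
  scaleval <- cache$scaleval
  dUmat <- matrix(dU, n * k, s)
  gWo <- crossprod(matrix(cache$Hcat, n * k, s), dUmat)
  dHcat <- array(dUmat %*% t(mhsa$Wo), c(n, k, s))
  dEmat <- matrix(0, n * k, s)
  gWq <- gWk <- gWv <- vector("list", h)
  for (j in seq_len(h)) {
    hd <- cache$heads[[j]]
    dUh <- dHcat[, , (j - 1L) * l + seq_len(l), drop = FALSE]
    dA <- array(0, c(n, k, k))
    dV <- array(0, c(n, k, l))
    for (i in seq_len(k)) {
      dUhi <- matrix(dUh[, i, ], n, l)
      for (m in seq_len(k)) {
        dA[, i, m] <- rowSums(dUhi * matrix(hd$V[, m, ], n, l))
      }
    }
    for (m in seq_len(k)) {
      acc <- matrix(0, n, l)
      for (i in seq_len(k)) {
        acc <- acc + hd$A[, i, m] * matrix(dUh[, i, ], n, l)
      }
      dV[, m, ] <- acc
    }
    dS <- array(0, c(n, k, k))
    for (i in seq_len(k)) {
      Ai <- matrix(hd$A[, i, ], n, k)
      dAi <- matrix(dA[, i, ], n, k)
      dS[, i, ] <- Ai * (dAi - rowSums(dAi * Ai))
    }
    dS <- dS / scaleval
    dQ <- array(0, c(n, k, l))
    dK <- array(0, c(n, k, l))
    for (i in seq_len(k)) {
      acc <- matrix(0, n, l)
      for (m in seq_len(k)) {
        acc <- acc + dS[, i, m] * matrix(hd$K[, m, ], n, l)
      }
      dQ[, i, ] <- acc
    }
    for (m in seq_len(k)) {
      acc <- matrix(0, n, l)
      for (i in seq_len(k)) {
        acc <- acc + dS[, i, m] * matrix(hd$Q[, i, ], n, l)
      }
      dK[, m, ] <- acc
    }
    dQmat <- matrix(dQ, n * k, l)
    dKmat <- matrix(dK, n * k, l)
    dVmat <- matrix(dV, n * k, l)
    gWq[[j]] <- crossprod(cache$Emat, dQmat)
    gWk[[j]] <- crossprod(cache$Emat, dKmat)
    gWv[[j]] <- crossprod(cache$Emat, dVmat)
    dEmat <- dEmat + dQmat %*% t(mhsa$Wq[[j]]) +
      dKmat %*% t(mhsa$Wk[[j]]) + dVmat %*% t(mhsa$Wv[[j]])
  }
  list(dE = array(dEmat, c(n, k, s)),
       grads = list(Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo))
}

.encoderBlockBackward <- function(dZ, blockPar, config, block, cache) {
  n <- dim(dZ)[1L]; k <- dim(dZ)[2L]; s <- dim(dZ)[3L]
  nb <- .normBackward(dZ, blockPar$norm, config$norm, cache$norm)
  dR <- nb$dR
  mh <- .mhsaBackward(dR, blockPar$mhsa, cache$mhsa)
  dE <- mh$dE
  if (config$residual) dE <- dE + dR
  gGfcn <- vector("list", k)
  dInput <- if (block > 1L) array(0, c(n, k, s)) else NULL
  for (i in seq_len(k)) {
    fb <- .fcnBackward(matrix(dE[, i, ], n, s), blockPar$gfcn[[i]],
                       cache$gfcn[[i]])
    gGfcn[[i]] <- fb$grads
    if (block > 1L) dInput[, i, ] <- fb$dIn
  }
  list(grads = list(gfcn = gGfcn, mhsa = mh$grads, norm = nb$grads),
       dInput = dInput)
}

.predictorBackward <- function(dOut, pred, config, cache) {
  gOut <- list(W = crossprod(dOut, cache$lastH), b = colSums(dOut))
  dH <- dOut %*% pred$out$W
  nLayers <- length(pred$layers)
  gLayers <- vector("list", nLayers)
  gNorms <- vector("list", nLayers)
  for (d in rev(seq_len(nLayers))) {
    lc <- cache$layers[[d]]
    if (config$norm == "layer") {
      nb <- .layerNormBackward(dH, lc$norm, pred$norms[[d]]$gain)
      gNorms[[d]] <- list(gain = nb$dgain, bias = nb$dbias)
    } else {
      nb <- .batchNormBackward(dH, lc$norm, pred$norms[[d]]$gain)
      gNorms[[d]] <- list(gain = array(nb$dgain, dim(pred$norms[[d]]$gain)),
                          bias = array(nb$dbias, dim(pred$norms[[d]]$gain)))
    }
    fb <- .fcnBackward(nb$dX, pred$layers[d], list(lc$fcl))
    gLayers[[d]] <- fb$grads[[1L]]
    dH <- fb$dIn
  }
  list(grads = list(layers = gLayers, norms = gNorms, out = gOut), dZflat = dH)
}

# Full-network backward from d(loss)/d(logits). Returns a gradient tree
# congruent with model@params.
.modelBackward <- function(model, cache, dLogits) {
  cfg <- model@config
  k <- nGroups(model@partition); s <- cfg$s
  pb <- .predictorBackward(dLogits, model@params$pred, cfg, cache$pred)
  dZ <- .unflattenZ(pb$dZflat, k, s)
  gBlocks <- vector("list", cfg$nBlocks)
  for (b in rev(seq_len(cfg$nBlocks))) {
    eb <- .encoderBlockBackward(dZ, model@params$blocks[[b]], cfg, b,
                                cache$blocks[[b]])
    gBlocks[[b]] <- eb$grads
    if (b > 1L) dZ <- eb$dInput
  }
  list(blocks = gBlocks, pred = pb$grads)
}

# Adam over congruent parameter/gradient trees. Running-statistic leaves
# (runMean/runVar) are carried through untouched.
.adamUpdate <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      out <- vector("list", length(p)); names(out) <- nm
      mo <- vector("list", length(p)); names(mo) <- nm
      vo <- vector("list", length(p)); names(vo) <- nm
      for (i in seq_along(p)) {
        key <- if (is.null(nm)) "" else nm[i]
        if (key %in% c("runMean", "runVar")) {
          out[[i]] <- p[[i]]; mo[[i]] <- 0; vo[[i]] <- 0
          next
        }
        r <- walk(p[[i]], g[[i]],
                  if (is.null(m)) NULL else m[[i]],
                  if (is.null(v)) NULL else v[[i]])
        out[[i]] <- r$p; mo[[i]] <- r$m; vo[[i]] <- r$v
      }
      list(p = out, m = mo, v = vo)
    } else {
      if (is.null(m)) { m <- p * 0; v <- p * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  walk(params, grads, state$m, state$v)
}

# Apply the running-statistic updates produced by a training-mode forward.
.applyRunningStats <- function(params, newRuns) {
  for (b in seq_along(newRuns$blocks)) {
    nr <- newRuns$blocks[[b]]
    if (!is.null(nr)) {
      dm <- dim(params$blocks[[b]]$norm$runMean)
      params$blocks[[b]]$norm$runMean <- array(nr$mean, dm)
      params$blocks[[b]]$norm$runVar <- array(nr$var, dm)
    }
  }
  for (d in seq_along(newRuns$pred)) {
    nr <- newRuns$pred[[d]]
    if (!is.null(nr)) {
      dm <- dim(params$pred$norms[[d]]$runMean)
      params$pred$norms[[d]]$runMean <- array(nr$mean, dm)
      params$pred$norms[[d]]$runVar <- array(nr$var, dm)
    }
  }
  params
}
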