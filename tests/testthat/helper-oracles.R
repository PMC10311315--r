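# Independent oracles used to cross-check the implementation. These are
# deliberately naive (explicit loops, dense algebra) and share no code with
# the package internals.

# Concordance index by explicit pair enumeration of the pairwise formula.
oracleCindex <- function(risks, times, events) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (times[j] < times[i] && events[j] == 1) {
        den <- den + 1
        if (risks[j] > risks[i]) num <- num + 1
      }
    }
  }
  num / den
}

# Weighted cross-entropy by per-sample loop.
oracleWce <- function(P, y, w) {
  tot <- 0
  for (i in seq_len(nrow(P))) tot <- tot + (-w[y[i]] * log(P[i, y[i]]))
  tot / nrow(P)
}

# Cox negative mean log partial likelihood with explicit risk-set enumeration.
oracleCox <- function(scores, times, events) {
  terms <- c()
  for (i in seq_along(scores)) {
    if (events[i] == 1) {
      rs <- which(times >= times[i])
      terms <- c(terms, scores[i] - log(sum(exp(scores[rs]))))
    }
  }
  -mean(terms)
}

# Single-sample multi-head self-attention by dense algebra, straight from the
# defining equations (E: k x s; W's as in mhsaForward).
oracleMhsa <- function(E, Wq, Wk, Wv, Wo, scaleval) {
  k <- nrow(E); s <- ncol(E); h <- length(Wq); l <- ncol(Wq[[1]])
  Hcat <- matrix(0, k, 0)
  A <- list()
  for (j in seq_len(h)) {
    Q <- E %*% Wq[[j]]; K <- E %*% Wk[[j]]; V <- E %*% Wv[[j]]
    S <- (Q %*% t(K)) / scaleval
    Aj <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    Hcat <- cbind(Hcat, Aj %*% V)
    A[[j]] <- Aj
  }
  list(U = Hcat %*% Wo, A = A)
}

# Closed-form parameter count for equal-group configurations (1 encoder
# block, layer norm): per-group FCN chain + h heads of Q/K/V + W^O + norm
# affine + predictor.
oracleParamCount <- function(groupSizes, s, h, predictorWidths, nOut,
                             reductionRatio = 2) {
  chainCount <- function(widths) {
    tot <- 0
    for (d in seq_len(length(widths) - 1)) {
      tot <- tot + widths[d] * widths[d + 1] + widths[d + 1]
    }
    tot
  }
  gfcn <- 0
  for (pi in groupSizes) {
    d <- max(1, ceiling(log(pi / s, base = reductionRatio) - 1e-9))
    widths <- round(pi * (s / pi)^(seq_len(d) / d))
    widths[d] <- s
    gfcn <- gfcn + chainCount(c(pi, pmax(widths, 1)))
  }
  l <- s / h
  mhsa <- 3 * h * s * l + s * s
  norm <- 2 * s
  k <- length(groupSizes)
  pred <- chainCount(c(k * s, predictorWidths)) +
    sum(2 * predictorWidths) +
    (if (length(predictorWidths)) predictorWidths[length(predictorWidths)] else k * s) * nOut + nOut
  gfcn + mhsa + norm + pred
}
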