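#' Inverse-frequency class weights
#'
#' Weights for the weighted cross-entropy loss, inversely proportional to
#' class size and normalized so that balanced data yields unit weights:
#' \eqn{w_c = n / (M n_c)}.
#'
#' @param labels factor (or coercible) of class labels; every class must be
#'   represented.
#' @return named numeric vector of per-class weights.
#' @examples
#' classWeights(factor(c(rep("a", 90), rep("b", 10))))
#' @export
classWeights <- function(labels) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("at least 2 classes are required")
  counts <- table(labels)
  if (any(counts == 0L)) {
    stop("empty class(es): ", paste(names(counts)[counts == 0L], collapse = ", "))
  }
  n <- length(labels); M <- nlevels(labels)
  stats::setNames(as.numeric(n / (M * counts)), names(counts))
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of \eqn{-w_{c(y)} \log p_{c(y)}}, the multi-class
#' cross-entropy with per-class weights compensating class imbalance.
#' Probabilities are clamped at \code{eps} (with a message) so a confident
#' wrong prediction yields a large finite loss rather than NaN.
#'
#' @param P numeric matrix (n x M) of predicted class probabilities.
#' @param Y true classes: integer indices, a factor, or an n x M one-hot
#'   matrix.
#' @param weights per-class weights (length M), e.g. from
#'   \code{\link{classWeights}}; defaults to 1.
#' @param eps clamping floor for probabilities.
#' @return scalar loss.
#' @examples
#' weightedCrossEntropy(matrix(c(0.5, 0.5), 1), 1)  # log(2)
#' @export
weightedCrossEntropy <- function(P, Y, weights = NULL, eps = 1e-12) {
  P <- as.matrix(P)
  M <- ncol(P)
  if (is.matrix(Y)) Y <- max.col(Y, ties.method = "first")
  if (is.factor(Y)) Y <- as.integer(Y)
  if (length(Y) != nrow(P)) stop("P and Y disagree on batch size")
  if (is.null(weights)) weights <- rep(1, M)
  ptrue <- P[cbind(seq_len(nrow(P)), Y)]
  if (any(ptrue < eps)) {
    message("weightedCrossEntropy: ", sum(ptrue < eps),
            " probability value(s) clamped at eps")
    ptrue <- pmax(ptrue, eps)
  }
  mean(-weights[Y] * log(ptrue))
}

#' Cox partial-likelihood loss
#'
#' The negated mean log partial likelihood over the batch's risk sets,
#' \deqn{-\frac{1}{N_{\delta=1}} \sum_{i:\delta_i=1}\Big(\hat{Y}_i -
#'   \log \sum_{j \in R(T_i)} e^{\hat{Y}_j}\Big),}
#' computed with log-sum-exp stabilization. The default risk set
#' \eqn{R(T_i) = \{j: T_j \ge T_i\}} (Breslow/DeepSurv convention) includes
#' the failing patient; \code{riskSet = "printed"} uses the strict inequality
#' \eqn{T_j > T_i}, under which an event with an empty risk set contributes an
#' infinite term.
#'
#' @param scores numeric vector of predicted log-risks \eqn{\hat{Y}}.
#' @param times follow-up times.
#' @param events 0/1 event flags; at least one event is required.
#' @param riskSet \code{"breslow"} (default) or \code{"printed"}.
#' @return scalar loss (shift-invariant in \code{scores}).
#' @examples
#' coxPartialLikelihoodLoss(c(0, 0), times = c(1, 2), events = c(1, 1))
#' @export
coxPartialLikelihoodLoss <- function(scores, times, events,
                                     riskSet = c("breslow", "printed")) {
  riskSet <- match.arg(riskSet)
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n)
  ev <- which(events == 1)
  if (length(ev) == 0L) {
    stop("Cox partial likelihood requires at least one observed event")
  }
  m <- max(scores)
  es <- exp(scores - m)
  terms <- vapply(ev, function(i) {
    inset <- if (riskSet == "breslow") times >= times[i] else times > times[i]
    scores[i] - (m + log(sum(es[inset])))
  }, numeric(1))
  -mean(terms)
}

# Loss + gradient wrt scores (Breslow risk set), used by the training loop.
.coxLossGrad <- function(scores, times, events) {
  n <- length(scores)
  ev <- which(events == 1)
  Nev <- length(ev)
  m <- max(scores)
  es <- exp(scores - m)
  atRisk <- outer(times[ev], times, "<=")        # row i: R(T_i) membership
  riskSum <- as.vector(atRisk %*% es)
  loss <- -mean(scores[ev] - (m + log(riskSum)))
  coef <- as.vector(crossprod(atRisk, 1 / riskSum))  # per j: sum over events i
  grad <- (-(events == 1) + es * coef) / Nev
  list(loss = loss, grad = grad)
}
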