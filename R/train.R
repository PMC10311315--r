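#' Training configuration
#'
#' Defaults follow the architecture's published protocol: Adam with learning
#' rate 1e-4, batch size 512, at most 100 epochs, early stopping with
#' patience 8 and min improvement delta 0.001 on the validation metric.
#'
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch cap.
#' @param patience epochs without improvement before stopping.
#' @param minDelta improvement must exceed this (strictly) to reset patience.
#' @param monitor \code{"val_error"}, \code{"val_cindex"} or \code{"val_loss"};
#'   default is val_error for classification heads and val_cindex for
#'   survival heads.
#' @param seed integer seed controlling shuffling (weight init is seeded by
#'   the model's own seed).
#' @return a named list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 512L,
                        maxEpochs = 100L, patience = 8L, minDelta = 0.001,
                        monitor = NULL, seed = 1L) {
  stopifnot(learningRate >= 0, batchSize >= 1, maxEpochs >= 1,
            patience >= 1, minDelta >= 0)
  if (!is.null(monitor)) {
    monitor <- match.arg(monitor, c("val_error", "val_cindex", "val_loss"))
  }
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
                 minDelta = minDelta, monitor = monitor, seed = as.integer(seed)),
            class = "trainConfig")
}

#' Early-stopping state machine
#'
#' \code{earlyStoppingState} initializes the monitor; each epoch,
#' \code{earlyStoppingUpdate} records the metric and decides whether to
#' continue. An epoch counts as an improvement only when the metric beats the
#' best seen by strictly more than \code{minDelta}; after \code{patience}
#' consecutive non-improving epochs, \code{$stop} becomes TRUE.
#'
#' @param patience allowed consecutive non-improving epochs.
#' @param minDelta strict improvement threshold.
#' @param mode \code{"min"} (lower metric is better) or \code{"max"}.
#' @return \code{earlyStoppingState}: a state list; \code{earlyStoppingUpdate}:
#'   the updated state with fields \code{best}, \code{improved}, \code{wait},
#'   \code{stop}.
#' @examples
#' st <- earlyStoppingState(patience = 2, minDelta = 0.01, mode = "min")
#' st <- earlyStoppingUpdate(st, 0.5)  # first value: baseline
#' st <- earlyStoppingUpdate(st, 0.5); st <- earlyStoppingUpdate(st, 0.5)
#' st$stop
#' @export
earlyStoppingState <- function(patience = 8L, minDelta = 0.001,
                               mode = c("min", "max")) {
  mode <- match.arg(mode)
  list(best = NULL, wait = 0L, patience = as.integer(patience),
       minDelta = minDelta, mode = mode, stop = FALSE, improved = FALSE)
}

#' @rdname earlyStoppingState
#' @param state state from \code{earlyStoppingState} or a previous update.
#' @param metric this epoch's validation metric.
#' @export
earlyStoppingUpdate <- function(state, metric) {
  if (is.null(state$best)) {
    state$best <- metric
    state$improved <- TRUE
    state$wait <- 0L
    return(state)
  }
  delta <- if (state$mode == "min") state$best - metric else metric - state$best
  state$improved <- delta > state$minDelta
  if (state$improved) {
    state$best <- metric
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

.batchIndices <- function(n, batchSize) {
  split(seq_len(n), ceiling(seq_len(n) / batchSize))
}

#' Train an AttOmics model
#'
#' End-to-end minibatch training with Adam. Classification heads minimize the
#' weighted cross-entropy (weights from the training labels); survival heads
#' minimize the Cox partial-likelihood loss over each batch's risk sets
#' (batches without any event are skipped). The validation metric is tracked
#' every epoch, early stopping is applied, and the best-validation weights
#' are restored before returning. Fully deterministic under the config seed.
#'
#' @param model an \linkS4class{AttOmicsModel}.
#' @param trainData,valData standardized \linkS4class{OmicsDataset}s with the
#'   annotations the head requires (labels, or time + event).
#' @param config a \code{\link{trainConfig}}.
#' @return list with \code{model} (best weights, class levels preserved) and
#'   \code{history}, a data.frame with epoch, train_loss, val_metric.
#' @export
trainAttOmics <- function(model, trainData, valData, config = trainConfig()) {
  stopifnot(methods::is(model, "AttOmicsModel"), inherits(config, "trainConfig"))
  cfg <- model@config
  Xtr <- omicsMatrix(trainData)
  Xval <- omicsMatrix(valData)
  if (cfg$head == "classification") {
    ytr <- factor(as.character(classLabels(trainData)), levels = cfg$classLevels)
    yval <- factor(as.character(classLabels(valData)), levels = cfg$classLevels)
    if (anyNA(ytr) || anyNA(yval)) stop("labels outside the model's class levels")
    w <- classWeights(ytr)[cfg$classLevels]
    monitor <- if (is.null(config$monitor)) "val_error" else config$monitor
  } else {
    ttr <- survTime(trainData); evtr <- survEvent(trainData)
    tval <- survTime(valData); evval <- survEvent(valData)
    if (is.null(ttr) || is.null(tval)) stop("survival head requires time/event annotations")
    if (sum(evtr == 1) < 1) stop("training data has no observed events")
    monitor <- if (is.null(config$monitor)) "val_cindex" else config$monitor
  }
  mode <- if (monitor == "val_cindex") "max" else "min"

  valMetric <- function(params) {
    mtmp <- model; mtmp@params <- params
    out <- .modelForward(mtmp, Xval, training = FALSE)$logits
    if (monitor == "val_error") {
      pred <- cfg$classLevels[max.col(out, ties.method = "first")]
      errorRate(pred, yval)
    } else if (monitor == "val_cindex") {
      concordanceIndex(exp(out[, 1L] - max(out[, 1L])), tval, evval)
    } else {
      if (cfg$head == "classification") {
        weightedCrossEntropy(.softmaxRows(out), yval, w)
      } else {
        coxPartialLikelihoodLoss(out[, 1L], tval, evval)
      }
    }
  }

  params <- model@params
  adamState <- list(m = NULL, v = NULL)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_metric = numeric())
  es <- earlyStoppingState(config$patience, config$minDelta, mode)
  bestParams <- params
  step <- 0L
  n <- nrow(Xtr)

  .withSeed(.deriveSeed(config$seed, "train"), {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(n)
      epochLoss <- 0; epochN <- 0L
      for (batch in .batchIndices(n, config$batchSize)) {
        idx <- ord[batch]
        mtmp <- model; mtmp@params <- params
        fw <- .modelForward(mtmp, Xtr[idx, , drop = FALSE],
                            training = TRUE, cache = TRUE)
        if (cfg$head == "classification") {
          P <- .softmaxRows(fw$logits)
          yi <- as.integer(ytr[idx])
          ptrue <- pmax(P[cbind(seq_along(idx), yi)], 1e-12)
          loss <- mean(-w[yi] * log(ptrue))
          Y1 <- matrix(0, length(idx), cfg$nClasses)
          Y1[cbind(seq_along(idx), yi)] <- 1
          dLogits <- w[yi] * (P - Y1) / length(idx)
        } else {
          ti <- ttr[idx]; di <- evtr[idx]
          if (sum(di == 1) == 0L) next  # no events: risk sets undefined
          cg <- .coxLossGrad(fw$logits[, 1L], ti, di)
          loss <- cg$loss
          dLogits <- matrix(cg$grad, ncol = 1L)
        }
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (step ", step + 1L, "); learning rate ", config$learningRate)
        }
        grads <- .modelBackward(mtmp, fw$cache, dLogits)
        params <- .applyRunningStats(params, fw$newRuns)
        step <- step + 1L
        upd <- .adamUpdate(params, grads, adamState, config$learningRate, step)
        params <- upd$p
        adamState <- list(m = upd$m, v = upd$v)
        epochLoss <- epochLoss + loss * length(idx)
        epochN <- epochN + length(idx)
      }
      vm <- valMetric(params)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = epochLoss / max(epochN, 1L),
                                           val_metric = vm))
      es <- earlyStoppingUpdate(es, vm)
      if (es$improved || epoch == 1L) bestParams <- params
      if (es$stop) break
    }
  })
  model@params <- bestParams
  attr(history, "monitor") <- monitor
  list(model = model, history = history)
}

#' Predict from a trained model
#'
#' Applies the model's stored standardization statistics when \code{newdata}
#' is an unstandardized \linkS4class{OmicsDataset} matching the raw feature
#' universe; a plain matrix is assumed already standardized to the model's
#' feature set.
#'
#' @param object an \linkS4class{AttOmicsModel}.
#' @param newdata an \linkS4class{OmicsDataset} or numeric matrix.
#' @return classification: matrix of class probabilities (samples x classes);
#'   survival: named numeric vector of log-risks \eqn{\hat{Y}} (risk is
#'   \eqn{e^{\hat{Y}}}).
#' @export
setMethod("predict", "AttOmicsModel", function(object, newdata) {
  if (methods::is(newdata, "OmicsDataset")) {
    st <- object@stats
    if (!is.null(st) && identical(featureIds(newdata), st@featureId)) {
      newdata <- applyStandardizer(newdata, st)
    }
    ids <- sampleIds(newdata)
    X <- omicsMatrix(newdata)
  } else {
    X <- as.matrix(newdata)
    ids <- rownames(X)
  }
  out <- attOmicsForward(object, X)$output
  if (object@config$head == "classification") {
    rownames(out) <- ids
    out
  } else {
    stats::setNames(out[, 1L], ids)
  }
})
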