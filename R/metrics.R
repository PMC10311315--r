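#' Classification error rate
#'
#' @param predicted,truth equal-length class vectors.
#' @return fraction misclassified.
#' @export
errorRate <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) == 0L) stop("empty input")
  mean(as.character(predicted) != as.character(truth))
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1. A class absent from both predictions and
#' truth contributes F1 = 0 with a warning (so the score is conservative when
#' classes are missing).
#'
#' @param predicted,truth class vectors.
#' @param levels class universe; defaults to the union of observed labels.
#' @return macro F1 in [0, 1]; per-class F1 attached as attribute
#'   \code{"perClass"}.
#' @export
macroF1 <- function(predicted, truth, levels = NULL) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (is.null(levels)) levels <- sort(unique(c(predicted, truth)))
  f1 <- vapply(levels, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (2 * tp + fp + fn == 0) {
      warning("class '", cl, "' absent from predictions and truth; F1 set to 0")
      return(0)
    }
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  out <- mean(f1)
  attr(out, "perClass") <- f1
  out
}

#' Concordance index for survival risk scores
#'
#' The pairwise ratio
#' \deqn{C = \frac{\sum_{i,j} 1[T_j < T_i]\, 1[\eta_j > \eta_i]\, \delta_j}
#'   {\sum_{i,j} 1[T_j < T_i]\, \delta_j},}
#' counting a pair as comparable when the earlier patient j experienced the
#' event, and as concordant when the earlier patient carries the higher
#' predicted risk. 0.5 is random ranking, 1 is perfect. Risk ties receive no
#' credit under the default strict inequality; \code{ties = "half"} awards
#' them half credit (the convention of some C-index implementations).
#'
#' @param risks predicted risks \eqn{\eta} (any monotone transform of risk,
#'   e.g. \eqn{e^{\hat{Y}}}).
#' @param times follow-up times.
#' @param events 0/1 event flags.
#' @param ties \code{"strict"} (default) or \code{"half"}.
#' @return concordance index in [0, 1].
#' @examples
#' concordanceIndex(c(3, 2, 1), times = 1:3, events = c(1, 1, 1))  # 1
#' @export
concordanceIndex <- function(risks, times, events, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  n <- length(risks)
  stopifnot(length(times) == n, length(events) == n)
  comparable <- outer(times, times, "<") & (events == 1)   # [j, i]: T_j < T_i, delta_j = 1
  den <- sum(comparable)
  if (den == 0) stop("no comparable pairs (denominator is zero)")
  concordant <- outer(risks, risks, ">")                   # [j, i]: eta_j > eta_i
  num <- sum(comparable & concordant)
  if (ties == "half") num <- num + 0.5 * sum(comparable & outer(risks, risks, "=="))
  num / den
}
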