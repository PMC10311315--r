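#' Per-group FCN width schedules
#'
#' Groups of different sizes are projected to the shared embedding dimension s
#' with different depths so that every group undergoes roughly the same
#' per-layer reduction ratio: a group of size \eqn{p_i} gets depth
#' \eqn{d_i = \max(1, \lceil \log_{ratio}(p_i / s) \rceil)} and geometrically
#' interpolated widths ending exactly at s.
#'
#' @param partition a \linkS4class{GroupPartition}.
#' @param s target embedding dimension.
#' @param reductionRatio per-layer width shrink factor (> 1).
#' @return list of integer width vectors, one per group, each starting at the
#'   group size and ending at s.
#' @examples
#' part <- randomGrouping(1010, 2, seed = 1)
#' planGroupFcn(part, s = 10, reductionRatio = 10)
#' @export
planGroupFcn <- function(partition, s, reductionRatio = 2) {
  s <- .assertScalarCount(s, "s")
  if (reductionRatio <= 1) stop("'reductionRatio' must be > 1")
  lapply(as.integer(lengths(partition@groups)), function(pi) {
    d <- max(1L, ceiling(log(pi / s, base = reductionRatio) - 1e-9))
    widths <- round(pi * (s / pi)^(seq_len(d) / d))
    widths[d] <- s
    widths <- pmax(widths, 1L)
    as.integer(c(pi, widths))
  })
}

.initLinear <- function(nOut, nIn) {
  lim <- sqrt(6 / nIn)
  list(W = matrix(runif(nOut * nIn, -lim, lim), nOut, nIn),
       b = runif(nOut, -1 / sqrt(nIn), 1 / sqrt(nIn)))
}

# right-multiplication matrix (nIn x nOut), fan-in init
.initMat <- function(nIn, nOut) {
  lim <- sqrt(6 / nIn)
  matrix(runif(nIn * nOut, -lim, lim), nIn, nOut)
}

.initNorm <- function(type, k, s) {
  if (type == "layer") {
    list(gain = rep(1, s), bias = rep(0, s))
  } else {
    list(gain = matrix(1, k, s), bias = matrix(0, k, s),
         runMean = matrix(0, k, s), runVar = matrix(1, k, s))
  }
}

#' Build an AttOmics model
#'
#' Assembles and initializes the full architecture: block-1 group FCNs sized
#' by \code{\link{planGroupFcn}}, per-block multi-head self-attention
#' projections \eqn{W^Q_j, W^K_j, W^V_j} (s to l = s/h) and output projection
#' \eqn{W^O} (s x s), residual + normalization, later-block single-layer group
#' FCNs (s to s), and the prediction FCN. Weights use uniform Kaiming-style
#' fan-in initialization under \code{seed}.
#'
#' @param partition a \linkS4class{GroupPartition} over the model's features.
#' @param s group embedding dimension; must be divisible by \code{h}.
#' @param h number of attention heads.
#' @param nBlocks encoder depth (>= 1).
#' @param norm \code{"layer"} (default) or \code{"batch"}.
#' @param residual add the residual connection around the attention (default
#'   TRUE).
#' @param reductionRatio per-layer width ratio for the block-1 group FCNs.
#' @param predictorWidths integer vector of predictor hidden widths (possibly
#'   empty for a linear head on the flattened encoder output).
#' @param head \code{"classification"} or \code{"survival"}.
#' @param classLevels class labels (required for classification).
#' @param attentionScale \code{"s"} (divide attention scores by s, the printed
#'   form) or \code{"sqrt_l"} (the usual \eqn{\sqrt{d_k}} scaling).
#' @param seed integer seed for weight initialization.
#' @return an \linkS4class{AttOmicsModel}.
#' @examples
#' part <- randomGrouping(40, 4, seed = 1)
#' m <- attOmicsModel(part, s = 8, h = 2, classLevels = c("a", "b"), seed = 1)
#' countParameters(m)
#' @export
attOmicsModel <- function(partition, s, h = 1L, nBlocks = 1L,
                          norm = c("layer", "batch"), residual = TRUE,
                          reductionRatio = 2, predictorWidths = integer(),
                          head = c("classification", "survival"),
                          classLevels = NULL,
                          attentionScale = c("s", "sqrt_l"), seed = 1L) {
  stopifnot(methods::is(partition, "GroupPartition"))
  norm <- match.arg(norm); head <- match.arg(head)
  attentionScale <- match.arg(attentionScale)
  s <- .assertScalarCount(s, "s"); h <- .assertScalarCount(h, "h")
  nBlocks <- .assertScalarCount(nBlocks, "nBlocks")
  if (s %% h != 0L) stop("'s' must be divisible by 'h' (l = s/h must be an integer)")
  if (head == "classification") {
    if (is.null(classLevels) || length(classLevels) < 2L) {
      stop("classification head requires >= 2 'classLevels'")
    }
    classLevels <- as.character(classLevels)
  }
  k <- nGroups(partition)
  l <- s %/% h
  schedules <- planGroupFcn(partition, s, reductionRatio)
  nOut <- if (head == "classification") length(classLevels) else 1L

  params <- .withSeed(.deriveSeed(seed, "init"), {
    blocks <- lapply(seq_len(nBlocks), function(b) {
      gfcn <- if (b == 1L) {
        lapply(schedules, function(w) {
          lapply(seq_len(length(w) - 1L), function(d) .initLinear(w[d + 1L], w[d]))
        })
      } else {
        lapply(seq_len(k), function(i) list(.initLinear(s, s)))
      }
      mhsa <- list(
        Wq = lapply(seq_len(h), function(j) .initMat(s, l)),
        Wk = lapply(seq_len(h), function(j) .initMat(s, l)),
        Wv = lapply(seq_len(h), function(j) .initMat(s, l)),
        Wo = .initMat(s, s)
      )
      list(gfcn = gfcn, mhsa = mhsa, norm = .initNorm(norm, k, s))
    })
    widths <- c(k * s, as.integer(predictorWidths))
    layers <- lapply(seq_len(length(widths) - 1L),
                     function(d) .initLinear(widths[d + 1L], widths[d]))
    norms <- lapply(seq_len(length(widths) - 1L),
                    function(d) .initNorm(norm, 1L, widths[d + 1L]))
    pred <- list(layers = layers, norms = norms,
                 out = .initLinear(nOut, widths[length(widths)]))
    list(blocks = blocks, pred = pred)
  })

  methods::new("AttOmicsModel",
    partition = partition,
    config = list(s = s, h = h, l = l, nBlocks = nBlocks, norm = norm,
                  residual = isTRUE(residual), reductionRatio = reductionRatio,
                  predictorWidths = as.integer(predictorWidths), head = head,
                  nClasses = if (head == "classification") length(classLevels) else NA_integer_,
                  classLevels = classLevels, attentionScale = attentionScale,
                  seed = as.integer(seed)),
    schedules = schedules,
    params = params,
    stats = NULL
  )
}

.countList <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    drop <- if (is.null(nm)) rep(FALSE, length(x)) else nm %in% c("runMean", "runVar")
    sum(vapply(x[!drop], .countList, numeric(1)))
  } else {
    length(x)
  }
}

#' @rdname countParameters
#' @export
setMethod("countParameters", "AttOmicsModel", function(object, component = "all") {
  component <- match.arg(component, c("all", "encoder", "first_projection"))
  p <- object@params
  switch(component,
    all = .countList(p),
    encoder = .countList(p$blocks),
    first_projection = .countList(p$blocks[[1L]]$gfcn)
  )
})

#' Parameter count of a dense MLP stack
#'
#' Number of weights and biases of fully connected layers taking p inputs
#' through the given widths (optionally to an output layer), the quantity the
#' parameter-economy comparison with grouped projections is made against.
#'
#' @param p input dimension.
#' @param widths integer vector of successive layer widths.
#' @param nOut optional output layer size appended to the chain.
#' @return numeric parameter count.
#' @examples
#' mlpParamCount(100, 50)  # 100*50 + 50
#' @export
mlpParamCount <- function(p, widths, nOut = NULL) {
  dims <- c(p, widths, nOut)
  sum(vapply(seq_len(length(dims) - 1L),
             function(d) dims[d] * dims[d + 1L] + dims[d + 1L], numeric(1)))
}
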