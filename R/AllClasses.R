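#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Omics dataset container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}, features in rows, samples in columns) plus optional
#' phenotype labels and right-censored survival annotations in \code{colData}.
#' User-facing functions exchange matrices in the on-disk orientation
#' (samples in rows, features in columns); use \code{\link{omicsMatrix}}.
#'
#' @slot .Data inherited SummarizedExperiment internals.
#' @export
setClass("OmicsDataset", contains = "SummarizedExperiment")

setValidity("OmicsDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'exprs' is required")
  } else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x)) msg <- c(msg, "assay 'exprs' must be numeric")
    if (anyNA(x)) msg <- c(msg, "assay 'exprs' must not contain missing values")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("label" %in% colnames(cd)) {
    lab <- cd$label
    if (!is.factor(lab)) msg <- c(msg, "'label' must be a factor")
    else if (nlevels(lab) < 2L) msg <- c(msg, "'label' must have at least 2 classes")
  }
  if ("event" %in% colnames(cd)) {
    ev <- cd$event
    if (!all(ev %in% c(0, 1) | is.na(ev))) msg <- c(msg, "'event' must be 0/1 (NA allowed before filtering)")
    if (!"time" %in% colnames(cd)) msg <- c(msg, "'event' requires a 'time' column")
  }
  if ("time" %in% colnames(cd) && !"event" %in% colnames(cd)) {
    msg <- c(msg, "'time' requires an 'event' column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsDataset
#'
#' @param X numeric matrix, samples in rows and features in columns.
#' @param labels optional vector of class labels (coerced to factor, >= 2 levels).
#' @param time optional numeric vector of follow-up times (days).
#' @param event optional 0/1 event indicators (1 = event observed).
#' @param featureIds,sampleIds identifiers; default to \code{dimnames(X)}.
#' @return an \linkS4class{OmicsDataset}.
#' @examples
#' ds <- OmicsDataset(matrix(rnorm(12), 3, 4), labels = c("a", "b", "a"))
#' dim(ds)
#' @export
OmicsDataset <- function(X, labels = NULL, time = NULL, event = NULL,
                         featureIds = colnames(X), sampleIds = rownames(X)) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(featureIds)) featureIds <- paste0("f", seq_len(p))
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(n))
  if (anyDuplicated(featureIds)) stop("duplicated feature IDs: ",
    paste(unique(featureIds[duplicated(featureIds)]), collapse = ", "))
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  if (!is.null(labels)) {
    if (length(labels) != n) stop("'labels' must have one entry per sample")
    cd$label <- factor(labels)
  }
  if (!is.null(time) || !is.null(event)) {
    if (is.null(time) || is.null(event)) stop("'time' and 'event' must be given together")
    if (length(time) != n || length(event) != n) stop("'time'/'event' must have one entry per sample")
    cd$time <- as.numeric(time)
    cd$event <- as.numeric(event)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(X)),
    colData = cd,
    rowData = S4Vectors::DataFrame(row.names = featureIds)
  )
  methods::new("OmicsDataset", se)
}

#' Feature partition used as the attention token set
#'
#' Ordered collection of k feature-index groups over p features. Random and
#' clustering strategies yield disjoint covering partitions; gene-set (GMT)
#' partitions may overlap and may leave features uncovered.
#'
#' @slot groups list of k integer vectors (1-based feature indices).
#' @slot groupNames character vector of length k.
#' @slot overlapping logical; TRUE when groups may share features.
#' @slot p total number of features indexed.
#' @slot featureIds character of length p (may be empty when unknown).
#' @export
setClass("GroupPartition", representation(
  groups = "list",
  groupNames = "character",
  overlapping = "logical",
  p = "integer",
  featureIds = "character"
))

setValidity("GroupPartition", function(object) {
  msg <- character()
  k <- length(object@groups)
  if (k < 2L) msg <- c(msg, "a partition needs at least 2 groups")
  if (length(object@groupNames) != k) msg <- c(msg, "groupNames length must equal number of groups")
  sizes <- lengths(object@groups)
  if (any(sizes == 0L)) msg <- c(msg, "empty groups are not allowed")
  idx <- unlist(object@groups, use.names = FALSE)
  if (length(idx) && (any(idx < 1L) || any(idx > object@p))) {
    msg <- c(msg, "feature indices must lie in [1, p]")
  }
  if (!object@overlapping) {
    if (anyDuplicated(idx)) msg <- c(msg, "non-overlapping partition has duplicated feature indices")
    if (length(unique(idx)) != object@p) msg <- c(msg, "non-overlapping partition must cover all p features")
  }
  if (length(object@featureIds) && length(object@featureIds) != object@p) {
    msg <- c(msg, "featureIds must have length p")
  }
  if (length(msg)) msg else TRUE
})

.newPartition <- function(groups, groupNames, overlapping, p, featureIds = character()) {
  methods::new("GroupPartition",
    groups = lapply(groups, as.integer),
    groupNames = as.character(groupNames),
    overlapping = overlapping,
    p = as.integer(p),
    featureIds = as.character(featureIds)
  )
}

#' Per-feature standardization statistics
#'
#' Train-split means and population standard deviations; features constant on
#' the fitting rows are flagged (\code{keep = FALSE}) and removed on apply.
#'
#' @slot featureId character feature identifiers.
#' @slot mean,sd numeric vectors, one entry per feature.
#' @slot keep logical; FALSE marks constant features slated for removal.
#' @export
setClass("FeatureStats", representation(
  featureId = "character", mean = "numeric", sd = "numeric", keep = "logical"
))

setValidity("FeatureStats", function(object) {
  p <- length(object@featureId)
  if (length(object@mean) != p || length(object@sd) != p || length(object@keep) != p) {
    return("featureId, mean, sd and keep must have equal length")
  }
  if (any(object@sd[object@keep] <= 0)) return("retained features must have sd > 0")
  TRUE
})

#' Trained or untrained AttOmics network
#'
#' Holds the feature partition, the architecture configuration, the per-group
#' FCN width schedules and all trainable parameters (group FCN weights,
#' per-head attention projections, normalization affine terms, predictor).
#'
#' @slot partition the \linkS4class{GroupPartition} the encoder consumes.
#' @slot config named list: s, h, nBlocks, norm, residual, reductionRatio,
#'   predictorWidths, head, nClasses, classLevels, attentionScale, seed.
#' @slot schedules per-group width schedules for the first-block FCNs.
#' @slot params nested list of weight matrices and bias/affine vectors.
#' @slot stats \linkS4class{FeatureStats} used at prediction time (or NULL).
#' @export
setClass("AttOmicsModel", representation(
  partition = "GroupPartition",
  config = "list",
  schedules = "list",
  params = "list",
  stats = "ANY"
))

#' Phenotype-level attention map
#'
#' Element (i, m) is the attention weight with which group i attends to group
#' m, averaged over all samples carrying one phenotype (rows remain
#' probability distributions because the mean of row-stochastic matrices is
#' row-stochastic).
#'
#' @slot phenotype the phenotype label averaged over.
#' @slot map k x k numeric matrix with group names as dimnames.
#' @slot block encoder block index the map was read from.
#' @slot headMode "mean" or the index of a single head.
#' @slot nSamples number of samples averaged.
#' @export
setClass("AttentionMap", representation(
  phenotype = "character", map = "matrix", block = "integer",
  headMode = "character", nSamples = "integer"
))

setValidity("AttentionMap", function(object) {
  msg <- character()
  if (nrow(object@map) != ncol(object@map)) msg <- c(msg, "map must be square")
  if (any(abs(rowSums(object@map) - 1) > 1e-4)) msg <- c(msg, "map rows must sum to 1 (within 1e-4)")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (length(msg)) msg else TRUE
})
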