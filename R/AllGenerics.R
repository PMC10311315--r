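#' @include AllClasses.R
NULL

#' Accessors for OmicsDataset and GroupPartition
#'
#' \code{omicsMatrix} returns the expression matrix with samples in rows and
#' features in columns (the orientation used on disk and by the model);
#' \code{featureIds}/\code{sampleIds} return identifiers; \code{classLabels},
#' \code{survTime} and \code{survEvent} return the optional annotations (or
#' NULL); \code{featureGroups}, \code{groupNames}, \code{nGroups} and
#' \code{groupSizes} describe a partition.
#'
#' @param x an \linkS4class{OmicsDataset} or \linkS4class{GroupPartition}.
#' @return see Description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("omicsMatrix", function(x) standardGeneric("omicsMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))
#' @rdname accessors
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))
#' @rdname accessors
#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))
#' @rdname accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))
#' @rdname accessors
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))
#' @rdname accessors
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' Count trainable parameters
#'
#' @param object an \linkS4class{AttOmicsModel}.
#' @param component "all" (default), "encoder" (all encoder blocks), or
#'   "first_projection" (the raw-feature group FCNs of block 1 only).
#' @return integer parameter count (weights + biases + normalization affine
#'   gains/biases).
#' @export
setGeneric("countParameters", function(object, component = "all") {
  standardGeneric("countParameters")
})

#' @rdname accessors
#' @export
setMethod("omicsMatrix", "OmicsDataset", function(x) t(SummarizedExperiment::assay(x, "exprs")))
#' @rdname accessors
#' @export
setMethod("featureIds", "OmicsDataset", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "OmicsDataset", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("classLabels", "OmicsDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("label" %in% colnames(cd)) cd$label else NULL
})
#' @rdname accessors
#' @export
setMethod("survTime", "OmicsDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("time" %in% colnames(cd)) cd$time else NULL
})
#' @rdname accessors
#' @export
setMethod("survEvent", "OmicsDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("event" %in% colnames(cd)) cd$event else NULL
})

#' @rdname accessors
#' @export
setMethod("featureGroups", "GroupPartition", function(x) {
  stats::setNames(x@groups, x@groupNames)
})
#' @rdname accessors
#' @export
setMethod("groupNames", "GroupPartition", function(x) x@groupNames)
#' @rdname accessors
#' @export
setMethod("nGroups", "GroupPartition", function(x) length(x@groups))
#' @rdname accessors
#' @export
setMethod("groupSizes", "GroupPartition", function(x) {
  stats::setNames(lengths(x@groups), x@groupNames)
})

setMethod("show", "OmicsDataset", function(object) {
  cat("OmicsDataset:", ncol(object), "samples x", nrow(object), "features\n")
  lab <- classLabels(object)
  if (!is.null(lab)) {
    cat("  labels: ", nlevels(lab), " classes (",
        paste(utils::head(levels(lab), 5), collapse = ", "),
        if (nlevels(lab) > 5) ", ..." else "", ")\n", sep = "")
  }
  if (!is.null(survTime(object))) {
    ev <- survEvent(object)
    cat("  survival: ", sum(ev == 1, na.rm = TRUE), " events / ",
        length(ev), " samples\n", sep = "")
  }
})

setMethod("show", "GroupPartition", function(object) {
  sz <- lengths(object@groups)
  cat("GroupPartition: k =", length(sz), "groups over p =", object@p, "features",
      if (object@overlapping) "(overlapping)" else "(disjoint)", "\n")
  cat("  group sizes: min", min(sz), "/ median", stats::median(sz), "/ max", max(sz), "\n")
})

setMethod("show", "AttentionMap", function(object) {
  cat("AttentionMap for phenotype '", object@phenotype, "': ",
      nrow(object@map), "x", ncol(object@map),
      " (block ", object@block, ", heads = ", object@headMode,
      ", averaged over ", object@nSamples, " samples)\n", sep = "")
})

setMethod("show", "AttOmicsModel", function(object) {
  cfg <- object@config
  cat("AttOmicsModel (", cfg$head, " head)\n", sep = "")
  cat("  k =", nGroups(object@partition), "groups | s =", cfg$s,
      "| h =", cfg$h, "heads | blocks =", cfg$nBlocks,
      "| norm =", cfg$norm, "| residual =", cfg$residual, "\n")
  if (identical(cfg$head, "classification")) {
    cat("  classes:", paste(cfg$classLevels, collapse = ", "), "\n")
  }
  cat("  trainable parameters:", countParameters(object), "\n")
})
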