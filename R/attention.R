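#' Collect per-sample attention matrices
#'
#' Runs the model in evaluation mode over a dataset and retains, for every
#' sample, the k x k row-stochastic attention matrix of every encoder block
#' and head.
#'
#' @param model a trained \linkS4class{AttOmicsModel}.
#' @param dataset an \linkS4class{OmicsDataset} standardized consistently with
#'   the model (or a plain matrix).
#' @param batchSize samples per forward pass.
#' @return list of class \code{"attentionRecords"} with elements
#'   \code{attention} (list over blocks, each a list over heads of n x k x k
#'   arrays), \code{sampleIds}, \code{labels} (or NULL), \code{k}, \code{h},
#'   \code{nBlocks}, \code{groupNames}.
#' @export
collectAttention <- function(model, dataset, batchSize = 512L) {
  if (methods::is(dataset, "OmicsDataset")) {
    X <- omicsMatrix(dataset)
    labels <- classLabels(dataset)
    ids <- sampleIds(dataset)
  } else {
    X <- as.matrix(dataset); labels <- NULL; ids <- rownames(X)
  }
  cfg <- model@config
  k <- nGroups(model@partition)
  n <- nrow(X)
  att <- lapply(seq_len(cfg$nBlocks), function(b) {
    lapply(seq_len(cfg$h), function(j) array(0, c(n, k, k)))
  })
  for (batch in .batchIndices(n, batchSize)) {
    r <- attOmicsForward(model, X[batch, , drop = FALSE], collectAttention = TRUE)
    for (b in seq_len(cfg$nBlocks)) {
      for (j in seq_len(cfg$h)) {
        att[[b]][[j]][batch, , ] <- r$attention[[b]][[j]]
      }
    }
  }
  structure(list(attention = att, sampleIds = ids, labels = labels,
                 k = k, h = cfg$h, nBlocks = cfg$nBlocks,
                 groupNames = groupNames(model@partition)),
            class = "attentionRecords")
}

#' Per-phenotype attention map
#'
#' Averages the per-sample attention matrices of one encoder block over all
#' samples carrying the requested phenotype, with heads averaged
#' (\code{headMode = "mean"}) or a single head selected.
#'
#' @param records an \code{"attentionRecords"} object from
#'   \code{\link{collectAttention}}.
#' @param labels per-sample labels; defaults to the labels stored in the
#'   records.
#' @param phenotype the phenotype to average over.
#' @param block encoder block index; default the last block.
#' @param headMode \code{"mean"} or a head index.
#' @return an \linkS4class{AttentionMap}.
#' @export
phenotypeAttentionMap <- function(records, labels = records$labels, phenotype,
                                  block = records$nBlocks, headMode = "mean") {
  stopifnot(inherits(records, "attentionRecords"))
  if (is.null(labels)) stop("no labels available")
  block <- .assertScalarCount(block, "block")
  if (block > records$nBlocks) stop("block index out of range (nBlocks = ",
                                    records$nBlocks, ")")
  sel <- which(as.character(labels) == as.character(phenotype))
  if (length(sel) == 0L) {
    stop("phenotype '", phenotype, "' not present; available: ",
         paste(unique(as.character(labels)), collapse = ", "))
  }
  heads <- if (identical(headMode, "mean")) seq_len(records$h) else {
    j <- .assertScalarCount(headMode, "headMode")
    if (j > records$h) stop("head index out of range (h = ", records$h, ")")
    j
  }
  k <- records$k
  acc <- matrix(0, k, k)
  for (j in heads) {
    a <- records$attention[[block]][[j]]
    acc <- acc + apply(a[sel, , , drop = FALSE], c(2L, 3L), mean)
  }
  map <- acc / length(heads)
  dimnames(map) <- list(records$groupNames, records$groupNames)
  methods::new("AttentionMap", phenotype = as.character(phenotype), map = map,
               block = block,
               headMode = if (identical(headMode, "mean")) "mean" else as.character(headMode),
               nSamples = length(sel))
}

#' Top group-group interactions of an attention map
#'
#' @param map an \linkS4class{AttentionMap}.
#' @param m number of interactions to return.
#' @param includeDiagonal include self-attention entries (default FALSE).
#' @return data.frame (group_i, group_j, weight) sorted by weight descending;
#'   ties are broken by row then column index so the order is stable.
#' @export
topInteractions <- function(map, m, includeDiagonal = FALSE) {
  stopifnot(methods::is(map, "AttentionMap"))
  m <- .assertScalarCount(m, "m")
  k <- nrow(map@map)
  idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  if (!includeDiagonal) idx <- idx[idx$i != idx$j, ]
  w <- map@map[cbind(idx$i, idx$j)]
  ord <- order(-w, idx$i, idx$j)
  avail <- length(ord)
  if (m > avail) {
    warning("requested ", m, " interactions but only ", avail,
            " available; truncating")
    m <- avail
  }
  sel <- ord[seq_len(m)]
  nms <- rownames(map@map)
  data.frame(group_i = nms[idx$i[sel]], group_j = nms[idx$j[sel]],
             weight = w[sel], row.names = NULL)
}

#' Export an attention map
#'
#' Writes the k x k matrix as TSV with group names in the header and first
#' column (orientation: row i attends to column m); \code{format = "png"}
#' additionally renders a heatmap via pheatmap when available.
#'
#' @param map an \linkS4class{AttentionMap}.
#' @param path output file (for png, the image path; the TSV is always
#'   written to \code{paste0(path, ".tsv")} unless path ends in .tsv).
#' @param format \code{"tsv"} or \code{"png"}.
#' @return path(s) written, invisibly.
#' @export
exportAttention <- function(map, path, format = c("tsv", "png")) {
  format <- match.arg(format)
  stopifnot(methods::is(map, "AttentionMap"))
  if (nrow(map@map) == 0L) stop("refusing to export an empty attention map")
  tsvPath <- if (grepl("\\.tsv$", path)) path else paste0(path, ".tsv")
  df <- data.frame(group = rownames(map@map), map@map, check.names = FALSE)
  data.table::fwrite(df, tsvPath, sep = "\t")
  written <- tsvPath
  if (format == "png") {
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
      warning("pheatmap not available; heatmap not rendered")
    } else {
      pngPath <- if (grepl("\\.png$", path)) path else paste0(path, ".png")
      grDevices::png(pngPath, width = 900, height = 800)
      pheatmap::pheatmap(map@map, cluster_rows = FALSE, cluster_cols = FALSE,
                         main = paste0("Attention map: ", map@phenotype,
                                       " (block ", map@block, ")"))
      grDevices::dev.off()
      written <- c(written, pngPath)
    }
  }
  invisible(written)
}

#' Read back an exported attention matrix
#'
#' @param path TSV written by \code{\link{exportAttention}}.
#' @return numeric matrix with group-name dimnames.
#' @export
readAttentionMatrix <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
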