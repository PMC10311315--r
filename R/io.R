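#' Read a samples-by-features omics table
#'
#' Reads a TSV/CSV matrix whose header row holds feature IDs and whose first
#' column holds sample IDs. Columns named in \code{labelCol}, \code{timeCol}
#' and \code{eventCol} are routed to the phenotype / survival annotations
#' instead of the expression matrix.
#'
#' @param path file path.
#' @param labelCol,timeCol,eventCol optional column names to route to
#'   metadata.
#' @param sep field separator; \code{"auto"} lets \code{data.table::fread}
#'   sniff tab or comma.
#' @return an \linkS4class{OmicsDataset}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tg1\tg2\tgrp", "s1\t1\t2\tA", "s2\t3\t4\tB"), tf)
#' readOmicsTable(tf, labelCol = "grp")
#' @export
readOmicsTable <- function(path, labelCol = NULL, timeCol = NULL,
                           eventCol = NULL, sep = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr1 <- readLines(path, n = 1L)
  rawIds <- if (identical(sep, "auto")) {
    cand <- strsplit(hdr1, "\t", fixed = TRUE)[[1L]]
    if (length(cand) < 2L) cand <- strsplit(hdr1, ",", fixed = TRUE)[[1L]]
    cand
  } else {
    strsplit(hdr1, sep, fixed = TRUE)[[1L]]
  }
  rawIds <- rawIds[-1L]
  if (anyDuplicated(rawIds)) {
    stop("duplicated feature ID(s): ",
         paste(unique(rawIds[duplicated(rawIds)]), collapse = ", "))
  }
  dt <- data.table::fread(path, sep = if (identical(sep, "auto")) "auto" else sep,
                          header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("table must have a sample-ID column plus at least one feature")
  sample_ids <- as.character(dt[[1L]])
  dt <- dt[, -1L, drop = FALSE]

  meta <- list()
  for (col in c(labelCol, timeCol, eventCol)) {
    if (!is.null(col) && !col %in% colnames(dt)) {
      stop("declared metadata column '", col, "' not found in header")
    }
  }
  takeCol <- function(col) {
    v <- dt[[col]]
    dt[[col]] <<- NULL
    v
  }
  labels <- if (!is.null(labelCol)) takeCol(labelCol) else NULL
  time <- if (!is.null(timeCol)) suppressWarnings(as.numeric(takeCol(timeCol))) else NULL
  event <- if (!is.null(eventCol)) suppressWarnings(as.numeric(takeCol(eventCol))) else NULL

  feature_ids <- colnames(dt)
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature ID(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  X <- matrix(NA_real_, nrow(dt), ncol(dt), dimnames = list(sample_ids, feature_ids))
  for (j in seq_along(feature_ids)) {
    v <- dt[[j]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop(sprintf("non-numeric or missing value in feature column '%s', row %d (sample '%s')",
                   feature_ids[j], bad, sample_ids[bad]))
    }
    X[, j] <- num
  }
  OmicsDataset(X, labels = labels, time = time, event = event,
               featureIds = feature_ids, sampleIds = sample_ids)
}

#' Write an OmicsDataset as a TSV table
#'
#' Inverse of \code{\link{readOmicsTable}}: samples in rows, feature IDs in
#' the header, metadata appended as `label` / `time` / `event` columns.
#'
#' @param dataset an \linkS4class{OmicsDataset}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeOmicsTable <- function(dataset, path) {
  df <- data.frame(id = sampleIds(dataset), omicsMatrix(dataset),
                   check.names = FALSE)
  if (!is.null(classLabels(dataset))) df$label <- as.character(classLabels(dataset))
  if (!is.null(survTime(dataset))) {
    df$time <- survTime(dataset)
    df$event <- survEvent(dataset)
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Fit per-feature standardization statistics
#'
#' Computes feature means and population (divide-by-n) standard deviations on
#' the rows \code{idx} only — intended to be the training split, so that
#' validation/test standardization never leaks held-out information.
#' Features constant on \code{idx} are flagged for removal.
#'
#' @param dataset an \linkS4class{OmicsDataset}.
#' @param idx row (sample) indices to fit on; defaults to all samples.
#' @return a \linkS4class{FeatureStats}.
#' @export
fitStandardizer <- function(dataset, idx = seq_len(ncol(dataset))) {
  if (length(idx) == 0L) stop("'idx' must be non-empty")
  X <- omicsMatrix(dataset)[idx, , drop = FALSE]
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(X^2) - mu^2)
  sdev[sdev < 0] <- 0  # guard tiny negative from cancellation
  keep <- sdev > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant feature(s) flagged for removal: ",
            paste(utils::head(featureIds(dataset)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
  }
  methods::new("FeatureStats", featureId = featureIds(dataset),
               mean = unname(mu), sd = unname(sdev), keep = unname(keep))
}

#' Apply standardization statistics
#'
#' Centers and scales every feature column with train-fitted statistics and
#' drops the features flagged constant, consistently from the matrix and the
#' feature IDs.
#'
#' @param dataset an \linkS4class{OmicsDataset}.
#' @param stats a \linkS4class{FeatureStats} fitted on the same feature set.
#' @return a standardized \linkS4class{OmicsDataset}.
#' @export
applyStandardizer <- function(dataset, stats) {
  stopifnot(methods::is(stats, "FeatureStats"))
  if (!identical(featureIds(dataset), stats@featureId)) {
    stop("feature set mismatch between dataset and standardizer")
  }
  X <- omicsMatrix(dataset)
  keep <- stats@keep
  Xs <- sweep(X[, keep, drop = FALSE], 2L, stats@mean[keep], "-")
  Xs <- sweep(Xs, 2L, stats@sd[keep], "/")
  OmicsDataset(Xs,
               labels = classLabels(dataset),
               time = survTime(dataset), event = survEvent(dataset),
               featureIds = featureIds(dataset)[keep],
               sampleIds = sampleIds(dataset))
}

#' Serialize / read FeatureStats as TSV
#'
#' Three-column TSV (feature_id, mean, sd); dropped features are written with
#' sd 0 and restored as \code{keep = FALSE}.
#'
#' @param stats a \linkS4class{FeatureStats}.
#' @param path file path.
#' @return \code{writeFeatureStats}: path invisibly; \code{readFeatureStats}:
#'   a \linkS4class{FeatureStats}.
#' @export
writeFeatureStats <- function(stats, path) {
  df <- data.frame(feature_id = stats@featureId, mean = stats@mean,
                   sd = ifelse(stats@keep, stats@sd, 0))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname writeFeatureStats
#' @export
readFeatureStats <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  methods::new("FeatureStats", featureId = as.character(df$feature_id),
               mean = df$mean, sd = df$sd, keep = df$sd > 0)
}

#' Remove records with unusable survival information
#'
#' Drops samples with missing follow-up time, non-positive time, or missing
#' event flag; the number removed is reported via \code{message}.
#'
#' @param dataset an \linkS4class{OmicsDataset} with time/event columns.
#' @return the filtered \linkS4class{OmicsDataset}.
#' @export
filterSurvival <- function(dataset) {
  tt <- survTime(dataset); ev <- survEvent(dataset)
  if (is.null(tt) || is.null(ev)) stop("dataset has no survival annotations")
  ok <- !is.na(tt) & tt > 0 & !is.na(ev)
  if (!any(ok)) stop("all samples have invalid survival information")
  if (any(!ok)) message("filterSurvival: removed ", sum(!ok), " of ", length(ok), " samples")
  dataset[, ok]
}

#' Stratified train/validation/test split
#'
#' Allocates samples to splits per class with largest-remainder rounding so
#' every class's train proportion is within one sample of its target, then
#' assigns members by a seeded shuffle. Unlabeled datasets are split by simple
#' seeded random allocation. Classes with fewer members than splits trigger a
#' warning and are assigned best-effort, favoring the training split.
#'
#' @param dataset an \linkS4class{OmicsDataset}.
#' @param fractions positive fractions summing to 1, in order
#'   (train, validation, test).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test} (disjoint, covering all samples).
#' @examples
#' ds <- OmicsDataset(matrix(rnorm(40), 20, 2), labels = rep(c("a", "b"), 10))
#' sp <- stratifiedSplit(ds, c(0.7, 0.15, 0.15), seed = 1)
#' lengths(sp)
#' @export
stratifiedSplit <- function(dataset, fractions = c(0.7, 0.15, 0.15), seed) {
  if (length(fractions) != 3L || any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("'fractions' must be 3 non-negative numbers summing to 1")
  }
  .assertScalarCount(seed, "seed", min = 0L)
  n <- ncol(dataset)
  lab <- classLabels(dataset)
  groups <- if (is.null(lab)) list(all = seq_len(n)) else split(seq_len(n), lab)

  allocate <- function(m) {
    # largest-remainder apportionment of m members over the three splits
    q <- m * fractions
    base <- floor(q)
    rem <- m - sum(base)
    if (rem > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]  # ties: split order
      base[extra] <- base[extra] + 1
    }
    base
  }

  out <- list(train = integer(), val = integer(), test = integer())
  .withSeed(.deriveSeed(seed, "split"), {
    for (g in groups) {
      m <- length(g)
      if (m < 3L && !is.null(lab)) {
        warning("class with only ", m, " member(s): assigned to train (best effort)")
        alloc <- c(m, 0L, 0L)
      } else {
        alloc <- allocate(m)
      }
      g <- g[sample.int(m)]
      out$train <- c(out$train, g[seq_len(alloc[1])])
      out$val <- c(out$val, g[seq_len(alloc[2]) + alloc[1]])
      out$test <- c(out$test, g[seq_len(alloc[3]) + alloc[1] + alloc[2]])
    }
  })
  lapply(out, sort)
}
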