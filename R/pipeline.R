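# YAML-driven pipeline: validate config, run split -> standardize -> group ->
# build -> train -> evaluate, and the checkpoint-based commands the CLI wraps.

.configSchema <- list(
  seed = NULL, verbosity = NULL,
  data = c("path", "labelCol", "timeCol", "eventCol", "sep", "fractions",
           "filterSurvival"),
  grouping = c("strategy", "k", "minSize", "gmt", "minGroupSize", "restGroup"),
  model = c("s", "h", "nBlocks", "norm", "residual", "reductionRatio",
            "predictorWidths", "head", "attentionScale"),
  training = c("learningRate", "batchSize", "maxEpochs", "patience",
               "minDelta", "monitor"),
  output = c("dir", "overwrite")
)

#' Read and validate a run configuration
#'
#' YAML with sections \code{data}, \code{grouping}, \code{model},
#' \code{training}, \code{output} plus a global \code{seed}. Unknown sections
#' or keys are rejected before any computation.
#'
#' @param path YAML file, or a pre-parsed named list.
#' @return validated config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), names(.configSchema))
  if (length(unknown)) stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in setdiff(names(.configSchema), c("seed", "verbosity"))) {
    bad <- setdiff(names(cfg[[sec]]), .configSchema[[sec]])
    if (length(bad)) stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("config must declare a global 'seed'")
  .assertScalarCount(cfg$seed, "seed", min = 0L)
  if (is.null(cfg$data$path)) stop("config must declare data.path")
  if (is.null(cfg$grouping$strategy)) stop("config must declare grouping.strategy")
  cfg$grouping$strategy <- match.arg(cfg$grouping$strategy,
                                     c("random", "kmeans", "geneset"))
  cfg$model$head <- if (is.null(cfg$model$head)) "classification" else
    match.arg(cfg$model$head, c("classification", "survival"))
  if (is.null(cfg$data$fractions)) cfg$data$fractions <- c(0.7, 0.15, 0.15)
  if (is.null(cfg$output$dir)) cfg$output$dir <- "attomics_run"
  cfg
}

.configHash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

.buildPartition <- function(cfg, Xtrain, fids) {
  g <- cfg$grouping
  switch(g$strategy,
    random = randomGrouping(length(fids), g$k, seed = .deriveSeed(cfg$seed, "grouping"),
                            featureIds = fids),
    kmeans = constrainedKmeansGrouping(Xtrain, g$k,
                                       minSize = g$minSize,
                                       seed = .deriveSeed(cfg$seed, "grouping")),
    geneset = genesetGrouping(fids, g$gmt,
                              minGroupSize = if (is.null(g$minGroupSize)) 2L else g$minGroupSize,
                              restGroup = isTRUE(g$restGroup))
  )
}

#' Run the full training pipeline from a config
#'
#' Reads the data table, optionally filters survival records, makes a
#' stratified split, fits the standardizer on the training split, builds the
#' partition and model, trains with early stopping, evaluates on the test
#' split and writes all artifacts (checkpoint.rds, metrics.json, history.csv,
#' resolved config copy) into the output directory.
#'
#' @param config path to a YAML config or a config list.
#' @return (invisibly) list with model, history, metrics, split and paths.
#' @export
runTraining <- function(config) {
  cfg <- readRunConfig(config)
  outDir <- cfg$output$dir
  if (dir.exists(outDir) && length(dir(outDir)) && !isTRUE(cfg$output$overwrite)) {
    stop("output dir '", outDir, "' is non-empty; set output.overwrite: true")
  }
  message("attomics run: seed ", cfg$seed, ", config hash ", .configHash(cfg))
  ds <- readOmicsTable(cfg$data$path, labelCol = cfg$data$labelCol,
                       timeCol = cfg$data$timeCol, eventCol = cfg$data$eventCol,
                       sep = if (is.null(cfg$data$sep)) "auto" else cfg$data$sep)
  survivalHead <- cfg$model$head == "survival"
  if (survivalHead && !isFALSE(cfg$data$filterSurvival)) ds <- filterSurvival(ds)
  split <- stratifiedSplit(ds, cfg$data$fractions, seed = cfg$seed)
  stats <- suppressWarnings(fitStandardizer(ds, split$train))
  std <- applyStandardizer(ds, stats)
  Xtr <- omicsMatrix(std)[split$train, , drop = FALSE]
  partition <- .buildPartition(cfg, Xtr, featureIds(std))
  mcfg <- cfg$model
  model <- attOmicsModel(partition,
    s = if (is.null(mcfg$s)) 16L else mcfg$s,
    h = if (is.null(mcfg$h)) 1L else mcfg$h,
    nBlocks = if (is.null(mcfg$nBlocks)) 1L else mcfg$nBlocks,
    norm = if (is.null(mcfg$norm)) "layer" else mcfg$norm,
    residual = if (is.null(mcfg$residual)) TRUE else mcfg$residual,
    reductionRatio = if (is.null(mcfg$reductionRatio)) 2 else mcfg$reductionRatio,
    predictorWidths = if (is.null(mcfg$predictorWidths)) integer() else unlist(mcfg$predictorWidths),
    head = mcfg$head,
    classLevels = if (survivalHead) NULL else levels(classLabels(ds)),
    attentionScale = if (is.null(mcfg$attentionScale)) "s" else mcfg$attentionScale,
    seed = .deriveSeed(cfg$seed, "model_init"))
  tcfg <- do.call(trainConfig, c(cfg$training, list(seed = .deriveSeed(cfg$seed, "training"))))
  fit <- trainAttOmics(model, std[, split$train], std[, split$val], tcfg)
  model <- fit$model
  model@stats <- stats

  testDs <- std[, split$test]
  metrics <- if (survivalHead) {
    lr <- as.numeric(predict(model, omicsMatrix(testDs)))
    list(c_index = concordanceIndex(exp(lr - max(lr)), survTime(testDs),
                                    survEvent(testDs)))
  } else {
    P <- predict(model, omicsMatrix(testDs))
    pred <- colnames(P)[max.col(P, ties.method = "first")]
    truth <- as.character(classLabels(testDs))
    f1 <- macroF1(pred, truth, levels = model@config$classLevels)
    list(error_rate = errorRate(pred, truth), macro_f1 = as.numeric(f1),
         per_class_f1 = as.list(attr(f1, "perClass")))
  }

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    checkpoint = file.path(outDir, "checkpoint.rds"),
    metrics = file.path(outDir, "metrics.json"),
    history = file.path(outDir, "history.csv"),
    config = file.path(outDir, "config.yaml")
  )
  saveRDS(model, paths$checkpoint)
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE, digits = NA)
  data.table::fwrite(fit$history, paths$history)
  yaml::write_yaml(cfg, paths$config)
  invisible(list(model = model, history = fit$history, metrics = metrics,
                 split = split, paths = paths))
}

#' Predict from a saved checkpoint
#'
#' @param checkpoint path to a checkpoint.rds written by \code{runTraining}
#'   (or an \linkS4class{AttOmicsModel}).
#' @param data path to a data table or an \linkS4class{OmicsDataset}; must
#'   contain every feature the checkpoint was trained on.
#' @param out optional TSV path for the predictions.
#' @return data.frame of per-sample class probabilities, or risk scores
#'   \eqn{\eta = e^{\hat{Y}}} for survival checkpoints.
#' @export
# Read a table routing the conventional metadata column names if present.
.readTableAuto <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "[\t,]")[[1L]]
  readOmicsTable(path,
    labelCol = if ("label" %in% hdr) "label" else NULL,
    timeCol = if ("time" %in% hdr) "time" else NULL,
    eventCol = if ("event" %in% hdr) "event" else NULL)
}

predictFromCheckpoint <- function(checkpoint, data, out = NULL) {
  model <- if (is.character(checkpoint)) readRDS(checkpoint) else checkpoint
  ds <- if (is.character(data)) .readTableAuto(data) else data
  st <- model@stats
  if (!is.null(st)) {
    missing <- setdiff(st@featureId, featureIds(ds))
    if (length(missing)) {
      stop("data lacks ", length(missing), " model feature(s): ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..." else "")
    }
    ds <- ds[match(st@featureId, featureIds(ds)), ]
  }
  res <- predict(model, ds)
  df <- if (model@config$head == "classification") {
    data.frame(id = rownames(res), res, check.names = FALSE)
  } else {
    data.frame(id = names(res), risk = exp(res - max(res)) * exp(max(res)))
  }
  if (!is.null(out)) data.table::fwrite(df, out, sep = "\t")
  df
}

#' Attention maps from a saved checkpoint
#'
#' Computes the per-phenotype attention map(s) on labeled data and writes one
#' TSV (and optionally a heatmap and a top-interaction JSON) per phenotype.
#'
#' @param checkpoint checkpoint path or model.
#' @param data data table path or \linkS4class{OmicsDataset} with labels.
#' @param phenotype one phenotype, or NULL for all observed phenotypes.
#' @param block encoder block (default last).
#' @param headMode "mean" or a head index.
#' @param outPrefix output path prefix; files are
#'   \code{<prefix>_<phenotype>.tsv} etc.
#' @param topM number of top interactions to rank.
#' @param format "tsv" or "png".
#' @return list of \linkS4class{AttentionMap}s, invisibly.
#' @export
attentionMapFromCheckpoint <- function(checkpoint, data, phenotype = NULL,
                                       block = NULL, headMode = "mean",
                                       outPrefix = "attention", topM = 10L,
                                       format = "tsv") {
  model <- if (is.character(checkpoint)) readRDS(checkpoint) else checkpoint
  ds <- if (is.character(data)) .readTableAuto(data) else data
  if (nGroups(model@partition) == 1L) warning("k = 1: attention map is degenerate")
  st <- model@stats
  if (!is.null(st) && identical(featureIds(ds), st@featureId)) {
    ds <- applyStandardizer(ds, st)
  }
  labels <- classLabels(ds)
  if (is.null(labels)) stop("attention maps require labeled data")
  phenos <- if (is.null(phenotype)) unique(as.character(labels)) else phenotype
  bad <- setdiff(phenos, as.character(labels))
  if (length(bad)) {
    stop("unknown phenotype(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(unique(as.character(labels)), collapse = ", "))
  }
  records <- collectAttention(model, ds)
  if (is.null(block)) block <- records$nBlocks
  maps <- lapply(phenos, function(ph) {
    map <- phenotypeAttentionMap(records, labels, ph, block = block,
                                 headMode = headMode)
    exportAttention(map, paste0(outPrefix, "_", ph), format = format)
    jsonlite::write_json(topInteractions(map, min(topM, records$k^2 - records$k)),
                         paste0(outPrefix, "_", ph, "_top.json"),
                         auto_unbox = TRUE, digits = NA)
    map
  })
  names(maps) <- phenos
  invisible(maps)
}

#' Generate synthetic data from a YAML spec
#'
#' @param specPath YAML file with the \code{\link{syntheticSpec}} fields plus
#'   \code{task: classification|survival} and optional \code{gmtOverlap}.
#' @param outDir output directory.
#' @param force overwrite a non-empty directory.
#' @return written paths, invisibly.
#' @export
makeSynthetic <- function(specPath, outDir, force = FALSE) {
  raw <- if (is.character(specPath)) yaml::read_yaml(specPath) else specPath
  task <- if (is.null(raw$task)) "classification" else
    match.arg(raw$task, c("classification", "survival"))
  gmtOverlap <- raw$gmtOverlap
  raw$task <- NULL; raw$gmtOverlap <- NULL
  spec <- do.call(syntheticSpec, raw)
  if (dir.exists(outDir) && length(dir(outDir)) && !force) {
    stop("output dir '", outDir, "' is non-empty; use force = TRUE")
  }
  gen <- if (task == "classification") generateClassificationDataset(spec) else
    generateSurvivalDataset(spec)
  writeSyntheticDataset(gen, outDir, gmtOverlap = gmtOverlap)
}

# Dispatch for the command-line wrapper (inst/cli/attomics.R). Returns an exit
# code: 0 success, 1 user error, 2 internal error.
.cliMain <- function(args) {
  usage <- paste(
    "usage: attomics <command> [args]",
    "  train <config.yaml>",
    "  predict <checkpoint.rds> <data.tsv> <out.tsv>",
    "  evaluate <checkpoint.rds> <data.tsv> <labelCol>",
    "  attention-map <checkpoint.rds> <data.tsv> <labelCol> <outPrefix> [phenotype]",
    "  make-synthetic <spec.yaml> <outDir>",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(1L) }
  cmd <- args[[1L]]; rest <- args[-1L]
  need <- function(nmin) {
    if (length(rest) < nmin) stop("missing argument(s); see usage", call. = FALSE)
  }
  code <- tryCatch({
    switch(cmd,
      "train" = { need(1); runTraining(rest[[1L]]); 0L },
      "predict" = { need(3); predictFromCheckpoint(rest[[1L]], rest[[2L]], rest[[3L]]); 0L },
      "evaluate" = {
        need(3)
        ds <- readOmicsTable(rest[[2L]], labelCol = rest[[3L]])
        df <- predictFromCheckpoint(rest[[1L]], ds)
        pred <- colnames(df)[-1L][max.col(df[, -1L, drop = FALSE], ties.method = "first")]
        cat(jsonlite::toJSON(list(
          error_rate = errorRate(pred, classLabels(ds)),
          macro_f1 = as.numeric(macroF1(pred, classLabels(ds)))
        ), auto_unbox = TRUE), "\n")
        0L
      },
      "attention-map" = {
        need(4)
        ds <- readOmicsTable(rest[[2L]], labelCol = rest[[3L]])
        attentionMapFromCheckpoint(rest[[1L]], ds,
          phenotype = if (length(rest) >= 5) rest[[5L]] else NULL,
          outPrefix = rest[[4L]])
        0L
      },
      "make-synthetic" = { need(2); makeSynthetic(rest[[1L]], rest[[2L]]); 0L },
      { message("unknown command '", cmd, "'\n", usage); 1L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  code
}
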