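#' Specification for synthetic omics datasets
#'
#' Describes the generator shared by the classification and survival
#' simulators: p standardized continuous features organized in kTrue planted
#' blocks whose within-block correlation comes from one shared Gaussian latent
#' factor per block; class signal is a mean shift (in feature-sd units)
#' concentrated in class-specific blocks; survival log-risk is linear in the
#' block means with independent censoring.
#'
#' @param n number of samples.
#' @param p number of features.
#' @param kTrue number of planted feature blocks.
#' @param M number of classes (classification generator).
#' @param effectSize class mean shift in units of feature sd.
#' @param withinBlockCorr within-block correlation in [0, 1).
#' @param survival list with \code{beta} (per-block log-risk coefficients,
#'   recycled to kTrue), \code{baselineScale} (baseline exponential rate) and
#'   \code{censorFraction} in [0, 1).
#' @param seed integer seed; generation is bit-reproducible.
#' @return a validated list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(n, p, kTrue, M = 2L, effectSize = 1,
                          withinBlockCorr = 0.3,
                          survival = list(beta = 1, baselineScale = 1,
                                          censorFraction = 0.2),
                          seed = 1L) {
  n <- .assertScalarCount(n, "n"); p <- .assertScalarCount(p, "p")
  kTrue <- .assertScalarCount(kTrue, "kTrue"); M <- .assertScalarCount(M, "M", 2L)
  if (kTrue > p) stop("kTrue must not exceed p")
  if (effectSize < 0) stop("effectSize must be >= 0")
  if (withinBlockCorr < 0 || withinBlockCorr >= 1) stop("withinBlockCorr must be in [0, 1)")
  cf <- survival$censorFraction
  if (is.null(cf)) cf <- 0.2
  if (cf < 0 || cf >= 1) stop("censorFraction must be in [0, 1)")
  if (cf > 0.9) warning("censorFraction ", cf, " leaves very few events")
  structure(list(n = n, p = p, kTrue = kTrue, M = M, effectSize = effectSize,
                 withinBlockCorr = withinBlockCorr,
                 survival = list(beta = rep(survival$beta, length.out = kTrue),
                                 baselineScale = if (is.null(survival$baselineScale)) 1 else survival$baselineScale,
                                 censorFraction = cf),
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

# Contiguous near-equal planted block membership for p features.
.plantedBlocks <- function(p, kTrue) {
  sizes <- rep(p %/% kTrue, kTrue)
  rem <- p %% kTrue
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  rep(seq_len(kTrue), times = sizes)
}

# Single-factor block-correlated feature matrix: x = sqrt(rho) f_block +
# sqrt(1 - rho) noise, so every feature has unit variance and within-block
# correlation rho.
.blockFeatures <- function(n, p, membership, rho) {
  kTrue <- max(membership)
  Fct <- matrix(rnorm(n * kTrue), n, kTrue)
  sqrt(rho) * Fct[, membership, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
}

#' Generate a labeled classification dataset
#'
#' Classes are exactly balanced (within one sample); class c shifts the means
#' of its designated block(s) — block \eqn{((c-1) \bmod kTrue) + 1} — by
#' \code{effectSize}, so the discriminative signal is concentrated in a
#' class-specific subset of feature blocks.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{dataset} (an \linkS4class{OmicsDataset} with
#'   labels) and \code{truth} (block membership, per-class informative blocks,
#'   spec echo).
#' @export
generateClassificationDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  membership <- .plantedBlocks(spec$p, spec$kTrue)
  classBlocks <- lapply(seq_len(spec$M), function(c) ((c - 1L) %% spec$kTrue) + 1L)
  .withSeed(.deriveSeed(spec$seed, "synthetic_classification"), {
    X <- .blockFeatures(spec$n, spec$p, membership, spec$withinBlockCorr)
    y <- rep(seq_len(spec$M), length.out = spec$n)
    for (c in seq_len(spec$M)) {
      cols <- membership %in% classBlocks[[c]]
      X[y == c, cols] <- X[y == c, cols] + spec$effectSize
    }
    ds <- OmicsDataset(X, labels = paste0("class", y),
                       featureIds = paste0("f", seq_len(spec$p)),
                       sampleIds = paste0("s", seq_len(spec$n)))
    list(dataset = ds,
         truth = list(blockMembership = membership,
                      classBlocks = classBlocks,
                      informativeBlocks = sort(unique(unlist(classBlocks))),
                      spec = spec))
  })
}

#' Generate a right-censored survival dataset
#'
#' Each sample's log-risk is linear in its planted-block means,
#' \eqn{r_i = \sum_b \beta_b \bar{x}_{b}(i)}; event times are exponential
#' with rate proportional to \eqn{e^{r_i}} (proportional hazards by
#' construction) and censoring times are drawn independently from a uniform
#' distribution whose upper bound is calibrated to hit the requested
#' censoring fraction.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{dataset} (an \linkS4class{OmicsDataset} with
#'   time/event) and \code{truth} (log-risks \code{r}, beta, block
#'   membership, spec echo).
#' @export
generateSurvivalDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  membership <- .plantedBlocks(spec$p, spec$kTrue)
  beta <- spec$survival$beta
  .withSeed(.deriveSeed(spec$seed, "synthetic_survival"), {
    X <- .blockFeatures(spec$n, spec$p, membership, spec$withinBlockCorr)
    blockMeans <- vapply(seq_len(spec$kTrue), function(b) {
      rowMeans(X[, membership == b, drop = FALSE])
    }, numeric(spec$n))
    r <- as.vector(blockMeans %*% beta)
    tEvent <- rexp(spec$n, rate = spec$survival$baselineScale * exp(r))
    cf <- spec$survival$censorFraction
    if (cf <= 0) {
      time <- tEvent
      event <- rep(1, spec$n)
    } else {
      u <- runif(spec$n)
      frac <- function(cmax) mean(u * cmax < tEvent)
      lo <- min(tEvent) * 1e-6; hi <- max(tEvent) * 2
      while (frac(hi) > cf && hi < 1e12) hi <- hi * 2
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (frac(mid) > cf) lo <- mid else hi <- mid
      }
      cens <- u * ((lo + hi) / 2)
      event <- as.numeric(tEvent <= cens)
      time <- pmin(tEvent, cens)
    }
    ds <- OmicsDataset(X, time = time, event = event,
                       featureIds = paste0("f", seq_len(spec$p)),
                       sampleIds = paste0("s", seq_len(spec$n)))
    list(dataset = ds,
         truth = list(r = r, beta = beta, blockMembership = membership,
                      spec = spec))
  })
}

#' Write planted blocks as a GMT file
#'
#' Serializes a generator's planted blocks as gene sets (one set per block);
#' \code{overlapFraction} duplicates the leading fraction of each block's
#' features into the next block's set, exercising overlapping-group handling.
#'
#' @param truth the \code{truth} component returned by a generator.
#' @param path output GMT path.
#' @param overlapFraction fraction of each block duplicated into the
#'   neighboring set.
#' @return \code{path}, invisibly.
#' @export
writeSyntheticGmt <- function(truth, path, overlapFraction = 0) {
  membership <- truth$blockMembership
  if (is.null(membership) || length(membership) == 0L) {
    stop("ground truth has no block membership")
  }
  if (overlapFraction < 0 || overlapFraction >= 1) {
    stop("overlapFraction must be in [0, 1)")
  }
  kTrue <- max(membership)
  ids <- paste0("f", seq_along(membership))
  sets <- lapply(seq_len(kTrue), function(b) ids[membership == b])
  if (overlapFraction > 0) {
    for (b in seq_len(kTrue)) {
      donor <- sets[[b]]
      nDup <- ceiling(overlapFraction * length(donor))
      nxt <- (b %% kTrue) + 1L
      sets[[nxt]] <- unique(c(sets[[nxt]], donor[seq_len(nDup)]))
    }
  }
  lines <- vapply(seq_len(kTrue), function(b) {
    paste(c(paste0("BLOCK", b), paste0("planted block ", b), sets[[b]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a generated dataset plus ground truth to a directory
#'
#' @param generated list returned by a generator
#'   (\code{\link{generateClassificationDataset}} or
#'   \code{\link{generateSurvivalDataset}}).
#' @param dir output directory (created if needed).
#' @param gmtOverlap if non-NULL, also write the planted blocks as
#'   \code{blocks.gmt} with this overlap fraction.
#' @return named character vector of written paths, invisibly.
#' @export
writeSyntheticDataset <- function(generated, dir, gmtOverlap = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dataPath <- file.path(dir, "data.tsv")
  writeOmicsTable(generated$dataset, dataPath)
  truthPath <- file.path(dir, "truth.json")
  tr <- generated$truth
  tr$spec <- unclass(tr$spec)
  jsonlite::write_json(tr, truthPath, auto_unbox = TRUE, digits = NA)
  paths <- c(data = dataPath, truth = truthPath)
  if (!is.null(gmtOverlap)) {
    gmtPath <- file.path(dir, "blocks.gmt")
    writeSyntheticGmt(generated$truth, gmtPath, gmtOverlap)
    paths <- c(paths, gmt = gmtPath)
  }
  invisible(paths)
}
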