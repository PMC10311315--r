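#' Random feature grouping
#'
#' Partitions p features into k groups of near-equal size (sizes differ by at
#' most one) by a seeded permutation.
#'
#' @param p number of features.
#' @param k number of groups (2 <= k <= p).
#' @param seed integer seed.
#' @param featureIds optional character vector of length p carried into the
#'   partition for serialization.
#' @return a disjoint, covering \linkS4class{GroupPartition}.
#' @examples
#' groupSizes(randomGrouping(101, 10, seed = 1))
#' @export
randomGrouping <- function(p, k, seed, featureIds = character()) {
  p <- .assertScalarCount(p, "p"); k <- .assertScalarCount(k, "k", min = 2L)
  if (k > p) stop("k must not exceed p")
  sizes <- rep(p %/% k, k)
  rem <- p %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  perm <- .withSeed(.deriveSeed(seed, "random_grouping"), sample.int(p))
  groups <- split(perm, rep(seq_len(k), times = sizes))
  .newPartition(lapply(groups, sort), paste0("G", seq_len(k)),
                overlapping = FALSE, p = p, featureIds = featureIds)
}

# Squared Euclidean distances between rows of A (m x d) and rows of C (k x d).
.sqDist <- function(A, C) {
  d2 <- outer(rowSums(A^2), rowSums(C^2), "+") - 2 * tcrossprod(A, C)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding over the rows of F.
.kmeansppInit <- function(F, k) {
  m <- nrow(F)
  centers <- integer(k)
  centers[1L] <- sample.int(m, 1L)
  closest <- .sqDist(F, F[centers[1L], , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    pr <- closest / sum(closest)
    centers[j] <- if (all(closest == 0)) sample.int(m, 1L) else sample.int(m, 1L, prob = pr)
    closest <- pmin(closest, .sqDist(F, F[centers[j], , drop = FALSE])[, 1L])
  }
  F[centers, , drop = FALSE]
}

# Exact minimum-cost assignment of m objects to k clusters with a per-cluster
# minimum size, solved as a square linear sum assignment problem: each cluster
# contributes minSize mandatory slots plus optional slots up to its capacity;
# dummy objects (cost 0 on optional slots, prohibitive on mandatory ones)
# absorb the surplus so every mandatory slot is filled by a real object.
.constrainedAssign <- function(D, minSize) {
  m <- nrow(D); k <- ncol(D)
  cap <- m - (k - 1L) * minSize
  slots_per <- cap
  ncolT <- k * slots_per
  big <- max(D) * (m + 1) + 1
  cost <- matrix(0, ncolT, ncolT)
  slot_cluster <- rep(seq_len(k), each = slots_per)
  slot_mandatory <- rep(seq_len(slots_per) <= minSize, times = k)
  cost[seq_len(m), ] <- D[, slot_cluster, drop = FALSE]
  if (ncolT > m) {
    cost[(m + 1L):ncolT, ] <- 0
    cost[(m + 1L):ncolT, slot_mandatory] <- big
  }
  sol <- clue::solve_LSAP(cost)
  slot_cluster[sol[seq_len(m)]]
}

#' Constrained K-means feature grouping
#'
#' Clusters features (columns of a training-split expression matrix, each
#' feature represented by its values across training samples) with a K-means
#' variant whose assignment step is an exact minimum-cost assignment under a
#' per-cluster minimum size, so that group sizes stay comparable. The
#' within-cluster sum of squares is non-increasing across iterations.
#'
#' @param X numeric matrix of training rows (samples x features), typically
#'   standardized.
#' @param k number of groups (>= 2).
#' @param minSize minimum features per group; default \code{floor(0.5 * p / k)}.
#' @param seed integer seed (k-means++ initialization).
#' @param maxIter,tol iteration cap and centroid-shift convergence threshold.
#' @param nStart number of seeded k-means++ restarts; the run with the lowest
#'   final within-cluster sum of squares is kept.
#' @return a disjoint, covering \linkS4class{GroupPartition}; the achieved
#'   within-cluster sum of squares trajectory is attached as metadata via
#'   \code{attr(..., "wcss")} on the returned object's \code{groups} list.
#' @export
constrainedKmeansGrouping <- function(X, k, minSize = NULL, seed = 1L,
                                      maxIter = 50L, tol = 1e-6, nStart = 5L) {
  k <- .assertScalarCount(k, "k", min = 2L)
  p <- ncol(X)
  if (k > p) stop("k must not exceed the number of features")
  if (is.null(minSize)) minSize <- max(1L, floor(0.5 * p / k))
  minSize <- .assertScalarCount(minSize, "minSize", min = 1L)
  if (minSize * k > p) stop("infeasible minSize: minSize * k exceeds p")
  F <- t(X)  # features as objects

  runOnce <- function() {
    wcss <- numeric()
    assign_vec <- NULL
    C <- .kmeansppInit(F, k)
    for (iter in seq_len(maxIter)) {
      D <- .sqDist(F, C)
      new_assign <- .constrainedAssign(D, minSize)
      wcss <- c(wcss, sum(D[cbind(seq_len(p), new_assign)]))
      unchanged <- !is.null(assign_vec) && identical(new_assign, assign_vec)
      assign_vec <- new_assign
      Cnew <- C
      for (c in seq_len(k)) {
        Cnew[c, ] <- colMeans(F[assign_vec == c, , drop = FALSE])
      }
      shift <- sqrt(max(rowSums((Cnew - C)^2)))
      C <- Cnew
      if (unchanged || shift < tol) break
    }
    list(assign = assign_vec, wcss = wcss)
  }

  best <- NULL
  .withSeed(.deriveSeed(seed, "ckmeans"), {
    for (r in seq_len(nStart)) {
      res <- runOnce()
      if (is.null(best) || res$wcss[length(res$wcss)] < best$wcss[length(best$wcss)]) {
        best <- res
      }
    }
  })
  assign_vec <- best$assign
  wcss <- best$wcss
  groups <- split(seq_len(p), factor(assign_vec, levels = seq_len(k)))
  part <- .newPartition(groups, paste0("C", seq_len(k)), overlapping = FALSE,
                        p = p,
                        featureIds = if (is.null(colnames(X))) character() else colnames(X))
  attr(part@groups, "wcss") <- wcss
  part
}

#' Gene-set (GMT) feature grouping
#'
#' Builds one group per gene set from a GMT file, restricted to the features
#' actually present. Groups may overlap (a gene can belong to several sets)
#' and features in no surviving set are left ungrouped, which acts as an
#' implicit feature selection; the achieved coverage is reported.
#'
#' @param featureIds character vector of available feature identifiers.
#' @param gmtPath path to a tab-separated GMT file (set name, description,
#'   member genes).
#' @param minGroupSize sets retaining fewer features are dropped (warning).
#' @param restGroup if TRUE, uncovered features are collected into an extra
#'   group named \code{"rest"}.
#' @return an overlapping \linkS4class{GroupPartition}.
#' @export
genesetGrouping <- function(featureIds, gmtPath, minGroupSize = 2L,
                            restGroup = FALSE) {
  if (length(featureIds) == 0L) stop("'featureIds' must be non-empty")
  sets <- fgsea::gmtPathways(gmtPath)
  if (length(sets) == 0L) stop("no gene sets found in ", gmtPath)
  idx <- lapply(sets, function(g) sort(match(intersect(g, featureIds), featureIds)))
  sizes <- lengths(idx)
  drop <- sizes < minGroupSize
  if (any(drop)) {
    warning(sum(drop), " gene set(s) below minGroupSize dropped: ",
            paste(utils::head(names(sets)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
    idx <- idx[!drop]
  }
  if (length(idx) == 0L) stop("no gene set retained at least ", minGroupSize, " features")
  covered <- unique(unlist(idx, use.names = FALSE))
  coverage <- length(covered) / length(featureIds)
  message(sprintf("genesetGrouping: %d groups, coverage %.1f%% of %d features",
                  length(idx), 100 * coverage, length(featureIds)))
  if (restGroup) {
    rest <- setdiff(seq_along(featureIds), covered)
    if (length(rest)) idx <- c(idx, list(rest = rest))
  }
  if (length(idx) < 2L) stop("at least 2 groups are required; got ", length(idx))
  .newPartition(idx, names(idx), overlapping = TRUE,
                p = length(featureIds), featureIds = featureIds)
}

#' Summarize a partition
#'
#' @param partition a \linkS4class{GroupPartition}.
#' @return data.frame with one row per group (name, size) and attributes
#'   \code{meanMembership} (mean number of groups per covered feature) and
#'   \code{coverage} (fraction of features in at least one group).
#' @export
partitionSummary <- function(partition) {
  stopifnot(methods::is(partition, "GroupPartition"))
  sizes <- lengths(partition@groups)
  idx <- unlist(partition@groups, use.names = FALSE)
  covered <- unique(idx)
  out <- data.frame(group = partition@groupNames, size = as.integer(sizes))
  attr(out, "meanMembership") <- length(idx) / length(covered)
  attr(out, "coverage") <- length(covered) / partition@p
  out
}

#' Serialize / read a partition as JSON
#'
#' JSON object mapping each group name to its member feature IDs (or 1-based
#' indices when the partition carries no IDs).
#'
#' @param partition a \linkS4class{GroupPartition}.
#' @param path file path.
#' @param featureIds feature universe used to resolve IDs on read.
#' @return \code{writePartition}: path invisibly; \code{readPartition}: a
#'   \linkS4class{GroupPartition}.
#' @export
writePartition <- function(partition, path) {
  hasIds <- length(partition@featureIds) > 0L
  obj <- lapply(partition@groups, function(g) {
    if (hasIds) partition@featureIds[g] else g
  })
  names(obj) <- partition@groupNames
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writePartition
#' @param overlapping declared overlap flag for the reconstructed partition;
#'   default infers it from duplicated membership.
#' @export
readPartition <- function(path, featureIds = NULL, overlapping = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(featureIds)) {
    if (!all(vapply(obj, is.numeric, logical(1)))) {
      stop("partition stores feature IDs; supply 'featureIds' to resolve them")
    }
    groups <- lapply(obj, as.integer)
    p <- max(unlist(groups))
    featureIds <- character()
  } else {
    groups <- lapply(obj, function(g) {
      m <- match(g, featureIds)
      if (anyNA(m)) stop("partition references unknown feature(s): ",
                         paste(utils::head(g[is.na(m)], 5), collapse = ", "))
      m
    })
    p <- length(featureIds)
  }
  idx <- unlist(groups, use.names = FALSE)
  if (is.null(overlapping)) {
    overlapping <- anyDuplicated(idx) > 0L || length(unique(idx)) < p
  }
  .newPartition(groups, names(obj), overlapping = overlapping, p = p,
                featureIds = featureIds)
}
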