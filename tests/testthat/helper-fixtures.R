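# Small in-code fixtures shared across test files.

tinyDataset <- function(n = 12, p = 6, labels = TRUE, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
  OmicsDataset(X, labels = if (labels) rep(c("a", "b"), length.out = n) else NULL)
}

tinyModel <- function(p = 12, k = 3, s = 4, h = 2, nBlocks = 1,
                      head = "classification", seed = 3, ...) {
  part <- randomGrouping(p, k, seed = 7)
  attOmicsModel(part, s = s, h = h, nBlocks = nBlocks, head = head,
                classLevels = if (head == "classification") c("a", "b") else NULL,
                predictorWidths = 5, seed = seed, ...)
}

# contiguous partition with the given group sizes
.newPartitionForTest <- function(sizes) {
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  groups <- mapply(seq, starts, ends, SIMPLIFY = FALSE)
  attomics:::.newPartition(groups, paste0("G", seq_along(sizes)),
                           overlapping = FALSE, p = sum(sizes))
}

writeTinyTsv <- function(path, withNA = FALSE) {
  lines <- c("id\tg1\tg2\tgrp",
             "s1\t1\t2\tA",
             "s2\t3\t4\tB",
             if (withNA) "s3\tNA\t6\tA" else "s3\t5\t6\tA")
  writeLines(lines, path)
  path
}
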