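## Long-range assembly: reconstruct overlapping blocks of SNP columns
## independently, then phase consecutive blocks together by matching their
## haplotypes over the shared overlap columns.

#' Plan overlapping column blocks
#'
#' Spans step by `blockLen - overlap`; the final span is truncated at `l`
#' (and always retains more than `overlap` columns). If `l <= blockLen` a
#' single span covers everything.
#'
#' @param l number of SNP columns.
#' @param blockLen block length in SNPs (default 250).
#' @param overlap overlap between consecutive blocks in SNPs (default 50).
#' @return a `blockPlan` list with `blockLen`, `overlap` and `spans`, a list
#'   of 0-based half-open column intervals `c(start, end)`.
#' @export
planBlocks <- function(l, blockLen = 250L, overlap = 50L) {
  l <- as.integer(l); blockLen <- as.integer(blockLen); overlap <- as.integer(overlap)
  if (overlap >= blockLen) stop("overlap must be smaller than blockLen")
  if (overlap < 1L) stop("overlap must be positive")
  if (l <= blockLen) {
    spans <- list(c(0L, l))
  } else {
    step <- blockLen - overlap
    starts <- 0L
    while (starts[length(starts)] + blockLen < l)
      starts <- c(starts, starts[length(starts)] + step)
    spans <- lapply(starts, function(s) c(s, min(s + blockLen, l)))
  }
  structure(list(blockLen = blockLen, overlap = overlap, spans = spans),
            class = "blockPlan")
}

#' @export
print.blockPlan <- function(x, ...) {
  cat(sprintf("blockPlan: %d block(s), length %d, overlap %d\n",
              length(x$spans), x$blockLen, x$overlap))
  invisible(x)
}

#' Match haplotypes across a block overlap
#'
#' Finds the permutation `p` minimizing the total Hamming distance between
#' row i of the earlier block's haplotypes and row `p[i]` of the newer
#' block's haplotypes over the shared overlap columns, by exhaustive search
#' over the k! permutations; ties go to the lexicographically smallest
#' permutation.
#'
#' @param prev,new k x w allele matrices (or [Haplotypes-class]) over the
#'   same w overlap columns.
#' @return integer permutation of 1..k: row i of the stitched haplotypes
#'   continues with row `p[i]` of the new block.
#' @export
stitchPermutation <- function(prev, new) {
  H <- .hapAlleles(prev); P <- .hapAlleles(new)
  stopifnot(all(dim(H) == dim(P)))
  best <- NULL; bestCost <- Inf
  for (pm in .permutations(nrow(H))) {
    cost <- sum(H != P[pm, , drop = FALSE])
    if (cost < bestCost) { bestCost <- cost; best <- pm }
  }
  best
}

#' Assemble haplotypes over a long SNP range by overlapping blocks
#'
#' The fragment matrix is restricted to each planned block in turn
#' (dropping fragments covering fewer than two of the block's columns),
#' each block is assembled with [assembleHaplotypes()], and consecutive
#' blocks are phased together with [stitchPermutation()] over their overlap
#' columns; in overlap regions the earlier block's alleles are kept. A
#' block without informative fragments breaks the phasing: its columns are
#' imputed with the all-reads consensus and a new phase set starts.
#'
#' @param m a [FragmentMatrix-class] spanning the plan.
#' @param k ploidy.
#' @param tcfg,ecfg training and encoder configuration; `tcfg$seed` drives
#'   every block (shifted per block for independence).
#' @param plan a [planBlocks()] plan; default plans over `nSnps(m)`.
#' @return a [PhasingResult-class] over all columns; `phaseSets` lists the
#'   column sets that are internally phased.
#' @export
assembleLongRange <- function(m, k, tcfg = trainConfig(),
                              ecfg = encoderConfig(),
                              plan = planBlocks(nSnps(m))) {
  stopifnot(is(m, "FragmentMatrix"))
  l <- nSnps(m)
  spans <- plan$spans
  if (length(spans) == 1L) return(assembleHaplotypes(m, k, tcfg, ecfg))
  f <- m@fragments
  hap <- matrix(0L, k, l)
  phaseSets <- list()
  current <- integer(0)
  history <- NULL
  prevEnd <- 0L                                  # columns already written
  prevOk <- FALSE
  mecTotal <- 0
  for (bi in seq_along(spans)) {
    sp <- spans[[bi]]
    cols <- (sp[1L] + 1L):sp[2L]
    sub <- f[, cols, drop = FALSE]
    keep <- which(rowSums(sub != .UNCOVERED) >= 2L)
    ok <- length(keep) >= k
    if (ok) {
      bm <- new("FragmentMatrix", fragments = sub[keep, , drop = FALSE],
                readIds = m@readIds[keep],
                snpPositions = m@snpPositions[cols])
      btcfg <- tcfg
      btcfg$seed <- tcfg$seed + bi * 7919L
      fit <- assembleHaplotypes(bm, k, btcfg, ecfg)
      bh <- fit@haplotypes@alleles
      h <- fit@history
      h$block <- bi
      history <- rbind(history, h)
      if (prevOk) {
        ovCols <- (sp[1L] + 1L):prevEnd         # overlap with written columns
        off <- length(ovCols)
        pm <- stitchPermutation(hap[, ovCols, drop = FALSE],
                                bh[, seq_len(off), drop = FALSE])
        bh <- bh[pm, , drop = FALSE]
        newCols <- cols[cols > prevEnd]
        hap[, newCols] <- bh[, ncol(bh) - length(newCols) + seq_along(newCols),
                             drop = FALSE]
        current <- c(current, newCols)
      } else {
        hap[, cols] <- bh
        if (length(current)) phaseSets[[length(phaseSets) + 1L]] <- current
        current <- cols
      }
      prevOk <- TRUE
    } else {
      ## unphaseable block: impute with the global consensus, break phasing
      newCols <- cols[cols > prevEnd]
      if (length(newCols)) {
        gm <- max.col(vapply(1:4, function(b) colSums(f == b) + (4 - b) * 1e-3,
                             numeric(l)), ties.method = "first")
        hap[, newCols] <- rep(gm[newCols], each = k)
      }
      if (length(current)) phaseSets[[length(phaseSets) + 1L]] <- current
      current <- integer(0)
      prevOk <- FALSE
    }
    prevEnd <- max(prevEnd, sp[2L])
  }
  if (length(current)) phaseSets[[length(phaseSets) + 1L]] <- current
  h <- Haplotypes(hap, snpPositions = m@snpPositions)
  dist <- vapply(seq_len(k), function(j) {
    rowSums((f != rep(hap[j, ], each = nrow(f))) & f != .UNCOVERED)
  }, numeric(nrow(f)))
  if (nrow(f) == 1L) dist <- matrix(dist, nrow = 1L)
  labels <- max.col(-dist, ties.method = "first")
  new("PhasingResult", haplotypes = h, labels = as.integer(labels),
      sigma = matrix(numeric(0), 0L, 0L), mec = mec(m, h),
      history = if (is.null(history)) data.frame() else history,
      phaseSets = phaseSets)
}
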