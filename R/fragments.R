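## Construction of the read-fragment (SNP) matrix S: SNP calling from a
## pileup, matrix assembly from alignments, filtering of uninformative
## fragments, connectivity-based block splitting and one-hot encoding.

#' Call heterozygous SNP sites from per-position allele counts
#'
#' A site is called when at least two distinct alleles each reach a variant
#' allele frequency (VAF) of at least `vafThreshold` among the reads covering
#' that site (frequencies are computed against the covered depth of the
#' column, not the total read count). At a called site only the
#' `maxAlleles` most frequent alleles are retained; other alleles are
#' treated as uncovered downstream.
#'
#' @param counts 4 x P integer matrix of allele counts with rownames
#'   A,C,G,T (one column per candidate position).
#' @param positions 0-based reference coordinates of the P columns; defaults
#'   to `0..P-1`.
#' @param vafThreshold minimum VAF in (0,1); default 0.2.
#' @param maxAlleles maximum number of alleles retained per called site
#'   (typically the ploidy); default 4 (all).
#' @return a [SnpCallSet-class] with the called positions.
#' @examples
#' counts <- cbind(c(6, 4, 0, 0), c(0, 0, 10, 0), c(7, 0, 0, 3))
#' rownames(counts) <- c("A", "C", "G", "T")
#' snpPositions(callSnps(counts, positions = c(5, 9, 20)))
#' @export
callSnps <- function(counts, positions = NULL, vafThreshold = 0.2,
                     maxAlleles = 4L) {
  if (is.list(counts) && !is.matrix(counts)) {
    cm <- matrix(0L, 4L, length(counts), dimnames = list(.BASES, NULL))
    for (i in seq_along(counts)) {
      v <- counts[[i]]
      cm[match(names(v), .BASES), i] <- as.integer(v)
    }
    counts <- cm
  }
  if (length(counts) == 0L || ncol(counts) == 0L) stop("no positions")
  stopifnot(nrow(counts) == 4L, all(counts >= 0))
  if (vafThreshold <= 0 || vafThreshold >= 1)
    stop("vafThreshold must lie in (0,1)")
  if (is.null(positions)) positions <- seq_len(ncol(counts)) - 1L
  rownames(counts) <- .BASES

  depth <- colSums(counts)
  called <- which(depth > 0 &
    colSums(sweep(counts, 2L, pmax(depth, 1L), "/") >= vafThreshold) >= 2L)
  if (length(called) == 0L) {
    return(new("SnpCallSet", positions = integer(0), refAllele = integer(0),
               alleleCounts = list(), vafThreshold = vafThreshold))
  }
  alleleCounts <- lapply(called, function(j) {
    v <- counts[, j]
    keep <- which(v / depth[j] >= vafThreshold)
    keep <- keep[order(-v[keep], keep)]          # most frequent first
    keep <- keep[seq_len(min(length(keep), maxAlleles))]
    setNames(as.integer(v[keep]), .BASES[keep])
  })
  refAllele <- vapply(alleleCounts, function(v) match(names(v)[1L], .BASES), 0L)
  ord <- order(positions[called])
  new("SnpCallSet",
      positions = as.integer(positions[called])[ord],
      refAllele = refAllele[ord],
      alleleCounts = alleleCounts[ord],
      vafThreshold = vafThreshold)
}

#' Build the read-fragment matrix from aligned reads and called SNPs
#'
#' Each alignment record contributes its base at every called SNP position it
#' spans. Records sharing a `readId` (paired-end mates) are merged into one
#' fragment row; positions in the intervening insert remain uncovered, and a
#' position covered by both mates with conflicting bases is set to uncovered.
#' Bases other than A,C,G,T (N, `-` for deletions) are treated as uncovered.
#'
#' @param alignments data.frame with columns `readId`, `start` (0-based
#'   reference coordinate of the first base) and `seq` (aligned sequence in
#'   reference coordinates, i.e. deletions as `-`, no insertions).
#' @param calls a [SnpCallSet-class]; only alleles retained at each called
#'   site are kept, others become uncovered.
#' @return a [FragmentMatrix-class] with one row per distinct `readId` (rows
#'   covering no called SNP are kept as all-uncovered rows; remove them with
#'   [filterFragments()]).
#' @export
buildFragmentMatrix <- function(alignments, calls) {
  stopifnot(is(calls, "SnpCallSet"))
  pos <- calls@positions
  l <- length(pos)
  if (l < 2L) stop("need at least two called SNP positions")
  ids <- unique(alignments$readId)
  n <- length(ids)
  frag <- matrix(.UNCOVERED, n, l)
  conflict <- matrix(FALSE, n, l)
  row <- match(alignments$readId, ids)
  allowed <- lapply(calls@alleleCounts, function(v) match(names(v), .BASES))
  for (r in seq_len(nrow(alignments))) {
    s <- as.integer(alignments$start[r])
    seq <- toupper(alignments$seq[r])
    w <- nchar(seq)
    j <- which(pos >= s & pos < s + w)
    if (length(j) == 0L) next
    base <- encodeBases(substring(seq, pos[j] - s + 1L, pos[j] - s + 1L))
    keep <- base != .UNCOVERED & mapply(function(b, a) b %in% a, base, allowed[j])
    i <- row[r]
    for (t in which(keep)) {
      jj <- j[t]
      cur <- frag[i, jj]
      if (cur == .UNCOVERED && !conflict[i, jj]) {
        frag[i, jj] <- base[t]
      } else if (cur != base[t]) {          # mate disagreement -> uncovered
        frag[i, jj] <- .UNCOVERED
        conflict[i, jj] <- TRUE
      }
    }
  }
  FragmentMatrix(frag, snpPositions = pos, readIds = ids)
}

#' Remove fragments covering too few SNPs
#'
#' Fragments covering fewer than `minSnps` SNP columns carry no phasing
#' information and are discarded; row order is otherwise preserved and the
#' column set is unchanged. The operation is idempotent.
#'
#' @param m a [FragmentMatrix-class].
#' @param minSnps minimum number of covered SNP columns per fragment
#'   (default 2).
#' @return the filtered [FragmentMatrix-class].
#' @export
filterFragments <- function(m, minSnps = 2L) {
  stopifnot(is(m, "FragmentMatrix"))
  cov <- rowSums(m@fragments != .UNCOVERED)
  keep <- cov >= minSnps
  if (!any(keep)) stop("no informative fragments")
  new("FragmentMatrix", fragments = m@fragments[keep, , drop = FALSE],
      readIds = m@readIds[keep], snpPositions = m@snpPositions)
}

#' Split a fragment matrix into independently phaseable blocks
#'
#' Two SNP columns belong to the same block when they are connected in the
#' read-SNP bipartite graph, i.e. when a chain of fragments links them.
#' Phasing across a boundary where no fragment bridges adjacent covered
#' columns is impossible, so such columns start a new block; columns covered
#' by no read are dropped. Within each block, rows are restricted to
#' fragments covering at least two of its columns.
#'
#' @param m a [FragmentMatrix-class].
#' @return a list with elements `blocks` (list of [FragmentMatrix-class]),
#'   `columns` (list of integer column indices of `m` per block, in order)
#'   and `rows` (list of integer row indices of `m` per block).
#' @export
splitBlocks <- function(m) {
  stopifnot(is(m, "FragmentMatrix"))
  f <- m@fragments
  l <- ncol(f)
  parent <- seq_len(l)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(f))) {
    j <- which(f[i, ] != .UNCOVERED)
    if (length(j) > 1L) {
      r <- find(j[1L])
      for (t in j[-1L]) { rt <- find(t); if (rt != r) parent[rt] <- r }
    }
  }
  covered <- which(colSums(f != .UNCOVERED) > 0L)
  if (length(covered) == 0L) return(list(blocks = list(), columns = list(), rows = list()))
  comp <- vapply(covered, find, 0L)
  groups <- split(covered, factor(comp, levels = unique(comp)))
  ord <- order(vapply(groups, min, 0L))
  groups <- groups[ord]
  blocks <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  for (b in seq_along(groups)) {
    cols <- groups[[b]]
    sub <- f[, cols, drop = FALSE]
    keep <- which(rowSums(sub != .UNCOVERED) >= 2L)
    rows[[b]] <- keep
    blocks[[b]] <- new("FragmentMatrix",
                       fragments = sub[keep, , drop = FALSE],
                       readIds = m@readIds[keep],
                       snpPositions = m@snpPositions[cols])
  }
  list(blocks = blocks, columns = unname(groups), rows = rows)
}

#' One-hot encode a fragment matrix
#'
#' A,C,G,T map to the unit vectors (1,0,0,0) .. (0,0,0,1); uncovered cells
#' map to (0,0,0,0), so each (read, position) slice sums to 1 when covered
#' and 0 otherwise. The encoding is invertible on covered cells.
#'
#' @param m a [FragmentMatrix-class].
#' @return numeric array of dimension n x 4 x l.
#' @seealso [decodeOneHot()]
#' @export
oneHot <- function(m) {
  stopifnot(is(m, "FragmentMatrix"))
  f <- m@fragments
  n <- nrow(f); l <- ncol(f)
  a <- array(0, dim = c(n, 4L, l))
  idx <- which(f != .UNCOVERED, arr.ind = TRUE)
  if (nrow(idx)) a[cbind(idx[, 1L], f[idx], idx[, 2L])] <- 1
  a
}

#' Decode a one-hot array back to a fragment matrix
#'
#' @param a n x 4 x l array as produced by [oneHot()].
#' @param snpPositions,readIds metadata for the reconstructed object.
#' @return a [FragmentMatrix-class].
#' @export
decodeOneHot <- function(a, snpPositions = seq_len(dim(a)[3]) - 1L,
                         readIds = NULL) {
  stopifnot(length(dim(a)) == 3L, dim(a)[2] == 4L)
  n <- dim(a)[1]; l <- dim(a)[3]
  f <- matrix(.UNCOVERED, n, l)
  for (b in 1:4) f[a[, b, ] == 1] <- b
  FragmentMatrix(f, snpPositions = snpPositions, readIds = readIds)
}

## internal: one-hot as an (n*l) x 4 matrix, rows ordered position-fast
## within read (row (i-1)*l + p), the layout used by the neural network.
.oneHotFlat <- function(frag) {
  n <- nrow(frag); l <- ncol(frag)
  codes <- as.integer(t(frag))                 # position-fast
  x <- matrix(0, n * l, 4L)
  cov <- which(codes != .UNCOVERED)
  x[cbind(cov, codes[cov])] <- 1
  x
}
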