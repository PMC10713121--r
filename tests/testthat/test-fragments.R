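test_that("callSnps keeps sites where two alleles pass the VAF threshold", {
  counts <- cbind(c(5, 5, 0, 0), c(9, 1, 0, 0), c(6, 4, 0, 0),
                  c(0, 0, 10, 0), c(7, 0, 0, 3))
  rownames(counts) <- c("A", "C", "G", "T")
  calls <- callSnps(counts, positions = c(3, 8, 12, 20, 31), vafThreshold = 0.2)
  expect_identical(snpPositions(calls), c(3L, 12L, 31L))
  # frequencies are per covered depth, not total reads
  counts2 <- cbind(c(2, 2, 0, 0), c(200, 0, 0, 0))
  rownames(counts2) <- c("A", "C", "G", "T")
  expect_identical(snpPositions(callSnps(counts2, vafThreshold = 0.4)), 0L)
  expect_error(callSnps(matrix(0, 4, 0)), "no positions")
  expect_error(callSnps(counts, vafThreshold = 1.2), "vafThreshold")
})

test_that("callSnps retains at most maxAlleles alleles per site", {
  counts <- matrix(c(5, 4, 3, 0), 4, 1, dimnames = list(c("A", "C", "G", "T")))
  calls <- callSnps(counts, vafThreshold = 0.2, maxAlleles = 2L)
  expect_named(calls@alleleCounts[[1]], c("A", "C"))
})

test_that("buildFragmentMatrix places bases at called positions", {
  counts <- cbind(c(5, 5, 0, 0), c(5, 0, 5, 0), c(5, 0, 0, 5), c(0, 5, 5, 0))
  rownames(counts) <- c("A", "C", "G", "T")
  calls <- callSnps(counts, positions = c(2, 5, 9, 14), vafThreshold = 0.2)
  # single read spanning the first two SNPs
  aln <- data.frame(readId = "r1", start = 1, seq = "AAAAG")
  m <- buildFragmentMatrix(aln, calls)
  expect_identical(as.vector(as.matrix(m)), c("A", "G", "-", "-"))
  expect_identical(snpPositions(m), snpPositions(calls))
  # paired mates merged into one row, insert gap left uncovered
  aln2 <- data.frame(readId = c("p", "p"), start = c(2, 14),
                     seq = c("A", "C"))
  m2 <- buildFragmentMatrix(aln2, calls)
  expect_equal(nReads(m2), 1L)
  expect_identical(as.vector(as.matrix(m2)), c("A", "-", "-", "C"))
})

test_that("buildFragmentMatrix matches a hand coordinate scan", {
  counts <- cbind(c(5, 5, 0, 0), c(5, 0, 5, 0), c(5, 0, 0, 5), c(0, 5, 5, 0))
  rownames(counts) <- c("A", "C", "G", "T")
  pos <- c(2L, 5L, 9L, 14L)
  calls <- callSnps(counts, positions = pos, vafThreshold = 0.2)
  aln <- data.frame(readId = c("a", "b", "c"),
                    start = c(0, 4, 8),
                    seq = c("CCACCG", "CGAAAT", "CTAAAACG"))
  m <- buildFragmentMatrix(aln, calls)
  # independent scan: for each read and called position, index into the string
  expected <- matrix("-", 3, 4)
  starts <- c(0, 4, 8); seqs <- c("CCACCG", "CGAAAT", "CTAAAACG")
  allowed <- list(c("A", "C"), c("A", "G"), c("A", "T"), c("C", "G"))
  for (i in 1:3) for (j in 1:4) {
    off <- pos[j] - starts[i] + 1
    if (off >= 1 && off <= nchar(seqs[i])) {
      b <- substr(seqs[i], off, off)
      if (b %in% allowed[[j]]) expected[i, j] <- b
    }
  }
  expect_identical(unname(as.matrix(m)), expected)
})

test_that("filterFragments drops rows below the coverage floor", {
  m <- fragFromStrings(c("AC-G", "A---", "ACGG"))
  f <- filterFragments(m)
  expect_equal(nReads(f), 2L)
  expect_identical(readIds(f), c("read1", "read3"))
  expect_identical(snpPositions(f), snpPositions(m))
  # identity when all rows pass, and idempotence
  expect_identical(filterFragments(f)@fragments, f@fragments)
  expect_error(filterFragments(fragFromStrings(c("A---", "--G-"))),
               "no informative fragments")
})

test_that("filterFragments survivor count matches a brute-force scan", {
  set.seed(42)
  f <- matrix(sample(0:4, 200, replace = TRUE, prob = c(0.6, rep(0.1, 4))),
              20, 10)
  f[1, ] <- c(1L, 2L, rep(0L, 8))            # guarantee one survivor
  m <- FragmentMatrix(f)
  expected <- sum(apply(f, 1, function(r) sum(r != 0) >= 2))
  expect_equal(nReads(filterFragments(m)), expected)
})

test_that("splitBlocks separates disconnected column groups", {
  # fully bridged: one block
  one <- splitBlocks(fragFromStrings(c("ACG-", "-CGT", "AC-T")))
  expect_length(one$blocks, 1L)
  expect_identical(one$columns[[1]], 1:4)
  # middle column uncovered: two blocks, empty column dropped
  two <- splitBlocks(fragFromStrings(c("AC---", "AC---", "---GT", "---GT")))
  expect_length(two$blocks, 2L)
  expect_identical(two$columns, list(1:2, 4:5))
  # covered but unbridged adjacent columns also split
  unb <- splitBlocks(fragFromStrings(c("AC--", "--GT")))
  expect_length(unb$blocks, 2L)
})

test_that("splitBlocks agrees with a union-find oracle on random masks", {
  set.seed(7)
  for (rep in 1:20) {
    f <- matrix(sample(0:4, 12 * 8, replace = TRUE, prob = c(0.7, rep(0.075, 4))),
                12, 8)
    f[1, 1:2] <- 1L                          # keep the object valid
    m <- FragmentMatrix(f)
    sb <- splitBlocks(m)
    # oracle: BFS over the read-SNP bipartite graph restricted to covered cols
    covered <- which(colSums(f != 0) > 0)
    adj <- lapply(covered, function(j) {
      rows <- which(f[, j] != 0)
      unique(unlist(lapply(rows, function(r) which(f[r, ] != 0))))
    })
    names(adj) <- covered
    seen <- c(); ncomp <- 0
    for (j in covered) {
      if (j %in% seen) next
      ncomp <- ncomp + 1
      queue <- j
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        if (cur %in% seen) next
        seen <- c(seen, cur)
        queue <- c(queue, setdiff(adj[[as.character(cur)]], seen))
      }
    }
    expect_equal(length(sb$blocks), ncomp)
    # block column sets partition the covered columns, in order
    allCols <- unlist(sb$columns)
    expect_identical(sort(allCols), covered)
    expect_false(is.unsorted(vapply(sb$columns, min, 0L)))
  }
})

test_that("one-hot encoding is the documented unit-vector map and inverts", {
  m <- fragFromStrings(c("AC", "A-"))
  a <- oneHot(m)
  expect_equal(dim(a), c(2L, 4L, 2L))
  expect_equal(a[1, , 1], c(1, 0, 0, 0))
  expect_equal(a[1, , 2], c(0, 1, 0, 0))
  expect_equal(a[2, , 2], c(0, 0, 0, 0))     # uncovered -> zero vector
  # slice sums: 1 where covered, 0 otherwise
  expect_equal(apply(a, c(1, 3), sum), (m@fragments != 0) * 1)
  # round trip on random matrices
  set.seed(11)
  for (rep in 1:5) {
    f <- matrix(sample(0:4, 60, replace = TRUE), 6, 10)
    f[1, 1:2] <- 1L
    mm <- FragmentMatrix(f)
    expect_identical(decodeOneHot(oneHot(mm))@fragments, mm@fragments)
  }
})
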