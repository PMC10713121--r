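# Shared fixture builders. Everything is generated in code; a tiny encoder
# configuration keeps the neural-network tests fast.

tinyEncoder <- function(dR = 8L) encoderConfig(dR = dR, dFF = 2L * dR)

# fragment matrix from a character vector of rows like "AC-G"
fragFromStrings <- function(rows, positions = NULL) {
  m <- do.call(rbind, strsplit(rows, ""))
  if (is.null(positions)) positions <- seq_len(ncol(m)) - 1L
  FragmentMatrix(m, snpPositions = positions)
}

# error-free diploid toy: truth 2 x l, reads are sliding windows alternating
# between the two haplotypes; dense bridging so phasing is unambiguous
toyDiploid <- function(l = 16L, width = 6L, step = 1L, seed = 1L) {
  set.seed(seed)
  ref <- sample.int(4L, l, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(1:4, r), 1L), 0L)
  truth <- rbind(ref, alt)
  starts <- seq(1L, l - width + 1L, by = step)
  frag <- matrix(0L, 2L * length(starts), l)
  origin <- integer(2L * length(starts))
  r <- 0L
  for (s in starts) for (h in 1:2) {
    r <- r + 1L
    frag[r, s:(s + width - 1L)] <- truth[h, s:(s + width - 1L)]
    origin[r] <- h
  }
  list(m = FragmentMatrix(frag), truth = Haplotypes(truth), origin = origin)
}

# brute-force within-cluster kernel objective used as the k-means oracle
kernelObjective <- function(K, labels) {
  tot <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    tot <- tot + sum(diag(K)[idx]) - sum(K[idx, idx]) / length(idx)
  }
  tot
}
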