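## Semi-experimental data generator: k-ploid haplotypes with log-normally
## spaced heterozygous SNPs over a reference region, sampled by short
## paired-end (MiSeq-like) or long erroneous (PacBio-like) reads, emitted
## directly as a read-fragment matrix plus ground truth.

#' Simulator configuration
#'
#' Defaults follow the semi-experimental setup the package is calibrated to:
#' mutations spaced by a log-normal with log-mean 3.03 and log-sd 1.293 over
#' a 10 kb region in short-read mode (mean spacing about 48 bp, about 200
#' variants), or log-mean 6.07 over 100 kb in long-read mode (about 100
#' variants). Short mode draws 2 x 250 bp paired-end fragments with insert
#' length 550 +- 10 bp and substitution error rate 0.1%; long mode draws
#' reads of mean length 9000 bp (log-normal, CV 0.3) with error rate 5%.
#'
#' @param refLength region length in bases.
#' @param ploidy number of haplotypes k (>= 2).
#' @param mode `"short"` or `"long"`.
#' @param logMu,logSigma parameters of the log-normal inter-SNP distance.
#' @param coverage mean fold coverage.
#' @param readLen per-mate read length in short mode.
#' @param insertMu,insertSigma insert-length distribution in short mode.
#' @param meanReadLen mean read length in long mode.
#' @param errorRate per-base substitution error rate at SNP cells.
#' @param vafThreshold VAF threshold mimicked by the generator's SNP set.
#' @param seed integer seed making the whole dataset reproducible.
#' @return a `simConfig` list.
#' @export
simConfig <- function(refLength = 10000L, ploidy = 2L,
                      mode = c("short", "long"),
                      logMu = NULL, logSigma = 1.293,
                      coverage = 30,
                      readLen = 250L, insertMu = 550, insertSigma = 10,
                      meanReadLen = 9000L,
                      errorRate = NULL, vafThreshold = 0.2,
                      seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(logMu)) logMu <- if (mode == "short") 3.03 else 6.07
  if (is.null(errorRate)) errorRate <- if (mode == "short") 0.001 else 0.05
  structure(list(refLength = as.integer(refLength), ploidy = as.integer(ploidy),
                 mode = mode, logMu = logMu, logSigma = logSigma,
                 coverage = coverage, readLen = as.integer(readLen),
                 insertMu = insertMu, insertSigma = insertSigma,
                 meanReadLen = as.integer(meanReadLen),
                 errorRate = errorRate, vafThreshold = vafThreshold,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' @export
print.simConfig <- function(x, ...) {
  cat(sprintf(
    "simConfig: %d bp, ploidy %d, %s reads, %gx, logMu %.3f, logSigma %.3f, error %.4f, seed %d\n",
    x$refLength, x$ploidy, x$mode, x$coverage, x$logMu, x$logSigma,
    x$errorRate, x$seed))
  invisible(x)
}

#' Generate ground-truth haplotypes with log-normal SNP spacing
#'
#' SNP positions are placed by accumulating inter-SNP distances drawn from a
#' log-normal with parameters `logMu` and `logSigma` (each rounded distance
#' is at least 1 bp), truncated at the region end. Sites are biallelic: a
#' reference base is drawn uniformly, one alternative base is drawn from the
#' remaining three, and each haplotype independently carries the reference
#' or the alternative allele; draws leaving the site homozygous are
#' rejected, so every column is heterozygous by construction.
#'
#' @param cfg a [simConfig()].
#' @return list with `haplotypes` (a [Haplotypes-class] over the SNP
#'   columns), `snpPositions` (0-based) and `refAllele` (integer codes).
#' @export
generateHaplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  if (cfg$refLength < 1000L) stop("refLength must be at least 1000")
  if (cfg$ploidy < 2L) stop("ploidy must be at least 2")
  set.seed(cfg$seed)
  ## expected number of gaps, padded; truncation discards the overshoot
  nGuess <- ceiling(cfg$refLength / exp(cfg$logMu + cfg$logSigma^2 / 2)) * 3 + 50
  gaps <- pmax(1, round(stats::rlnorm(nGuess, cfg$logMu, cfg$logSigma)))
  pos <- cumsum(gaps)
  while (pos[length(pos)] < cfg$refLength) {
    gaps <- pmax(1, round(stats::rlnorm(nGuess, cfg$logMu, cfg$logSigma)))
    pos <- c(pos, pos[length(pos)] + cumsum(gaps))
  }
  pos <- pos[pos < cfg$refLength]
  l <- length(pos)
  if (l < 2L) stop("region too short")
  k <- cfg$ploidy
  ref <- sample.int(4L, l, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(1:4, r), 1L), 0L)
  hap <- matrix(0L, k, l)
  for (j in seq_len(l)) {
    repeat {
      pick <- stats::runif(k) < 0.5
      if (any(pick) && !all(pick)) break
    }
    hap[, j] <- ifelse(pick, alt[j], ref[j])
  }
  list(haplotypes = Haplotypes(hap, snpPositions = as.integer(pos)),
       snpPositions = as.integer(pos), refAllele = ref)
}

#' Simulate sequencing reads over known haplotypes
#'
#' The number of fragments is `round(coverage * refLength / basesPerFragment)`
#' with `basesPerFragment = 2 * readLen` (short mode) or `meanReadLen` (long
#' mode). Each fragment samples one haplotype uniformly at random; short
#' fragments cover two `readLen` windows at the ends of an insert of length
#' `N(insertMu, insertSigma)`, long reads cover one log-normally distributed
#' window (mean `meanReadLen`, CV 0.3). Substitution errors hit covered SNP
#' cells i.i.d. at `errorRate`, replacing the true allele by one of the
#' other three bases uniformly. As in the alignment-and-calling pipeline the
#' simulator emulates, the matrix is then restricted to the sites called
#' from the reads themselves (two alleles at VAF >= `cfg$vafThreshold`
#' among covering reads) and filtered to fragments covering at least two
#' called SNPs.
#'
#' @param truth output of [generateHaplotypes()].
#' @param cfg the same [simConfig()].
#' @return list with `fragments` (a [FragmentMatrix-class]), `readOrigins`
#'   (haplotype index per retained fragment), `nFragmentsTotal` (fragment
#'   count before the two-SNP filter), `calledColumns` (indices of the
#'   called sites among the truth columns) and `intervals` (covered base
#'   intervals per retained fragment, for FASTQ export).
#' @export
simulateReads <- function(truth, cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  if (cfg$coverage <= 0) stop("coverage must be positive")
  pos <- truth$snpPositions
  hap <- truth$haplotypes@alleles
  l <- length(pos)
  L <- cfg$refLength
  bpf <- if (cfg$mode == "short") 2L * cfg$readLen else cfg$meanReadLen
  nFrag <- max(1L, round(cfg$coverage * L / bpf))
  origin <- sample.int(nrow(hap), nFrag, replace = TRUE)

  if (cfg$mode == "short") {
    ins <- pmax(2L * cfg$readLen, round(stats::rnorm(nFrag, cfg$insertMu, cfg$insertSigma)))
    ins <- pmin(ins, L)
    start <- floor(stats::runif(nFrag, 0, L - ins + 1))
    w1s <- start; w1e <- start + cfg$readLen            # [s, s+readLen)
    w2s <- start + ins - cfg$readLen; w2e <- start + ins
    covers <- function(i, p) (p >= w1s[i] & p < w1e[i]) | (p >= w2s[i] & p < w2e[i])
    intervals <- cbind(w1s, w1e, w2s, w2e)
  } else {
    sig2 <- log(1 + 0.3^2)
    len <- pmin(L, pmax(50, round(stats::rlnorm(nFrag, log(cfg$meanReadLen) - sig2 / 2,
                                                sqrt(sig2)))))
    start <- floor(stats::runif(nFrag, 0, L - len + 1))
    w1s <- start; w1e <- start + len
    covers <- function(i, p) p >= w1s[i] & p < w1e[i]
    intervals <- cbind(w1s, w1e, w1s, w1s)              # second window empty
  }

  frag <- matrix(.UNCOVERED, nFrag, l)
  for (i in seq_len(nFrag)) {
    j <- which(covers(i, pos))
    if (length(j) == 0L) next
    base <- hap[origin[i], j]
    err <- stats::runif(length(j)) < cfg$errorRate
    if (any(err)) {
      base[err] <- vapply(base[err],
                          function(b) sample(setdiff(1:4, b), 1L), 0L)
    }
    frag[i, j] <- base
  }
  ## the pipeline this emulates calls SNPs from the aligned reads: a site is
  ## kept only when at least two alleles reach the VAF threshold among the
  ## covering reads. Sites covered by reads of a single haplotype (coverage
  ## tapers at region edges) show no variant and are never called.
  pileup <- vapply(1:4, function(b) colSums(frag == b), numeric(l))
  depth <- rowSums(pileup)
  called <- which(depth > 0 &
    rowSums(pileup / pmax(depth, 1L) >= cfg$vafThreshold) >= 2L)
  if (length(called) < 2L) stop("fewer than two callable SNP sites")
  frag <- frag[, called, drop = FALSE]
  keep <- rowSums(frag != .UNCOVERED) >= 2L
  if (!any(keep)) stop("no informative fragments")
  fm <- FragmentMatrix(frag[keep, , drop = FALSE], snpPositions = pos[called],
                       readIds = paste0("sim", which(keep)))
  list(fragments = fm, readOrigins = origin[keep], nFragmentsTotal = nFrag,
       calledColumns = called, intervals = intervals[keep, , drop = FALSE])
}

#' Generate a complete simulated dataset
#'
#' Composes [generateHaplotypes()] and [simulateReads()]; fully reproducible
#' from `cfg$seed`. `truth` is restricted to the SNP sites actually called
#' from the simulated reads (so it aligns column-for-column with
#' `fragments`); the unrestricted ground truth is returned as `fullTruth`.
#'
#' @param cfg a [simConfig()].
#' @return list with `fragments`, `truth` (called sites), `fullTruth` (all
#'   generated variant sites), `readOrigins` and `nFragmentsTotal`.
#' @export
makeDataset <- function(cfg) {
  truth <- generateHaplotypes(cfg)
  reads <- simulateReads(truth, cfg)
  called <- reads$calledColumns
  truthCalled <- list(
    haplotypes = Haplotypes(truth$haplotypes@alleles[, called, drop = FALSE],
                            snpPositions = truth$snpPositions[called]),
    snpPositions = truth$snpPositions[called],
    refAllele = truth$refAllele[called])
  list(fragments = reads$fragments, truth = truthCalled, fullTruth = truth,
       readOrigins = reads$readOrigins,
       nFragmentsTotal = reads$nFragmentsTotal)
}

#' Export simulated reads as FASTQ
#'
#' Writes the full-length simulated reads (bases at SNP positions from the
#' fragment matrix, reference-matching filler elsewhere) with constant
#' quality. Useful for feeding external aligners; the assembly pipeline
#' itself consumes the fragment matrix directly.
#'
#' @param reads output of [simulateReads()].
#' @param truth output of [generateHaplotypes()].
#' @param cfg the [simConfig()] used.
#' @param path output FASTQ path.
#' @export
writeReadsFastq <- function(reads, truth, cfg, path) {
  set.seed(cfg$seed + 7L)
  refSeq <- sample(.BASES, cfg$refLength, replace = TRUE)
  refSeq[truth$snpPositions + 1L] <- .BASES[truth$refAllele]
  fm <- reads$fragments
  recs <- character(0)
  for (i in seq_len(nReads(fm))) {
    iv <- reads$intervals[i, ]
    windows <- list(c(iv[1L], iv[2L]), c(iv[3L], iv[4L]))
    for (w in windows) {
      if (w[2L] <= w[1L]) next
      seq <- refSeq[(w[1L] + 1L):w[2L]]
      j <- which(fm@snpPositions >= w[1L] & fm@snpPositions < w[2L] &
                   fm@fragments[i, ] != .UNCOVERED)
      if (length(j)) seq[fm@snpPositions[j] - w[1L] + 1L] <- .BASES[fm@fragments[i, j]]
      recs <- c(recs, paste0("@", fm@readIds[i]), paste(seq, collapse = ""),
                "+", strrep("I", length(seq)))
    }
  }
  writeLines(recs, path)
}

#' Export simulator ground truth
#'
#' Writes the true haplotypes as FASTA (one record per haplotype over the
#' SNP alleles) and the SNP positions as a minimal VCF.
#'
#' @param truth output of [generateHaplotypes()].
#' @param fastaPath,vcfPath output paths (either may be NULL to skip).
#' @param chrom contig name for the VCF.
#' @export
writeGroundTruth <- function(truth, fastaPath = NULL, vcfPath = NULL,
                             chrom = "ref") {
  if (!is.null(fastaPath)) writeHaplotypesFasta(truth$haplotypes, fastaPath)
  if (!is.null(vcfPath)) {
    hap <- truth$haplotypes@alleles
    counts <- lapply(seq_along(truth$snpPositions), function(j) {
      tab <- table(.BASES[hap[, j]])
      ref <- .BASES[truth$refAllele[j]]
      ord <- order(names(tab) != ref)          # reference allele first
      setNames(as.integer(tab)[ord], names(tab)[ord])
    })
    calls <- new("SnpCallSet", positions = truth$snpPositions,
                 refAllele = truth$refAllele, alleleCounts = counts,
                 vafThreshold = 0.2)
    writeSnpVcf(calls, vcfPath, chrom = chrom)
  }
  invisible(NULL)
}
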