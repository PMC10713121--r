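## Evaluation metrics against known ground truth: correct phasing rate
## (CPR) under the optimal haplotype-to-haplotype mapping, switch error
## rate (SWER) for diploids and its polyploid generalization, the vector
## error rate (VER). The MEC score lives with the assembly engine.

## all permutations of 1..k in lexicographic order
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- .permutations(k - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[p])
  }
  out
}

.hapAlleles <- function(h) {
  if (is(h, "Haplotypes")) h@alleles
  else if (is.character(h)) encodeBases(h)
  else h
}

#' Correct phasing rate
#'
#' Fraction of alleles reconstructed correctly under the best one-to-one
#' mapping between reconstructed and true haplotypes; the mapping is found
#' by exhaustive search over the k! permutations.
#'
#' @param truth,pred k x l [Haplotypes-class] objects (or allele matrices).
#' @return fraction in \[0, 1\]; 1 for a perfect reconstruction (up to row
#'   permutation).
#' @export
cpr <- function(truth, pred) {
  H <- .hapAlleles(truth); P <- .hapAlleles(pred)
  stopifnot(all(dim(H) == dim(P)))
  k <- nrow(H); l <- ncol(H)
  if (k > 8L) stop("use heuristic matching")
  best <- Inf
  for (perm in .permutations(k)) {
    d <- sum(H != P[perm, , drop = FALSE])
    if (d < best) best <- d
  }
  1 - best / (k * l)
}

## per-column permutation track shared by swer and ver: for each column pick
## the permutation of predicted rows best matching the truth; ambiguous
## columns (ties, e.g. homozygous sites) inherit the previous permutation
.permTrack <- function(H, P) {
  k <- nrow(H); l <- ncol(H)
  perms <- .permutations(k)
  track <- integer(l)
  prev <- 1L                                   # identity first
  for (j in seq_len(l)) {
    cost <- vapply(perms, function(pm) sum(H[, j] != P[pm, j]), 0L)
    minc <- min(cost)
    prev <- if (cost[prev] == minc) prev else which.min(cost)
    track[j] <- prev
  }
  track
}

#' Switch error rate (diploid)
#'
#' Fraction of adjacent SNP pairs at which the relative phase of the two
#' reconstructed haplotypes flips with respect to the truth. A globally
#' swapped reconstruction has SWER 0. Predicted alleles absent from the true
#' allele pair count as mismatches under every pairing; columns where both
#' pairings fit equally well (e.g. homozygous truth) inherit the phase of
#' the previous column and never count as switches.
#'
#' @param truth,pred 2 x l [Haplotypes-class] objects (or allele matrices).
#' @return fraction in \[0, 1\] of the l - 1 adjacent pairs.
#' @export
swer <- function(truth, pred) {
  H <- .hapAlleles(truth); P <- .hapAlleles(pred)
  stopifnot(all(dim(H) == dim(P)))
  if (nrow(H) != 2L) stop("swer is defined for diploids; use ver")
  if (ncol(H) < 2L) stop("need at least two SNP columns")
  track <- .permTrack(H, P)
  mean(track[-1L] != track[-length(track)])
}

#' Vector error rate (polyploid switch errors)
#'
#' Generalizes [swer()] to ploidy k: per column the best permutation of the
#' k reconstructed rows is determined and the rate of permutation changes
#' between adjacent columns is reported. Coincides with [swer()] for k = 2.
#'
#' @param truth,pred k x l [Haplotypes-class] objects (or allele matrices).
#' @return fraction in \[0, 1\].
#' @export
ver <- function(truth, pred) {
  H <- .hapAlleles(truth); P <- .hapAlleles(pred)
  stopifnot(all(dim(H) == dim(P)))
  if (nrow(H) > 8L) stop("use heuristic matching")
  if (ncol(H) < 2L) stop("need at least two SNP columns")
  track <- .permTrack(H, P)
  mean(track[-1L] != track[-length(track)])
}

#' Evaluate a reconstruction against ground truth
#'
#' Convenience wrapper computing MEC, CPR and SWER (diploid) or VER
#' (polyploid) in one call. When the reconstruction consists of several
#' independently phased blocks, supply matching lists of truth/prediction
#' pairs (one per block): CPR is then averaged weighted by block length and
#' switch errors are pooled over within-block adjacent pairs, the
#' convention used when methods return fragmented haplotypes.
#'
#' @param truth a [Haplotypes-class], or list of per-block truths.
#' @param pred a [Haplotypes-class], or list of per-block reconstructions.
#' @param fragments optional [FragmentMatrix-class] (or list per block) for
#'   the MEC score.
#' @return list with `cpr`, `swer` (named `ver` semantics for k > 2),
#'   `mec` (NA without fragments) and `blocks`.
#' @export
evaluatePhasing <- function(truth, pred, fragments = NULL) {
  if (!is.list(truth)) truth <- list(truth)
  if (!is.list(pred)) pred <- list(pred)
  stopifnot(length(truth) == length(pred))
  if (!is.null(fragments) && !is.list(fragments)) fragments <- list(fragments)
  ls <- vapply(truth, nSnps, 0L)
  k <- ploidy(truth[[1L]])
  cprs <- mapply(cpr, truth, pred)
  switches <- mapply(function(H, P) {
    if (nSnps(H) < 2L) return(0)
    (if (k == 2L) swer(H, P) else ver(H, P)) * (nSnps(H) - 1L)
  }, truth, pred)
  mecs <- if (is.null(fragments)) NA_real_ else
    sum(mapply(mec, fragments, pred))
  list(cpr = sum(cprs * ls) / sum(ls),
       swer = sum(switches) / max(sum(ls - 1L), 1L),
       mec = mecs, blocks = length(truth))
}
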