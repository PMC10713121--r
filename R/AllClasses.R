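## Central S4 containers. Allele values are stored internally as integer
## codes 0..4 where 0 = position not covered by the read and 1..4 = A,C,G,T.

.BASES <- c("A", "C", "G", "T")
.UNCOVERED <- 0L

#' @import methods
NULL

#' Encode bases as internal integer codes
#'
#' @param x character vector/matrix over A,C,G,T (case-insensitive); anything
#'   else (N, "-", gaps, deletions) maps to the uncovered code 0.
#' @return integer vector/matrix of codes in 0..4.
#' @keywords internal
encodeBases <- function(x) {
  out <- match(toupper(as.character(x)), .BASES, nomatch = 0L)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Decode internal integer codes to bases
#'
#' @param x integer vector/matrix of codes 0..4.
#' @param uncovered character used for code 0 (default `"-"`).
#' @return character vector/matrix over A,C,G,T and `uncovered`.
#' @keywords internal
decodeBases <- function(x, uncovered = "-") {
  out <- c(uncovered, .BASES)[as.integer(x) + 1L]
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' FragmentMatrix: the read-fragment (SNP) matrix
#'
#' An n x l matrix of read observations restricted to heterozygous SNP
#' columns. Entries are integer allele codes (0 = uncovered, 1..4 = A,C,G,T).
#' Rows are read fragments (paired-end mates merged into one fragment), and
#' columns are SNP sites at strictly increasing reference coordinates
#' (0-based).
#'
#' @slot fragments integer matrix, n x l, values in 0..4.
#' @slot readIds character vector of length n.
#' @slot snpPositions integer vector of length l, strictly increasing,
#'   0-based reference coordinates.
#'
#' @seealso [buildFragmentMatrix()], [filterFragments()], [splitBlocks()]
#' @export
setClass("FragmentMatrix",
  representation(
    fragments = "matrix",
    readIds = "character",
    snpPositions = "integer"
  )
)

setValidity("FragmentMatrix", function(object) {
  f <- object@fragments
  msg <- character()
  if (!is.numeric(f)) msg <- c(msg, "fragments must be a numeric/integer matrix")
  if (nrow(f) < 1L) msg <- c(msg, "need at least one fragment (n >= 1)")
  if (ncol(f) < 2L) msg <- c(msg, "need at least two SNP columns (l >= 2)")
  if (any(f < 0L | f > 4L)) msg <- c(msg, "allele codes must lie in 0..4")
  if (length(object@readIds) != nrow(f))
    msg <- c(msg, "readIds length must equal the number of rows")
  if (length(object@snpPositions) != ncol(f))
    msg <- c(msg, "snpPositions length must equal the number of columns")
  if (length(object@snpPositions) > 1L && any(diff(object@snpPositions) <= 0L))
    msg <- c(msg, "snpPositions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentMatrix
#'
#' @param fragments integer matrix of allele codes (0..4) or character matrix
#'   over A,C,G,T with `"-"` (or any non-ACGT symbol) for uncovered cells.
#' @param snpPositions 0-based reference coordinates of the SNP columns.
#' @param readIds optional read identifiers; defaults to `read1..readN`.
#' @return a [FragmentMatrix-class] object.
#' @examples
#' m <- FragmentMatrix(rbind(c("A", "C"), c("A", "-")), snpPositions = c(10, 40))
#' nReads(m)
#' @export
FragmentMatrix <- function(fragments, snpPositions = seq_len(ncol(fragments)) - 1L,
                           readIds = NULL) {
  if (is.character(fragments)) fragments <- encodeBases(fragments)
  storage.mode(fragments) <- "integer"
  if (is.null(readIds)) readIds <- paste0("read", seq_len(nrow(fragments)))
  new("FragmentMatrix", fragments = fragments, readIds = as.character(readIds),
      snpPositions = as.integer(snpPositions))
}

#' Haplotypes: a k x l allele matrix
#'
#' Holds either the ground-truth haplotypes H or a reconstruction. A
#' finalized haplotype matrix contains no uncovered cells.
#'
#' @slot alleles integer matrix, k x l, values in 1..4 (0 permitted only for
#'   unfinalized intermediate objects).
#' @slot snpPositions integer vector of length l (0-based), or length 0 when
#'   coordinates are not tracked.
#' @export
setClass("Haplotypes",
  representation(alleles = "matrix", snpPositions = "integer")
)

setValidity("Haplotypes", function(object) {
  a <- object@alleles
  msg <- character()
  if (nrow(a) < 2L) msg <- c(msg, "ploidy k must be >= 2")
  if (any(a < 0L | a > 4L)) msg <- c(msg, "allele codes must lie in 0..4")
  np <- length(object@snpPositions)
  if (np > 0L && np != ncol(a))
    msg <- c(msg, "snpPositions must be empty or match the number of columns")
  if (length(msg)) msg else TRUE
})

#' Construct a Haplotypes object
#'
#' @param alleles k x l integer codes (1..4) or character matrix over A,C,G,T.
#' @param snpPositions optional 0-based coordinates of the l columns.
#' @return a [Haplotypes-class] object.
#' @export
Haplotypes <- function(alleles, snpPositions = integer(0)) {
  if (is.character(alleles)) alleles <- encodeBases(alleles)
  storage.mode(alleles) <- "integer"
  new("Haplotypes", alleles = alleles, snpPositions = as.integer(snpPositions))
}

#' SnpCallSet: called heterozygous SNP sites
#'
#' @slot positions integer, 0-based reference coordinates, strictly increasing.
#' @slot refAllele integer codes of the (presumed) reference allele per site.
#' @slot alleleCounts list, one named integer vector of allele counts per site
#'   (names among A,C,G,T), restricted to the alleles retained at the site.
#' @slot vafThreshold numeric in (0,1): minimum variant allele frequency.
#' @export
setClass("SnpCallSet",
  representation(
    positions = "integer",
    refAllele = "integer",
    alleleCounts = "list",
    vafThreshold = "numeric"
  )
)

setValidity("SnpCallSet", function(object) {
  msg <- character()
  n <- length(object@positions)
  if (n > 1L && any(diff(object@positions) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@alleleCounts) != n)
    msg <- c(msg, "one allele-count vector per position required")
  if (length(object@refAllele) != n)
    msg <- c(msg, "one reference allele per position required")
  if (object@vafThreshold <= 0 || object@vafThreshold >= 1)
    msg <- c(msg, "vafThreshold must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' PhasingResult: output of the assembly engine
#'
#' @slot haplotypes a [Haplotypes-class] reconstruction.
#' @slot labels integer read-to-haplotype attribution in 1..k.
#' @slot sigma learned n x n read-correlation matrix (unit diagonal, PSD).
#' @slot mec numeric minimum error correction score of the reconstruction.
#' @slot history data.frame with one row per epoch (loss terms and MEC).
#' @slot phaseSets list of integer column index vectors, one per phase set
#'   (a single entry when the haplotypes are fully phased).
#' @export
setClass("PhasingResult",
  representation(
    haplotypes = "Haplotypes",
    labels = "integer",
    sigma = "matrix",
    mec = "numeric",
    history = "data.frame",
    phaseSets = "list"
  )
)

## ---- accessors ----

#' @describeIn FragmentMatrix number of read fragments (rows).
#' @param x,object a FragmentMatrix.
#' @export
nReads <- function(x) nrow(x@fragments)

#' @describeIn FragmentMatrix number of SNP columns.
#' @export
nSnps <- function(x) {
  if (is(x, "Haplotypes")) ncol(x@alleles) else ncol(x@fragments)
}

#' Generic accessor for SNP positions
#' @param x a FragmentMatrix, Haplotypes or SnpCallSet.
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))

#' @rdname snpPositions
#' @export
setMethod("snpPositions", "FragmentMatrix", function(x) x@snpPositions)

#' @rdname snpPositions
#' @export
setMethod("snpPositions", "Haplotypes", function(x) x@snpPositions)

#' @rdname snpPositions
#' @export
setMethod("snpPositions", "SnpCallSet", function(x) x@positions)

#' Read identifiers of a FragmentMatrix
#' @param x a FragmentMatrix.
#' @export
readIds <- function(x) x@readIds

#' Ploidy (number of haplotype rows)
#' @param x a Haplotypes or PhasingResult.
#' @export
ploidy <- function(x) {
  if (is(x, "PhasingResult")) nrow(x@haplotypes@alleles) else nrow(x@alleles)
}

#' @export
#' @describeIn PhasingResult the reconstructed haplotypes.
haplotypes <- function(object) object@haplotypes

#' Cluster labels (read-to-haplotype attribution)
#' @param object a PhasingResult.
#' @export
clusterLabels <- function(object) object@labels

#' Learned read-correlation matrix
#' @param object a PhasingResult.
#' @export
sigmaMatrix <- function(object) object@sigma

#' MEC score stored in a PhasingResult
#' @param object a PhasingResult.
#' @export
mecScore <- function(object) object@mec

setMethod("dim", "FragmentMatrix", function(x) dim(x@fragments))

#' @export
setMethod("as.matrix", "FragmentMatrix", function(x, ...) {
  out <- decodeBases(x@fragments)
  dimnames(out) <- list(x@readIds, x@snpPositions)
  out
})

#' @export
setMethod("as.matrix", "Haplotypes", function(x, ...) decodeBases(x@alleles))

#' Coerce haplotypes to a DNAStringSet
#' @param x a Haplotypes object.
#' @return a [Biostrings::DNAStringSet] with one record per haplotype; any
#'   uncovered cell becomes N.
#' @export
asDNAStringSet <- function(x) {
  stopifnot(is(x, "Haplotypes"))
  seqs <- apply(decodeBases(x@alleles, uncovered = "N"), 1L, paste, collapse = "")
  Biostrings::DNAStringSet(setNames(seqs, paste0("haplotype_", seq_along(seqs))))
}

setMethod("show", "FragmentMatrix", function(object) {
  f <- object@fragments
  cat(sprintf("FragmentMatrix: %d fragments x %d SNPs\n", nrow(f), ncol(f)),
      sprintf("  positions %d..%d (0-based), %.1f%% of cells covered\n",
              object@snpPositions[1L], object@snpPositions[length(object@snpPositions)],
              100 * mean(f != .UNCOVERED)))
})

setMethod("show", "Haplotypes", function(object) {
  cat(sprintf("Haplotypes: ploidy %d, %d SNPs\n",
              nrow(object@alleles), ncol(object@alleles)))
})

setMethod("show", "SnpCallSet", function(object) {
  cat(sprintf("SnpCallSet: %d sites (VAF threshold %.2f)\n",
              length(object@positions), object@vafThreshold))
})

setMethod("show", "PhasingResult", function(object) {
  cat(sprintf("PhasingResult: ploidy %d, %d SNPs, %d reads\n",
              ploidy(object), nSnps(object@haplotypes), length(object@labels)),
      sprintf("  MEC %d, %d phase set(s), %d training epochs\n",
              as.integer(object@mec), length(object@phaseSets),
              nrow(object@history)))
})
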