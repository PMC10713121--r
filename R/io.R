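## Text I/O: the tabular fragment format, minimal VCF export of SNP calls,
## FASTA export of haplotypes, SAM input and YAML (de)serialization of
## configuration lists.

#' Write a fragment matrix in the tabular fragment format
#'
#' One fragment per line: `read_id TAB start_column TAB alleles`, where
#' `start_column` is the 0-based index of the first covered SNP column and
#' `alleles` is the run of bases from the first to the last covered column
#' with `-` marking uncovered cells. A header line `#positions p1,p2,...`
#' records the 0-based reference coordinates of the SNP columns.
#'
#' @param m a [FragmentMatrix-class].
#' @param path output file path.
#' @export
writeFragments <- function(m, path) {
  stopifnot(is(m, "FragmentMatrix"))
  f <- m@fragments
  lines <- c(paste0("#positions ", paste(m@snpPositions, collapse = ",")))
  for (i in seq_len(nrow(f))) {
    j <- which(f[i, ] != .UNCOVERED)
    if (length(j) == 0L) next
    span <- decodeBases(f[i, j[1L]:j[length(j)]])
    lines <- c(lines, paste(m@readIds[i], j[1L] - 1L,
                            paste(span, collapse = ""), sep = "\t"))
  }
  writeLines(lines, path)
}

#' Read a fragment matrix from the tabular fragment format
#'
#' @param path file written by [writeFragments()] (or produced externally in
#'   the same format).
#' @param nSnps number of SNP columns; inferred from the `#positions` header
#'   or, failing that, from the rightmost covered column.
#' @return a [FragmentMatrix-class].
#' @export
readFragments <- function(path, nSnps = NULL) {
  lines <- readLines(path)
  positions <- NULL
  hdr <- grep("^#positions ", lines)
  if (length(hdr)) {
    positions <- as.integer(strsplit(sub("^#positions ", "", lines[hdr[1L]]),
                                     ",")[[1L]])
  }
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no fragments in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  starts <- as.integer(vapply(parts, `[`, "", 2L))
  seqs <- vapply(parts, `[`, "", 3L)
  if (is.null(nSnps)) {
    nSnps <- if (!is.null(positions)) length(positions) else
      max(starts + nchar(seqs))
  }
  f <- matrix(.UNCOVERED, length(lines), nSnps)
  for (i in seq_along(lines)) {
    codes <- encodeBases(strsplit(seqs[i], "")[[1L]])
    f[i, starts[i] + seq_along(codes)] <- codes
  }
  if (is.null(positions)) positions <- seq_len(nSnps) - 1L
  FragmentMatrix(f, snpPositions = positions, readIds = ids)
}

#' Export called SNP sites as a minimal VCF
#'
#' Writes CHROM, POS (1-based), REF (majority allele), ALT (retained
#' alternative alleles) and an INFO field carrying the alternative-allele
#' VAFs.
#'
#' @param calls a [SnpCallSet-class].
#' @param path output path.
#' @param chrom chromosome/contig name to write (default "ref").
#' @export
writeSnpVcf <- function(calls, path, chrom = "ref") {
  stopifnot(is(calls, "SnpCallSet"))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=CorrHap (VAF threshold %.3f)", calls@vafThreshold),
              "##INFO=<ID=VAF,Number=A,Type=Float,Description=\"Variant allele frequency\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- vapply(seq_along(calls@positions), function(i) {
    cnt <- calls@alleleCounts[[i]]
    ref <- .BASES[calls@refAllele[i]]
    alt <- setdiff(names(cnt), ref)
    vaf <- cnt[alt] / sum(cnt)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%s",
            chrom, calls@positions[i] + 1L, ref,
            paste(alt, collapse = ","),
            paste(sprintf("%.4f", vaf), collapse = ","))
  }, "")
  writeLines(c(header, rows), path)
}

#' Write haplotypes as FASTA over the SNP alleles
#'
#' @param h a [Haplotypes-class].
#' @param path output path.
#' @export
writeHaplotypesFasta <- function(h, path) {
  Biostrings::writeXStringSet(asDNAStringSet(h), filepath = path)
}

#' Read haplotypes from a FASTA of SNP alleles
#'
#' @param path FASTA file with one record per haplotype, all of equal length.
#' @return a [Haplotypes-class].
#' @export
readHaplotypesFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) stop("haplotype records differ in length")
  Haplotypes(do.call(rbind, strsplit(as.character(ss), "")))
}

#' Build a fragment matrix from a coordinate-sorted SAM/BAM file
#'
#' Alignments are laid onto reference coordinates (deletions become gaps,
#' insertions and clips are removed) and their bases at the called SNP
#' positions are collected; mates sharing a query name are merged into one
#' fragment.
#'
#' @param file path to a SAM or BAM file.
#' @param calls a [SnpCallSet-class] in the same (0-based) coordinate system.
#' @return a [FragmentMatrix-class].
#' @export
readFragmentsSam <- function(file, calls) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  gal <- GenomicAlignments::readGAlignments(
    file, param = Rsamtools::ScanBamParam(what = c("qname", "seq")))
  if (length(gal) == 0L) stop("no alignments in ", file)
  laid <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal))
  buildFragmentMatrix(
    data.frame(readId = S4Vectors::mcols(gal)$qname,
               start = BiocGenerics::start(gal) - 1L,   # SAM is 1-based
               seq = as.character(laid)),
    calls)
}

#' Write a configuration list as YAML
#' @param cfg a configuration list (e.g. from [simConfig()], [trainConfig()]
#'   or [encoderConfig()]).
#' @param path output path.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(c(list(.class = class(cfg)[1L]), unclass(cfg)), path)
}

#' Read a configuration list written by [writeConfig()]
#' @param path YAML file.
#' @return the configuration list with its class restored.
#' @export
readConfig <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  structure(x, class = cls)
}
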