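Package: CorrHap
Title: Haplotype Assembly from Learned Pairwise Read Correlations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reference-guided haplotype assembly for diploid and polyploid
    genomes. Sequencing reads restricted to heterozygous SNP positions are
    embedded by a convolutional encoder, pairwise read correlations are
    learned by a transformer encoder trained with a contrastive loss against
    the current read-to-haplotype attribution, and reads are clustered by
    kernel k-means using the learned correlation matrix as the kernel;
    cluster consensus sequences yield the reconstructed haplotypes. Includes
    a semi-experimental data simulator (log-normal SNP spacing, short
    paired-end or long erroneous reads), the standard evaluation metrics
    (MEC, correct phasing rate, switch/vector error rate) and overlapping
    block reconstruction with stitching for long SNP ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
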