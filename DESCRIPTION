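Package: orfscout
Title: Reference-Guided Open Reading Frame Assignment for Transcript Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns open reading frames (ORFs) to known and novel gene
    transcripts by maximizing protein-level similarity to annotated reference
    ORFs at the same locus. Instead of sequence alignment, candidate ORFs are
    scored by interval pseudo-alignment of exon chains: the in-frame length
    (IL, the number of coding bases shared with a reference in the same
    reading frame) and its fraction of the reference coding length (ILPI)
    drive a successive selection cascade. Includes GTF/GFF3 and FASTA input
    and output with exact coordinate and phase semantics, same-strand
    bundling of overlapping reference coding regions, annotation-comparison
    reports, protein percent-identity via pairwise alignment, a synthetic
    locus simulator with ground-truth ORFs, and a brute-force ORF enumeration
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
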