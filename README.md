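# orfscout

Reference-guided assignment of open reading frames (ORFs) to gene
transcripts by interval pseudo-alignment.

## The problem

Transcriptome assemblies from RNA-seq experiments (StringTie-style GTFs)
and even curated annotation databases contain large numbers of transcripts
at protein-coding loci with no annotated coding region, or with an ORF that
differs needlessly from the canonical protein of the gene. Proteins
produced by different isoforms of the same gene should be as similar as
possible, so the natural way to annotate a novel transcript is to pick,
among all ORFs it can accommodate, the one most similar to the reference
ORFs at that locus.

orfscout does this without any sequence alignment. Query exon structures
and reference CDS chains are compared as interval chains, and reading
frames are tracked across exon junctions. For a candidate ORF *c* and a
reference ORF *r* the package computes:

* **IL** (in-frame length) — the number of coding bases of *c* belonging
  to codons fully shared with *r* in the same reading frame (these codons
  encode identical residues); stop codons are excluded.
* **ILPI** (in-frame length percent identity) — `IL / length(r)`, with the
  reference coding length also excluding its stop codon. ILPI is an
  alignment-free proxy for protein percent identity.
* **length** — the candidate's coding length.

Candidate ORFs are generated per locus "bundle" (overlapping reference CDS
chains plus the query transcripts that overlap them, strand-specific),
anchored on query/reference interval intersections: each in-frame stop
reachable from a shared region is extended to, and the optimal start codon
for that stop maximizes the number of reference-matching codons. The best
candidate is then chosen by a successive cascade — by default max ILPI,
then max IL, then max length (`mode = "ilpi"`); `mode = "il"` swaps the
first two criteria and will accept more novel sequence when that increases
the number of in-frame matches. The selected ORF is guaranteed to have the
highest ILPI among every valid ORF the transcript can accommodate.

## Worked example

Everything below is generated in code — `make_locus()` simulates a multi-
exon gene with a known canonical ORF and derives splice variants from it:

```r
library(orfscout)

loc <- make_locus(seed = 5, n_isoforms = 3)   # canonical + 2 splice variants
loc$reference
#> <transcript_record ref1 (gene gene1) chrS(+) 4 exon(s), CDS 213 bp>

# hide the isoform ORFs and re-derive them from the canonical reference
queries <- lapply(loc$isoforms, function(r)
  transcript_record(r$transcript_id, r$gene_id, r$exons))
ann <- annotate_orfs(list(loc$reference), queries, loc$genome)
ann$stats[, c("transcript_id", "IL", "ILPI", "orf_length", "novel_bases")]
#>   transcript_id  IL      ILPI orf_length novel_bases
#> 1          iso1 210 1.0000000        210           0
#> 2          iso2 126 0.6000000        129           0
#> 3          iso3 195 0.9285714        246          51
```

`iso1` is the canonical transcript and gets back exactly the canonical ORF
(ILPI 1). `iso2` carries an alternative 3' splice site that shifts frame:
the best ORF it can accommodate conserves 126 of the 210 reference coding
bases (ILPI 0.6). `iso3` retains an intron: its ORF keeps 93% of the
reference codons plus 51 novel coding bases from the retained intron.
ILPI tracks alignment-based identity closely:

```r
p  <- translate_cds(spliced_sequence(ann$records[[2]]$cds, loc$genome))
pr <- translate_cds(spliced_sequence(loc$reference$cds, loc$genome))
protein_identity(p, pr)$percent_identity
#> [1] 0.6
```

From the shell, the same engine drives a conventional three-file workflow
(the launcher is installed under `inst/cli/`):

```sh
orfscout annotate --reference ref.gtf --query assembly.gtf --genome genome.fa \
  --output annotated.gtf --stats scores.tsv
orfscout compare --annotated annotated.gtf --original refseq.gtf --canonical canonical.gtf
```

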