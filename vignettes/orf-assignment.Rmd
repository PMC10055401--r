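---
title: "Reference-guided ORF assignment by interval pseudo-alignment"
author: "orfscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided ORF assignment by interval pseudo-alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfscout)
```

## The model

orfscout assigns an open reading frame to a query transcript by choosing,
among all valid ORFs the transcript can accommodate, the one most similar
to a set of reference ORFs at the same locus. The underlying assumption is
biological: alternative isoforms of a gene should produce proteins as
similar as possible, so when a novel transcript is observed at a coding
locus, the ORF most concordant with the annotated proteins is the best
hypothesis. The method therefore does *not* find ORFs de novo — a query
with no same-strand overlap with any reference CDS is deliberately left
non-coding, which also makes the method usable as a noise filter for
assembled transcripts that cannot accommodate any reference-like ORF.

Similarity is measured without sequence alignment. All structures are
chains of genomic intervals (0-based, half-open internally). For a
candidate ORF $c$ and a reference ORF $r$:

* $IL(c, r)$ — *in-frame length*: 3 times the number of codons of $c$
  whose three bases map to three consecutive coding positions of $r$
  starting on a codon boundary. Such codons encode identical residues.
  Stop codons of both chains are excluded.
* $ILPI(c, r) = IL(c, r) / L_r$, where $L_r$ is the reference coding
  length excluding its stop codon.
* $length(c)$ — coding length of $c$, stop excluded.

A valid ORF begins with a start codon (default `ATG`), ends at the first
in-frame stop codon (`TAA`, `TAG`, `TGA`), contains no internal in-frame
stop and no codon with an ambiguous base.

### Counting IL in whole codons

IL is counted as $3\times$(fully shared codons) rather than raw shared
bases. Raw base counting over partial interval overlaps would produce IL
values that are not multiples of 3 and — worse — would drop codons that
span an exon junction present in both chains, so that a candidate
identical to a multi-exon reference would score ILPI < 1. Whole-codon
counting makes "identical chain $\Leftrightarrow$ ILPI = 1" exact and
corresponds directly to matching residues. Implementation-wise, shared
intervals are merged into runs contiguous in *both* chains' coding
coordinates before codons are counted, so codons split across shared
junctions count while codons straddling a junction present in only one
chain do not.

## The search

1. **Bundling.** References (only their CDS chains are used; non-coding
   exons of reference transcripts are ignored, which limits damage from
   readthrough annotations) are swept left-to-right per (seqid, strand);
   a reference joins the open bundle while its CDS span overlaps the
   bundle's growing span. Queries attach to every bundle whose span their
   exon span overlaps on the same strand. Bundles are independent work
   units: `--threads` distributes bundles over workers with
   order-preserving collection, so output is byte-identical at any thread
   count. With `group_by_gene`, references are partitioned by gene id
   first, so genuinely overlapping but unrelated genes are never compared.
2. **Candidate generation.** For each (reference, reading frame, in-frame
   stop codon) of the query's spliced sequence, the optimal start is the
   start codon upstream of the stop (with no intervening in-frame stop or
   ambiguous codon) that maximizes the number of reference-matching codons
   of the resulting ORF. Ties are resolved by mode: ILPI mode takes the
   3'-most tied start (least novel sequence), IL mode the 5'-most (longest
   ORF). Candidates with identical genomic chains are deduplicated.
3. **Scoring and selection.** Each candidate is scored against *every*
   reference in the bundle and keeps the best score under the mode's
   cascade (the attaining reference is recorded). Candidates sharing no
   in-frame codon with any reference (IL = 0) are discarded. The cascade
   is: ILPI mode — max ILPI, then max IL, then max length; IL mode — max
   IL, then max ILPI, then max length. Any remaining tie goes to the
   5'-most transcript-space start, which makes the whole procedure
   deterministic. A query that joined several bundles is searched in each
   and the single best-scoring candidate wins overall.

ILPI values are compared exactly by integer cross-multiplication
($IL_a L_{r_b}$ vs $IL_b L_{r_a}$), never by floating-point division, so
tie detection cannot depend on rounding.

Two selection modes exist because they answer different questions: ILPI
mode maximizes conservation of the reference protein and admits as little
novel sequence as possible; IL mode will extend into novel sequence
whenever that adds in-frame matches, which can recover longer variants at
the cost of extra unsupported coding sequence. For any query, the ILPI of
the ILPI-mode selection is $\ge$ that of the IL-mode selection, and the IL
of the IL-mode selection is $\ge$ that of the ILPI-mode selection; the
ILPI-mode winner's ILPI also dominates every other valid ORF of the
transcript — both properties are asserted by the test suite.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `mode` | `"ilpi"` | selection cascade (see above). ILPI mode is the default because its output carries the conservation guarantee. |
| `start_codons` | `ATG` | permitted start codons; extendable for organisms using alternative starts. |
| `stop_codons` | `TAA, TAG, TGA` | the standard-code stops. |
| `min_orf_length` | 1 codon | minimum coding length (start included, stop excluded). Independently of this floor, single-codon ORFs (start immediately followed by stop) are never reported. |
| `group_by_gene` | off | never mix gene ids within a bundle. |

Degenerate and edge inputs: soft-masked (lowercase) genome bases are
uppercased on input; any codon containing `N` matches neither codon set
and invalidates ORFs that span it; selenoprotein-style stop-codon
readthrough is not modeled. Reference records whose CDS fails the
valid-ORF check are dropped with a warning before the search.

## File semantics

GTF and GFF3 coordinates (1-based, inclusive) are converted to the
internal convention at the file boundary only. Internal CDS chains always
*include* the stop codon; on GTF output the final three coding bases are
emitted as `stop_codon` features and excluded from `CDS` lines (GENCODE
dialect), while GFF3 output keeps the stop inside the CDS (NCBI dialect).
`stop_codon` features in input GTFs are merged back into the CDS chain, so
read → write → read is coordinate-identical. CDS phase is recomputed on
output by 5'→3' accumulation in transcript orientation. Records carrying
CDS but no exon features (the usual shape of a CDS-only reference load)
get exons synthesized from the CDS chain; reference CDS records that do
not form a valid ORF in the genome (no start, no stop, internal stop,
length not divisible by three) are dropped rather than completed, since
guessing a completion would manufacture reference signal that is not in
the input.

`clean_reference()` reproduces the standard preparation of a reference
set: invalid ORFs are removed with per-record reasons, and both members of
any pair of genomically overlapping CDS chains labeled with different gene
ids are removed (such loci have ambiguous guidance).

## Protein-level comparison

`protein_identity()` aligns two proteins with BLOSUM62 and affine gap
penalties (open 10, extend 1 — the EMBOSS default family) and reports
matches / alignment columns. The default is a *global* alignment: the
quantity ILPI approximates is how much of each protein is conserved, and a
local alignment of two same-locus variants would simply re-find the shared
core at ~100% identity regardless of how much of the protein is missing.
A classic Smith–Waterman local mode (`type = "local"`) is available and is
validated against an independent Gotoh dynamic-programming implementation
in the tests.

## The synthetic locus generator

`make_locus()` builds a 3–10 kb random sequence containing one multi-exon
gene (3–6 exons, 3–30 codons of coding sequence per exon, uniform base
composition, no `N` by default) with 5'/3' UTRs and a guaranteed-valid
canonical ORF; exon boundaries may split codons, so CDS phase is
exercised. Isoforms apply one splice event each — exon skipping,
alternative first exon, alternative 3' splice site, or intron retention —
and each isoform's ground-truth ORF is computed by the exhaustive oracle
(`oracle_best_orf()`), which enumerates every valid ORF of the spliced
sequence by brute force and applies the documented selection semantics
through an independent per-position implementation. With
`preserve_cds = TRUE` events touch only UTRs, producing isoforms that all
contain the canonical CDS chain. About half of generated loci are mirrored
to the minus strand. Generation is deterministic in its seed, down to
byte-identical FASTA/GTF fixture files.

What the generator deliberately does **not** emulate: realistic splice-site
motifs, codon usage and GC structure, sequencing or assembly errors,
expression levels, multi-gene loci and readthrough, and population
variation. Passing tests on these fixtures therefore demonstrate the
correctness of the interval arithmetic, frame tracking and selection logic
under arbitrary exon structures — not calibrated performance on real
assemblies, where reference completeness and annotation quality dominate.

## Verification design and problem sizes

The test suite checks the search against the oracle on 500 random loci in
both modes (score triples must agree exactly), self-annotation identity on
merged multi-locus annotations, perfect recovery of hidden ORFs whose
chain is contained in every isoform, non-decreasing mean ILPI against
held-out truth as the guide fraction grows through 25/50/75% of a 4-guide
pool (random nested subsets — a fixed inclusion order would degenerately
score the first guide perfectly), Spearman ρ ≥ 0.9 between ILPI and
global alignment identity over 200+ ORF pairs spanning ILPI 0–1 (random
unrelated ORFs all tie at ILPI 0, so each transcript contributes one
zero-overlap control rather than its full mass of spurious ORFs), the
ILPI-dominance guarantee against full enumeration, strand-mirror symmetry
on 50 loci, exact annotation round trips, thread-count invariance of
output bytes, and sweep bundling against brute-force connected components
on 100 random interval sets. These sizes keep the whole suite around two
minutes on one CPU while exercising every code path; `scripts/acceptance.R`
re-runs the same designs under a caller-supplied seed.

## Known limitations

* No de novo mode: queries without same-strand reference CDS overlap are
  returned non-coding by design.
* Aggregation over multiple references takes the per-candidate maximum;
  no weighting by reference quality or expression is attempted.
* The cross-bundle winner for a readthrough query spanning several loci is
  simply the best-scoring candidate across its bundles; no readthrough
  detection is performed.
* Stop-codon readthrough (selenoproteins), non-standard genetic codes and
  polycistronic transcripts are out of scope.
* Bundle sweeping assumes inputs sorted by (seqid, CDS start); unsorted
  input is re-sorted with a warning.
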