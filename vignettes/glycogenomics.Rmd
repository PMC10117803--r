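---
title: "Comparative glycogenomics of giant-virus fibril glycosylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative glycogenomics of giant-virus fibril glycosylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscan)
```

## The problem

Giant viruses of the *Megavirinae* subfamily carry a layer of glycosylated
fibrils around their capsids, and — unusually for eukaryotic viruses —
encode their own machinery to build the sugars: clusters of six to over
thirty *glycogenes* covering nucleotide-sugar biosynthetic pathways
(UDP-l-rhamnose, UDP-d-GlcNAc, viosamine, quinovosamine, bacillosamine and
relatives) plus the glycosyltransferases that assemble the glycans. The
comparative question is phyletic: which genomes carry which enzymes, how
conserved is each, how are the genes organized on the genome, and are the
clusters compositionally foreign (GC-shifted) or ancient residents?

`glycoscan` implements that comparison as a tested pipeline:

1. **Translated search** — each query protein is aligned against the
   stop-to-stop ORFs of each genome's six-frame translation, a
   deterministic re-implementation of what a tblastn search measures.
2. **Conservation score** — the best raw alignment score is divided by the
   query's self-alignment score ("score/autoscore"), giving a value in
   [0, 1]: 1 for an exact copy, 0 for no qualifying hit.
3. **Phyletic profile** — the N proteins x M genomes score matrix,
   exported as TSV and drawn as a blue-to-red heatmap.
4. **Cluster delineation** — glycogene clusters from ordered annotations,
   by contiguity with gap bridging and by helicase/thioredoxin-like anchor
   genes.
5. **Site audits** — catalytic residues mapped through a precomputed MSA,
   with loss-of-function substitutions flagged.
6. **Pathway calls** — per-genome completeness of declared enzyme-step
   chains (complete / partial / absent, with impaired steps).
7. **GC comparison** — glycogene GC content against seven core marker
   genes, with a Mann–Whitney test.
8. **Synthetic genomes** — a seeded simulator that implants diverged
   ortholog clusters with full ground truth, so every stage is validated
   end to end without downloads.

## The conservation score

For query $q$ and genome $g$,

$$C(q, g) = \frac{\max_{o \in \mathrm{ORFs}(g)} S(q, o)}{S(q, q)}$$

where $S$ is the optimal Smith–Waterman local alignment score under
BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $k$ costs
$11 + k$), and $S(q,q)$ is the ungapped sum of diagonal matrix entries
over the query. Because BLOSUM62 is diagonal-dominant (each diagonal
entry is the maximum of its row), no alignment can outscore the identity
alignment, so $C \in [0, 1]$; the package asserts this at run time and
treats a violation under a diagonal-dominant scheme as an error.

Raw scores, not bit scores, are used on both sides of the ratio: the
ratio is invariant to the affine rescaling that bit scoring applies, and
raw scores keep the arithmetic exact. This is a deliberate deviation
from BLAST's reported units and is the reason replicated identity
percentages for published ortholog pairs can differ by a point or two
from table values produced with unstated BLAST parameterizations.

### ORF definition

ORFs are maximal stop-free stretches of each of the six frames — no start
codon required — closed by a stop codon in their frame; a stretch running
into the end of the sequence never terminates and is not reported. This
is the surrogate for a translated search's implicit scan: local alignment
scores translated stretches, not annotated genes. The minimum peptide
length defaults to 30 aa, and the minimum accepted alignment score to a
raw 40, which in practice suppresses spurious matches from the many
short ORFs an AT-rich genome produces. Coordinates are 0-based half-open
on the forward strand internally, 1-based inclusive in written tables.
Translation uses the standard genetic code; any codon containing N is
rendered X (even when the ambiguity would be synonymous — a deliberate,
simple rule), and X scores through the matrix's X row.

### Alignment kernel

The affine-gap Smith–Waterman (Gotoh) kernel is compiled code with a
fixed traceback tie-break (diagonal, then up, then left; best cell =
first maximum in scan order), so alignments are deterministic. Two
independent routes check it: a plain pure-R dynamic program (the
brute-force oracle, exhaustively on short pairs) and an established
aligner on longer pairs. Identity is computed over all aligned columns,
gap columns included in the denominator; coverage is the aligned query
span over query length.

## Cluster delineation

Contiguity calls find maximal runs of glyco-flagged genes, bridging
interior runs of at most `max_gap` non-glyco genes and trimming ends to
glyco genes; single genes are reported as singletons. `max_gap = 3` is
calibrated to the published clusters: the largest interior non-glyco run
inside one (the permease/thioredoxin/hypothetical stretch in the
*Cotonvirus* cluster) is exactly three genes. The glyco flag derives
from a declared class-to-flag map (sugar-pathway and transfer enzyme
classes are glyco; hypothetical, papain-like, GMC-oxidoreductase and
other unrelated classes are not) with per-gene overrides, e.g. the
*Tupanvirus* UDP-glucose 6-dehydrogenase, an oxidoreductase by class but
a pathway enzyme by role.

Anchor calls return the genes strictly between a unique upstream and
downstream anchor class (helicase / thioredoxin-like), the conserved
flanking arrangement of these regions in most clades. The *Tupanvirus*
table is packaged but excluded from boundary validation: its published
region ends in non-glyco genes, which the trim rule by design does not
include, so the trimmed call (25 genes) is knowingly shorter than the
published full region.

## Site audits and pathway calls

Audits consume a precomputed aligned FASTA — building structural
alignments is out of scope — and map 1-based ungapped reference positions
to alignment columns by counting non-gap reference characters. A site's
status is exact: only residues listed as expected count as conserved
(D is not E), and only listed loss substitutions (e.g. the
aspartate-to-asparagine change that inactivates the UDP-GlcNAc
4,6-dehydratase) raise a loss flag. The packaged alignments are
synthetic reconstructions (the published ones exist only as figures)
that preserve exactly the stated correspondences; they are labelled
`synthetic` in their filenames and only those correspondences are
asserted.

A pathway is an ordered list of enzyme steps, each supported by one or
more reference queries combined by max — mirroring the practice of
scoring against the closest characterized homolog. A step is *present*
when its best conservation reaches the threshold and no attached audit
flags a loss, *impaired* when conserved but loss-flagged, *absent*
otherwise; a genome's call is *complete* / *partial* / *absent*
accordingly. The packaged library declares seven pathways (UDP-l-Rha,
UDP-d-GlcNAc, UDP-d-2OMeVio4NAc, UDP-l-Qui2NAc via Rha2NAc,
UDP-d-diNAcBac, UDP-d-Qui2N/Fuc2N, UDP-d-GlcA). Two notes: the
methylation step of the viosamine pathway is included without ordering
semantics (whether it acts on the UDP-sugar or the polymerized glycan is
experimentally open), and the GlcNAc pathway is flagged host-redundant
in metadata but called identically.

The presence threshold defaults to 0.3. The published analysis used
expert judgment rather than a stated cutoff; 0.3 sits well below the
score an ortholog at 40% amino-acid divergence retains (about 0.5 in
the simulations below) and well above random-ORF background (below 0.1
with the score floor), and step status is monotone in the threshold, so
moderate changes move calls predictably. Treat it as a tunable and sweep
it when in doubt.

## The synthetic-data generator

`build_genome()` reverse-translates query peptides (uniform synonymous
codons, one appended stop), mutates them to a requested amino-acid
divergence (each position independently, replacement uniform over the 19
other residues), and implants them in order — on either strand — into
random intergenic DNA at a target GC fraction (default 0.25, the AT-rich
regime of these genomes), with at least 50 bp spacing and a
`TTAATTAATTAA` cassette flanking every implant. That cassette is
revcomp-palindromic and contains stop codons in all six frames, so ORF
extraction cannot fuse adjacent genes; the CDS round-trip is verified in
tests rather than trusted. Decoy genes (random 30–80 aa peptides) are
placed inside and outside the cluster, and a machine-readable truth
table records every implant's coordinates, strand, realized peptide and
realized divergence, plus any implanted catalytic point mutations. One
integer seed drives all sampling.

What the generator deliberately does not emulate: matrix-biased
substitution processes (uniform substitution keeps the divergence-score
relationship monotone and analyzable), indels, codon-usage bias, and
gene-density patterns of real genomes. Passing tests therefore
demonstrate correctness of the pipeline's computations and calibration
under a clean substitution model — not performance on real genomes with
frameshifts, splicing or compositional bias.

## Numerical and design choices

* **Tie-breaking**: equal-scoring best hits resolve to the smaller
  forward-strand start, then forward strand over reverse; alignment
  traceback prefers diagonal, then up, then left. Determinism is tested
  (byte-identical exports).
* **Heatmaps**: rendered with `pheatmap`; when clustering is enabled it
  is hierarchical with Euclidean distance and complete linkage (the
  tool's defaults), but clustering is off by default so curated,
  pathway-grouped gene orders can be reproduced. A sidecar TSV of the
  final row/column order is always written so ordering is testable
  without parsing images.
* **Matrix serialization**: four decimals, exact round-trip at that
  precision; ragged files are rejected on import.
* **Degenerate inputs**: genomes with no qualifying ORFs give zero
  columns with a warning; empty ORF lists give conservation 0 with a
  warning; gene groups of size one degrade the GC report to descriptive
  statistics with a warning; all-N sequences are an error for GC.
* **GC test**: the published comparison is visual; the two-sided
  Mann–Whitney test here is a quantitative extension, labelled as such.

## Problem sizes used in validation

The packaged validation exercises, chosen as realistic for multi-kb
glycogene regions while keeping the suite quick: 1000 short pairs for
the oracle equivalence; 30 replicates x 4 divergence levels (0, 0.2,
0.4, 0.6) of a 200-aa query in 20 kb genomes for score decay; 50 seeded
15 kb genomes with 4-gene clusters for detection (conservation > 0.3 at
divergence <= 0.4) and exact boundary recovery; 200 seeded MSAs for
loss-flag detection with zero false flags; a 10-genome panel for
complete/partial/absent recovery; and n = 20 per group, 1 kb genes for
GC calibration (matched groups within 0.02; a 0.25-vs-0.45 shift
detected at p < 0.05). The analysis scripts under `analysis/` run a
seven-genome, 30 kb-per-genome panel through every stage.

## Known limitations

* Identity replication for published ortholog pairs depends on sequences
  cited by accession; without them the check cannot run, and even with
  them a 1–2 point difference from published tables is expected given
  unstated search parameterizations.
* The conservation score is a homology signal, not an activity call;
  site audits temper it only at positions a spec declares.
* Anchor delineation requires single-copy anchors and reports nothing
  when an anchor is missing, by design.
* No E-values, composition adjustment, frameshift-aware alignment or HSP
  chaining; genomes beyond several hundred kb are better served by the
  optional seed prefilter or an external search tool, with this package
  consuming the hits.
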