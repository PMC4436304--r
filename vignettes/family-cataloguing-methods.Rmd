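---
title: "Cataloguing a transcription-factor family and tracking homoeolog evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing a transcription-factor family and tracking homoeolog evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofamcat)
```

## The problem

Allotetraploid cotton carries two diverged diploid genomes (A and D), and
every gene family exists in multiple, partially redundant annotations:
two independent annotations of the D-genome diploid, one of the A-genome
diploid, tetraploid unigene and contig assemblies, and cloned mRNAs.
Cataloguing a family such as the basic/helix-loop-helix (bHLH)
transcription factors therefore means answering four questions in order:

1. **Which proteins carry the domain?**  Candidates are found by local
   alignment against a probe set (one representative domain per known
   subfamily) and accepted only if they satisfy two rules: at least two
   continuous sub-regions among *basic*, *helix1* and *helix2*, and more
   than 60% of the consensus residues of plant bHLHs.
2. **Which entries are the same gene?**  Copies of one gene reappear
   across annotation sources as alleles and homoeologs.  Leaf-to-leaf
   branch lengths (BL) on an alignment guide tree classify each pair:
   BL < 0.03 alleles, 0.03–0.15 orthologs of the two genomes, > 0.15
   distinct paralogs.  Single-linkage clusters at the 0.15 cut are the
   orthologous groups; one representative per group gets a reference code
   (`GobHLH001`, `GobHLH002`, ...).
3. **How do the genes partition into subfamilies?**  Trees are built by
   neighbour joining (with a 1000-replicate bootstrap), maximum parsimony,
   and maximum likelihood.  A clade becomes a subfamily only when its NJ
   bootstrap exceeds 88% *and* the bipartition also appears in at least
   one of the other two methods' trees; names propagate from anchor
   sequences of known subfamily.
4. **What happened to the doubled copies?**  For homoeologous pairs the
   package assigns genome origin (nearest diploid ortholog), maps
   exon–intron structure (GT..AG splice constraint), and detects in-frame
   indels, (GAA)~n~ SSR tract-length differences, and large intronic
   insertions flanked by direct terminal repeats — the LTR-retrotransposon
   hallmark.  Relative transcript levels come from qRT-PCR Ct tables with
   two internal-standard genes.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `allele_thr` | 0.03 | substitutions/site (BL) | allele vs ortholog boundary; strict `<` |
| `ortholog_thr` | 0.15 | substitutions/site (BL) | ortholog vs paralog boundary; closed (0.15 is still ortholog) |
| `consensus_thr` | 0.60 | fraction | consensus-residue rule; strict `>` |
| `min_support` | 88 | % bootstrap | subfamily rule; strict `>` |
| `bootstrap_reps` | 1000 | replicates | NJ bootstrap |
| `min_score` | 60 | alignment score | probe-hit cut-off (a config knob, not a biological constant) |
| `min_intron` | 40 | nt | shortest legal intron in gene models |
| `min_insert` | 500 | nt | gap run treated as an insertion |
| `min_tr_len`, `min_tr_identity` | 100 nt, 0.85 | — | direct-terminal-repeat evidence for the LTR call |

Boundary conventions follow the wording of the underlying rules: "over
60%" and ">88%" are strict inequalities, "0.03 to 0.15" is a closed
ortholog band.

## Design choices in the open points

**BL as patristic distance.**  The guide tree's "branch length between
two sequences" is read as the leaf-to-leaf patristic distance.  The guide
tree itself is NJ on pairwise p-distances: a full progressive multiple
alignment would add cost but no information here, because only the BL
matrix is consumed downstream.  When all inputs are equal-length,
substitution-only sequences (as generator output is), distances are exact
Hamming fractions; otherwise pairwise global alignments supply them.

**Local alignment instead of BLAST.**  The probe screen needs only the
hit footprint, never E-values, so exact Smith–Waterman (BLOSUM62, gap
open 11 / extend 1 — the BLAST protein defaults) replaces the heuristic.
Truncated hits are padded out to the probe's domain frame so validation
always sees full-width candidates.

**Consensus-fraction denominator.**  Whether the 60% rule counts all
consensus columns or only those a truncated candidate covers is
ambiguous; this package counts the columns inside the candidate's aligned
span (internal gaps still count against it).  Genome annotations truncate
termini often enough that the alternative would reject genuine domains
for reasons unrelated to domain identity.

**"Continuous sub-region".**  Operationalised as ≥80% of the sub-region's
columns occupied with no internal gap run longer than 2 columns, so a
single-residue alignment jitter cannot flip a verdict.

**Simplified ML.**  The maximum-likelihood tree uses the Poisson
amino-acid model (equal rates, uniform frequencies) rather than a
JTT/WAG-style matrix.  The classification rule uses ML only as a
concordance check on topology, and the Poisson model keeps the likelihood
closed-form-checkable: the two-taxon MLE satisfies
$\hat p = \frac{19}{20}\left(1 - e^{-20t/19}\right)$, which the test
suite inverts analytically.  Branch lengths are optimised one at a time
with inside/outside partials, under which each update is exact given the
rest of the tree — the log-likelihood never decreases.  NNI candidates
are screened at current branch lengths and re-optimised on acceptance.

**"Two methods".**  "Supported by at least two methods" is read as: the
clade is in the NJ tree (with support) *plus* at least one of MP/ML — NJ
counts as a method.  `require_both = TRUE` switches to the stricter
reading.

**Chained pairs.**  Single-linkage clustering can join a pair at
BL > 0.15 through intermediates.  Such pairs are kept in the group but
labelled `chained` with a warning; splitting them would make the
partition input-order dependent.

**Subfamily splits and merges.**  Cases like an S5a/S5b split or an
S18–S22 merge need no special code: they are expressed entirely through
the anchor→name map (two anchors with different names force a split
wherever the tree separates them; several anchors sharing one name merge
their clades).  Anchors of different names that no candidate clade
separates are reported *unresolved*, never silently merged.

## What the generator emulates — and what it does not

`make_family()` plants a fully known truth with the two roles of a real
domain family kept apart, the way they are in nature.  Subfamily identity
lives in the domain: every copy keeps the consensus profile's conserved
columns (so planted domains validate), and each subfamily founder carries
a distinctive *signature* in the domain's variable columns — nearly fixed
within the subfamily (slow per-gene drift, rate 0.05), distinct between
subfamilies — just as real subfamily-diagnostic residues behave.
Gene-level divergence lives in the flanking regions: gene founders
diverge at the paralog target (default 0.45), A/D genome copies at the
ortholog target (0.08), allele copies at the allele target (0.01), all
measured on the whole protein.  Without this separation the paralog band
would saturate the domain columns and subfamily clades would lose
bootstrap support — the generator would then be simulating a family whose
subfamilies are phylogenetically unrecoverable by construction, which is
not the system the method addresses.  Realised class-mean divergences are
verified
post hoc against the requested targets, with a tolerance of ±30% of the
target or three standard errors of the class mean under binomial site
sampling, whichever is wider (small families have noisier class means
through no fault of the calibration) — the bands are measured,
not assumed, which keeps tests near the 0.03/0.15 boundaries honest.
`emulate_sources()` mimics the fragmented annotation landscape: the two
D-genome annotations carry the two D alleles, the A-genome annotation an
A allele, tetraploid sources copies of both genomes, each gene surviving
per source with probability `1 - dropout`.  `make_gene()` and
`plant_variants()` build exon–intron structures with GT..AG introns and
plant the three signature variants (15-nt in-frame exon deletion, (GAA)~n~
copy-number difference, 2-kb intron insertion with 300-nt direct terminal
repeats).  `simulate_ct()` writes dual-reference Ct tables with three
technical replicates.

The generator deliberately omits: insertion/deletion evolution inside
domains (alignment columns stay comparable), codon structure and
selection, rate heterogeneity across sites, segmental duplication, and
annotation errors other than dropout.  Passing tests therefore show that
the *rules and algorithms* behave as specified under the stated
divergence structure — not that real annotations are this clean.  On real
proteomes the BL bands can blur (recent tandem paralogs under 0.15,
diverged alleles over 0.03), which is exactly why the thresholds are
config values surfaced in every manifest.

## Numerical and degenerate-input conventions

* All coordinates in code are 0-based, half-open; 1-based values appear
  only in rendered reports (e.g. "intron 4").
* NJ branch-length estimates below zero are clamped to 0; the clamped
  total rides along as an attribute.
* Ties: the local aligner's traceback is deterministic; MP score ties
  break on the lexicographically smallest canonical Newick; representative
  ties break on the smallest id after source priority.
* `p_distance` errors on a pair with zero comparable columns rather than
  imputing.
* Undetected qPCR reactions (missing Ct or Ct > 40) are excluded from
  replicate means and never imputed as numbers; a gene is *undetectable*
  only when every replicate is undetected, and renders as `"ND"`, never 0.
* Exon-boundary mapping is leftmost-longest deterministic with a short
  resume anchor; the generator avoids donor-site ambiguity (the base after
  a planted boundary is never G), and mapping requires exons of at least
  the anchor length (4 nt) — real genes with micro-exons would need a
  spliced aligner proper.

## Problem sizes used by the tests

The default generator family is 6 subfamilies × 4 genes × 4 copies = 96
proteins of length 300; the classification fixtures use 9–30 leaves with
200-replicate bootstraps; variant round-trips run on 720–900-nt CDSs with
six introns.  These sizes keep every property testable in minutes while
leaving each statistic (bootstrap saturation, band separation, planted
variant recovery) far from its decision boundary.

## Known limitations

* The MP search above 8 taxa is an NNI hill-climb with random restarts —
  a heuristic, like any parsimony search at scale.
* The LTR call reports direct-terminal-repeat evidence from a windowed
  prefix/suffix comparison; it does not classify the element or find
  nested insertions.
* Genome-origin assignment presumes both diploid orthologs are available;
  with only one, the margin-based ambiguity flag cannot fire.
* The pipeline classifies group representatives (plus anchors), not every
  copy; copies inherit their representative's subfamily through the group.
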