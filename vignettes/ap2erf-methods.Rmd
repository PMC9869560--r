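---
title: "Methods: AP2/ERF family characterization with erfkit"
author: "erfkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AP2/ERF family characterization with erfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erfkit)
```

## The problem

The AP2/ERF superfamily is one of the largest transcription-factor
families in plants and a central player in abiotic-stress signalling.
Its members are defined by one or two copies of the ~57–70 aa AP2/ERF
DNA-binding domain (Pfam PF00847) and fall into six subfamilies — ERF,
DREB, AP2, ANT, RAV and Soloist — refined into twelve subgroups (A1–A4
within DREB, B1–B4 within ERF, plus the four single-subgroup
subfamilies). `erfkit` packages the full desk-side analysis of such a
family: domain-hit cleaning, rule-based classification, conservation
profiling, cross-species synteny and specificity analysis, synonymous
substitution (Ks) dating of duplicates, and a stress-expression stage.
A synthetic-data generator with complete ground truth makes every stage
testable without genome downloads.

## Classification model

Classification is a short decision ladder over the cleaned domain
architecture:

1. **RAV** — an AP2 domain co-occurring with a B3 domain (PF02362).
2. **AP2 vs ANT** — two or more AP2 domains; AP2 when at least one
   domain carries the characteristic ~10-residue insertion, ANT
   otherwise. The insertion is measured from a global alignment of the
   domain against a bundled 57-column model (BLOSUM62, gap open 10,
   extend 1); the calling threshold defaults to 8 contiguous inserted
   residues (nominal 10) to tolerate small alignment shifts.
3. **ERF vs DREB vs Soloist** — a single AP2 domain; the residues at
   two diagnostic model columns decide: Ala/Asp calls ERF, Val/Glu
   calls DREB. The diagnostic pair defaults to columns 14/19; the
   literature also states the same rule as 15/20 in a shifted
   coordinate convention, so the pair is a configuration parameter
   (`classifier_config(d1=, d2=)`) rather than a constant. Domains
   matching neither pattern (including ambiguous residues) are assigned
   to the nearest bundled subfamily profile by per-column negative log
   likelihood; unalignable domains go to Soloist.

Subgroups: ERF genes map to B1–B4 by the residue pair at model columns
49 and 56 — (F,L), (L,T), (F,T), (M,L) respectively — falling back to
the nearest bundled B profile; DREB genes map to A1–A4 by nearest
bundled A profile, because no residue key exists for the A subgroups
(the field assigns them by tree position; a deterministic
nearest-profile rule is the desk-scale equivalent). The remaining
subfamilies map to their identically named subgroup.

A neighbor-joining coherence check (`nj_tree()`) substitutes for a full
maximum-likelihood phylogeny: p-distances over the aligned domains,
canonical NJ, and a coherence score — the fraction of leaves whose
nearest leaf by patristic distance (ties included) shares their
subgroup label. Identical sequences produce a star tree whose
coherence is 1 when the labels agree.

## Domain-hit cleaning

Hits parsed from InterProScan-style Pfam TSVs (or found by the bundled
PSSM scanner) are cleaned with two rules: drop hits with e-value above
1e-5, and among mutually overlapping hits (≥ 1 shared residue) keep the
lowest e-value (ties: lowest start, then longest). Hits lacking
e-values — the PSSM path reports bit scores only — are kept and ranked
below any numeric e-value, so evidence is never silently lost; the
1e-5 filter applies only where an e-value exists, because inventing an
e-value calibration for the PSSM scores would be arbitrary. The filter
is idempotent and its output is sorted and non-overlapping.

## Conservation profile

Per-column residue frequencies are computed over domains aligned to the
model width, with gaps excluded from the denominator (the consensus is
a statement about amino acids, and counting gaps would make the ratios
depend on indel artifacts). The consensus residue per column is the
most frequent amino acid (ties broken alphabetically), written
uppercase only when its frequency strictly exceeds one half. The AP2
domain's secondary structure (β1 = columns 1–7, β2 = 14–20, β3 =
31–33, α = 48–57) partitions the model into eight divisions; the
"consensus ratio" of a division is the mean per-column consensus
fraction, all-gap columns excluded. This fraction-based score is a
deliberate stand-in for alignment-information-system consensus scores
that weight physicochemical similarity; published division-level
percentages from such tools are therefore not comparable targets.

## Comparative stage

Orthologs are reciprocal best hits under the same BLOSUM62 global
scoring; score ties disqualify a pair. Collinear blocks chain ortholog
pairs whose ranks increase strictly on one genome and monotonically
(either direction) on the other, with at most 25 intervening genes
between consecutive pairs on both genomes and at least 5 pairs per
block — the MCScanX defaults. Chaining is by longest-chain dynamic
programming with earliest-start tie-breaking, and rank gaps are
measured within the gene set that defines the pairs (the family genes,
`rerank_loci()`), since that is the set the chain is built from.
Species-specificity counting is deliberately synteny-based: a gene has
an ortholog in another species only if it sits in a collinear block
against it, because isolated best-hit pairs are weak evidence.
Tandem arrays are maximal runs of ≥ 2 same-subgroup genes with at most
10 intervening genes of any kind, measured in global gene ranks.

## Ks dating

Duplicate pairs (within-species reciprocal best hits among family
genes, tagged tandem or dispersed) are dated with the Nei–Gojobori
(1986) method. Synonymous site fractions per codon position are
computed over the single-nucleotide changes that do not create a stop
codon, so S + N = 3 per codon; differences between codons differing at
multiple positions are averaged over all minimal mutation paths with
equal weights, paths through stop codons receiving zero weight (uniform
fallback if every path is blocked). pS = sd/S is corrected with
Jukes–Cantor, Ks = −(3/4)·ln(1 − (4/3)·pS), undefined at pS ≥ 3/4.
Recency uses strict thresholds: Ks < 0.1 postdates the tomato–potato
split, Ks < 0.3 the pepper–*Solanum* split; pairs with Ks ≥ 3 are
flagged saturated/not retained. NG86 was chosen over the MYN model
because it is closed-form and oracle-testable at desk scale; published
counts computed under MYN are consequently not comparable.

## Expression stage

FPKM is the usual counts·1e9 / (library size · gene length).
Differential expression uses a two-sided Welch test on log2(FPKM+1)
across replicates with BH adjustment within the contrast and the
standard call rule |log2FC| > 1 and adjusted p < 0.05 (pseudocount 1
for zero-count stability). This is a deliberately dependency-light
substitute for a negative-binomial Wald test; its type-I and power
behaviour is exercised directly by the test suite, and absolute DEG
counts from NB-based pipelines are not comparable. Time-course
clustering is fuzzy c-means (fuzzifier m = 2, a conventional default;
20 seeded restarts, keep the lowest objective) on per-gene standardized
profiles; constant profiles are excluded with a warning. GO enrichment
is the one-sided Fisher exact test via the hypergeometric tail with BH
FDR ≤ 0.01; when no ontology graph is supplied every annotated term is
tested (term-level filtering would need an OBO graph and is out of
scope). Ortholog expression correlation averages the time-resolved
species over its five time points per condition and reports Pearson r
across pairs, undefined below 3 pairs.

## What the generator emulates

`truth_config()` defaults describe a three-species Solanaceae-like
study: ~150 family genes per species (real species carry 142–355), an
ERF-dominated subgroup mix (55% ERF, with B2/B4 heaviest), tandem B2
and B3 arrays on chromosomes 1 and 4 of the first species, 30% of genes
species-specific, Ks targets spanning 0.05–0.5, negative-binomial
counts at dispersion 0.1 with 3 biological replicates, and a five-point
stress time course (3, 6, 12, 24, 72 h) under cold/heat/salt/mannitol
with controls sampled at the same time points — the standard parallel
design, which also gives the Welch stand-in realistic power.

Domains are emitted from bundled per-subgroup position-frequency
profiles with the diagnostic and key columns always at consensus;
`domain_noise` (default 0.05 per column) perturbs the rest. Ortholog
groups share one sequence template with per-species flank mutations, so
reciprocal best hits are unique; tandem-array members are progressively
mutated copies of one seed. Background genes carry no domain and are
interleaved at a fixed spacing (default 12) after every family gene or
array: family genes in real genomes are sparse, and this spacing keeps
unrelated same-subgroup genes farther apart than the 10-gene tandem
rule while planted arrays stay strictly consecutive — which is what
makes "arrays recovered exactly" a well-defined statement. CDS
duplicate pairs are calibrated analytically: only four-fold degenerate
third positions are mutated, each with probability pS*·S/n4 where
pS* = (3/4)(1 − e^(−4K/3)), so the expected NG86 estimate equals the
target (observed bias < 0.03 at 300 codons).

What the generator does **not** model: intron structure, assembly or
read-level noise, evidence tiers for annotations, lineage-specific
codon usage, overlapping genes, and expression correlation structure
beyond the planted effects. Passing tests therefore demonstrate
algorithmic correctness on clean, fully labelled data, not robustness
to every artifact of real genomes.

## Numerical choices and degenerate inputs

- All stochastic stages draw from one seeded generator; identical
  configurations produce byte-identical files, and pipeline reruns
  reproduce identical manifest checksums.
- Alignment scoring is fixed (BLOSUM62, open 10, extend 1) everywhere
  so classification, orthology and codon threading are mutually
  consistent; alignments scoring below 0 are "unalignable" and route to
  Soloist.
- Ties: consensus ties break alphabetically; overlap resolution breaks
  e-value ties by start then length; chain DP ties prefer the earliest
  start; RBH score ties yield no pair.
- Degenerate inputs: empty hit sets give empty architectures; sequences
  shorter than the model width give empty scans (not errors); zero
  library sizes, missing gene lengths, internal stop codons,
  non-multiple-of-3 CDS, and sub-minimum codon counts are errors.
- Problem sizes used by the packaged checks (chosen as comfortable
  desk-scale study conditions): classification at 3 × 200 noise-free
  genes; Ks calibration at 5 targets × 50 pairs × 300 codons;
  comparative recovery at 3 × 60 genes; expression at ~1,000 genes with
  100 planted effects; the determinism double-run at 3 × 24 genes.

## Known limitations

- The nearest-profile rule for A1–A4 (and the Soloist fallback) depends
  on the bundled profiles; on real data these should be re-estimated
  from curated alignments.
- Specificity counting ignores two-species blocks smaller than
  `min_block`, so short true syntenic segments read as specific.
- The Welch DEG test has limited power in 3-vs-3 single-time-point
  contrasts; the pipeline pools time courses per condition.
- GO term-level (ontology-depth) filtering is not implemented; all
  supplied terms are tested.
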