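---
title: "Methods: family-contrast SNV screening and candidate-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-contrast SNV screening and candidate-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design and its assumptions

`extremediff` implements an extreme-phenotype sib-pair screen. The study
unit is a set of full- or half-sib families, each contributing one
high- and one low-breeding-value animal; the default cohort shape is four
families, eight diploid samples. The screen's core statistic is not a
test but a deterministic set operation: a *common differential SNV* is a
biallelic site at which all high samples are homozygous for one allele A,
all low samples are homozygous for a different allele B. The logic relies
on three assumptions:

* per-sample variant calls are trustworthy after simple quality gates
  (no joint calling, no imputation);
* sites are biallelic SNVs — multi-allelic positions are split into
  biallelic records, and positions with more than two observed alternate
  alleles are dropped with a warning, because "opposite fixed" is only
  well-defined on two alleles;
* a consistent orientation across families (the same A and B everywhere)
  is required. Reporting a single high/low allele per SNV is only
  well-defined under this reading; the looser within-family-only reading
  is deliberately not offered, so results cannot silently change meaning.
  The intermediate "polymorphic between the sib pair" list remains
  inspectable via `family_differential(..., polymorphic_only = TRUE)`.

A single heterozygous or missing call anywhere among the eight samples
removes a site. The screen is therefore conservative by construction and
its recall degrades with missingness, which the synthetic module can
emulate.

# Call filtering

`passes_call_filters()` applies three thresholds, read literally from
their usual statement: base quality ≥ 20 (phred), read depth < 100
(strict: depth 100 fails), alt-supporting reads > 3 (strict: 4 or more).
Missing genotypes never pass. One semantic decision deserves a note:
an *explicit homozygous-reference record* asserts the absence of a
variant and carries zero alt reads by definition, so the alt-read
threshold applies only to variant (het / hom-alt) records; hom-ref
records are judged on quality and depth. Without this reading every
hom-ref record would be demoted to missing and a fixed reference
genotype could never participate in the contrast.

Single-sample VCFs cannot distinguish "reference" from "no data" at a
site another sample reports. The `absent_means` policy makes both
readings available (`"missing"`, the conservative default, or
`"hom_ref"`); the simulator emits explicit hom-ref records so the
default path is exercised rather than bypassed.

# Functional annotation

`assign_category()` reproduces ANNOVAR-style region classes against a
GFF3 gene model: `exonic` (in CDS), `UTR5`, `UTR3`, `intronic` inside
coding genes; `ncRNA_exonic` / `ncRNA_intronic` inside non-coding genes;
strand-aware `upstream` / `downstream` within 1 kb of a gene (upstream is
the 5′ side of the transcription start); `upstream;downstream` when a
site lies within the window upstream of one gene and downstream of a
*different* gene; `intergenic` otherwise. Precedence when a position
matches several features is fixed and documented: exonic > UTR5 > UTR3 >
intronic > ncRNA_exonic > ncRNA_intronic > up/downstream > intergenic;
among equal-priority genes the nearest wins, ties broken by the smaller
gene id. The test suite checks this against a plain-loop
interval-membership oracle on a fixture that includes overlapping genes
and both window boundaries.

Two windows matter and both are boundary-inclusive: 1 kb (`near_gene_bp`)
for the up/downstream class and 5 kb (`gene_window_bp`) for attaching an
SNV to a gene for gene-level analysis. Distances are
`min(|pos − start|, |pos − end|)` for sites outside the gene span and 0
inside; with 1-based inclusive gene spans, inclusive bounds avoid
off-by-one ambiguity.

Coding effects are called by building the reference codon from the
spliced CDS in strand orientation, substituting the alternate base
(reverse-complemented on the minus strand) and translating with the
standard genetic code: synonymous, nonsynonymous, stopgain, stoploss. Two
degeneracies map to `unknown` rather than an error or a silent drop: a
CDS whose length is not divisible by three, and a reference-sequence
disagreement with the record's reference allele (such records are also
flagged `ref_mismatch` in the annotation table). Category percentages in
summaries are rounded half-up to two decimals — the convention of printed
annotation tables — via `round_half_up()`, since base R's half-to-even
rounding prints boundary values differently.

# Over-representation and functional selection

`ora_test()` is the one-sided upper-tail hypergeometric probability
P(X ≥ k), computed in log space via `stats::phyper`; tests compare it to
direct binomial-coefficient enumeration for all margins with N ≤ 25 at
10⁻⁹. No multiple-testing correction is applied by default and the
significance level is a raw P < 0.05, matching the selection criterion
this screen mechanizes; a Benjamini–Hochberg flag exists
(`bh_correction`) for users who prefer rigor over fidelity. The
background universe is all genes in the gene-model file, not the union of
the gene sets — the annotation set is the population actually sampled.

The post-enrichment curation step ("keep genes in significant sets
relevant to protein/lipid/fatty-acid metabolism, plus genes in well-known
metabolism pathways even when not significant") is mechanized, not
re-judged: rule (a) keeps query genes in significant sets whose label
matches a configurable keyword list (case-insensitive substring); rule
(b) keeps query genes in any whitelisted pathway set regardless of
significance. The default whitelist is the eight-pathway list (mTOR,
insulin, AMPK, PPAR, Jak-STAT, PI3K-Akt, MAPK, TGF-β); keyword defaults
are `protein`, `lipid`, `fatty acid`, `amino acid`, `fat`, `insulin`.
Each selected gene carries the rule(s) that admitted it.

# Map interpolation and QTL proximity

Physical positions are mapped to cM by piecewise-linear interpolation
between per-chromosome anchors, exact at anchors; queries beyond the
terminal anchors extrapolate with the terminal segment's slope (this is
why the few lines are hand-written rather than delegated to
`stats::approx`, which clamps). A gene is reduced to one position via its
span start by default (`gene_position = "midpoint"` is available); the
choice is deterministic and documented rather than inferred, since a
single printed cM per gene does not reveal the convention used.

The proximity rule is strict: a gene is retained when its *unrounded*
minimum distance to any QTL peak (trait-filtered, default PP/PY/FP/FY;
multiple peaks per record supported, minimum taken) is < 1.0 cM. The
one-decimal rounding of reported distances is display-only and half-up.
A chromosome without any QTL record yields a "no QTL" sentinel and the
gene is excluded. The final candidate rule is the conjunction:
functionally selected, near a peak, and supported by at least one common
differential SNV whose category is exonic, UTR or up/downstream —
intronic or intergenic support alone never qualifies.

# The synthetic study: what it does and does not emulate

`simulate_study()` generates the whole input bundle with planted truth.
Design choices, made once:

* **Genome and genes.** Five chromosomes of 1 Mb by default; 60 genes
  dealt round-robin across chromosomes, non-overlapping, separated by at
  least 12 kb so the 1 kb and 5 kb distance classes are never ambiguous
  (overlapping-gene behaviour is exercised separately with hand-built
  fixtures). Coding genes carry one transcript (2–4 exons, 5′/3′ UTRs);
  the reference is rewritten under each CDS so the spliced ORF starts
  with ATG, ends with a stop, has no internal stop and length divisible
  by three. The non-coding gene count is exactly
  `round(fraction_noncoding_genes × n_genes)`.
* **Cohort.** Eight samples in four families. Planted differential sites
  are homozygous-opposite between the groups; one site per planted
  candidate gene cycles through the qualifying categories (exonic, UTR5,
  UTR3, upstream, downstream), the remainder alternate between introns
  of non-candidate genes and positions more than 6 kb from every gene.
  Background genotypes are drawn independently of the group labels and
  are *constrained* never to form an opposite-fixed pattern (a matching
  draw is redrawn), so planted-truth precision is exact by construction,
  not merely probable.
* **Per-call metrics.** No per-site metric distributions are published
  for this kind of study, so the simulator's are stand-ins, not
  estimates: base quality ~ round(N(30, 4)) clamped to [20, 60], depth ~
  Poisson(8) clamped into threshold-passing ranges, alt reads consistent
  with the genotype. A configurable `filter_fail_rate` fraction of
  records is pushed outside exactly one threshold (low quality, depth ≥
  100, or ≤ 3 alt reads), and `missing_rate` drops records entirely.
* **Resources.** One gene set labelled with a relevance keyword contains
  exactly the planted candidates; whitelist-named pathway sets contain
  candidates plus SNV-free decoys; neutral background sets are random.
  The genetic map uses six anchors per chromosome with segment slopes
  drawn from 3–6 cM per 200 kb (deliberately steep so that distinct cM
  positions exist at this genome scale). Each planted candidate gets a
  milk-trait QTL peak within 0.05–0.85 cM; decoy QTLs sit at least 3 cM
  from every gene.
* **Determinism.** All draws derive from `sim_config(seed)`; the three
  generator stages use fixed offsets of that seed so each is individually
  reproducible, and all emitted files are byte-identical across runs.

What passing tests on this simulator show — and what they do not: they
verify the *logic* (filters, contrast, annotation, enrichment, proximity,
and their composition) exactly, on data whose statistical structure
matches the analysis' assumptions. They do not validate behaviour on real
resequencing data, where linkage between neighbouring sites, shared sib
haplotypes, calling artefacts correlated across samples, and incomplete
gene models all exist and are not emulated.

# Problem sizes and numerical notes

The test suite runs the end-to-end recovery at the study's natural scale
(8 samples, 2,000 background SNVs, 50 planted sites, 5 planted candidate
genes) and smaller variants for the property checks; the category oracle
uses 1,000 random sites over a 20-gene fixture; the hypergeometric
enumeration covers every margin with N ≤ 25. These sizes were chosen as
the smallest at which every code path (both window boundaries, both
strands, splicing, decoys, noise) is exercised.

Degenerate inputs are defined rather than accidental: an empty design or
empty background is an error; a simulation with zero planted sites
produces empty differential and candidate tables and a valid (empty)
summary; `k = 0` yields P = 1; a gene on a chromosome without QTLs is
excluded with a sentinel, not an NA comparison. Ordering is deterministic
everywhere: sites by natural chromosome order then position, enrichment
by P then set id, candidates by chromosome then gene start.

# Known limitations

* Indels, CNVs and structural variants are out of scope; so are
  selection statistics (F~ST~, XP-EHH) and any significance test of
  fixation itself.
* Annotation handles one precedence-ranked consequence per site; it does
  not rank consequences across multiple transcripts beyond the stated
  rule, nor classify splice sites or frameshifts.
* Gene-set handling is flat: no GO graph propagation or term ancestry.
* The genetic map is assumed monotone; real maps with local inversions
  need cleaning upstream.
* The curation keyword/whitelist mechanism reproduces a *rule*, not the
  judgment of human curators it replaces.
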