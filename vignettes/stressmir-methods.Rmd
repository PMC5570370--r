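---
title: "Classifying HSF-1-regulated miRNAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying HSF-1-regulated miRNAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmir)
```

## The experimental design and the question

Heat shock factor 1 (HSF-1) is the master transcriptional regulator of the
heat shock response. Beyond inducing chaperone genes, it also shapes the
microRNA complement of the cell. The design this package analyzes crosses
an *hsf-1* knockdown (RNAi feeding vs. empty-vector control) with a brief
heat shock, giving four conditions measured in biological duplicates by
small-RNA sequencing:

| label | genotype/treatment | role |
|-------|--------------------|------|
| `C0`  | hsf-1(+); −HS      | control |
| `C1`  | hsf-1(+); +HS      | heat-shocked control |
| `C2`  | hsf-1(−); +HS      | heat-shocked knockdown |
| `C3`  | hsf-1(−); −HS      | untreated knockdown |

The question for each miRNA is whether HSF-1 regulates it **during** heat
shock (the heat-induced change requires HSF-1) or **independently** of
heat shock (the knockdown changes it with or without heat), and in which
direction. Four regulatory classes plus `unclassified` capture the
answers.

## The decision logic

For each miRNA, five contrasts are computed on the detection-filtered
count matrix: the three control-relative comparisons `C1 vs C0`,
`C2 vs C0`, `C3 vs C0`, and the confirmatory pairs `C1 vs C2` and
`C2 vs C3`. Each contrast reports `log2FC = log2(mean_b) − log2(mean_a)`
on depth-normalized counts, a p-value, and a Benjamini–Hochberg q-value
adjusted within the contrast. Significance is strict: `q < α` with
`α = 0.05` by default.

* **HS-dependent up/down**: significantly up/down in `C1 vs C0` *and*
  `q(C1 vs C2) < α`. The confirmatory test asks whether the heat-shock
  response differs between intact and knocked-down animals; if it does,
  the change needed HSF-1.
* **HS-independent up/down**: significantly changed in `C3 vs C0` with
  `q(C2 vs C3) ≥ α`. The confirmation here is *non-significance*: the two
  knockdown conditions must agree, showing the change does not depend on
  heat. The reported fold change is negated ("reversed comparison") so
  that it expresses HSF-1's normal regulatory direction — a miRNA that
  rises when HSF-1 is removed is normally *down*-regulated by HSF-1.

A miRNA eligible for both a dependent and an independent class keeps the
dependent label; both memberships are preserved in provenance columns,
since a single miRNA can genuinely appear in both analyses. A miRNA
passing a control-relative (Venn) stage but failing its confirmation is
flagged as a candidate and left unclassified. Using non-significance as
the independence criterion is a deliberate literal choice — it is the
weaker reading (absence of evidence), and an equivalence-test variant
would be stricter; we document rather than hide this asymmetry.

## Test statistics

The counting nature of small-RNA-seq admits two backends in
`mir_contrast()`:

* **Exact conditional binomial** (`test = "exact"`, the default): pool
  raw counts across each side's replicates, condition on the pooled
  total, and test whether side b's share differs from its effective
  library share with a two-sided exact binomial test. This is
  deterministic, has no tuning parameters, and is exactly calibrated when
  counts are Poisson across replicates. It ignores biological
  (extra-Poisson) variance: with overdispersed replicates it is
  anticonservative, which is measurable in this package's own null
  simulations at nonzero dispersion.
* **Quasi-likelihood** (`test = "ql"`): a negative-binomial
  quasi-likelihood F-test fitted across all four conditions, which
  estimates and uses the replicate-level dispersion. This is the backend
  to use whenever replicates carry biological variance — including the
  default synthetic data, whose dispersion is 0.05.

Fold changes are always the control-relative ratio of normalized means,
independent of the test backend, so effect estimates stay on the scale
the classification and reporting conventions expect. Depth normalization
(`size_factors()`: column total over mean total) precedes the
control-relative averaging; without it, sequencing depth masquerades as
regulation.

`bh_adjust()` applies the step-up procedure per contrast over all
retained miRNAs; q-values from different contrasts are never pooled into
one family.

## Read-level quantification rules

`quantify_sample()` reproduces the stated read-processing rules against a
mature-miRNA reference rather than a genome: adapter trimming at the
leftmost adapter-prefix occurrence (minimum overlap 5 nt), removal of
reads shorter than 18 nt, positional (Hamming) matching with **zero
mismatches in the first 18 nt** and **at most two afterwards**, and
discarding of reads with hit multiplicity above five. Within a read's
best tier (minimum mismatch count), ties share the count fractionally
(1/k each) so column totals equal the number of counted reads. Choices
the source rules leave open, fixed here and configurable:

* reads may overhang the reference 3′ end by up to 3 nt (untemplated
  addition), not counted as mismatches; shorter reads are compared over
  the read length;
* no indels — the rules are positional mismatch counts;
* "low-quality read" removal is approximated by dropping reads with more
  than 10% N bases;
* per-record genome copy counts (`copies=` in the FASTA header) inflate a
  hit's multiplicity for the ≤5 rule, standing in for multi-locus genome
  mappings;
* U is normalized to T on input.

## Target integration and networks

"Inverse correlation" is implemented as discrete sign opposition with a
significance gate: a predicted edge miRNA→gene survives iff the miRNA is
classified, the gene is significantly regulated in the parallel mRNA
data, and the gene's log2FC (on the HSF-1-regulation scale, sign
convention already applied) is opposite to the miRNA's direction. No
correlation coefficient is involved; the operation is a directed list
intersection, which matches how the integration is used downstream.

`expand_network()` adds unaffected genes that interact with **at least
two** affected genes, and `find_linkers()` reports the connections lying
on paths of length ≤ 2 between the up- and down-regulated clusters:
direct up–down edges and nodes adjacent to both clusters. The path-≤2
rule is our generalization of the worked linker examples
(oxidative-stress and insulin-like-signaling factors bridging induced and
suppressed genes); interaction edges are treated as undirected.

## Enrichment

`hypergeom_test()` is the plain upper-tail hypergeometric
over-representation test; the universe defaults to all annotated genes in
the supplied table (an external annotation database's background is not
reproducible offline, so the table is its own universe unless
overridden). `cluster_terms()` groups terms by single linkage on Jaccard
similarity of their overlapping-gene sets at 0.5 — a transparent
surrogate for proprietary kappa-based annotation clustering — and scores
each cluster by the **arithmetic mean of −log10 member p-values** —
identically, the negative log of the geometric mean of the p-values. The
grouping is a surrogate; the scoring formula is implemented exactly.

## The synthetic-data generator

`design_config()` defaults encode the study conditions: 1,000 miRNAs,
biological duplicates, control mean 500 reads, shared negative-binomial
dispersion 0.05, planted |log2FC| of 3, and 200 regulated miRNAs (50 per
class). Classes act multiplicatively where the biology says they should:
dependent classes perturb `C1` only; independent classes perturb both
knockdown conditions equally — the cleanest signal consistent with
requiring no difference between `C2` and `C3`. Library sizes get
lognormal multiplicative jitter (sdlog 0.2, a realistic depth spread that
keeps factors positive). Dispersion 0 degenerates to Poisson, which is
the regime used to check the exact test's calibration.

What the generator deliberately does **not** emulate, and what that means
for the tests: per-miRNA abundance is a single constant baseline, not the
heavy-tailed abundance distribution of real miRNomes, so recovery results
say nothing about power at very low counts; there is no 5p/3p arm
structure, no precursor context, and no sequence-driven mapping bias
(reference sequences are random and mutually distant, so multimapping is
rare by construction); target maps assign each gene to at most one miRNA
edge so that the planted "keepable" set is exactly what the integration
rule should retain — real target maps overlap, which affects counts but
not the rule itself. Passing recovery tests therefore validates the
decision logic and its calibration, not performance on any particular
real library.

## Numerical and degenerate-input choices

* `q = α` exactly is **not** significant (strict inequality throughout).
* `−log10(q)` for an underflowed `q = 0` is reported as 300 — a display
  cap with no inferential role.
* Fold changes use pseudocount 0 by default (the detection filter has
  already removed rows with zeros); 0.5 is available for unfiltered use.
* Pooled counts (0, 0) in the exact test give p = 1.
* A condition with a single replicate yields `NA` concordance, flagged
  but not fatal; `log2(x + 1)` underlies all QC correlations.
* Tied best-tier hits share counts fractionally, preserving column sums;
  a seeded random-winner mode would also conserve counts but destroys
  determinism, so it is not the default behavior.
* All randomness flows from one root seed, split per stage with a fixed
  integer recurrence, so multi-stage runs are bitwise reproducible.

## Problem sizes

The shipped validation uses the scales the analyses are designed for:
class recovery on 1,000 miRNAs × 8 samples over repeated simulated
experiments; null calibration on 2,000 miRNAs; the adjustment and
hypergeometric oracles on exhaustive or thousand-fold random cases;
read-level round trips on 15–20 miRNA references at moderate depth
(read-level simulation at full library depth is possible but
unnecessary — the mapping rules are depth-independent). A full pipeline
run at 1,000 miRNAs and 500 genes completes in seconds on one CPU.

## Known limitations

* The exact test's validity is conditional on Poisson sampling; the
  package measures (rather than hides) its anticonservatism under
  overdispersion, and offers the quasi-likelihood backend as the remedy.
* Classification sensitivity degrades for effects near the significance
  boundary or baselines near the detection filter; the planted-effect
  recovery figures quantify the clean-signal regime only.
* The Venn-region shading that selects which overlap regions feed each
  class in the original figures is figure-only information; candidates
  are therefore defined directly by the relevant control contrast, with
  the confirmatory pairwise tests binding.
* Term clustering at Jaccard 0.5 is a surrogate; scores are exact, group
  composition may differ from kappa-based groupings.
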