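---
title: "Indirect miRNA targeting through TF networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect miRNA targeting through TF networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTFenrich)
```

## The model

A miRNA represses its direct targets post-transcriptionally; when one of
those targets is a transcription factor (TF), the TF's whole regulon is
perturbed transcriptionally. `mirTFenrich` models this as a single
composition step over two predicted layers:

* **Layer 1 (miRNA → gene):** TargetScan-style records scored by the
  cumulative weighted context++ score. More negative means stronger
  predicted repression; records with score < −0.1 are treated as
  high-confidence and kept (the comparison is strict, so a score of
  exactly −0.1 is excluded). Multiple records for one (miRNA, gene)
  pair — different sites or transcripts — are collapsed to the minimum
  score, i.e. the strongest prediction.
* **Layer 2 (TF → gene):** a tissue-specific edge list such as the
  PANDA networks. "Being a TF" is defined operationally as appearing as
  a regulator in the chosen tissue's network; no separate TF catalogue
  is consulted. Edge weights are accepted but not filtered by default
  (`weightThreshold` exposes a cutoff), because regulatory-network
  resources differ in how their weights are scaled.

The *indirect* target set of a miRNA is the union of its direct targets
and the genes regulated by its directly-targeted TFs. Including the
direct targets is deliberate: the combined set is what the enrichment
step operates on, and it is what makes a pathway that contains both the
TF and its regulon count the TF itself as covered (the nine-gene toy of
`fig1Toy()` counts 6/9, not 5/9). `indirectTargets(..., includeDirect =
FALSE)` gives the downstream-only set for users who want to isolate the
transcriptional layer. Exactly one TF layer is composed; TF→TF→gene
chains are out of scope because each extra predicted hop multiplies the
false-positive rate of both input resources.

When several miRNAs are supplied, their per-miRNA indirect sets are
intersected — the genes all of them reach — which sharpens signals that
the miRNAs share. A union option exists but is non-canonical: a union
grows with every added miRNA regardless of coherence.

### Top-fraction slicing

Predicted target lists have many false positives, so every target
resolution accepts a `topFraction` in (0, 1]: the miRNA's records are
sorted ascending by score (strongest first) and the first
`ceiling(topFraction * count)` genes are kept. Three details matter:

* slicing happens on the *full per-miRNA target list*, before the TF
  intersection — the fraction controls target-list confidence, not TF
  count;
* `ceiling()` guarantees a non-empty slice whenever the miRNA has any
  record;
* score ties at the boundary are broken by gene symbol, so a run is
  reproducible to the byte.

## The enrichment statistic

For a resolved target set the package tests every GO term of size ≥ 5
with the upper-tail hypergeometric probability P(X ≥ k), where the
population is the **annotation universe** — all genes annotated to at
least one retained term of the chosen namespace. This universe choice is
the standard one for over-representation analysis and keeps N
independent of the tissue network, so direct and indirect runs are
scored against the same population. Target genes outside the universe
are discarded from n; if none remain the run stops with a data error
(this almost always means a gene-identifier mismatch — all symbols are
uppercased on load to reduce that risk).

The tail probability is computed with `stats::phyper`, which works in
log space internally; the test suite checks it against a brute-force
subset-enumeration oracle over the complete grid N ≤ 12 at 1e-9.

Terms are ranked by raw p-value ascending, ties broken by accession so
that ranks are bit-identical across runs. A Benjamini–Hochberg FDR is
reported per term but does not affect the ranking: the evaluation
protocol below consumes ranks, and BH is a monotone transform of the
p-value order, so ranking by adjusted values would change nothing while
hiding the raw values users expect to see. A term's *percentile rank* is
rank divided by the number of terms tested, in (0, 1].

Annotations are used flat — no propagation up the GO graph. The
annotation source is assumed to be pre-propagated or to be used
consistently in both modes; since direct and indirect runs share the
same `AnnotationSet`, any incompleteness affects both arms equally.

## TF density

Development-related processes are disproportionately made of TFs, which
is why indirect expansion helps there most. The statistic is

    density(term) = |term genes ∩ TF universe| / |term genes|

and a term counts as development-related if any of the keywords
*development, cell fate, differentiation, stem cell, morphogenesis,
cell specification, formation* occurs as a case-insensitive substring of
its name. Substring (not word-boundary) matching is chosen for recall —
"cardiac ventricle formation" must match "formation" — at the cost of
occasional false positives such as "pattern formation" variants; users
can supply their own keyword list. The group comparison (development vs.
other, restricted to terms with at least one TF — terms with none carry
no information about TF enrichment) is a Wilcoxon rank-sum test,
one-sided by default because the hypothesis is directional; a two-sided
alternative is a flag.

## The benchmark protocol

Given gold-standard (miRNA, GO term) pairs, the benchmark groups pairs
by miRNA, resolves the miRNA's target set in each mode, runs the
enrichment, and records the known term with the smallest p-value along
with its percentile rank. Grouping per miRNA (rather than scoring every
pair separately) is the primary reading because the protocol picks "the
related term with the smallest p-value"; a `perPair` flag provides the
other reading. miRNAs whose known terms were all removed by the size
filter, or that have no targets in the table, are skipped and reported,
not errored — a benchmark should degrade gracefully.

Direct and indirect arms are compared with a Wilcoxon signed-rank test
on the paired percentiles, one-sided (indirect lower). Zero differences
are dropped before ranking — Wilcoxon's original treatment, and the one
`stats::wilcox.test` implements; implementations differ here (Pratt's
method keeps zeros), so the choice is documented. If every difference is
zero the test refuses rather than returning a meaningless p-value. For
small tie-free samples the p-value is exact (enumeration-equivalent, and
tested against an explicit 2^n sign-flip oracle); larger or tied samples
use the tie-corrected normal approximation.

The fraction sweep repeats both arms over fractions {0.2, 0.4, 0.6,
0.8, 1.0} and reports mean percentile with standard error sd/√n per
cell. The tissue for the indirect arm is user-specified: gold-standard
collections rarely record tissue context, so tying the benchmark to one
tissue is an explicit user decision, not something the package guesses.

## The synthetic generator

`generateFixture()` writes the four input files in exactly the dialects
the loaders read, from one seeded Mersenne–Twister stream (the global
RNG state is saved and restored). What it emulates is the *structure* of
the real resources — scored target records, a long-format tissue edge
list, long-format annotations, gold-standard pairs — plus a planted
causal chain: each planted miRNA directly targets a few bridge TFs, and
each bridge TF regulates a prefix of a permutation of the planted GO
term's genes. Prefix sampling means raising `downstream_per_tf` only
adds downstream genes while leaving every other draw untouched, which
is what makes the planted-signal-monotonicity property testable at all.

Design choices, fixed once:

* **Default sizes** (360 non-TF genes, 40 TFs, 40 terms of 8–20 genes,
  6 miRNAs × 30 targets, 3 bridges × 6 downstream genes, 2% background
  edge density): large enough that the background gives every term a
  non-trivial null (universe ≈ 300 genes, ~400 network edges) and the
  whole test bench, including the 2×5 benchmark sweep, runs in seconds.
* **Bridge TFs get the strongest scores** in the planted miRNA's list.
  The generator's contract is that the planted signal flows through the
  TF layer at every top fraction; had the bridges weak scores, small
  fractions would sever the planted chain and the fixture would test
  score ordering rather than the expansion logic.
* **Planted terms contain only non-TF genes**, and every miRNA's
  non-bridge targets are drawn from non-TF genes outside all planted
  terms. The direct-mode overlap with a planted term is therefore zero
  by construction — the clean null against which indirect recovery is
  judged.
* Scores are uniform on the score range and background edges are
  Bernoulli; no attempt is made to match real context++ score or PANDA
  weight distributions. Consequently, passing tests demonstrate the
  correctness of the expansion/enrichment machinery and the benchmark's
  ability to detect a true TF-mediated signal — they say nothing about
  how strong such signals are in real TargetScan/PANDA/GO snapshots,
  where annotation bias, correlated terms and shared seed families all
  blur the picture.

The nine-gene toy (`fig1Toy()`) is the minimal worked example: direct
coverage 1/9 ≈ 11%, indirect 6/9 ≈ 67%.

## Gold-standard filtering

GAF 2.1/2.2 input is filtered to high-confidence annotations: evidence
codes ISS, NAS and TAS are excluded (sequence-similarity inferences and
author statements are the weakest classes for a benchmark), annotations
without a literature reference are dropped, and three generic
miRNA-machinery terms (miRNA-mediated translational inhibition, gene
silencing by miRNA, gene silencing by RNA) are removed because nearly
every miRNA is annotated to them, so they would reward any method that
ranks them early. Their accessions live in
`inst/extdata/generic_go_terms.tsv` and can be overridden. Only GAF
columns 2, 5, 6 and 7 are consumed; the column count (17) is enforced
per line by counting tabs, since trailing GAF columns are routinely
empty.

## Degenerate inputs and numerical corners

* Empty input files with valid headers load as empty containers.
* A miRNA absent from the target table resolves to an empty set with a
  warning, so batch runs continue; an empty *final* target set in the
  CLI is a data error.
* `hypergeomUpperTail` returns 1 at k = 0 and 0 for impossible k, and
  validates 0 ≤ K ≤ N, 0 ≤ n ≤ N up front.
* Location→broad-tissue aggregation takes edge-set unions and fails
  loudly on unmapped locations, listing them.
* All containers use set semantics (duplicate edges, annotations and
  records collapse deterministically), so loading a file the package
  wrote reproduces the in-memory object exactly.

## Known limitations

* Both layers are computational predictions; composing them compounds
  false positives. The score threshold and top-fraction knobs mitigate
  but cannot remove this.
* Gene symbols are the join key across all three resources; symbol
  drift between database versions silently shrinks overlaps (uppercasing
  catches case differences only).
* One TF layer, flat annotations, and intersection-only multi-miRNA
  semantics are deliberate simplifications, documented above.
* Tissue choice for the indirect arm is user-supplied; results are
  conditional on it.
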