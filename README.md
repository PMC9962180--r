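# mirTFenrich

GO enrichment of microRNA targets expanded through tissue-specific
transcription-factor networks.

## The problem

MicroRNAs (miRNAs) repress their target mRNAs post-transcriptionally, and a
miRNA's function is usually predicted by testing its predicted targets for
Gene Ontology (GO) over-representation. But a miRNA's influence does not
stop at the genes it binds: when a miRNA represses a **transcription
factor (TF)**, every gene that TF regulates is perturbed too. Conventional
enrichment pipelines, built on direct binding-site predictions alone, miss
pathways that a miRNA controls almost entirely through one or two TFs —
which is typical of developmental and cell-differentiation processes,
whose GO terms are unusually rich in TFs.

`mirTFenrich` is for computational biologists who want that second,
transcriptional layer in their miRNA functional analysis. It consumes
three standard resources — TargetScan-style scored target predictions,
PANDA-style tissue-specific TF→gene edge lists, and Biomart-style GO
annotations — and tests the *expanded* target set for GO
over-representation.

## The method

1. **Direct targets.** For a miRNA *m*, keep predicted targets with
   cumulative weighted context++ score < −0.1 (more negative = stronger
   repression) and optionally restrict to the top fraction of the
   score-sorted list. Call this set *D*.
2. **Indirect expansion.** Given a tissue network with edge set *E* and
   TF universe *F*, the combined target set is

       T = D ∪ { g : (f, g) ∈ E, f ∈ D ∩ F }

   i.e. direct targets plus everything regulated by a directly-targeted
   TF (one TF layer, no multi-hop chains). Multiple input miRNAs are
   combined by intersecting their per-miRNA sets.
3. **Over-representation.** For every GO term with ≥ 5 annotated genes,
   with universe size *N* (all annotated genes), term size *K*, target
   size *n* = |T ∩ universe| and overlap *k*, the upper-tail
   hypergeometric p-value is

       P(X ≥ k) = Σ_{j≥k} C(K, j) · C(N−K, n−j) / C(N, n)

   Terms are ranked by p-value (ties broken by accession), a
   Benjamini–Hochberg FDR is reported alongside, and each term's
   **percentile rank** is rank / number of terms tested.

Two companion analyses are included: a **TF-density** statistic per GO
term (number of TFs in the term / term size, with a Wilcoxon rank-sum
comparison of development-keyword terms against the rest) and a
**gold-standard benchmark** that scores known miRNA–GO pairs by the
percentile rank of the best known term, compares direct vs. indirect
targeting with a paired Wilcoxon signed-rank test, and sweeps the
top-fraction grid 20–100%.

## Worked example

The package ships a deterministic synthetic-data generator that emulates
all four input files with a planted indirect signal (each of six miRNAs
targets three "bridge" TFs whose regulons sit inside one planted GO
term):

```r
library(mirTFenrich)

fx   <- generateFixture(defaultFixtureSpec(), "demo")
tab  <- loadTargetTable(fx$paths$targets)
net  <- loadTissueNetworks(fx$paths$network)[["brain"]]
ann  <- loadAnnotationsBiomart(fx$paths$annotations)
gold <- loadGoldStandardTsv(fx$paths$gold_standard)

ts  <- indirectTargets(gold$mirna[1], tab, net)
ts
#> TargetSet: 57 genes | miRNAs: hsa-miR-1-5p | mode: indirect | tissue: brain | top fraction: 1
enrich(ts, ann)
#> EnrichmentResult: 40 terms tested, n = 48 of N = 306
#>   top terms:
#>     1. GO:0000001 synthetic process 0000001 (k=14/K=19, p=5.88e-09)
#>     2. GO:0000016 synthetic process 0000016 (k=4/K=15, p=0.195)
#>     3. GO:0000033 synthetic process 0000033 (k=3/K=10, p=0.195)
```

The miRNA's 30 direct targets reach 57 genes after TF expansion, and the
planted term (GO:0000001) ranks first: 14 of its 19 genes are covered,
far beyond the hypergeometric expectation (p ≈ 6e-09). The benchmark
sweep shows the planted associations are recovered in indirect mode at
every target fraction but not in direct mode:

```r
sw <- fractionSweep(gold, tab, net, ann)
print(sw$summary, digits = 3)
#>        mode top_fraction n mean_percentile     se
#> 1    direct          0.2 6           0.242 0.0363
#> ...
#> 5    direct          1.0 6           0.642 0.0286
#> 6  indirect          0.2 6           0.025 0.0000
#> ...
#> 10 indirect          1.0 6           0.025 0.0000
```

A mean percentile of 0.025 means the known term ranked 1st of the 40
terms tested for every miRNA; the paired signed-rank test on the full
fraction gives one-sided p = 0.016 with all six differences favouring
indirect targeting.

The same pipeline is exposed as a command line:

```sh
inst/scripts/mirtfenrich fixtures --out demo --seed 1234
inst/scripts/mirtfenrich enrich --targets demo/targets.tsv \
    --network demo/network.tsv --annotations demo/annotations.tsv \
    --tissue brain --mode indirect --out result.tsv hsa-miR-1-5p
```

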