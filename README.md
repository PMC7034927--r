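# chefind

Identification and characterization of **chromatin-enriched RNAs (cheRNA)**
from fractionated nuclear RNA-seq.

Biochemical fractionation of the nucleus separates a chromatin pellet extract
(CPE) from a soluble nuclear extract (SNE). Transcripts significantly more
abundant in the chromatin pellet — cheRNAs — are candidate *cis*-regulatory
RNAs: the intergenic subset (icheRNA) behaves like enhancer RNA and tends to
correlate positively with neighboring gene expression, while antisense
cheRNAs are associated with local silencing of their overlapping mRNA.
chefind is for computational biologists analyzing such fractionation
experiments: it takes a transcript annotation (GTF), a raw count matrix over
CPE/SNE samples (TSV + sample sheet), chromatin signal tracks (bedGraph) with
peak calls (BED), and structural-motif interval sets (BED with a family
column), and produces the full downstream analysis.

## The statistics at the core

* **Noise filter** — a transcript is *expressed* iff CPM ≥ 1 in at least half
  of the samples.
* **Chromatin-class call** — an exact negative-binomial two-group test on
  library-size-normalized counts: group sums of *n* i.i.d. NB(μ, 1/φ) counts
  are NB(nμ, n/φ), and the p-value sums, conditional on the total, the
  probabilities of all splits no more likely than the observed one.
  Dispersion φ is method-of-moments, floored and shrunk toward the global
  median. BH correction; `cheRNA` = FDR < 0.05 with log2FC(CPE/SNE) > 0,
  `sneRNA` the mirror call, otherwise `independent`.
* **Positional class** — against coding genes by span overlap (≥ 1 base):
  `sense_overlap` → `antisense` → `intergenic`, first matching rule wins.
* **Neighbor correlation** — each intergenic RNA is paired with the
  same-strand flanking gene of maximal |Pearson r| across all CPE and SNE
  samples; the density of pair correlations is divided by that of a
  random-gene control (relative density), with significance cutoffs at
  r = ±0.8.
* **Metagene profiles** — strand-oriented ChIP-vs-input ratios binned around
  the TSS (±1 kb) or across scaled transcript bodies; transcripts grouped
  high/low by histone-mark peak proximity and compared by two-sided Wilcoxon
  rank-sum tests.
* **RR-score** — overrepresentation of a motif family *r* in a set *t*
  against the noncoding universe *T* under a full-containment rule:
  RR(t, r) = (|t∩r|/|t|) / (|T∩r|/|T|); RR > 1 = overrepresented.
* **Fisher co-enrichment** — two-sided exact test on the 2×2 membership
  table; enriched when OR > 2 and p < 0.05.
* **Evaluation** — ROC/AUC against a proxy gold standard, canonical-locus
  PPV, cell-type specificity R1, and spike-in qPCR abundance A = 2^(−ΔCq).

A seeded synthetic-data generator (`sim_config()`,
`simulate_cherna_experiment()`) emits annotation, counts, tracks, peaks and
motifs with known ground truth, so the whole pipeline runs and is tested
without any external download.

## Worked example

```r
library(chefind)

cfg <- sim_config(seed = 1)                    # reference fixture
fx  <- simulate_cherna_experiment(cfg)         # annotation, counts, tracks, motifs

expressed <- filter_expressed(compute_cpm(fx$counts))
length(expressed)
#> [1] 1000

m <- count_matrix(fx$counts$counts[expressed, ], fx$counts$samples)
calls <- test_fraction_enrichment(m)
table(calls$chromatin_class)
#>      cheRNA independent      sneRNA
#>         209         582         209

tr  <- fx$annotation$transcripts
pos <- setNames(classify_position(tr[match(expressed, tr$transcript_id), ],
                                  coding_genes(fx$annotation)), expressed)
calls <- combine_labels(calls, pos)
table(calls$combined_label)
#>              as-cheRNA              as-sneRNA                icheRNA
#>                     60                     41                    123
#>  independent-antisense independent-intergenic       independent-mRNA
#>                     99                    143                    340
#>                isneRNA            mRNA-cheRNA            mRNA-sneRNA
#>                     34                     26                    134

head(calls[calls$combined_label == "icheRNA", c("transcript_id", "log2fc", "fdr")], 3)
#>     transcript_id   log2fc          fdr
#> 502      lnc_0002 1.604148 6.596348e-07
#> 505      lnc_0005 1.937415 3.006373e-11
#> 506      lnc_0006 1.820389 7.096352e-10
```

The generator planted 200 cheRNAs and 200 sneRNAs at |log2FC| = 2 among 1000
expressed transcripts; the call table above recovers them (209/209 calls,
sensitivity 0.99 at empirical FDR ≈ 0.04 against the ground truth in
`fx$truth`). The `log2fc` column is the CPE-over-SNE log2 fold change of each
intergenic cheRNA and `fdr` its BH-adjusted exact-test p-value.

Co-enrichment of chromatin enrichment with antisense position, on the same
fixture:

```r
f <- fisher_co_enrichment(calls$transcript_id[calls$chromatin_class == "cheRNA"],
                          calls$transcript_id[calls$positional_class == "antisense"],
                          calls$transcript_id)
c(odds_ratio = round(f$odds_ratio, 2), p = signif(f$p_value, 3))
#> odds_ratio          p
#>   1.870000   0.000634
f$enriched       # the flag requires OR > 2 *and* p < 0.05
#> [1] FALSE
```

The full pipeline (filter → call → classify → correlate → metagene → rr →
fisher → evaluate) runs off one config and writes provenance-stamped TSVs:

```r
res <- run_pipeline(pipeline_config(seed = 1), "out/")
res$roc$auc          # ROC-AUC of the cheRNA ranking vs the planted classes
res$metagene$comparison$tier   # Wilcoxon tier, high- vs low-mark icheRNA TSS signal
```

A thin command-line wrapper ships in `inst/scripts/chefind`
(`simulate`, `filter`, `call`, `classify`, `run-all`; `--seed`, `--out`).

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch: it builds
the reference simulated fixture at the given seed, executes the full pipeline
(noise filter, enrichment calls, positional classes, correlation, metagene,
RR, Fisher, evaluation), and writes the JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
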