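# crmclass

Classification of CBP/p300 co-activator binding sites into
regulatory-element classes from multi-factor ChIP signal tracks.

CBP is routinely used (with H3K4me1) as an enhancer mark, but it also
occupies active promoters, Polycomb response elements (PREs) embedded in
H3K27me3 chromatin, and most insulators — where its acetyltransferase
activity can decide whether repressive H3K27me3 spreads into neighbouring
chromatin. `crmclass` is a tidyverse-style R package implementing the full
analysis pipeline for dissecting this repertoire:

1. **Peak calling** — smoothed log2 IP/input enrichment
   (`log2((ip + α)/(input* + α))`, median-smoothed in 100 bp windows);
   high-confidence sites are runs of bins above the 95th percentile of all
   genome bins, ≥ 200 bp long.
2. **Binding matrix** — per peak and dataset, the *top-three-consecutive-bins*
   statistic: the maximal mean of three adjacent bins within ±150 bp
   (proteins) or ±250 bp (histone marks) of the summit, in log2 scale,
   floored at the dataset's genomic mean.
3. **Classification** — PCA after unit-variance scaling, significant-component
   selection (fixed-k or broken stick), Ward clustering (Ward.D2) of the
   scores, tree cut into classes numbered by dendrogram leaf order.
4. **Class characterization** — gene-feature assignment
   (promoter > exon > intron > intergenic), expression tertiles via nearest
   TSS, overlap fractions against reference region sets with seeded
   random-genomic-region controls, inter-class gene-sharing matrices,
   within-class Spearman correlations against the IP, developmental
   expression profiles, and distance-to-domain statistics.
5. **Insulator boundary analysis** — histone-based subclassification
   (acetylation-high vs -low), oriented H3K27me3 metaprofiles in ±10 kb
   flanks (stronger flank forced right), and ChIP-qPCR ΔΔCq fold analysis
   normalized to two intergenic control sites and total histone H3.
6. **Word enrichment** — overlapping k-mer counts versus A/T-matched control
   sequences, log2 rate ratios with one-sided binomial p-values and
   reverse-complement pooling.

A first-class synthetic-data generator (`simulate_dataset()`,
`simulate_sequences()`, `simulate_qpcr()`) plants promoter-, enhancer-,
PRE- and insulator-like archetypes with known ground truth so the whole
pipeline is testable at desk scale.

## Quick start

```r
library(crmclass)

sim <- simulate_dataset(seed = 1)           # 5 Mb genome, 6 archetypes x 40 elements
pl  <- run_pipeline(sim, pipeline_config(n_classes = 6, seed = 1))
pl
#> <crm_pipeline> 240 peaks, 6 classes
#>   recovery: sensitivity 1.000, FDR 0.000, ARI 1.000

glance(pl$model)
#> # A tibble: 1 x 5
#>   n_obs n_vars n_significant n_classes explained_significant
#> 1   240     14             3         6                 0.878
```

All 240 planted elements are recovered as peaks (sensitivity 1.000), no
called peak falls outside a planted element (FDR 0.000), and the six classes
match the planted archetypes exactly (adjusted Rand index 1.000), with three
principal components carrying 87.8% of the variance. The strongest scaled
IP signal sits in the PRE-like class:

```r
es <- enrichment_summary(pl$matrix, pl$model$classes)
head(dplyr::arrange(es[es$dataset == "CBP", ], dplyr::desc(mean)), 3)
#> # A tibble: 3 x 6
#>   class dataset  mean ci_lo ci_hi     n
#> 1     4 CBP     0.774 0.764 0.784    40
#> 2     5 CBP     0.662 0.654 0.670    40
#> 3     6 CBP     0.593 0.585 0.602    40
```

(0 = genomic mean, 1 = genomic maximum; class 4 holds the planted PREs.)
`autoplot(pl$model)` draws the PCA score plot coloured by class;
`oriented_profile()` + `autoplot()` draw the H3K27me3 boundary metaprofiles.

A thin command-line wrapper lives in `inst/cli/crmclass.R`
(`simulate`, `run`, `callpeaks` verbs over the same functions).

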