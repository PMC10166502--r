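# peakscape

Transposable-element (TE) composition, enrichment and expression analysis
of protein–DNA binding peaks, in R.

KRAB-domain zinc-finger proteins silence transposable elements, and
genome-wide binding assays (CUT&RUN, ChIP-seq) for such factors produce
peak sets that sit largely over repeats — mouse B1/Alu SINE elements being
a classic target. Interpreting such a peak set requires a small but
specific toolkit that this package provides end to end:

* **Peak annotation** against RepeatMasker repeat tracks (with the
  replicated peak × TE row layout used for supplementary tables), gene
  models (promoter / 5'UTR / CDS / 3'UTR / intron / intergenic by summit
  position) and ENCODE candidate cis-regulatory elements (cCREs).
* **Enrichment statistics**: for each repeat class or family the genomic
  *coverage ratio* `c_g` (merged bp of the group divided by genome
  length) and the *fold enrichment* `E_g = f_g / c_g`, where `f_g` is the
  group's frequency among peaks (incidence-, bp- or peak-based).
* **Motif accounting**: position-weight matrix scanning with *exact*
  p-values (position-wise convolution of the discretised score
  distribution under an i.i.d. background, FIMO-style), and assignment of
  motif hits to the repeats under the peaks. A frameshift ORF predictor
  translates an indel-bearing CDS to its premature stop and counts
  missense residues.
* **TE expression**: TE-transcripts-style counting of multi-mapped reads
  (uniform, hash-deterministic random assignment), median-of-ratios
  normalisation, a simplified negative-binomial Wald test with
  Benjamini–Hochberg FDR, run genome-wide or independently per
  chromosome, plus significance threshold summaries.
* **Synthetic-data generators** for every input class — repeat
  annotations at controllable coverage ratios, peaks with a planted
  placement bias whose fold is the exact estimand of the enrichment
  statistic, NB count matrices with known fold changes, multi-mapped
  alignments with known origins, and motif-planted sequences — so every
  stage is testable without any download.

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe; DE results support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

```r
library(peakscape)
library(tibble)

# a small genome annotated with four repeat families
genome <- tibble(chrom = c("chr1", "chr2"), length = c(5e5, 5e5))
te_spec <- tibble(
  rep_name   = c("B1_Mus1", "L1Md_F", "IAPLTR1_Mm", "MER1_type"),
  rep_family = c("Alu", "L1", "ERVK", "hAT-Charlie"),
  rep_class  = c("SINE", "LINE", "LTR", "DNA"),
  mean_len   = c(1200, 2500, 1500, 1000),
  target_ratio = c(0.10, 0.08, 0.05, 0.03))
repeats <- simulate_repeat_annotation(genome, te_spec, seed = 1)

# 2000 peaks placed with a 6-fold preference for the Alu (B1) family
peaks <- simulate_peaks(repeats, genome, n_peaks = 2000,
                        bias = c(Alu = 6), peak_len = 30, seed = 2)

annotation <- annotate_peaks_with_tes(peaks, repeats)
te_composition(annotation, level = "class")
#> Composition summary (level: class; denominator: 1561 = distinct
#> (peak, class) incidences)
#> peaks with >=1 TE: 78.0%
#> # A tibble: 4 × 3
#>   group count percentage
#>   <chr> <int>      <dbl>
#> 1 SINE   1213      77.7
#> 2 LINE    170      10.9
#> 3 LTR      99       6.34
#> 4 DNA      79       5.06

enrichment_fold(
  peak_frequency(annotation, "family", mode = "peak_fraction"),
  genome_coverage_ratio(repeats, sum(genome$length), "family"))
#> # A tibble: 4 × 5
#>   group       frequency  ratio zero_coverage enrichment
#>   <chr>           <dbl>  <dbl> <lgl>              <dbl>
#> 1 Alu            0.606  0.101  FALSE              6.02
#> 2 hAT-Charlie    0.0395 0.0299 FALSE              1.32
#> 3 L1             0.085  0.0795 FALSE              1.07
#> 4 ERVK           0.0495 0.0498 FALSE              0.994
```

78% of the peaks contain at least one repeat; the planted 6-fold
placement bias comes back as an enrichment of ~6 for the Alu family while
unbiased families sit near 1 (any-overlap counting inflates the fold of a
short peak over a long repeat by roughly `1 + peak_len /
mean_repeat_len`, a percent or two here).

A full run — annotation, compositions, enrichment, motif scan,
differential expression, TSV tables, `summary.json` and a log — is one
call:

```r
cfg <- write_demo_dataset("demo_inputs", seed = 7)   # synthetic bundle
run_pipeline(cfg, "demo_out")
```

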