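# mztseq

Analysis of the maternal-to-zygotic transition (MZT) from paired
poly(A)-selected and rRNA-depleted RNA-seq timecourses, for embryologists
and genomicists who want to separate what early embryos *transcribe* from
what they merely *readenylate* or *deadenylate*.

## The problem and the approach

Early embryos run on maternally deposited mRNA until zygotic genome
activation (ZGA), while maternal transcripts are cleared in parallel.
Poly(A)+ RNA-seq alone cannot tell these programs apart: its signal for
gene *g* in sample *s* is proportional to abundance × capture,

```
E[K_pA]  ∝  M_g(t) · A_g(t) · len_g        (poly(A)+ library)
E[K_rd]  ∝  M_g(t) · len_g                 (rRNA-depleted library)
```

where `M_g(t)` is transcript abundance and `A_g(t) ∈ [0,1]` the
poly(A)-capture efficiency (a proxy for tail length). Building both
library types from each biological sample makes `A_g(t)` identifiable:
a poly(A)+-only decrease is deadenylation, a decrease in both libraries is
degradation, and a poly(A)+-only increase is cytoplasmic readenylation.
Intronic reads in the rRNA-depleted libraries, quantified as pre-mRNA
counts minus exon counts and RPKM-filtered, time transcription directly —
they reveal re-activation of genes whose large maternal pools swamp any
exon-level increase.

On top of this design the package provides:

* negative-binomial Wald differential expression (median-of-ratios size
  factors, moment dispersions with a 1/µ trend, BH adjustment) — a
  transparent, simulation-calibrated analogue of a DESeq2-style analysis;
* ZGA calling from combined exon + intron tables, maternal/zygotic route
  classification (egg TPM ≥ 1 = maternal; < 0.5 = pure zygotic), class
  transcriptome-fraction trajectories and a 10-kb windowed activation scan;
* clearance timing per library type with an oscillation filter, tail-
  dynamics classes (readenylated / deadenylated-only / deadenylate-then-
  degrade / degraded-without-lead / stable), and Wilcoxon signed-rank
  tests of transcription dependence under Triptolide;
* stage-specific clustering, chi-squared GO enrichment, codon adaptation
  index (CAI), and a discriminative 3'UTR k-mer screen;
* cnidarian-style miRNA discovery (homology + Nussinov base-pair-maximized
  hairpins + inhibition dependence) and target prediction by near-full
  antisense complementarity scoring Watson–Crick pairs 1 and G:U wobbles
  0.5 (hits need score ≥ length − 4);
* a synthetic-data generator emulating the full study design — paired
  libraries, egg/0.5/1–7 h timecourse, Triptolide arm, larval poly(A)+
  references, eight ground-truth trajectory classes, planted miRNA
  precursors and target sites — for end-to-end validation.

## Worked example

```r
library(mztseq)
cfg     <- sim_config(n_genes = 500, seed = 7)
fixture <- file.path(tempdir(), "mzt_fixture")
sim     <- simulate_study(fixture, cfg)             # writes TSV/GTF/FASTA
res     <- run_pipeline(fixture, file.path(tempdir(), "mzt_results"))

table(res$zga$calls$route)
#>        ambiguous    maternal_only maternal_zygotic     zygotic_only
#>               10              356              111               23
```

356 genes are maternal with no detected re-expression, 111 maternal genes
are re-activated by the embryo (mostly via intron evidence), 23 are purely
zygotic, and 10 sit in the ambiguous 0.5–1 TPM egg band.

```r
res$clearance$inhibition[, 1:5]
#>          group  n median_diff  direction            p
#>    early_polyA 83  0.12744534 stabilized 7.365764e-04
#>  early_ribodep 83  0.07204367 stabilized 1.334812e-01
#>     late_polyA 34  1.96589639 stabilized 1.309453e-06
#>   late_ribodep 34  1.84002711 stabilized 4.180083e-07
```

Late-cleared mRNA (first poly(A)+ decrease ≥ 5 h) are strongly stabilized
by transcription inhibition (median ≈ +2 log2 units vs mock): their
clearance needs zygotic products. Early deadenylation proceeds essentially
unimpeded (medians near zero), the signature of a maternally catalysed
first clearance phase.

```r
res$mirna$candidates[res$mirna$candidates$candidate,
                     c("mirna_id", "transcript_id", "mismatches",
                       "stem_fraction", "reason")]
#>   mirna_id transcript_id mismatches stem_fraction    reason
#>  ref-miR-1        g00164          1             1 candidate
#>  ref-miR-2        g00095          1             1 candidate

cat(res$mirna$diagrams[1])
#> target g00051 1172-1193
#> 5'-AAAGGCCCACCCAAGGUCCGUA-3'
#>    ||||||||||||||||||||||
#> 3'-UUUCCGGGUGGGUUCCAGGCAU-5' ref-miR-1
```

Both planted precursors survive all four candidate filters (homology ≤ 2
mismatches, activated host, ≥ 0.6 stem-paired fraction, Triptolide-down
host), and the planted 22-nt antisense site in a cleared transcript is
recovered as a perfect duplex.

```r
fr <- res$zga$fractions
fr[fr$class == "histone" & fr$timepoint_h %in% c(0, 3, 4, 7), ]
#>    class timepoint_h    fraction net_activation
#>  histone           0 0.005574706       1.000000
#>  histone           3 0.011292565       2.025679
#>  histone           4 0.089082667      15.979797
#>  histone           7 0.094828676      17.010525
```

Histone-class mRNA double their transcriptome share by 3 h and reach a
~16-fold share increase by 4 h — the non-adenylated histone burst that
only the rRNA-depleted libraries can see.

Every stage also lands on disk as a TSV (`de_*.tsv`,
`activation_calls.tsv`, `clearance_calls.tsv`, `inhibition_tests.tsv`,
`stage_clusters.tsv`, `cai.tsv`, `kmer_enrichment.tsv`,
`mirna_candidates.tsv`, `mirna_targets.tsv`, …) plus a deterministic
`log.txt`; rerunning on the same inputs reproduces every file byte for
byte.

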