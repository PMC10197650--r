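---
title: "Dissecting the maternal-to-zygotic transition from paired poly(A)+ and rRNA-depleted RNA-seq"
author: "mztseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the maternal-to-zygotic transition from paired poly(A)+ and rRNA-depleted RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztseq)
```

## The measurement problem

Early embryos start life running on maternally deposited mRNA. The
maternal-to-zygotic transition (MZT) replaces that inheritance with the
embryo's own transcripts through two overlapping programs: zygotic genome
activation (ZGA) and maternal mRNA clearance. Standard poly(A)-selected
RNA-seq conflates the two kinds of change that happen during this window:
a transcript whose poly(A) tail shortens drops out of the poly(A)+ library
even though every copy of it is still present, and a transcript that is
readenylated after fertilization looks "induced" without a single new
molecule having been made. Non-adenylated species — most prominently
replication-dependent histone mRNA — are invisible to poly(A)+ selection
altogether.

`mztseq` analyses timecourses in which every biological sample was split
into two libraries: a poly(A)-selected one, whose signal is abundance
times poly(A)-capture efficiency, and an rRNA-depleted one, whose signal
is abundance alone. The difference between the two library types is the
estimator of poly(A)-tail dynamics; the rRNA-depleted libraries alone
carry absolute abundance, intronic (pre-mRNA) signal, and histone mRNA.

## Model and analysis stages

For gene $g$ at time $t$ the generator (and, implicitly, the analysis)
works with three latent per-gene trajectories:

* $M_g(t)$ — transcript abundance,
* $A_g(t) \in [0,1]$ — poly(A)-capture efficiency, a multiplicative
  stand-in for poly(A)-tail length,
* $Z_g(t) \ge 0$ — transcription rate, visible only as intronic signal
  from unspliced pre-mRNA in rRNA-depleted libraries.

Expected counts are multinomial shares of the library depth:
$\mathbb{E}[K^{\mathrm{pA}}_{gs}] \propto M_g A_g \ell_g$ and
$\mathbb{E}[K^{\mathrm{rd}}_{gs}] \propto M_g \ell_g$, with pre-mRNA
contributing $\kappa Z_g \iota_g$ to the rRNA-depleted pool ($\ell_g$,
$\iota_g$: summed exon and intron lengths). Counts are negative binomial
with variance $\mu + \phi\mu^2$.

### Differential expression

Each timepoint is tested against the egg (0 h) reference per library type
with a deliberately transparent negative-binomial Wald test:
median-of-ratios size factors; method-of-moments gene-wise dispersions
clamped at zero per replicate group and pooled with df weights; a
$\phi(\mu) = a_0 + a_1/\mu$ trend fit by least squares; the final
dispersion is the geometric mean of the gene-wise estimate (floored at
$10^{-8}$) and the trend. The fold change is
$\log_2\!\big((\bar m_t + \tfrac12)/(\bar m_0 + \tfrac12)\big)$ on
normalized group means, its standard error comes from the delta method,
and $z$ is referred to the standard normal. BH adjustment is per
contrast. This is an explicit simplified analogue of a DESeq2-style
analysis — shrunken fold changes, Cook's filtering and GLM covariates are
non-goals — and its calibration is checked by simulation in the test
suite rather than by concordance with another package.

Genes with fewer than 10 reads summed over the samples of a library are
discarded before testing.

### Genome activation from intron signal

Re-activated maternal genes are largely invisible at the exon level: the
new transcription adds a modest increment to a large maternal pool.
Intronic reads, however, can only come from unspliced pre-mRNA, so they
time transcription directly. The intron table is pre-mRNA counts minus
exon counts (clamped at zero), filtered to genes whose intronic RPKM —
summed intron length as the length factor, summed pre-mRNA counts as the
library factor — reaches 0.5 in at least one sample. Exon and intron
entries are stacked into one table so that they share size factors and
enter BH adjustment jointly within each contrast; a gene is activated by
intron evidence when its intron entry is significantly up.

Maternal status uses egg TPM in the rRNA-depleted libraries with two
thresholds: maternal at $\ge 1$ TPM and pure-zygotic below $0.5$ TPM. The
band in between is reported as `ambiguous` rather than forced into either
class, because the two thresholds answer different questions (is there
appreciable maternal product? / is the egg effectively empty of it?).

### Clearance: deadenylation versus degradation

A gene's first significant $\ge 2$-fold decrease versus egg is computed
independently in the two library types. The poly(A)+ decrease times
deadenylation; the rRNA-depleted decrease times degradation of the
transcript body; their difference (`lead_h`) measures how long tails
shorten before the transcript is destroyed. Genes whose normalized mean
trajectory rises by more than 1.5-fold between consecutive stages are
disqualified outright (the oscillation filter), keeping only
monotone-looking clearance profiles. Tail classes follow from the two
times plus poly(A)+ up-calls (readenylation = poly(A)+ rise without a
matching rRNA-depleted rise at the same timepoint).

The oscillation filter deserves a caveat: it is applied to the point
estimates of stage means, so with shallow libraries or few replicates
counting noise alone disqualifies an appreciable fraction of genuinely
monotone genes (at dispersion 0.05 with duplicates, roughly a quarter to
a third per library over ten stages). The filter is kept in its literal
form because it is part of the analysis definition; sensitivity numbers
on synthetic data should be read with this in mind.

### Transcription inhibition

The Triptolide arm asks which clearance is zygotically triggered. Per
gene, the log2 fold change versus egg under inhibition is paired with the
mock value, and the paired differences are tested by Wilcoxon signed rank
(exact for $n \le 25$ without ties, normal approximation with continuity
correction otherwise; zeros dropped). `stabilized` means inhibition
raised the fold change, i.e. clearance needed transcription. Early
deadenylation (onset 2–4 h) is expected to proceed regardless; late
clearance (onset $\ge 5$ h) is expected to stabilize in both library
types.

### Downstream analyses

*Stage-specific expression*: stage means of poly(A)+ TPM; specific genes
fall below 1 TPM in some stage, exceed 5 TPM in another, and differ
significantly from egg somewhere; the peak stage clusters them (ties go
to the earliest stage, deterministically). *GO enrichment*: per term, a
2×G table of annotated versus not across the G stage clusters, Pearson
chi-squared on G−1 df (df adjusts and is logged when G ≠ 5), BH over
terms; tables with expected cells below 1 are flagged rather than
dropped. *Codon adaptation*: relative adaptiveness $w_c = f_c/\max f$
within each synonymous family from the reference set's codon counts
(pseudocount 0.5 on unseen codons), CAI as the geometric mean of $w$ over
a gene's codons excluding Met, Trp and stops; cleared versus stable
groups compared by two-sided Mann–Whitney (the rank test makes no
distributional assumption about CAI). *3'UTR motifs*: a discriminative
k-mer screen (k = 5–8, one-sided Fisher per k-mer, BH within each k,
UTRs ≤ 20 nt discarded) — an explicit, transparent stand-in for EM-based
motif discovery, and labelled as such in outputs.

### miRNA discovery and targets

Candidate miRNAs are transcript segments that (a) match a reference
mature miRNA with at most 2 mismatches (ungapped sense scan), (b) sit in
a significantly activated host transcript, (c) fold into a hairpin whose
paired fraction over the mature positions is at least 0.6, and (d) lose
their host's expression under Triptolide — i.e. are zygotically encoded.
Folding is Nussinov-style base-pair maximization (minimum loop 3, G:U
admitted): a pair-count criterion is a deliberate simplification of
thermodynamic folding, sufficient to recognize the long near-perfect
stems of miRNA precursors, and is validated against brute-force
enumeration in the tests. Mismatch and score thresholds replace the
E-value cutoffs a BLAST-based search would use, because E-values depend
on database size and are not reproducible in a reimplementation; both are
configuration keys.

Target prediction reflects the cnidarian regime of near-full-length
complementarity rather than bilaterian seed matching: every ungapped
antisense window is scored with Watson–Crick pairs worth 1, G:U wobbles
0.5 and mismatches 0, and windows scoring at least mature length − 4 are
reported, labelled by membership in the cleared and stable gene sets,
with a three-line text rendering of each duplex.

## The synthetic study design

`sim_config()` encodes the emulated design: 2000 genes; timepoints egg,
0.5 h and hourly 1–7 h; two replicates; paired libraries per sample at
2×10⁶ expected reads; a Triptolide arm and its DMSO mock (identical to
untreated, as observed in practice) collected at 7 h; optional
poly(A)+-only larval references at 24/48/72 h as single libraries;
NB dispersion 0.05; pre-mRNA fraction κ = 0.05.

Eight trajectory classes carry the ground truth: `maternal_stable`
(constant M, A = 0.7), `readenylated` (A 0.2 → 0.9 by 2 h),
`deadenylated_only` (A 0.7 → 0.25 at an onset in {2,3,4} h → 0.15 an hour
later; the kinetics are a declared free default, the data constrain only
their observable), `cleared_early` (deadenylation plus a 4-fold M drop at
6–7 h), `cleared_late` (A falls from 5 h, M drops 4-fold at 7 h,
transcription-dependent), `zygotic_only` (maternal floor 5×10⁻⁴ of
baseline, i.e. egg TPM below 0.5 by construction; ramps to its plateau
over 3 h from an onset in {2,3,4} h; A = 0.9), `maternal_zygotic`
(baseline plus a zygotic increment of 10–30% of baseline), and
`histone_like` (A = 0.02, baseline scaled ×0.1, abundance ×2 by 3 h and
×18 by 4 h, single-exon gene models — replication-dependent histones are
intronless and non-adenylated).

Two generator choices deserve explicit justification. First, the
transcription rate of `maternal_zygotic` genes is an independent
lognormal scale, not the (small) exon-level increment: transcription
output at genome activation does not scale with how much maternal product
happens to sit in the cytoplasm, and tying the two together would erase
the intron-visible/exon-invisible signature this study design exists to
detect. Second, CDS sequences share one biased codon distribution
(lognormal weights over sense codons): with uniform codon usage, relative
adaptiveness is pure noise and the CAI of the reference genes correlates
with the estimate built from them, producing spurious group differences;
shared bias is both the realistic case and the regime in which the CAI
comparison is well defined. Baseline abundances are lognormal
(sdlog = 1); poly(A) capture is a single multiplicative efficiency —
sufficient for the observable (differential pulldown) and identifiable at
this scale, whereas explicit tail-length distributions would not be.

Planted sequence elements make the miRNA stage testable end to end: each
simulated precursor (mature + 8-nt loop + reverse complement) sits in the
3'UTR of a zygotic host; the reference FASTA carries one-mismatch
homologs of the planted matures plus unrelated decoys; 22-nt antisense
sites are planted in a configurable number of `cleared_late` 3'UTRs; an
AU-rich motif marks half of the cleared-gene UTRs.

What the generator does not emulate — and hence what green tests do not
show about real data: sequence-dependent library biases, time-varying
pre-mRNA fractions, partial or isoform-level splicing, tail-length
distributions (only their pulldown consequence), read-level alignment
ambiguity, and biological replicate structure beyond shared NB noise.

## Numerical choices and degenerate inputs

Pseudocounts: 0.5 on normalized group means in fold changes (bounded,
symmetric); 1 on depth-normalized window counts; 0.5 on unseen reference
codons. Dispersions are floored at 10⁻⁸; the trend is clamped positive.
Zero-depth samples yield zero abundances with a warning rather than an
error. Negative intron counts (exon > pre-mRNA, a counting-noise
artifact) clamp to zero with a warning. Wilcoxon zeros are dropped; with
fewer than five usable pairs the report says so instead of printing a
p-value. Peak-stage and traceback ties break deterministically (earliest
stage; rightmost admissible pairing partner). All randomness flows from
a single integer seed; rerunning the pipeline on the same inputs
reproduces every output byte for byte.

## Problem sizes

The shipped tests and the acceptance script run the full default study
(2000 genes, 47 samples) once and reuse it; the statistical calibration
uses 5000-gene null simulations, 50 CAI replicates, 100 dinucleotide
shuffles, 500 brute-force folding comparisons and 1000 BH vectors. These
sizes were chosen to make every property measurable with comfortable
margins on a single CPU.

## Known limitations

The Wald test with moment dispersions is mildly anticonservative at two
or three replicates — the null simulation places its type-I error near
the top of the acceptable band, driven by genes whose moment estimate
collapses to zero — and the literal oscillation filter costs clearance
sensitivity at realistic noise, as discussed above. Homology-based miRNA
discovery cannot find miRNAs without a related reference mature; the
hairpin criterion scores pair counts, not free energy; GO enrichment does
not propagate the term graph; and the windowed genome scan consumes
precomputed window counts rather than alignments.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 500, seed = 7)
fixture <- file.path(tempdir(), "mzt_fixture")
outdir <- file.path(tempdir(), "mzt_results")
sim <- simulate_study(fixture, cfg)
res <- run_pipeline(fixture, outdir)

head(res$zga$calls)                 # activation routes and evidence
res$clearance$inhibition            # Wilcoxon reports, early vs late
res$mirna$candidates                # homology + hairpin + inhibition
cat(res$mirna$diagrams[1])          # a rendered duplex
```
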