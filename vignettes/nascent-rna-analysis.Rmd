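---
title: "Methods: pausing, enhancer calling, and prioritization from nascent RNA sequencing"
author: "nascentr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pausing, enhancer calling, and prioritization from nascent RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentr)
```

# Scope and data model

`nascentr` analyses strand-specific nascent-RNA read alignments (GRO-seq,
PRO-seq) given as 6-column BED or BAM. Every read is reduced to a single
base — by default its 5′-most genomic base — so that window counts are
unambiguous at region borders; `count_mode` exposes 3′ and full-span
alternatives, and `flip_strand` accommodates library chemistries that
report the opposite strand. BAM records with mapping quality below 10 are
discarded; BED input is assumed pre-filtered upstream (it carries no MAPQ).
Coordinates are 0-based half-open (BED convention) everywhere internally.
rRNA-locus removal, adapter trimming and alignment are upstream concerns
and out of scope.

# Known-gene quantification

For each annotated gene the **promoter-proximal (pp) region** is the 50 bp
window with the largest sense-strand read count among windows placed every
5 bp across ±500 bp of the TSS. Ties are resolved deterministically:
largest count, then smallest distance of the window center to the TSS, then
the more upstream window (strand-aware). The **gene body (gb)** spans
TSS+1 kb to the TTS; genes of 1 kb or less have no body and are skipped
(reported, not erased). The **pausing index** is
`pp_density / gb_density` (both in reads/bp) and is `NA` when the body is
empty — a ratio against zero carries no information.

Pausing **significance** is a one-sided Fisher's exact test comparing the
observed `(pp, gb)` counts to the split expected from region lengths alone:
with `N = pp + gb`, the expected row is
`E_pp = round(N · pp_len/(pp_len + gb_len))`, `E_gb = N − E_pp`. Rounding
is required because an exact conditional test needs integer margins; the
one-sided alternative asks specifically for promoter enrichment.

A gene is **active** when its pp density is strictly positive and its
gene-body density strictly exceeds 4 reads/kb after scaling the library to
10⁷ mapped reads. Plain library-size scaling is used; when spike-ins or an
external background estimate are available, per-sample factors can be
supplied (`norm_factor`, `--norm-factors`) and take precedence. Both
inequalities are strict, so a gene at exactly 4 reads/kb is inactive.

Binned profiles (`signal_profile`, `tss_profile_matrix`) use ±5 kb / 200 bp
around TSSs and ±2 kb / 20 bp around enhancer centers by default, scale
each sample to 10⁷ reads, and compute per-bin
`log2((b + 1)/(a + 1))` between conditions — a pseudocount of one
normalized read keeps empty bins finite without dominating occupied ones.
Minus-strand rows are reversed so columns always read 5′→3′.

# Normalization and differential testing

**Size factors** are classical median-of-ratios: for sample *j*, the median
over features (restricted to rows positive in all samples) of
`count_ij / geometric_mean_i`. The median is taken in linear space; with no
all-positive feature the function stops and directs the user to supply
factors, rather than silently degrading.

The **negative-binomial differential test** is authored here rather than
delegated, and is validated in two independent ways: distributionally
(type-I error within [0.03, 0.07] at nominal 0.05; fold-change bias below
0.02 on planted 4-fold effects) and against DESeq2 as an external
cross-check (log2FC correlation > 0.95 on a mixed simulation). The
estimator:

* normalizes counts by the size factors;
* estimates per-feature dispersion by method-of-moments from the pooled
  within-condition variance (`Var(k/s) = μ/s + α μ²`);
* fits a mean–dispersion trend `α(μ) = a₁/μ + a₀` by iteratively
  re-weighted least squares with outliers above 15× the trend dropped;
* shrinks log-dispersions toward the trend with the gene-wise weight set to
  the residual degrees of freedom over two and a prior weight of 4
  pseudo-df. The prior weight was fixed once, by calibrating the null
  type-I error to nominal on simulation — with 2+2 designs the gene-wise
  moment estimate alone is far too noisy, while pure trend dispersion is
  over-conservative;
* tests `log2((μ₂ + ½)/(μ₁ + ½))` with a Wald statistic whose variance
  follows from the NB variance of the per-condition means, and adjusts by
  Benjamini–Hochberg across tested features. All-zero features are
  reported `NA` and excluded from the adjustment so they do not dilute it.

Conditions are taken in order of first appearance in the sample sheet; the
second condition is the numerator of the fold change.

**Pausing-index change** between conditions is tested per gene on the 2×2
table of (pp, gb) counts: a two-sided Fisher's exact test when each
condition has a single sample, and the continuity-corrected
Cochran–Mantel–Haenszel test over replicate-pair strata otherwise (stratum
*r* pairs replicate *r* of each condition; with unequal replicate counts
the first `min(n₁, n₂)` pairs are used). A zero margin yields `p = 1` and
an `NA` odds ratio. Genes enter differential testing only if active in at
least one sample; enhancers and long eRNAs only if they carry any reads.

The **replicate-change histograms** show per-feature log2 ratios between
replicate pairs after normalization; an adequate normalization centers them
at zero, which is the recommended visual check before trusting the
differential calls — especially when a global shift is suspected and
spike-in factors might be needed.

# Enhancer calling

Transcripts are called de novo on coverage pooled across all samples, per
strand, with 200 bp windows every 50 bp. A window belongs to transcript
territory when its density exceeds `body_fold = 3` times the local
background; runs of such windows joined across gaps shorter than
`max_gap = 1000` bp become a transcript if they contain at least one
window above `tss_fold = 4` times background and span at least
`min_length = 250` bp. Boundaries are therefore accurate to about one
window, which is the tolerance the tests assert.

The **local background** is a running median of window densities over a
100 kb flanking span, floored by a pseudo-density of 0.05 reads/bp. The
median is taken over *all* windows (zeros included): on sparse coverage the
median of only the nonzero windows degenerates to the signal's own density
and would suppress every call. Windows near a track edge inherit the
background of the nearest window with a full span, so a feature at the
start of a chromosome cannot inflate its own baseline. The fold thresholds
(4 and 3) are the method's published operating point and are CLI-exposed
along with every other caller knob.

**Intergenic restriction** removes any transcript overlapping a gene
extended 2 kb upstream of its TSS (promoter shadow) and 20 kb downstream of
its TTS (polymerase read-through), strand-aware in the extension and
strand-blind in the overlap.

**Pairing and centers.** A plus/minus transcript pair forms an enhancer
when the distance between their 5′ ends is at most 400 bp — inclusive, and
covering the overlapping-5′ case — with the center at the midpoint of the
two 5′ ends (odd spans round down); or when one transcript lies entirely
within the other, with the center at the contained transcript's 5′ end.
Both rules can fire on the same region, and one transcript can pair with
several partners: transcripts connected through shared pairs collapse into
a single enhancer carrying the sorted union of centers. Convergent
(3′-facing) geometries never satisfy either rule. Enhancers closer than
500 bp (strictly) are merged transitively; merging is idempotent and the
post-condition — all gaps ≥ 500 bp — is asserted in tests.

An enhancer is **known** when any center falls inside a catalog interval;
region overlap without center containment does not count. Quantification
sums both strands over the enhancer region, since both eRNAs report on the
same regulatory element. Unpaired unidirectional transcripts strictly
longer than 10 kb are **long eRNAs**, re-analyzed with the gene machinery
(TSS = 5′ end); transcripts consumed by a pair are never long eRNAs.

# Linking and prioritization

Enhancers are assigned only to **active** genes, by four strategies:
closest TSS (exact distance ties link all tied genes); all TSSs within
50 kb (inclusive); an enhancer–TSS association catalog (center containment
in the catalog's enhancer interval); and experimentally detected chromatin
interactions (center in one anchor, active TSS within ±2 kb of the other —
interaction anchors are coarse, so a tolerance is needed; 2 kb matches the
promoter scale used elsewhere). A tissue filter restricts interaction rows
first. An absent catalog skips its strategy with a notice rather than
failing the run.

The **binding-affinity score** is `B_s = exp(−d/d₀)` with `d` the smallest
peak-anchor–to–center distance and `d₀ = 5000` bp by default — an
exponential-decay regulatory-potential kernel at the kb scale typical of
such models; with no peak on the chromosome `B_s = 0` (the d→∞ limit).
narrowPeak summits are used as anchors when present, midpoints otherwise.

The **functional-activity score** averages, over the four strategies, the
indicator-weighted product of the enhancer's and its linked genes'
normalized transcriptional changes: `F_s = Σ I·C_en·C_g / 4`, with the mean
(default) or maximum over multiple genes linked by one strategy. The
changes are log2 fold changes floored at zero and divided by the maximum
over the scored set, so `C ∈ [0, 1]` and `B_s` and `F_s` are commensurable;
only concordant increases score, matching the use of the ranking on
upregulated enhancers. A rank-based normalization is available when the
raw fold-change scale is unstable. Promoter-proximal gene changes are the
default `C_g` source, since polymerase recruitment at the promoter is the
earliest transcriptional readout of enhancer action.

The combined score `E_s = w·B_s + (1−w)·F_s` (default `w = 0.5`) ranks
enhancers best-first; equal scores share a dense rank and order within a
tie by `B_s`, then id, so output is fully deterministic.

# The synthetic study

`default_sim_config()` defines the validation conditions: one 5 Mb
chromosome; 40 genes of 10 kb every 120 kb on alternating strands, each
with a 50 bp paused block at 2 reads/bp (pausing index 5) over a
0.4 reads/bp body; 20 enhancers of two divergent 800 bp transcripts at
0.5 reads/bp, centered 40 kb downstream of their gene's TSS — outside every
gene's exclusion zone, uniquely closest to their gene, and inside the 50 kb
link window; two replicates per condition at roughly 2×10⁵ reads per
sample. Genes 1–10 gain promoter signal (log2FC 1.2, gene 1 at 2.0),
genes 11–15 lose signal; enhancers 1–6 are upregulated (1.5; enhancer 1 at
2.5 with a ChIP peak at its center), 7–8 downregulated. Odd-numbered
enhancers are in the known catalog; enhancers 2–3 carry peaks displaced by
8 kb so binding evidence separates ranks.

Per-base counts are drawn NB(μ = rate·depth·2^(lfc·condition),
dispersion 0.05) independently per sample, written as 1 bp BED reads —
read length is irrelevant under 5′-base counting — and the generator is
byte-deterministic given its seed. It emulates localized pp signal, diffuse
gb signal, divergent eRNA pairs, NB count noise, and matching
annotation/catalog/peak files. It does **not** emulate fragment-length
structure, sequence or mappability bias, background transcriptional noise
(an optional uniform `bg_rate` exists but defaults to zero), overlapping
genes, or multi-isoform annotation — so passing tests demonstrate the
correctness of the rules and estimators, not robustness to every artifact
of real libraries.

Problem sizes in the test-suite and acceptance script (40 genes,
20 enhancers, 2 500 null features, 500 effect features, 1 000 random
window-search instances) were chosen as the smallest sizes at which the
stochastic assertions are stable across seeds.

# Numerical choices and degenerate inputs

* pp-window ties: count, then center-to-TSS distance, then upstream —
  deterministic and anchored to the biology (pausing sits near the TSS).
* Midpoints with odd spans round down; all thresholds are applied exactly
  as stated (≤ 400 pairing, < 500 merging, > 10 000 long eRNA, > 4 reads/kb
  activity) and boundary cases are pinned by tests on both sides.
* Zero-coverage promoters give count 0, not an error; empty inputs
  propagate as empty outputs; unknown chromosomes in queries warn and
  return 0.
* `fisher.test`'s conditional-MLE odds ratio is reported; `p = 1` and
  `OR = NA` on degenerate margins.

# Known limitations

Bidirectional transcription also marks some promoters and novel TSSs:
without orthogonal marks (H3K4me3, RNA-seq exon-junction evidence) an
apparent enhancer — especially a long eRNA — can be an unannotated
promoter. The linking strategies propose candidates, not validated
targets; chromatin-interaction support is as good as the catalog's tissue
match. Only two-condition designs are supported, and spike-in factors are
accepted but never estimated. The transcript caller is a windowed
fold-over-background rule; it does not model single-base pause structure
and its boundaries are only window-accurate.
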