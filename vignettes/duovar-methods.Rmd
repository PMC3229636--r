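---
title: "Methods: two-genome read-depth CNV detection and SNP annotation"
author: "duovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-genome read-depth CNV detection and SNP annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duovar)
```

duovar implements the analysis stages of a two-genome resequencing
comparison — two individuals (in the motivating application, a Holstein
and a Black Angus bull) mapped to a common reference and compared for
copy-number variants (CNVs) by read depth, and for SNPs by functional
consequence, conservation impact, array concordance and qPCR follow-up.
This vignette explains each model, the tunable parameters, the synthetic
data the package tests itself on, and the numerical and design choices
that were genuinely open.

## The read-depth CNV model

Every chromosome is tiled with sliding windows of length $L$ advanced by
$L/2$ (half overlap). For window $i$, let $x_i$ and $y_i$ be the read
starts of samples A and B inside it, with library totals $N_A$, $N_B$.
The signal is the normalized log ratio

$$r_i = \log_2 \frac{x_i / N_A}{y_i / N_B},$$

which is 0 under equal dosage and $+1$ when A carries twice B's copy
number.

**Significance.** Under the null, $x_i$ and $y_i$ are Poisson with means
$\mu_x = N_A/W$, $\mu_y = N_B/W$ ($W$ = number of windows). The ratio
$z_i = x_i / y_i$ is assessed with the Geary–Hinkley transformation of a
ratio of Poisson variables,

$$t_i = \frac{\mu_y z_i - \mu_x}{\sqrt{\mu_y z_i^2 + \mu_x}},$$

treated as standard normal; the two-sided p-value is $2\Phi(-|t_i|)$.
This is a normal approximation: its tail probabilities track Monte-Carlo
simulation of the same statistic to within a few percent at moderate
tails, with growing relative error deeper into the tail. What matters
operationally is calibration at the decision threshold, and at
$p \le 0.001$ with window means $\ge 30$ the observed null rejection
fraction is well under 0.002 (the test suite and the acceptance script
both measure it, typically ~4.5×10⁻⁴). Windows with $x_i = y_i = 0$ are
excluded; $y_i = 0$ with $x_i > 0$ yields a $+\infty$ log-ratio sentinel
and the transform's analytic limit $t_i \to \sqrt{\mu_y}$.

**Calling.** A window is significant when $p_i \le 0.001$ **and**
$|r_i| \ge 0.6$ (both defaults changeable in `caller_config()`). Maximal
runs of at least `min_windows = 10` consecutive significant windows with
a common ratio sign become one call spanning the first window start to
the last window end; the call's `mean_log2_ratio` is the member-window
mean and `combined_p` the minimum member p-value (the aggregation rule
for reported region p-values is not standardized; the minimum is
conservative to report alongside the run-length requirement, and the
per-window values remain available). A single non-significant window —
a random depth dip — splits a run, which is exactly how a real dosage
change can surface as several adjacent calls.

**Window sizing.** `auto_window_length()` finds, by integer search, the
smallest $L$ at which a true ratio of exactly $\pm 0.6$ reaches the
critical value of the transform at $p = 0.001$, given per-window means
scaled from the library totals, and returns twice that minimum
(`window_multiplier = 2`). At that operating point the per-window mean
count is ~270 (for log2 threshold 0.6), so a true two-fold segment
($|r| = 1$) has per-window power near 1 and segments spanning ≥ 12
windows are recovered essentially always; this is the regime the
recovery property is measured in. At window means as low as 30 the
expected statistic for a two-fold window is only
$\sqrt{\mu/5} \approx 2.45$ — below the 0.001 critical value — so a
caller run far below its designed window size has no power; that is a
property of the detection configuration, not a defect of the
implementation.

## SNP quality filters

Two post-calling filters, applied in order:

1. **Depth percentile** (`depth_percentile_filter()`): SNPs with depth
   strictly greater than the nearest-rank 95th percentile of all the
   animal's SNP depths are removed ("higher than 95% of the other
   SNPs"); with 100 depths 1..100 the cutoff is 95 and depths 96–100 go.
   Self-inclusion in the percentile set changes nothing materially and
   keeps the rule a pure function of the input.
2. **Placement uniqueness** (`uniqueness_filter()`): the ±100 bp flank
   around each SNP must have exactly one placement in the reference.
   The built-in predicate is exact substring search of the
   $2 \cdot 100 + 1$ bp sequence over both strands (Biostrings pattern
   matching); a pluggable predicate accepts any external remapping
   oracle. Flanks truncated at contig edges are searched as-is and
   logged.

## Functional classification and the alignment score change

`classify_snps()` assigns one of fourteen classes per SNP. Per
transcript the rule set is positional — upstream/downstream within a
5 kb window of the transcript (the conventional promoter-proximal
window; the choice is configurable), 5′/3′ UTR, intronic with splice
windows (first/last 2 intronic bases essential, 3–8 bp splice site),
noncoding-gene and mature-miRNA containment — and, inside a CDS, by
substituting the alternate allele into the reference codon (alleles are
forward-strand; minus-strand CDSs complement them) and translating with
the standard genetic code: stop→stop counts as synonymous, non-stop→stop
as stop gained, stop→non-stop as stop lost. Overlapping transcripts are
reduced by a fixed severity order (essential splice > stop gained > stop
lost > nonsynonymous > splice > synonymous > 5′ UTR > 3′ UTR > mature
miRNA > noncoding gene > intronic > upstream > downstream > intergenic),
so exactly one class survives per SNP. A SNP whose stated reference
allele disagrees with the reference base is flagged and classified from
the actual base. The classifier is validated against an exhaustive
enumeration of all 61 sense codons × 3 positions × 3 substitutions on
both strands, with expected amino acids from an independent translation
implementation (seqinr).

For a nonsynonymous SNP with reference residue $r$, variant residue $v$
and $n \ge 1$ orthologous residues $o$, the **alignment score change**
is

$$a = \frac{\sum_o s(v, o)}{n} - \frac{\sum_o s(r, o)}{n},$$

with $s$ the BLOSUM62 log-odds matrix (embedded in the package and
test-verified against the Biostrings copy). $a < 0$ means the variant
breaks conservation. With $n = 0$ the score is undefined — not zero,
since zero is a meaningful "neutral" value. `asc_bin_profile()` bins
scores at width 3 with zero anchored on a bin edge (anchoring is not
standardized; an edge at zero keeps conservation-breaking and
conservation-restoring variants in disjoint bins) and reports per-bin
heterozygous and shared-with-other-animal proportions, the shape used to
show that strongly negative variants tend to be heterozygous and
private.

Two animals' class lists are combined by `tabulate_classes()` with the
intersection keyed on (chromosome, position, alternate allele) and the
union enforced by inclusion–exclusion per class.

## Concordance evaluation

`build_concordance()` compares array genotypes to the sequencing SNP
list. Array calls homozygous for the reference allele are undetectable
by a variant caller and are excluded; the rest are *detectable*. A
detectable site is *called* if any sequencing SNP overlaps its position,
and *concordant* if the unordered allele pairs match. The
false-negative rate per zygosity class is
$(1 - \text{concordant}/\text{detectable}) \times 100$, reported both
rounded (as such tables print it) and at full precision. Discordant
heterozygous sites split into *single allele* (sequencing saw only one
of the two array alleles, as a homozygous call) and *other* (alleles
incompatible with the array pair). The custom-panel false-positive rate
is monomorphic/tested × 100.

## qPCR copy-number calling

Per sample, $\Delta Ct$ is the mean target Ct minus the mean reference
Ct over replicates (quadruplicate by convention); per-replicate
$\Delta Ct$ values supply min/max error bars. Against a calibrator
assumed to carry two copies,
$CN = 2 \times 2^{-\Delta\Delta Ct}$; perfect doubling is assumed in the
caller (efficiency corrections belong to assay QC, where efficiencies
above 90% are required, not to the calling formula). Censored target
reactions (no amplification) give $\Delta Ct = +\infty$ and copy number
0; a censored replicate among valid ones is dropped with a warning; a
censored calibrator is an error. When the calibrator is unusable,
`mode_calibrate()` assumes the modal rounded level among the remaining
samples represents two copies and rescales; a tie between modes is an
error naming them, since no principled tie-break exists. Integer
reporting uses plain rounding; whether a likelihood-based integer caller
would differ is untested here and documented as a limitation.

## CNV summaries and enrichment

`summarize_by_chromosome()` emits per-chromosome CNV counts, lengths and
percent-of-chromosome, including explicit zero rows, plus a TOTAL row
whose mean is total length over total count. `overlap_genes()` counts a
gene as hit by a CNV on ≥ 1 bp intersection, converting BED-style
half-open CNVs to the 1-based inclusive gene convention internally.
`go_enrichment()` runs a one-sided (over-representation only) Fisher's
exact test per term against a user-supplied background and adjusts with
Benjamini–Yekutieli, valid under arbitrary dependence between terms.
The background is the full annotated gene set supplied by the user; web
enrichment services use their own internal backgrounds, so p-values are
comparable in procedure but not numerically. No GO-graph ancestor
propagation is performed — terms are taken as annotated.

## What the synthetic data emulates

- `simulate_read_placements()`: single-base read starts, Poisson per
  interval with rate proportional to planted copy number — read depth is
  the only signal the caller uses, so mate-pair structure, GC bias,
  mappability and color-space error profiles are deliberately absent.
  Passing recovery tests therefore show correctness of the
  counting/testing/merging chain, not robustness to mapping artifacts.
- `simulate_snp_callsets()`: truth sites with a set heterozygous
  fraction; hom sites missed with one rate; het sites missed with
  another, the misses emitted as single-allele homozygous calls with
  probability `allele_drop_fraction` (and as a third-allele call
  otherwise, so the discordance breakdown has both classes to
  estimate); false-discovery sites appended at a set fraction and
  flagged monomorphic in the panel table. No base-error model: the
  all-or-nothing miss plus allele-drop branch is exactly the granularity
  a concordance table measures.
- `simulate_gene_models()`: multi-exon genes with frame-complete CDSs,
  UTRs, GT..AG introns ≥ 60 bp, packed with gaps wide enough that
  upstream/downstream windows never collide, plus optional ncRNA and
  miRNA genes; `plant_classified_snps()` then derives SNPs whose class
  is known by construction.
- `simulate_qpcr()`: Ct values from the exponential amplification model
  with Gaussian replicate noise and censoring at copy number zero.
- Per-site read depth beyond genome averages is not characterized in
  typical study reports; Poisson is assumed throughout.

All generators take explicit seeds and are deterministic given them
(same seed ⇒ byte-identical output files).

## Problem sizes and runtime choices

The test suite and acceptance script run at desk scale, chosen so the
statistical checks are sharp but the whole suite stays in minutes: null
calibration on 10⁵-window tracks across 20 seeds; recovery on 200
planted two-fold segments of 14 windows through the full read pipeline
(~4.5 million reads); miss-rate recovery on 200,000 planted SNP sites;
10⁴ random orthologue panels against the brute-force score oracle; the
full 61 × 3 × 3 codon enumeration on both strands; 18-sample qPCR grids.
Genome-scale published results (millions of SNPs, hundreds of CNVs from
real reads) are reproduced at the level of their worked arithmetic —
the concordance, panel-validation, class-union and CNV-summary numbers
recompute exactly from the printed counts.

## Known limitations

- The window test is two-sample and relative: absolute copy number,
  single-sample CNV calling and X-chromosome handling are out of scope.
- The Geary–Hinkley p-value is approximate in deep tails; the caller
  depends only on the 0.001 threshold, where calibration is verified.
- The uniqueness filter's built-in oracle is exact-match only; real
  cross-assembly remapping (mismatches, indels) must come through the
  pluggable predicate.
- One orthologue panel per SNP is assumed; averaging across multiple
  transcripts or orthologue sets per SNP is not modelled.
- GO enrichment results depend on the supplied background set and
  annotation table; no term-graph propagation is applied.
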