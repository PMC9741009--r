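---
title: "Identifying radiation-induced mutations: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying radiation-induced mutations: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmut)
```

## The analytical problem

A seed-mutagenized, selfed plant population carries three kinds of
sequence variation relative to the reference genome: (i) *founder*
natural variation present in the seed bulk before irradiation, shared by
every descendant including non-irradiated controls; (ii) *species-wide*
natural variation catalogued by large resequencing efforts; and (iii)
the *induced* mutations we want, which are unique to a single mutant
line and — after seven generations of single-panicle descent — present
in both sibling plants sequenced for that line. The raw joint-genotyped
call set is dominated by (i) and (ii) by roughly three orders of
magnitude, so mutation discovery is above all a subtraction problem.

`radmut` implements that subtraction for 30× short-read data, plus the
structural-variant consolidation, effect annotation and spectrum
reporting that turn accepted calls into a per-line mutation landscape.

## Small-variant model and filters

Variant identity is the normalized tuple (chrom, pos, ref, alt):
multi-allelic records are split and indels left-aligned against the
reference, so set operations behave like `bcftools isec` on normalized
VCFs (`normalize_variants()` agrees with `bcftools norm` on
denormalized inputs; this is tested).

**Depth filter.** A sample's call is usable only with DP ≥ 20
(inclusive: "minimum depth 20×" is read as 20 allowed). Filtering is
per-sample, not per-site: a site may be usable in one replicate and not
the other, in which case the replicate-concordance step decides.

**Allele-ratio zygosity recalibration.** Joint genotypers over-call
heterozygotes at sites with skewed allele ratios. A heterozygous call
with alt fraction strictly below 0.20 is re-scored homozygous reference
(the alt reads are treated as noise); strictly above 0.80, homozygous
alternate. Fractions exactly at a bound stay heterozygous, since the
rule is stated with strict inequalities. The operation is idempotent,
and a heterozygous call at zero depth is unscorable (missing). The
package's validation fixture encodes a published 34-entry Sanger set in
which exactly the three entries with ratios 3/29, 2/21 and 2/25 plus one
low-coverage entry fail — none of which could be confirmed by Sanger
sequencing — while all 30 retained entries were confirmed.

**Four-step cascade.** In order: (1) subtract keys carried by any
non-irradiated control; (2) remove keys carried by more than one mutant
line; (3) keep only keys non-reference in *both* replicates of the
line; (4) subtract the database catalog. Steps 1, 2 and 4 are set
subtractions and step 3 an independent per-line predicate, so any
ordering yields the same accepted set; the implementation is
property-tested against a set-algebra oracle under permuted orderings.
Two points were genuinely open and decided as follows:

* *Sharing before or after replicate intersection?* Sharing (step 2) is
  evaluated on each line's carrier set **before** replicate
  intersection: one stray non-reference call in any sample of another
  line disqualifies the key everywhere. This is the maximally
  conservative reading and matches the listed step order.
* *Missing genotypes.* A missing genotype in one replicate counts as
  discordant, not as a wildcard — "present in both replicates" is taken
  literally.

Every candidate key of a line receives exactly one fate. When a
candidate's carrying calls all vanish during preprocessing, the label is
`allele_ratio_recalibrated_to_ref` if any carrier was recalibrated away
and `low_depth` otherwise; the tie (one replicate lost to depth, the
other to ratio) goes to the ratio label, an arbitrary but documented
choice.

## Structural variants

Four caller families are emulated rather than re-implemented; the
pipeline consumes their call tables. Support thresholds follow the
analysis the package mirrors: translocations need strictly more than
100 supporting reads; other types need a per-caller minimum, 50 by
default (a Lumpy-style caller may be dropped to 10 via
`caller_min_support`).

Merging is single-linkage: two same-type records link when both
breakpoints agree within ±2000 bp (for inter-chromosomal translocations,
the partner breakpoint on the same chromosome pair). The ±2000 bp
tolerance is stated for translocation merging in the source analysis;
lacking any other figure, it is applied to all SV types for
cross-caller and cross-line matching. A cluster collapses to
support-weighted mean coordinates with the maximum support. Single
linkage makes the partition independent of input order (tested against
a brute-force transitive-closure oracle and under permutation).

A consensus record is kept when seen by at least `min_callers` distinct
callers (default 1 — the source analysis states no cross-caller
consensus requirement) and in both replicates. Records matching a
record of another line or a control are natural-variation candidates.
Because large validated deletions demonstrably recur across lines
(recurrent breakpoints at repeat loci), the cross-line filter is
configurable: `strict` (default) removes them, `report_only` keeps them
flagged `shared = TRUE`.

The depth scan computes per-bin ratio (mutant + ε)/(control + ε) with
ε = 0.5 pseudodepth, and calls maximal runs with ratio ≤ 0.25 as
deletion candidates and ≥ 1.75 as duplication candidates. Those two
thresholds are this package's choice, not a published value: at 30×
coverage a homozygous deletion sits near ratio 0.02 and a single-copy
gain near 1.5–2.0, so 0.25/1.75 separate homozygous events from
coverage noise while ignoring heterozygous dosage. Bin sizes 1, 5, 10
and 100 kb are supported; candidates carry run-extent coordinates, so
boundary error is at most one bin.

**Accounting convention.** Translocations are also recorded as
deletions from their origin locus: the reported deletion count is
raw DEL + ITX + CTX, and the SV total is that reported deletion count
plus DUP + INV + INS. The package verified this identity against all 11
lines of the published spectrum table it ships as a regression fixture.

## Effect annotation

A deliberately small, self-contained codon classifier stands in for a
full annotation suite. Coding SNVs are classified by codon lookup on
the coding strand (standard genetic code): synonymous → silent/LOW;
stop gain → nonsense/HIGH; stop loss or damage to the initiator
codon → HIGH; other amino-acid changes → missense/MODERATE. Coding
indels: net length not a multiple of 3 → frameshift/HIGH; in-frame →
MODERATE, upgraded to HIGH when the in-frame edit introduces a
premature stop. Variants inside a gene but outside its CDS are
intronic; within 5 kb (the usual annotation-window convention, both
sides) upstream/downstream; otherwise intergenic — all MODIFIER.
Splice-site classes are deliberately omitted: variants within 2 bp of an
intron boundary are labeled intronic with a `splice_proximal` warning
flag.

Effects are counted per variant–annotation pair: a variant inside the
windows of two genes yields two rows. This mirrors how annotation
suites count and explains why published impact totals can exceed
accepted-variant totals; the counting unit is the annotation, not the
variant.

The classifier is validated against a brute-force oracle that rebuilds
the mutant CDS by string surgery on the chromosome, translates mutant
and reference proteins with `Biostrings::translate`, and diffs them —
1000+ random coding SNVs and indels per run, on both strands.

## Spectrum and density reporting

Mutation frequency is genome size divided by event count (bp/event,
2 decimals); the conventional 430 Mbp rice genome size is the default
and is overridden with the simulated genome size for synthetic runs.
The SV share is 100·SV/total. The shipped regression fixture confirms
that recomputing every derived column of the published 11-line spectrum
table from its printed counts reproduces the printed frequencies to
2 decimals, the printed totals exactly, and SV shares spanning
1.8–8.5% with deletions above 80% of all SVs in aggregate.

## The synthetic-data generator

The generator emulates the study design, not the reads: no
FASTQ/BAM-level simulation, no M1 chimerism, no selection. Its defaults
are fixed once as the package's study conditions:

* **Population**: 11 mutant lines with the treatments and doses of the
  mirrored screen (gamma 150–450 Gy, X-ray 75–150 Gy), two replicates
  each, plus one control line sequenced as two plants. Per-line induced
  loads are the published per-line spectra scaled by 1/100.
* **Genome**: 2 chromosomes × 500 kb, 30 genes (1–3 CDS exons, both
  strands, ATG…stop, length divisible by 3; ~10% flagged as
  transposon-annotated). 1 Mb keeps every stage fast while giving SVs
  enough room that unrelated lines rarely collide within the ±2000 bp
  matching tolerance; on a much smaller genome, coincidental cross-line
  SV matches become a desk-scale artifact that confounds the uniqueness
  filter.
* **Depths**: DP ~ Poisson(30), matching the ~30× design; heterozygous
  alt depth ~ Binomial(DP, 0.5); homozygous calls carry small symmetric
  read noise. `noiseless = TRUE` fixes DP = 30 and exact fractions — the
  regime in which the pipeline must achieve precision = recall = 1
  (tested).
* **Zygosity at M7**: induced mutations are homozygous-alt with a 5%
  heterozygous residual. The true distribution after seven selfed
  generations is not published; 5% reflects loci still segregating plus
  late-arising mutations and is a modeling choice.
* **Indel/SV scales**: induced indels 1–15 bp, SV sizes 179–10,000 bp,
  spanning the validated size range of the mirrored screen.
* **SV call sets**: 3 callers at 90% per-caller sensitivity (every truth
  SV is guaranteed by at least one caller per replicate), breakpoints
  jittered Normal(0, 150 bp) by default, supports Poisson(180) for
  translocations and Poisson(90) otherwise so genuine events clear the
  thresholds; false positives are caller- and replicate-specific with
  Poisson(25) support, so most die at the support or concordance steps.
* **Adversarial knobs** (off by default): cross-line collisions,
  database-planted induced variants, founder SVs in all samples — used
  by the tests to prove the corresponding filters fire with the right
  reason codes and zero leakage.

All randomness flows from one seed; the same configuration yields
byte-identical FASTA/GFF3/VCF/TSV output, which is tested at the byte
level.

### What passing synthetic tests does and does not show

The generator reproduces the *logical* structure of the design
(sharing, replication, depth and ratio noise, breakpoint jitter), so
the tests demonstrate that the filters implement their rules exactly
and recover a known truth under those rules. It does not reproduce
mapping artifacts, repeat-mediated systematic miscalls, segregation
distortion, or caller-specific error correlations — on real data the
same pipeline inherits whatever biases the upstream mapper and callers
carry, and absolute counts depend on those. Desk-scale mutation
densities here are ~25× the real per-bp densities, so per-line counts
and bp/event frequencies from synthetic runs are illustrative, not
comparable to full-genome values.

## Numerical and degenerate-input choices

* Depth threshold inclusive (≥ 20); ratio bounds strict (< 0.20,
  > 0.80).
* Coordinates are 1-based inclusive internally; BED export converts to
  0-based half-open.
* Zero-event frequencies are reported absent (NA), never 0; all-zero
  percentage denominators yield NA, not an error.
* Consensus coordinates round support-weighted means to integers;
  support is the cluster maximum.
* An empty gene set, an empty SV table and a zero-variant line are all
  valid inputs with empty (not failing) outputs.

## Problem sizes

The default test and analysis runs use the 1 Mb genome, ~1,000 founder
variants, ~900 induced variants, 45 induced SVs and 24 samples; the
complete test suite (including the 1000-variant classifier/oracle
comparison and end-to-end runs) and each analysis driver finish in well
under a minute on one CPU. These sizes are the package's chosen study
conditions for reproducible desk-scale validation.

## Known limitations

* The cascade treats the control and database catalogs as exhaustive
  for what they cover; founder variants that evade both controls (depth
  dips) are caught only by the cross-line filter, which needs ≥ 2
  carrier lines.
* The SV uniqueness filter cannot distinguish a genuinely recurrent
  induced breakpoint (e.g. at a repeat locus) from shared natural
  variation; `report_only` mode exists precisely because validated
  recurrent deletions occur in practice.
* The effect classifier omits splice-donor/acceptor classes, regulatory
  motifs, and canonical-transcript selection, and assumes gene models
  whose spliced CDS is well-formed.
* Indels spanning an exon–intron boundary are classified by the net
  length rule only; the premature-stop check applies to edits within a
  single exon.
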