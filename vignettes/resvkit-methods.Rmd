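---
title: "resvkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{resvkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resvkit)
library(data.table)
```

resvkit compares a resequenced *target genome* (TG) against a *reference
genome* (RG) using paired-end short-read alignments, and reports four
classes of variation: SNPs and short indels, copy-number variants (CNVs)
from depth-of-coverage ratios, presence/absence variants (PAVs, regions
with no target coverage at all), and large deletions from discordant
insert sizes with split-read breakpoint refinement. A built-in simulator
generates rearranged genomes, reads and oracle alignments with a known
truth set, so every caller can be validated end to end. This vignette
records the models, the tunable parameters and the design decisions a
maintainer would want to know about.

## Pileup construction and variant calling

`pileup_from_alignments()` accumulates per-position depth and A/C/G/T
allele counts from the M operations of each CIGAR, skipping bases with
quality below `min_baseq` (Phred+33 by default, configurable offset) and
never counting soft-clipped bases. Insertions and deletions register
evidence at the reference position of the preceding aligned base (their
*anchor*), so indel alleles have a single well-defined coordinate.

`call_variants()` applies four filters, all configurable through
`caller_config()`:

| parameter    | default | meaning                                        |
|--------------|---------|------------------------------------------------|
| `min_reads`  | 8       | minimum post-filter depth at the site          |
| `min_baseq`  | 15      | base-quality floor (applied at pileup build)   |
| `min_freq`   | 0.25    | minimum variant allele frequency               |
| `max_p`      | 0.01    | significance ceiling                           |
| `hom_freq`   | 0.75    | frequency at/above which a call is homozygous  |
| `error_rate` | 0.01    | per-base error probability under the null      |

The significance test is the one-sided binomial tail
P[X >= alt_count | X ~ Binomial(depth, error_rate)]: the probability that
sequencing error alone produced at least the observed variant support.
This is the classical pileup-caller test in its high-depth form; it is
self-contained and is verified in the test suite against direct summation
of the binomial mass function. Zygosity is assigned from the allele
frequency alone (`hom_freq = 0.75`, the conventional caller default),
since depth at typical coverages cannot distinguish subtler genotypes.
At multi-allelic sites the strongest non-reference allele is tested and
the runner-up is recorded in a `note` column.

## Coverage-ratio CNV and PAV detection

For windows of `window_size` bp (default 50 bp) tiling each chromosome,
the coverage ratio is

    rho(i) = TG_windCov(i) / RG_windCov(i),

with window means computed over *all* positions in the window (uncovered
positions count as zero; a window left undefined by zero reference
coverage is excluded from segmentation and reported as a reference
coverage gap). Windows with target coverage 0 but reference coverage > 0
are PAV seeds and are merged into zero-coverage intervals in the report.
Genome-wide averages `TG_avCov` and `RG_avCov` are computed over
informative (depth > 0) positions only.

Segments of homogeneous rho are found by a changepoint search in the
style of circular binary segmentation, run on a conditioned series:
the *winsorised log2 ratio*. The raw ratio is strongly right-skewed
(low-coverage windows of either genome sit in a denominator or spike the
numerator); the log transform symmetrises it, and clamping at the
chromosome median plus/minus 3 MAD stops isolated outlier windows from
driving spurious changepoints while leaving any multi-window event a
clear plateau -- the same conditioning the established depth-of-coverage
segmenters apply before their changepoint search. All reported segment
statistics (`rho_seg`, coverages, copy numbers) are computed on the
natural scale.

Two statistics are scanned at each recursion node: the binary split
statistic (every prefix/suffix split, pooled-variance two-sample t) and
an *arc* statistic comparing interior runs of up to 1,500 windows
against their complement (on long series the arc grid is strided and the
best strided arc is re-polished at single-window resolution). The arc
statistic is what isolates a short duplication inside a long neutral
stretch, where any binary split leaves near-identical flank means; the
binary statistic is what scales to whole-chromosome series. Because a
70-bp read can span one 50-bp window boundary, the noise of adjacent
windows is positively correlated (MA(1)); the lag-1 correlation is
estimated per chromosome from the lower quartiles of the first and
second absolute differences (insensitive to the sparse changepoint
outliers) and the observed statistic is deflated by
sqrt(1/(1 + 2 r1)) before being compared against the iid permutation
null -- without this, shuffling systematically understates the null and
noise runs segment out as spurious calls.

A split is accepted when its permutation p-value is below `alpha = 0.01`
(nominally 1,000 label permutations). Three standard shortcuts bound
the permutation cost: statistics beyond the Gaussian extreme-value
envelope for the number of scanned candidates are accepted outright,
statistics below the typical null maximum are rejected outright, and in
between the permutation loop stops at sequential checkpoints once the
decision is effectively made. After the recursion, each boundary is
polished to the exact SSE-minimising split of its two adjacent segments
(within 50 windows), and segments shorter than `min_windows = 4` are
merged into the neighbour with the closer mean. On short series the
reported boundaries agree with an exhaustive sum-of-squares oracle,
which the test suite checks directly.

Per segment j the caller computes

    rho_segNorm(j) = rho_seg(j) * RG_avCov / TG_avCov
    TG_segCopy(j)  = TG_segCov(j) / TG_avCov
    RG_segCopy(j)  = RG_segCov(j) / RG_avCov

and calls

    loss iff rho_segNorm(j) <= 1 - 0.5 / RG_segCopy(j)
    gain iff rho_segNorm(j) >= 1 + 0.5 / RG_segCopy(j),

the half-copy margin reflecting a diploid that gains or loses one
homologous copy. Both the ratio and the individual copy numbers are
reported (a ratio of 2 may be 2:1 or 4:2), plus a half-integer rounded
copy number for the diploid reading. Loss/gain calls shorter than
`min_sv_size` (500 bp in the simulation studies; 1,000 bp is a sensible
choice for real data) are suppressed.

Smoothing: adjacent segments whose mean rho values lie *closer* than
3 pooled window-rho standard deviations are merged, and calling is run on
both the raw and the smoothed segmentation (the report takes their
union). The merge-when-closer direction is the only one that smooths;
the width of the merge band scales with the empirical window noise, so
clean data merges almost nothing.

## Large deletions

`find_deletions()` proceeds in five steps.

1. **Discordant pairs.** A same-chromosome pair whose template length
   exceeds `insert_threshold` nominates a candidate deletion from the end
   of the leftmost mate to the start of the rightmost mate. The default
   threshold is estimated as mean + 4 SD of the template lengths of the
   first 100,000 proper pairs, since the insert distribution is a
   property of the library, not of the caller.
2. **Merging.** Candidates whose first-mate starts lie within
   `merge_dist = 200` bp are single-linkage clustered; the merged
   interval is the median envelope of the members and the cluster size is
   the call's `support` (minimum 3; the support filter is what suppresses
   scattered insert-size outliers).
3. **Split-read refinement.** Two ranges of 2,000 nt are centred on the
   approximate start and end. Pairs with one mate mapped in either range
   contribute their unmapped mates, which are locally aligned (both
   orientations) against both range sequences with Smith-Waterman, affine
   gaps, nucleotide-BLAST-like scoring (+1/-2, gap open -5, extend -2).
   A read whose prefix aligns upstream and whose suffix aligns downstream
   (each part at least 14 nt and 85% identity, with at most 6 nt overlap
   or 10 nt gap between the parts on the read) votes for the breakpoint
   pair; the refined breakpoints are the per-side lower medians of the
   votes. The per-part score floor is deliberately lower than the
   generic `min_score = 30`: a junction read whose shorter arm spans,
   say, 20 nt could otherwise never vote, and an exact 14-mer within a
   2-kb range arises by chance with probability on the order of 1e-2.
   With no votes the approximate coordinates stand and the refined fields
   stay NA.
4. **Ambiguity probe.** The first 200 nt beyond the refined upstream
   breakpoint (the start of the deleted sequence) are searched
   genome-wide by seeded local alignment (exact 20-mer seeds every 10 nt,
   then Smith-Waterman around seed hits). A hit away from the deletion
   locus with >= 90% identity covering >= 50% of the probe marks the call
   *ambiguous* and is reported with its position, identity and coverage:
   the discordant signal may reflect a duplication or paralog rather than
   a loss. Both cutoffs are configurable; the probe is skipped (and
   noted) when clipping leaves fewer than 50 nt.
5. **Zygosity hint.** The mean target depth inside the deletion is
   reported; below 0.1 x TG_avCov the call is hinted homozygous,
   otherwise heterozygous-or-paralog. The latter wording is deliberate:
   reads inside a "deletion" may equally come from a paralogous copy
   elsewhere, which is exactly what the ambiguity probe tests.

Breakpoint conventions: intervals are 0-based half-open in memory and
1-based inclusive in reports. When the deleted sequence shares its first
h bases with the sequence following the deletion (junction
micro-homology), the breakpoint is genuinely ambiguous by h; votes then
shift consistently, the reported interval is one of the equivalent
representations, and the signed breakpoint error distribution acquires a
few +-1/+-2 entries, which is why its median rather than its mean is the
headline statistic.

## Transcript consequences

`load_gene_models()` builds one model per gene (first mRNA) from GFF3
plus spliced CDS/UTR FASTA, validating interval lengths against sequence
lengths and flagging CDSs whose length is not a multiple of 3; flagged
models suppress amino-acid prediction but still map positions.
`map_variant()` converts genomic positions to spliced, strand-oriented
relative coordinates (on the minus strand, position 1 is the 5' end of
the region); `cds_effect()` translates the affected codon with the
standard nuclear code (the organism here is a plant; the table is a
package constant and easy to swap), reporting amino-acid changes,
premature stops (alt codon is a stop before the terminal codon) and lost
stops (terminal stop codon mutated away). Heterozygous variants are
annotated on the alternate allele -- "at least one allele" semantics.
Frameshift is simply indel length mod 3 != 0 inside a CDS. For
structural variants, `gene_extractor()` flags genes totally (1) or
partially (0) contained in an interval, judging containment on the
genomic *gene span* (the union-of-exons alternative differs only for
genes whose terminal exons straddle the SV boundary, and span containment
is the conservative reading).

## The simulator and what it does (not) emulate

`simulate_rearranged_genome()` places non-overlapping deletions and
tandem duplications (k extra copies, k uniform on 1..`max_dups`,
default 10) with at least `min_sv_gap = 2000` bp between events so that
neighbouring signals remain separable. `simulate_point_variants()`
produces a diploid haplotype pair: SNPs (alternate base uniform over the
three others), indels (geometric length, p = 0.5, capped at 10),
each homozygous or heterozygous with probability 1/2.
`simulate_paired_reads()` draws fragments uniformly, with insert length
Normal(300, 30) truncated at twice the 70-bp read length (values typical
of an Illumina paired-end library), and applies a per-base substitution
error ramping linearly from 0.0001 at the 5' end to 0.01 at the 3' end
of each read; error bases get their recorded quality lowered by 10
Phred units, and every base's quality encodes its position's error rate.

`oracle_align()` replaces an external mapper: because the simulator knows
every read's origin, reads wholly inside a reference-mapped block are
placed at their true coordinates (full-match CIGAR), reads crossing a
single point-indel junction receive the proper I/D CIGAR, and reads
crossing a structural-variant junction are emitted unmapped with their
mate's position preserved -- precisely the evidence the split-read
refinement consumes. Reads from extra duplication copies map onto the
source copy, producing the coverage-gain signal, which is
placement-invariant (the choice of tandem placement is therefore
inconsequential for the CNV caller).

What this idealises away: mapping ambiguity in repeats, soft-clipped
junction reads (here they are fully unmapped), reference bias,
GC-coverage bias, PCR duplicates and quality miscalibration. Passing the
simulation studies therefore demonstrates the *algorithmic* correctness
of the callers under a faithful error model, not robustness to
real-library artefacts; on real data the alignment and pileup inputs
come from external tools through the SAM/pileup readers.

## Evaluation

PPV is correct calls over all calls; sensitivity is correct calls over
all genuine variants. For structural variants both are computed over
*bases*: called intervals and truth intervals are unioned per chromosome,
and the intersection size is divided by the called (PPV) or truth
(sensitivity) base count. Point-variant matching is exact on
(chrom, pos, alternate allele) for SNPs and allows +-1 bp on the anchor
for indels (left/right-normalisation slack). Breakpoint errors pool the
signed start/end differences of calls matched to truth deletions by
>= 50% reciprocal overlap and report the median and the 10th/90th
percentiles. Copy-number recovery regresses detected `TG_segCopy`
against the simulated total copy count by ordinary least squares.

## Study designs and problem sizes

The packaged studies (also run by `scripts/acceptance.R` and the
acceptance tests) use synthetic genomes sized for a desktop run while
keeping the event designs of a full-genome validation: a 5-Mb genome at
20x for point variants (SNP rate 0.1%, indel rate 0.01%); a 10-Mb genome
with 50 deletions of 2,000 bp at 10x; a 20-Mb genome with 50 tandem
duplications of 50,000 bp (1-10 extra copies) at 10x for target and
reference; and a 10-Mb genome with 50 duplications of 2,000 bp at 10x.

One scale effect deserves an explicit warning. `TG_avCov` is an average
over the whole alignment, duplicated content included. In the 50-kb
duplication design the extra copies add an expected 13.75 Mb of
duplicated sequence to a 20-Mb genome, so `TG_avCov` is inflated by
roughly 70% and `rho_segNorm` of every segment is deflated by the same
factor: a single-extra-copy duplication lands near 1.2, below the gain
threshold of 1.5, and detected copy numbers (and hence the
detected-vs-expected slope) shrink accordingly. On a full-size genome
where duplicated content is a few percent of the total, the same
normalization deflates by only ~10% and single-copy gains clear the
threshold. This is a property of the whole-alignment normalization under
extreme duplication loads, not of the segmentation; the 2,000-bp
duplication study (duplicated content ~5% of the genome) does not suffer
from it. We kept the published normalization rather than re-centring on
the neutral mode, and report the effect rather than resizing the study
to hide it.

## Numerical choices and degenerate inputs

* Coordinates: 0-based half-open in memory, 1-based inclusive on disk;
  converting twice is the identity (round-trip tested for every format).
* Median votes and envelopes use the lower median, breaking ties toward
  the smaller coordinate.
* A zero-variance segment under the split statistic scores t = 0 when
  the means agree and effectively infinite when they differ.
* `variant_p_value(0, n)` is exactly 1; depth-0 sites never reach the
  caller.
* Chromosomes absent from an alignment produce zero-depth pileups, and
  an empty pileup folder chromosome reads back as zero coverage
  everywhere.
* Refinement ranges are clipped at chromosome ends; a probe shorter than
  50 nt after clipping skips the ambiguity test with a note.
* Every stochastic entry point consumes one integer seed; equal config
  plus seed gives byte-identical outputs (checksummed in the pipeline
  manifest and asserted in the tests).

## Known limitations

* Insertions, inversions and translocations are out of scope for the
  structural-variant callers (the simulator also does not generate
  them).
* The deletion finder realigns only range-anchored unmapped mates, not
  every unmapped read genome-wide; this is the designed speed/accuracy
  trade-off.
* A tandem duplication produces discordant pairs at its copy junctions
  that mimic a deletion spanning the source copy; such calls carry high
  interior coverage and are labelled heterozygous-or-paralog rather than
  suppressed.
* No GC-content coverage correction or mappability masking is applied;
  on real data, strong GC bias will leak into rho.
* The binomial caller has no strand-bias or BAQ machinery; it trusts the
  base qualities it is given.
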