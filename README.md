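# resvkit

Resequencing analysis of a target genome against a reference genome:
SNP/indel calling from filtered pileups, copy-number and
presence/absence variation from depth-of-coverage ratios, large-deletion
discovery from discordant paired-end insert sizes with split-read
breakpoint refinement, and transcript-level consequence annotation — 
plus a structural-variant simulator and an evaluation module so the
whole pipeline can be validated against a known truth set.

It is aimed at people analysing short-read resequencing data of a
genotype against a finished reference (the motivating use case is plant
accession resequencing) who want the variant classes above in one
self-contained toolkit, and at method developers who need a seeded,
truth-tracked simulator to benchmark callers.

## Methods in brief

**Point variants.** Per-position allele counts (bases under quality 15
discarded, soft clips never counted) feed four filters: depth ≥ 8,
allele frequency ≥ 0.25, and a one-sided binomial test
P[X ≥ alt | X ~ Bin(depth, 0.01)] ≤ 0.01; frequency ≥ 0.75 calls the
variant homozygous. Indel evidence is anchored at the preceding aligned
base and filtered identically.

**CNV/PAV.** For 50-bp windows, ρ(i) = TG_windCov(i)/RG_windCov(i); a
CBS-style changepoint search (binary split plus interior-arc statistics,
permutation-tested at α = 0.01) cuts the series into segments of
homogeneous ρ. With genome-wide averages over covered positions,

    ρ_segNorm(j) = ρ_seg(j) · RG_avCov / TG_avCov
    TG_segCopy(j) = TG_segCov(j)/TG_avCov,  RG_segCopy(j) = RG_segCov(j)/RG_avCov

and a segment is **lost** iff ρ_segNorm(j) ≤ 1 − 0.5/RG_segCopy(j),
**gained** iff ρ_segNorm(j) ≥ 1 + 0.5/RG_segCopy(j) — the half-copy
margin of a diploid losing or gaining one homologous copy. Windows with
target coverage 0 (reference covered) are merged into zero-coverage PAV
intervals. Copy numbers are reported alongside the ratio.

**Large deletions.** Same-chromosome pairs with template length above
mean + 4 SD of the proper-pair insert distribution nominate candidates;
candidates merging within 200 bp of first-mate distance and supported by
≥ 3 pairs survive. Around the approximate start and end, two 2,000-nt
ranges are extracted and the pairs' unmapped mates are Smith–Waterman
aligned against both; reads splitting across the two ranges vote for the
exact breakpoints (median vote). The 200 nt beyond the upstream
breakpoint are re-searched genome-wide to flag deletions whose flank has
a paralogous copy elsewhere, and interior target coverage yields a
homozygous / heterozygous-or-paralog hint.

See the methods vignette (`vignettes/resvkit-methods.Rmd`) for the full
account, including what the simulator does and does not emulate.

## Worked example

Simulate a 1-Mb genome with five 2,000-bp deletions, sequence it at 10×
with 70-bp paired-end reads (insert 300 ± 30, error ramp 0.0001–0.01),
align, and run the deletion finder:

```r
library(resvkit)
res <- study_deletions(genome_len = 1e6, n_del = 5L, sv_size = 2000L,
                       coverage = 10, seed = 7)
res$calls[, .(chrom, start, end, support, split_support,
              interior_cov, zygosity_hint)]
#>     chrom  start    end support split_support interior_cov zygosity_hint
#> 1:   chr1 207408 209408      16             5            0    homozygous
#> 2:   chr1 320866 322866      10             5            0    homozygous
#> 3:   chr1 465363 467363      12             6            0    homozygous
#> 4:   chr1 650567 652567       4             7            0    homozygous
#> 5:   chr1 798059 800058      14             7            0    homozygous
```

Each row is one refined deletion call: `support` discordant pairs
nominated it, `split_support` broken-alignment reads voted for the exact
breakpoints, and zero interior coverage marks it homozygous. Evaluated
against the simulation truth:

```r
c(res$eval$ppv, res$eval$sensitivity)   # base-level accuracy
#> [1] 1.0000 0.9999
res$bp[c("median", "q10", "q90")]       # signed breakpoint errors (bp)
#> $median [1] 0   $q10 [1] 0   $q90 [1] 0
```

No false positive bases are called and 99.99% of deleted bases are
recovered: the last call sits one base off its simulated interval
because that junction carries a one-base micro-homology, which makes
the breakpoint genuinely ambiguous by one position — the reason the
error distribution is summarised by its median.

A command-line front end covering every stage ships as `exec/resv-kit`
(`resv-kit pipeline --seed 1 --out out/` runs the full simulated
workflow; each analysis stage is also a subcommand taking SAM/FASTA/TSV
inputs).

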