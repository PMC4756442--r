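# Large-deletion discovery: discordant insert-size candidates, candidate
# merging, split-read breakpoint refinement by native local alignment
# within 2000-nt ranges centred on the approximate boundaries, the 200-nt
# flank ambiguity probe, and interior-coverage zygosity assessment.

#' Large-deletion finder configuration
#'
#' @param insert_threshold mapped mate distance (bp) above which a pair is
#'   discordant; `NULL` means estimate it as mean + 4 SD of the template
#'   lengths of the first 100,000 proper pairs.
#' @param merge_dist maximum distance between the first mates of two
#'   candidate pairs for merging (bp).
#' @param range_width width of the breakpoint refinement ranges (bp).
#' @param min_support minimum discordant pairs per reported candidate.
#' @param flank_len length of the ambiguity probe (bp).
#' @param min_score minimum local-alignment score.
#' @param split_min_score lower score floor used for the two partial
#'   alignments of a candidate split read (each part of a broken
#'   alignment can be short; an exact 14-bp match is still specific
#'   within a 2-kb range).
#' @param match,mismatch,gap_open,gap_ext local-alignment scoring.
#' @param ambig_identity,ambig_coverage identity and probe-coverage
#'   thresholds for recording a secondary flank alignment.
#' @return object of class `rk_deletion_config`.
#' @export
deletion_config <- function(insert_threshold = NULL, merge_dist = 200L,
                            range_width = 2000L, min_support = 3L,
                            flank_len = 200L, min_score = 30,
                            split_min_score = 14,
                            match = 1, mismatch = -2, gap_open = -5,
                            gap_ext = -2, ambig_identity = 0.90,
                            ambig_coverage = 0.50) {
    assert_that(range_width %% 2L == 0L, "range_width must be even")
    structure(list(insert_threshold = insert_threshold,
                   merge_dist = as.integer(merge_dist),
                   range_width = as.integer(range_width),
                   min_support = as.integer(min_support),
                   flank_len = as.integer(flank_len),
                   min_score = min_score,
                   split_min_score = split_min_score, match = match,
                   mismatch = mismatch, gap_open = gap_open,
                   gap_ext = gap_ext, ambig_identity = ambig_identity,
                   ambig_coverage = ambig_coverage),
              class = "rk_deletion_config")
}

#' Estimate the discordance threshold from proper pairs
#'
#' Mean + 4 SD of |tlen| over (at most) the first 100,000 proper pairs.
#'
#' @param aln alignment table.
#' @param n_pairs number of proper pairs to use.
#' @return threshold in bp.
#' @export
estimate_insert_threshold <- function(aln, n_pairs = 100000L) {
    tl <- aln[bitwAnd(flag, 2L) != 0L & tlen > 0L, tlen]
    assert_that(length(tl) >= 10L, "too few proper pairs to estimate insert")
    tl <- head(tl, n_pairs)
    mean(tl) + 4 * sd(tl)
}

#' Detect discordant read pairs (deletion candidates)
#'
#' A candidate arises from each same-chromosome pair whose mapped mate
#' distance (template length) exceeds the threshold. The approximate
#' deleted interval runs from the end of the leftmost mate to the start of
#' the rightmost mate (0-based half-open). Secondary alignments are
#' ignored.
#'
#' @param aln alignment table.
#' @param config [deletion_config()]; a `NULL` `insert_threshold` is
#'   estimated from the data.
#' @return `data.table` of candidates: chrom, first_start (0-based start
#'   of the leftmost mate), approx_start, approx_end, qname.
#' @export
detect_discordant <- function(aln, config = deletion_config()) {
    thr <- config$insert_threshold %||% estimate_insert_threshold(aln)
    left <- aln[unmapped == FALSE & secondary == FALSE &
                bitwAnd(flag, 8L) == 0L & chrom == mchrom &
                tlen > thr]
    if (nrow(left) == 0L)
        return(data.table(chrom = character(), first_start = integer(),
                          approx_start = integer(), approx_end = integer(),
                          qname = character()))
    span <- cigar_ref_span(left$cigar)
    cand <- left[, .(chrom, first_start = pos - 1L,
                     approx_start = pos - 1L + span,
                     approx_end = mpos - 1L, qname)]
    setorder(cand, chrom, first_start)
    cand[]
}

#' Merge discordant candidates into supported deletion candidates
#'
#' Single-linkage clustering along each chromosome: a new pair joins the
#' current cluster while its first-mate start is within `merge_dist` of
#' the previous one. The merged approximate interval is the median
#' envelope of the members; clusters with fewer than `min_support`
#' members are dropped.
#'
#' @param candidates output of [detect_discordant()], sorted.
#' @param config [deletion_config()].
#' @return `data.table`: chrom, approx_start, approx_end, support.
#' @export
merge_candidates <- function(candidates, config = deletion_config()) {
    if (nrow(candidates) == 0L)
        return(data.table(chrom = character(), approx_start = integer(),
                          approx_end = integer(), support = integer()))
    cand <- copy(candidates)
    setorder(cand, chrom, first_start)
    cand[, grp := cumsum(c(1L, (chrom[-1L] != chrom[-.N]) |
                               (diff(first_start) > config$merge_dist)))]
    merged <- cand[, .(chrom = chrom[1L],
                       approx_start = as.integer(median(approx_start)),
                       approx_end = as.integer(median(approx_end)),
                       support = .N), by = grp][, grp := NULL]
    merged <- merged[support >= config$min_support &
                     approx_start < approx_end]
    merged[]
}

#' Local alignment (Smith-Waterman with affine gaps)
#'
#' Native replacement for a BLASTn search in the breakpoint-refinement
#' role: finds all local maxima with score at least `min_score` by
#' aligning, then recursing on the unaligned query prefix and suffix.
#' Default scoring (+1/-2, gap open -5, extend -2) mirrors nucleotide
#' BLAST defaults.
#'
#' @param query,subject nucleotide strings over A,C,G,T,N.
#' @param config [deletion_config()] carrying the scoring.
#' @param min_score minimum reported score.
#' @return `data.table` of alignments: q_start, q_end, s_start, s_end
#'   (1-based inclusive), score, n_ident, aln_len, pct_identity.
#' @export
local_align <- function(query, subject, config = deletion_config(),
                        min_score = config$min_score) {
    assert_that(nchar(query) > 0 && nchar(subject) > 0,
                "empty sequence in local_align")
    res <- list()
    recurse <- function(q, off) {
        if (nchar(q) < max(10L, min_score)) return()
        a <- sw_best_cpp(q, subject, config$match, config$mismatch,
                         config$gap_open, config$gap_ext)
        if (a$score < min_score) return()
        res[[length(res) + 1L]] <<- data.table(
            q_start = a$q_start + off, q_end = a$q_end + off,
            s_start = a$s_start, s_end = a$s_end, score = a$score,
            n_ident = a$n_ident, aln_len = a$aln_len,
            pct_identity = 100 * a$n_ident / a$aln_len)
        if (a$q_start > 1L)
            recurse(substr(q, 1L, a$q_start - 1L), off)
        if (a$q_end < nchar(q))
            recurse(substr(q, a$q_end + 1L, nchar(q)), off + a$q_end)
    }
    recurse(query, 0L)
    if (!length(res))
        return(data.table(q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          score = numeric(), n_ident = integer(),
                          aln_len = integer(), pct_identity = numeric()))
    out <- rbindlist(res)
    setorder(out, -score)
    out[]
}

#' Refine a candidate deletion's breakpoints from split reads
#'
#' Two ranges of `range_width` nt are centred on the approximate start and
#' end. Read pairs with at least one mate mapped inside either range are
#' collected; their unmapped mates (broken alignments) are locally aligned
#' against both range sequences in both orientations. A read whose prefix
#' aligns in the upstream range and whose suffix aligns in the downstream
#' range votes for (upstream subject end, downstream subject start); the
#' refined breakpoints are the per-side lower medians of the votes. With
#' no votes the approximate coordinates stand.
#'
#' @param cand one row of [merge_candidates()] output.
#' @param aln alignment table (for the unmapped mates).
#' @param ref named character vector of reference sequences.
#' @param config [deletion_config()].
#' @return one-row `data.table` deletion call (0-based half-open
#'   refined/approx interval, support and split_support).
#' @export
refine_breakpoints <- function(cand, aln, ref, config = deletion_config()) {
    ch <- cand$chrom
    L <- nchar(ref[[ch]])
    half <- config$range_width %/% 2L
    up0 <- max(cand$approx_start - half, 0L)
    up1 <- min(cand$approx_start + half, L)
    dn0 <- max(cand$approx_end - half, 0L)
    dn1 <- min(cand$approx_end + half, L)
    up_seq <- seq_slices(ref[[ch]], up0, up1)
    dn_seq <- seq_slices(ref[[ch]], dn0, dn1)

    um <- aln[unmapped == TRUE & mchrom == ch &
              ((mpos - 1L >= up0 & mpos - 1L < up1) |
               (mpos - 1L >= dn0 & mpos - 1L < dn1))]
    votes_s <- integer(0); votes_e <- integer(0)
    for (i in seq_len(nrow(um))) {
        v <- split_read_vote(um$seq[i], up_seq, dn_seq, config)
        if (!is.null(v)) {
            votes_s <- c(votes_s, up0 + v$up_s_end)       # 0-based excl end
            votes_e <- c(votes_e, dn0 + v$dn_s_start - 1L) # 0-based start
        }
    }
    ok <- length(votes_s) > 0L
    refined_start <- if (ok) lower_median(votes_s) else NA_integer_
    refined_end <- if (ok) lower_median(votes_e) else NA_integer_
    if (ok && refined_start >= refined_end) {
        refined_start <- NA_integer_; refined_end <- NA_integer_
        ok <- FALSE
    }
    data.table(chrom = ch,
               approx_start = cand$approx_start,
               approx_end = cand$approx_end,
               refined_start = refined_start, refined_end = refined_end,
               start = if (ok) refined_start else cand$approx_start,
               end = if (ok) refined_end else cand$approx_end,
               support = cand$support,
               split_support = length(votes_s))
}

lower_median <- function(x) {
    x <- sort(x)
    x[ceiling(length(x) / 2)]
}

# align one unmapped read (both orientations) against the two range
# sequences; return subject coordinates of a compatible split, or NULL
split_read_vote <- function(seq, up_seq, dn_seq, config) {
    best <- NULL; best_score <- -Inf
    ms <- config$split_min_score %||% config$min_score
    for (s in c(seq, revcomp(seq))) {
        up <- local_align(s, up_seq, config, min_score = ms)
        dn <- local_align(s, dn_seq, config, min_score = ms)
        if (!nrow(up) || !nrow(dn)) next
        # best compatible pair: prefix in upstream, suffix in downstream
        for (i in seq_len(min(nrow(up), 3L))) {
            for (j in seq_len(min(nrow(dn), 3L))) {
                u <- up[i]; d <- dn[j]
                gap <- d$q_start - u$q_end - 1L
                if (gap < -6L || gap > 10L) next
                if (u$q_end - u$q_start + 1L < 14L ||
                    d$q_end - d$q_start + 1L < 14L) next
                if (u$pct_identity < 85 || d$pct_identity < 85) next
                cov <- (u$q_end - u$q_start + 1L) +
                       (d$q_end - d$q_start + 1L)
                if (cov < 0.8 * nchar(s)) next
                sc <- u$score + d$score
                if (sc > best_score) {
                    best_score <- sc
                    best <- list(up_s_end = u$s_end, dn_s_start = d$s_start)
                }
            }
        }
    }
    best
}

#' Probe the downstream flank of a refined deletion for paralogy
#'
#' The first `flank_len` nucleotides beyond the upstream breakpoint (the
#' start of the deleted sequence) are extracted from the reference and
#' searched genome-wide with a seeded local alignment. Any hit away from
#' the deletion locus with identity >= `ambig_identity` and probe coverage
#' >= `ambig_coverage` marks the call ambiguous: the discordant signal may
#' reflect a duplication/paralog rather than a loss.
#'
#' @param call one-row deletion call with `refined_start` present.
#' @param ref named character vector of reference sequences.
#' @param config [deletion_config()].
#' @return the call with added columns ambiguous, secondary_chrom,
#'   secondary_pos (1-based), secondary_identity, secondary_coverage,
#'   ambiguity_note.
#' @export
flag_ambiguous <- function(call, ref, config = deletion_config()) {
    out <- copy(call)
    out[, `:=`(ambiguous = FALSE, secondary_chrom = NA_character_,
               secondary_pos = NA_integer_, secondary_identity = NA_real_,
               secondary_coverage = NA_real_, ambiguity_note = "")]
    if (is.na(call$refined_start)) {
        out[, ambiguity_note := "no refined breakpoint; probe skipped"]
        return(out[])
    }
    ch <- call$chrom
    L <- nchar(ref[[ch]])
    p0 <- call$refined_start
    p1 <- min(p0 + config$flank_len, L)
    if (p1 - p0 < 50L) {
        out[, ambiguity_note := "probe shorter than 50 nt; test skipped"]
        return(out[])
    }
    probe <- seq_slices(ref[[ch]], p0, p1)
    hits <- seeded_genome_hits(probe, ref, config)
    # exclude the probe's own locus (within the deletion +/- one probe)
    excl0 <- p0 - (p1 - p0); excl1 <- call$refined_end %||% p1
    hits <- hits[!(chrom == ch & pos0 < excl1 + config$flank_len &
                   pos0 + (p1 - p0) > excl0)]
    hits <- hits[pct_identity >= 100 * config$ambig_identity &
                 coverage >= config$ambig_coverage]
    if (nrow(hits)) {
        setorder(hits, -score)
        out[, `:=`(ambiguous = TRUE,
                   secondary_chrom = hits$chrom[1L],
                   secondary_pos = hits$pos0[1L] + 1L,
                   secondary_identity = hits$pct_identity[1L],
                   secondary_coverage = hits$coverage[1L])]
    }
    out[]
}

# seed-and-extend search of a short probe against whole chromosomes:
# exact 20-mer seeds every 10 bp located with Biostrings, then local
# alignment of the probe against a window around each seed hit
seeded_genome_hits <- function(probe, ref, config, seed_len = 20L,
                               seed_step = 10L) {
    plen <- nchar(probe)
    starts <- seq(1L, max(plen - seed_len + 1L, 1L), by = seed_step)
    seeds <- unique(substring(probe, starts, starts + seed_len - 1L))
    seeds <- seeds[nchar(seeds) == seed_len]
    out <- list()
    for (ch in names(ref)) {
        subj <- Biostrings::DNAString(ref[[ch]])
        loci <- integer(0)
        for (k in seq_along(seeds)) {
            m <- Biostrings::matchPattern(seeds[k], subj)
            if (length(m))
                loci <- c(loci, BiocGenerics::start(m) - (starts[k] - 1L))
        }
        if (!length(loci)) next
        # cluster seed hits into candidate windows
        loci <- sort(unique(pmax(loci, 1L)))
        grp <- cumsum(c(1L, diff(loci) > plen))
        for (g in unique(grp)) {
            anchor <- loci[grp == g][1L]
            w0 <- max(anchor - 1L - plen %/% 2L, 0L)
            w1 <- min(w0 + 2L * plen, nchar(ref[[ch]]))
            win <- seq_slices(ref[[ch]], w0, w1)
            a <- local_align(probe, win, config)
            if (!nrow(a)) next
            a <- a[1L]
            out[[length(out) + 1L]] <- data.table(
                chrom = ch, pos0 = w0 + a$s_start - 1L,
                score = a$score, pct_identity = a$pct_identity,
                coverage = (a$q_end - a$q_start + 1L) / plen)
        }
    }
    if (!length(out))
        return(data.table(chrom = character(), pos0 = integer(),
                          score = numeric(), pct_identity = numeric(),
                          coverage = numeric()))
    rbindlist(out)
}

#' Interior coverage and zygosity hint for a deletion call
#'
#' The mean target depth inside the (refined, else approximate) interval
#' is reported; a deletion with interior coverage below one tenth of the
#' target genome's average coverage is hinted homozygous, anything higher
#' is heterozygous or a paralogous copy elsewhere in the genome.
#'
#' @param call one-row deletion call.
#' @param tg_pileup target pileup (`rk_pileup`).
#' @param tg_av_cov target average coverage; computed from the pileup
#'   when omitted.
#' @return the call with `interior_cov` and `zygosity_hint` columns.
#' @export
assess_zygosity <- function(call, tg_pileup,
                            tg_av_cov = average_coverage(tg_pileup)) {
    out <- copy(call)
    d <- tg_pileup$chroms[[call$chrom]]$depth
    s <- call$start; e <- call$end
    ic <- if (!is.null(d) && e > s) mean(d[(s + 1L):min(e, length(d))]) else NA_real_
    out[, interior_cov := ic]
    out[, zygosity_hint := ifelse(!is.na(ic) & ic < 0.1 * tg_av_cov,
                                  "homozygous", "heterozygous_or_paralog")]
    out[]
}

#' Run the whole large-deletion analysis
#'
#' Discordant-pair detection, merging, per-candidate split-read
#' refinement, flank ambiguity probing and zygosity assessment.
#'
#' @param aln alignment table (with unmapped mates present).
#' @param ref named character vector of reference sequences.
#' @param tg_pileup optional target pileup for interior coverage.
#' @param config [deletion_config()].
#' @return `data.table` of deletion calls.
#' @export
find_deletions <- function(aln, ref, tg_pileup = NULL,
                           config = deletion_config()) {
    if (is.null(config$insert_threshold))
        config$insert_threshold <- estimate_insert_threshold(aln)
    cand <- merge_candidates(detect_discordant(aln, config), config)
    if (nrow(cand) == 0L) return(empty_deletion_calls())
    um_all <- aln[unmapped == TRUE]
    calls <- rbindlist(lapply(seq_len(nrow(cand)), function(i) {
        call <- refine_breakpoints(cand[i], um_all, ref, config)
        call <- flag_ambiguous(call, ref, config)
        if (!is.null(tg_pileup)) call <- assess_zygosity(call, tg_pileup)
        call
    }), fill = TRUE)
    calls[]
}

empty_deletion_calls <- function() {
    data.table(chrom = character(), approx_start = integer(),
               approx_end = integer(), refined_start = integer(),
               refined_end = integer(), start = integer(), end = integer(),
               support = integer(), split_support = integer(),
               ambiguous = logical(), secondary_chrom = character(),
               secondary_pos = integer(), secondary_identity = numeric(),
               secondary_coverage = numeric(), ambiguity_note = character(),
               interior_cov = numeric(), zygosity_hint = character())
}
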