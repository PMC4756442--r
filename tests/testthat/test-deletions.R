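test_that("discordant pairs are detected from template-length geometry", {
    cfg <- deletion_config(insert_threshold = 1000)
    aln <- rbind(
        # mates ending/starting at 1,000 and 3,300 -> candidate
        make_aln("a", 99L, pos = 931L, mpos = 3301L, tlen = 2440L),
        make_aln("a", 147L, pos = 3301L, mpos = 931L, tlen = -2440L),
        # mate distance below threshold -> no candidate
        make_aln("b", 99L, pos = 5000L, mpos = 5280L, tlen = 350L),
        make_aln("b", 147L, pos = 5280L, mpos = 5000L, tlen = -350L),
        # interchromosomal pair -> ignored
        make_aln("c", 97L, pos = 100L, mchrom = "c2", mpos = 90000L,
                 tlen = 0L))
    cand <- detect_discordant(aln, cfg)
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$approx_start, 1000L)   # end of leftmost mate, 0-based
    expect_equal(cand$approx_end, 3300L)     # start of rightmost mate
})

test_that("candidate merging clusters by first-mate distance", {
    cfg <- deletion_config(insert_threshold = 1000, merge_dist = 200L,
                           min_support = 3L)
    mk <- function(first, qn) data.table(
        chrom = "c1", first_start = first, approx_start = first + 70L,
        approx_end = first + 2370L, qname = qn)
    # five pairs spread over 80 bp around one deletion
    c1 <- rbindlist(lapply(seq(1000L, 1080L, 20L),
                           function(s) mk(s, paste0("r", s))))
    m <- merge_candidates(c1, cfg)
    expect_equal(nrow(m), 1L)
    expect_equal(m$support, 5L)
    expect_equal(m$approx_start, 1110L)      # median envelope

    # two deletions 10 kb apart stay separate
    c2 <- rbind(c1, rbindlist(lapply(seq(11000L, 11080L, 20L),
                                     function(s) mk(s, paste0("q", s)))))
    expect_equal(nrow(merge_candidates(c2, cfg)), 2L)

    # singleton below min_support is dropped
    expect_equal(nrow(merge_candidates(mk(500L, "x"), cfg)), 0L)
})

test_that("local alignment finds exact and split matches", {
    set.seed(71)
    subject <- rand_dna(2000L)
    q <- substr(subject, 501, 540)
    a <- local_align(q, subject)
    expect_equal(a$s_start[1], 501L)
    expect_equal(a$s_end[1], 540L)
    expect_equal(a$pct_identity[1], 100)
    expect_equal(a$score[1], 40)

    # 35 bp of locus A + 35 bp of locus B -> one alignment per locus
    split_q <- paste0(substr(subject, 101, 135), substr(subject, 1201, 1235))
    a2 <- local_align(split_q, subject)
    expect_equal(nrow(a2), 2L)
    expect_setequal(a2$s_start, c(101L, 1201L))
    expect_error(local_align("", subject), "empty")
})

test_that("Smith-Waterman scores equal the DP oracle", {
    set.seed(72)
    for (i in 1:12) {
        q <- rand_dna(sample(20:80, 1))
        s <- rand_dna(sample(60:200, 1))
        if (i %% 3 == 0) {   # plant a noisy copy so scores are non-trivial
            ins <- substr(q, 5, min(nchar(q), 60))
            pos <- sample(nchar(s) - nchar(ins), 1)
            s <- paste0(substr(s, 1, pos), ins,
                        substr(s, pos + 1, nchar(s)))
        }
        got <- resvkit:::sw_best_cpp(q, s, 1, -2, -5, -2)
        expect_equal(got$score, sw_score_oracle(q, s), tolerance = 1e-9)
    }
})

test_that("random reads almost never align to unrelated sequence", {
    set.seed(73)
    subject <- rand_dna(2000L)
    hits <- 0L
    for (i in 1:50)
        if (nrow(local_align(rand_dna(70L), subject)) > 0) hits <- hits + 1L
    expect_lte(hits, 1L)  # >= 99% of trials produce no alignment
})

test_that("breakpoint refinement recovers simulated deletions exactly", {
    res <- study_deletions(genome_len = 8e5, n_del = 4L, sv_size = 2000L,
                           coverage = 12, seed = 31)
    expect_equal(nrow(res$calls), 4L)
    expect_true(all(!is.na(res$calls$refined_start)))
    expect_true(all(res$calls$refined_start < res$calls$refined_end))
    expect_true(all(res$calls$support >= 3L))
    expect_equal(res$bp$median, 0)
    expect_lte(abs(res$bp$q90), 2)
    expect_gte(res$eval$ppv, 0.97)
    expect_gte(res$eval$sensitivity, 0.97)
    # deletions are homozygous in this simulation
    expect_true(all(res$calls$zygosity_hint == "homozygous"))
})

test_that("refinement falls back to approximate coordinates without votes", {
    ref <- toy_genome(20000L, seed = 32)
    cand <- data.table(chrom = "c1", approx_start = 5000L,
                       approx_end = 8000L, support = 4L)
    no_reads <- resvkit:::empty_alignments()
    call <- refine_breakpoints(cand, no_reads, ref, deletion_config())
    expect_true(is.na(call$refined_start))
    expect_equal(call$start, 5000L)
    expect_equal(call$end, 8000L)
    expect_equal(call$split_support, 0L)
})

test_that("median vote is the lower median", {
    expect_equal(resvkit:::lower_median(c(1000L, 1000L, 1002L)), 1000L)
    expect_equal(resvkit:::lower_median(c(1000L, 1002L)), 1000L)
})

test_that("ambiguity probe flags duplicated flanks and skips self-hits", {
    set.seed(74)
    base <- rand_dna(30000L)
    flank <- substr(base, 10001, 10200)     # deleted-region start
    # plant a 100%-identity copy of the flank far away
    genome_dup <- c(c1 = paste0(substr(base, 1, 24000), flank,
                                substr(base, 24201, 30000)))
    call <- data.table(chrom = "c1", approx_start = 9990L,
                       approx_end = 12010L, refined_start = 10000L,
                       refined_end = 12000L, start = 10000L, end = 12000L,
                       support = 5L, split_support = 4L)
    out <- flag_ambiguous(call, genome_dup, deletion_config())
    expect_true(out$ambiguous)
    expect_equal(out$secondary_pos, 24001L)
    expect_gte(out$secondary_identity, 90)

    # unique flank -> no ambiguity (the self-hit is excluded)
    genome_uniq <- c(c1 = base)
    out2 <- flag_ambiguous(call, genome_uniq, deletion_config())
    expect_false(out2$ambiguous)

    # unrefined call skips the probe with a note
    call3 <- copy(call)[, `:=`(refined_start = NA_integer_,
                               refined_end = NA_integer_)]
    out3 <- flag_ambiguous(call3, genome_uniq, deletion_config())
    expect_false(out3$ambiguous)
    expect_match(out3$ambiguity_note, "skipped")
})

test_that("interior coverage drives the zygosity hint", {
    depth <- rep(20L, 10000L)
    depth[4001:6000] <- 0L
    pile <- structure(list(chroms = list(c1 = list(
        depth = depth, counts = NULL,
        ins = data.table(), del = data.table()))), class = "rk_pileup")
    call <- data.table(chrom = "c1", start = 4000L, end = 6000L)
    out <- assess_zygosity(call, pile)
    expect_equal(out$interior_cov, 0)
    expect_equal(out$zygosity_hint, "homozygous")

    depth[4001:6000] <- 10L   # about half the average -> het or paralog
    pile$chroms$c1$depth <- depth
    out2 <- assess_zygosity(call, pile)
    expect_equal(out2$zygosity_hint, "heterozygous_or_paralog")
})
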