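test_that("rearranged genome conserves length through deletions and dups", {
    ref <- toy_genome(10000L, seed = 1)
    cfg <- sim_config(n_del = 1L, sv_size = 2000L, min_sv_gap = 100L,
                      seed = 2)
    sim <- simulate_rearranged_genome(ref, cfg)
    expect_equal(nchar(sim$target[["c1"]]), 8000L)
    expect_equal(nrow(sim$truth$deletions), 1L)

    cfg <- sim_config(n_dup = 1L, sv_size = 1000L, max_dups = 10L,
                      min_sv_gap = 100L, seed = 3)
    sim <- simulate_rearranged_genome(ref, cfg)
    k <- sim$truth$duplications$extra_copies
    expect_gte(k, 1L); expect_lte(k, 10L)
    expect_equal(nchar(sim$target[["c1"]]), 10000L + 1000L * k)

    # general conservation with mixed events
    ref <- toy_genome(60000L, seed = 4)
    cfg <- sim_config(n_del = 3L, n_dup = 3L, sv_size = 2000L,
                      min_sv_gap = 500L, seed = 5)
    sim <- simulate_rearranged_genome(ref, cfg)
    expect_equal(nchar(sim$target[["c1"]]),
                 60000L - 3L * 2000L +
                     2000L * sum(sim$truth$duplications$extra_copies))
    # placed events do not overlap
    ev <- rbind(sim$truth$deletions,
                sim$truth$duplications[, .(chrom, start, end)])
    setorder(ev, start)
    expect_true(all(ev$start[-1L] >= ev$end[-nrow(ev)]))
})

test_that("fifty 2000-bp deletions excise 100,000 bp in total", {
    ref <- toy_genome(1e6L, seed = 6)
    cfg <- sim_config(n_del = 50L, sv_size = 2000L, min_sv_gap = 2000L,
                      seed = 7)
    sim <- simulate_rearranged_genome(ref, cfg)
    expect_equal(nrow(sim$truth$deletions), 50L)
    expect_equal(sum(sim$truth$deletions$end - sim$truth$deletions$start),
                 100000L)
    expect_equal(nchar(sim$target[["c1"]]), 1e6L - 100000L)
})

test_that("event placement fails loudly when impossible", {
    ref <- toy_genome(3000L, seed = 1)
    expect_error(simulate_rearranged_genome(
        ref, sim_config(n_del = 1L, sv_size = 5000L, seed = 1)),
        "chromosome")
    expect_error(simulate_rearranged_genome(
        ref, sim_config(n_del = 40L, sv_size = 1000L, min_sv_gap = 1000L,
                        seed = 1)),
        "budget")
})

test_that("point-variant simulation matches its rates and is seeded", {
    ref <- toy_genome(3e5L, seed = 8)
    cfg0 <- sim_config(snp_rate = 0, indel_rate = 0, seed = 9)
    pv0 <- simulate_point_variants(ref, cfg0)
    expect_identical(pv0$haplotypes$hap1, ref)
    expect_identical(pv0$haplotypes$hap2, ref)
    expect_equal(nrow(pv0$truth$snps), 0L)

    cfg <- sim_config(snp_rate = 0.001, indel_rate = 1e-4, seed = 10)
    pv <- simulate_point_variants(ref, cfg)
    n <- nrow(pv$truth$snps)
    mu <- 3e5 * 0.001; sdv <- sqrt(3e5 * 0.001 * 0.999)
    expect_gt(n, mu - 4 * sdv)
    expect_lt(n, mu + 4 * sdv)
    # truth alleles really differ from the reference
    expect_true(all(pv$truth$snps$ref != pv$truth$snps$alt))

    pv2 <- simulate_point_variants(ref, cfg)
    expect_identical(pv$truth, pv2$truth)
    expect_identical(pv$haplotypes, pv2$haplotypes)
})

test_that("paired-read simulation honours count, error and insert model", {
    ref <- toy_genome(2e5L, seed = 11)
    cfg <- sim_config(coverage = 10, err_min = 0, err_max = 0, seed = 12)
    reads <- simulate_paired_reads(ref, cfg)
    expect_equal(nrow(reads), 2L * floor(10 * 2e5 / 140))
    # error-free reads match their source slice exactly
    i <- which(reads$strand == "+")[1:50]
    expect_identical(reads$seq[i],
                     substring(ref[["c1"]], reads$gstart[i] + 1L,
                               reads$gstart[i] + 70L))
    j <- which(reads$strand == "-")[1:50]
    expect_identical(reads$seq[j], as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(
            substring(ref[["c1"]], reads$gstart[j] + 1L,
                      reads$gstart[j] + 70L)))))
    # law of large numbers for the insert size
    ins <- reads[mate == 1L | mate == 2L, insert[seq(1, .N, 2)]]
    expect_lt(abs(mean(ins) - 300) / 300, 0.01)
    expect_error(simulate_paired_reads(ref, sim_config(coverage = 0)),
                 "coverage")
})

test_that("oracle alignment reproduces deletion geometry", {
    ref <- toy_genome(50000L, seed = 13)
    cfg <- sim_config(coverage = 8, n_del = 1L, sv_size = 2000L,
                      min_sv_gap = 100L, err_min = 0, err_max = 0,
                      seed = 14)
    sim <- simulate_rearranged_genome(ref, cfg)
    del <- sim$truth$deletions
    cfg$seed <- 15
    reads <- simulate_paired_reads(sim$target, cfg)
    aln <- oracle_align(reads, sim$truth, ref, cfg)

    # mapped reads away from the deletion carry a full-match CIGAR and
    # their sequence equals the reference slice
    m <- aln[unmapped == FALSE & (pos + 70L < del$start - 300L)]
    expect_true(all(m$cigar == "70M"))
    k <- seq_len(min(30L, nrow(m)))
    expect_identical(m$seq[k], substring(ref[["c1"]], m$pos[k],
                                         m$pos[k] + 69L))
    # pairs flanking the deletion show tlen inflated by its size
    disc <- aln[tlen > 1000L]
    expect_gt(nrow(disc), 0L)
    expect_true(all(abs(disc$tlen - (2000 + 300)) < 4 * 30 + 140))
    # breakpoint-spanning reads are unmapped with the mate position kept
    um <- aln[unmapped == TRUE]
    expect_gt(nrow(um), 0L)
    expect_true(all(um$mpos > 0L))
    expect_true(all(um$cigar == "*"))
})

test_that("oracle alignment emits I/D CIGARs across point indels", {
    ref <- toy_genome(2000L, seed = 16)
    # hand-build one homozygous insertion and one homozygous deletion
    ins_at <- 600L; del_at <- 1400L
    ind <- data.table(pos = c(ins_at, del_at), kind = c("INS", "DEL"),
                      allele = c("GTAC",
                                 substr(ref[["c1"]], del_at + 1L,
                                        del_at + 3L)),
                      len = c(4L, 3L), zygosity = "hom", hap = 1L)
    built <- resvkit:::apply_indels(ref[["c1"]], ind, "c1")
    map <- built$map
    data.table::setattr(map, "kind", "point")
    cfg <- sim_config(err_min = 0, err_max = 0)
    # read crossing the insertion: starts 30 bp before the anchor
    # target coordinates: positions after the 4-bp insertion shift by +4
    reads <- data.table(pid = 1:2, src = "g", chrom = "c1",
                        gstart = c(ins_at - 30L, del_at + 4L - 30L),
                        strand = "+", mate = 1L, insert = 300L,
                        qname = c("a", "b"))
    reads[, seq := substring(built$seq, gstart + 1L, gstart + 70L)]
    reads[, qual := strrep("I", 70L)]
    data.table::setattr(reads, "read_len", 70L)
    # pair rows (mate 2) far away so pairing logic stays simple
    mate2 <- copy(reads)[, `:=`(gstart = 0L, mate = 2L, strand = "-",
                                seq = substring(built$seq, 1, 70),
                                qual = strrep("I", 70L))]
    rr <- rbind(reads, mate2)[order(pid)]
    aln <- oracle_align(rr, map, ref, cfg)
    expect_equal(aln[qname == "a" & bitwAnd(flag, 64L) > 0, cigar],
                 "30M4I36M")
    expect_equal(aln[qname == "b" & bitwAnd(flag, 64L) > 0, cigar],
                 "30M3D40M")

    pile <- pileup_from_alignments(aln, ref)
    expect_equal(pile$chroms$c1$ins$pos, ins_at)
    expect_equal(pile$chroms$c1$ins$allele, "GTAC")
    expect_equal(pile$chroms$c1$del$pos, del_at)
    expect_equal(pile$chroms$c1$del$len, 3L)
})

test_that("pileup depth, consensus and zero-coverage semantics hold", {
    ref <- toy_genome(500L, seed = 17)
    # ten error-free reads over one locus
    aln <- rbindlist(lapply(1:10, function(i)
        make_aln(paste0("r", i), flag = 0L, pos = 101L,
                 seq = substring(ref[["c1"]], 101L, 170L))))
    pile <- pileup_from_alignments(aln, ref)
    expect_equal(pile$chroms$c1$depth[120L], 10L)
    recs <- pileup_records(pile, ref)
    expect_true(all(recs$tg_base == recs$ref_base))
    expect_false(any(recs$snp_flag))

    # five reads C over ref A, five reads matching -> het evidence 0.5
    pos <- 130L
    refbase <- substring(ref[["c1"]], pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), refbase)[1]
    off <- pos - 101L + 1L    # offset of the locus within each read
    aln2 <- copy(aln)
    aln2[1:5, seq := vapply(seq, function(s)
        subst_base(s, off, alt), character(1))]
    pile2 <- pileup_from_alignments(aln2, ref)
    rec2 <- pileup_records(pile2, ref)
    r <- rec2[pos == 130L]
    expect_equal(r$alt_count, 5L)
    expect_true(r$snp_flag)

    # region with no reads yields no records (zero coverage)
    expect_false(any(recs$pos > 400L))
})

test_that("coverage recovers the configured depth away from SVs", {
    ref <- toy_genome(1e6L, seed = 18)
    cfg <- sim_config(coverage = 10, seed = 19)
    reads <- simulate_paired_reads(ref, cfg)
    aln <- oracle_align(reads, NULL, ref, cfg)
    pile <- pileup_from_alignments(aln, ref, want_counts = FALSE)
    d <- pile$chroms$c1$depth
    inner <- d[1000:(length(d) - 1000)]
    expect_lt(abs(mean(inner) - 10) / 10, 0.05)
})

test_that("identical config and seed give identical simulations", {
    ref <- toy_genome(30000L, seed = 20)
    cfg <- sim_config(coverage = 6, n_del = 1L, sv_size = 2000L,
                      min_sv_gap = 100L, seed = 21)
    run <- function() {
        sim <- simulate_rearranged_genome(ref, cfg)
        cfg$seed <- 22
        reads <- simulate_paired_reads(sim$target, cfg)
        list(truth = sim$truth, reads = reads)
    }
    a <- run(); b <- run()
    expect_identical(a$truth$deletions, b$truth$deletions)
    expect_identical(a$reads, b$reads)
})
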