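# a minimal gene model built directly (bypassing GFF3 parsing)
mk_model <- function(gene_id = "g1", chrom = "c1", strand = "+",
                     cds_iv, cds_seq, u5 = NULL, u3 = NULL,
                     gene_start = min(cds_iv$start),
                     gene_end = max(cds_iv$end), ok = TRUE) {
    m <- list(list(gene_id = gene_id, chrom = chrom, strand = strand,
                   gene_start = gene_start, gene_end = gene_end,
                   cds_intervals = cds_iv,
                   utr5_intervals = u5 %||% data.table(start = integer(),
                                                       end = integer()),
                   utr3_intervals = u3 %||% data.table(start = integer(),
                                                       end = integer()),
                   cds_seq = cds_seq, utr5_seq = NA_character_,
                   utr3_seq = NA_character_, ok = ok, note = ""))
    names(m) <- gene_id
    structure(m, class = "rk_gene_models")
}

test_that("variant positions map into spliced strand-aware coordinates", {
    gm <- mk_model(cds_iv = data.table(start = 101L, end = 160L),
                   cds_seq = strrep("A", 60L))
    hit <- map_variant("c1", 150L, gm)
    expect_equal(hit$region, "CDS")
    expect_equal(hit$rel_pos, 50L)

    gm_minus <- mk_model(strand = "-",
                         cds_iv = data.table(start = 101L, end = 160L),
                         cds_seq = strrep("A", 60L))
    expect_equal(map_variant("c1", 150L, gm_minus)$rel_pos, 11L)  # 160-150+1
    expect_equal(nrow(map_variant("c1", 90L, gm)), 0L)

    # spliced two-exon gene: second exon positions continue the count
    gm2 <- mk_model(cds_iv = data.table(start = c(101L, 201L),
                                        end = c(130L, 230L)),
                    cds_seq = strrep("A", 60L))
    expect_equal(map_variant("c1", 205L, gm2)$rel_pos, 35L)
})

test_that("CDS effects match codon arithmetic", {
    gm <- mk_model(cds_iv = data.table(start = 1L, end = 9L),
                   cds_seq = "ATGGAATAA")
    # G -> T at position 4 turns codon 2 GAA into TAA: premature stop
    e <- cds_effect(gm$g1, 4L, "G", "T")
    expect_true(e$premature_stop)
    expect_equal(e$codon_index, 2L)
    expect_equal(e$alt_aa, "*")
    # synonymous third-position change GAA -> GAG
    e2 <- cds_effect(gm$g1, 6L, "A", "G")
    expect_false(e2$aa_change)
    expect_equal(e2$ref_aa, "E")
    # terminal TAA -> TAC loses the stop codon
    e3 <- cds_effect(gm$g1, 9L, "A", "C")
    expect_true(e3$lost_stop)
    expect_false(e3$premature_stop)
    # disagreement with the annotated CDS base is an error
    expect_error(cds_effect(gm$g1, 4L, "C", "T"), "disagrees")
    # flagged (partial) models suppress effects
    gm_bad <- mk_model(cds_iv = data.table(start = 1L, end = 8L),
                       cds_seq = "ATGGAATA", ok = FALSE)
    expect_null(cds_effect(gm_bad$g1, 4L, "G", "T"))
})

test_that("CDS SNP effects agree with brute-force translation", {
    set.seed(81)
    for (i in 1:10) {
        n_codon <- sample(5:30, 1)
        cds <- paste0("ATG", rand_dna(3L * (n_codon - 2L)), "TAA")
        gm <- mk_model(cds_iv = data.table(start = 1L,
                                           end = nchar(cds)),
                       cds_seq = cds)
        rel <- sample(nchar(cds), 1)
        ref_nt <- substr(cds, rel, rel)
        alt_nt <- sample(setdiff(c("A", "C", "G", "T"), ref_nt), 1)
        e <- cds_effect(gm$g1, rel, ref_nt, alt_nt)
        mut <- translate_cds(subst_base(cds, rel, alt_nt))
        orig <- translate_cds(cds)
        ci <- ceiling(rel / 3)
        expect_equal(e$alt_aa, substr(mut, ci, ci))
        expect_equal(e$ref_aa, substr(orig, ci, ci))
        expect_equal(e$aa_change,
                     substr(mut, ci, ci) != substr(orig, ci, ci))
        expect_equal(e$premature_stop,
                     substr(mut, ci, ci) == "*" && ci < n_codon)
    }
})

test_that("indel frameshift is length mod 3", {
    gm <- mk_model(cds_iv = data.table(start = 1L, end = 9L),
                   cds_seq = "ATGGAATAA")
    expect_true(indel_effect(gm$g1, 4L, 1L))
    expect_false(indel_effect(gm$g1, 4L, 3L))
    expect_true(indel_effect(gm$g1, 4L, 4L))
})

test_that("a gene and its reverse-complement mirror annotate identically", {
    set.seed(82)
    L <- 500L
    genome <- toy_genome(L, seed = 83)
    cds_plus <- substr(genome[["c1"]], 201, 260)
    gm_plus <- mk_model(cds_iv = data.table(start = 201L, end = 260L),
                        cds_seq = cds_plus)
    # mirrored genome: the same gene sits on the minus strand
    mirror <- c(c1 = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(genome[["c1"]]))))
    mstart <- L - 260L + 1L; mend <- L - 201L + 1L
    gm_minus <- mk_model(strand = "-",
                         cds_iv = data.table(start = mstart, end = mend),
                         cds_seq = cds_plus)
    pos <- 230L
    ref_nt <- substr(genome[["c1"]], pos, pos)
    alt_nt <- setdiff(c("A", "C", "G", "T"), ref_nt)[1]
    v_plus <- data.table(chrom = "c1", pos = pos, kind = "SNP",
                         ref_allele = ref_nt, alt_allele = alt_nt,
                         allele = alt_nt, zygosity = "hom")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    v_minus <- data.table(chrom = "c1", pos = L - pos + 1L, kind = "SNP",
                          ref_allele = comp[[ref_nt]],
                          alt_allele = comp[[alt_nt]],
                          allele = comp[[alt_nt]], zygosity = "hom")
    e_plus <- annotate_variants(v_plus, gm_plus)
    e_minus <- annotate_variants(v_minus, gm_minus)
    expect_equal(e_plus$rel_pos, e_minus$rel_pos)
    expect_equal(e_plus$ref_aa, e_minus$ref_aa)
    expect_equal(e_plus$alt_aa, e_minus$alt_aa)
    expect_equal(e_plus$premature_stop, e_minus$premature_stop)
})

test_that("gene extractor flags containment and partial overlap", {
    gm <- c(mk_model("gA", cds_iv = data.table(start = 1000L, end = 2000L),
                     cds_seq = strrep("A", 1001L)),
            mk_model("gB", cds_iv = data.table(start = 2800L, end = 3400L),
                     cds_seq = strrep("A", 601L)),
            mk_model("gC", cds_iv = data.table(start = 9000L, end = 9400L),
                     cds_seq = strrep("A", 401L)))
    class(gm) <- "rk_gene_models"
    ge <- data.table(chrom = "c1", start = 499L, end = 3000L,
                     call = "loss")
    out <- gene_extractor(ge, gm)
    expect_equal(out[gene_id == "gA", flag], 1L)   # fully contained
    expect_equal(out[gene_id == "gB", flag], 0L)   # boundary-straddling
    expect_false("gC" %in% out$gene_id)            # outside -> omitted
    # every overlapping gene gets exactly one flag
    expect_equal(nrow(out), 2L)
    expect_true(all(out$flag %in% c(0L, 1L)))
})

test_that("sliding tracks compute coverage and variant frequencies", {
    pile <- structure(list(chroms = list(c1 = list(
        depth = rep(10L, 4000L), counts = NULL,
        ins = data.table(), del = data.table()))), class = "rk_pileup")
    v <- data.table(chrom = "c1", pos = 500L, kind = "SNP")
    tr <- sliding_tracks(pile, v, window = 1000L, step = 1000L)
    expect_equal(nrow(tr), 4L)
    expect_true(all(tr$coverage == 10))
    expect_equal(tr$snp_freq, c(0.001, 0, 0, 0))
    expect_equal(tr$indel_freq, rep(0, 4))

    tr2 <- sliding_tracks(pile, v, window = 1000L, step = 500L)
    expect_equal(nrow(tr2), 8L)    # half-window step doubles the rows
    expect_error(sliding_tracks(pile, v, window = 100L, step = 200L))
})
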