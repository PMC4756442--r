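# Transcript-level consequence annotation: mapping variants to CDS/UTR
# regions, amino-acid substitutions, premature/lost stop codons and
# frameshifts; gene/structural-variant intersection; windowed
# coverage-and-polymorphism tracks.

GENETIC_CODE_TABLE <- {
    b <- c("T", "C", "A", "G")
    # standard nuclear code, third base cycling fastest (TTT, TTC, ...)
    codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L),
                     rep(b, 16L))
    aas <- strsplit(paste0(
        "FFLLSSSSYY**CC*W",
        "LLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRR",
        "VVVVAAAADDEEGGGG"), "")[[1]]
    stats::setNames(aas, codons)
}

translate_codon <- function(codon) {
    aa <- unname(GENETIC_CODE_TABLE[toupper(codon)])
    ifelse(is.na(aa), "X", aa)
}

#' Map a genomic variant position into gene regions
#'
#' Converts a genomic position into spliced, strand-oriented relative
#' coordinates for every CDS/5'UTR/3'UTR region of every gene model that
#' contains it (overlapping genes give multiple entries; on the minus
#' strand positions count from the region's 5' end). Intergenic positions
#' return an empty table.
#'
#' @param chrom,pos genomic location (1-based).
#' @param gene_models an `rk_gene_models` list from [load_gene_models()].
#' @return `data.table` with gene_id, region (CDS/5UTR/3UTR), rel_pos
#'   (1-based within the spliced region).
#' @export
map_variant <- function(chrom, pos, gene_models) {
    out <- list()
    for (gm in gene_models) {
        if (gm$chrom != chrom) next
        for (reg in c("CDS", "5UTR", "3UTR")) {
            iv <- switch(reg, CDS = gm$cds_intervals,
                         `5UTR` = gm$utr5_intervals,
                         `3UTR` = gm$utr3_intervals)
            if (is.null(iv) || nrow(iv) == 0L) next
            rp <- rel_position(pos, iv, gm$strand)
            if (!is.na(rp))
                out[[length(out) + 1L]] <- data.table(
                    gene_id = gm$gene_id, region = reg, rel_pos = rp)
        }
    }
    if (!length(out))
        return(data.table(gene_id = character(), region = character(),
                          rel_pos = integer()))
    rbindlist(out)
}

# position within spliced strand-oriented region; intervals are sorted
# 5'->3' in strand orientation, 1-based inclusive
rel_position <- function(pos, iv, strand) {
    off <- 0L
    for (i in seq_len(nrow(iv))) {
        s <- iv$start[i]; e <- iv$end[i]
        if (pos >= s && pos <= e) {
            return(off + if (strand == "-") e - pos + 1L else pos - s + 1L)
        }
        off <- off + (e - s + 1L)
    }
    NA_integer_
}

#' Amino-acid consequence of a CDS SNP
#'
#' Translates the reference and alternate codons at the variant's codon
#' with the standard nuclear genetic code. Reports the substitution (or
#' nothing for a synonymous change), whether the alternate codon is a
#' premature stop, and whether the change destroys the terminal stop
#' codon. `ref_nt`/`alt_nt` must be given in the strand orientation of
#' the CDS (i.e. the coding strand).
#'
#' @param gene_model one gene model.
#' @param rel_pos 1-based position within the spliced CDS.
#' @param ref_nt,alt_nt reference and alternate nucleotides on the coding
#'   strand.
#' @return list with ref_aa, alt_aa, codon_index, aa_change (logical),
#'   premature_stop, lost_stop; or NULL when the model is flagged
#'   (partial CDS) and effects are suppressed.
#' @export
cds_effect <- function(gene_model, rel_pos, ref_nt, alt_nt) {
    if (!isTRUE(gene_model$ok)) return(NULL)
    cds <- gene_model$cds_seq
    n <- nchar(cds)
    assert_that(rel_pos >= 1L && rel_pos <= n,
                "rel_pos %d outside CDS of %s", rel_pos, gene_model$gene_id)
    have <- substr(cds, rel_pos, rel_pos)
    if (have != toupper(ref_nt))
        stopf("reference base %s disagrees with CDS base %s at %s:%d",
              ref_nt, have, gene_model$gene_id, rel_pos)
    ci <- ceiling(rel_pos / 3)
    c0 <- (ci - 1L) * 3L + 1L
    ref_codon <- substr(cds, c0, c0 + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, rel_pos - c0 + 1L, rel_pos - c0 + 1L) <- toupper(alt_nt)
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    n_codon <- n %/% 3L
    list(ref_aa = ref_aa, alt_aa = alt_aa, codon_index = ci,
         aa_change = ref_aa != alt_aa,
         premature_stop = alt_aa == "*" && ci < n_codon,
         lost_stop = ref_aa == "*" && alt_aa != "*" && ci == n_codon)
}

#' Frameshift flag for a CDS indel
#'
#' @param gene_model one gene model (unused beyond validation; kept for
#'   interface symmetry).
#' @param rel_pos 1-based position within the spliced CDS.
#' @param indel_len signed or unsigned length of the inserted/deleted
#'   sequence.
#' @return TRUE when the net length change is not a multiple of 3.
#' @export
indel_effect <- function(gene_model, rel_pos, indel_len) {
    abs(indel_len) %% 3L != 0L
}

#' Annotate called variants with transcript consequences
#'
#' Combines [map_variant()], [cds_effect()] and [indel_effect()] over a
#' variant table. Heterozygous variants are annotated on the alternate
#' allele ("at least one allele" semantics). For minus-strand genes the
#' alleles are complemented onto the coding strand before codon lookup.
#'
#' @param variants variant table from [call_variants()].
#' @param gene_models from [load_gene_models()].
#' @return `data.table` of effects: gene_id, region, rel_pos, chrom, pos,
#'   kind, ref_nt, alt_nt, zygosity, ref_aa, alt_aa, codon_index,
#'   aa_change, premature_stop, lost_stop, frameshift.
#' @export
annotate_variants <- function(variants, gene_models) {
    rows <- list()
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (v in seq_len(nrow(variants))) {
        hits <- map_variant(variants$chrom[v], variants$pos[v], gene_models)
        for (h in seq_len(nrow(hits))) {
            gm <- gene_models[[hits$gene_id[h]]]
            row <- data.table(
                gene_id = hits$gene_id[h], region = hits$region[h],
                rel_pos = hits$rel_pos[h], chrom = variants$chrom[v],
                pos = variants$pos[v], kind = variants$kind[v],
                ref_nt = variants$ref_allele[v],
                alt_nt = variants$alt_allele[v],
                zygosity = variants$zygosity[v],
                ref_aa = NA_character_, alt_aa = NA_character_,
                codon_index = NA_integer_, aa_change = FALSE,
                premature_stop = FALSE, lost_stop = FALSE,
                frameshift = FALSE)
            if (hits$region[h] == "CDS" && variants$kind[v] == "SNP" &&
                isTRUE(gm$ok)) {
                rn <- variants$ref_allele[v]; an <- variants$alt_allele[v]
                if (gm$strand == "-") {
                    rn <- comp[[rn]]; an <- comp[[an]]
                }
                eff <- cds_effect(gm, hits$rel_pos[h], rn, an)
                if (!is.null(eff))
                    row[, `:=`(ref_aa = eff$ref_aa, alt_aa = eff$alt_aa,
                               codon_index = eff$codon_index,
                               aa_change = eff$aa_change,
                               premature_stop = eff$premature_stop,
                               lost_stop = eff$lost_stop)]
            }
            if (hits$region[h] == "CDS" && variants$kind[v] %in%
                c("INS", "DEL")) {
                row[, frameshift := indel_effect(
                    gm, hits$rel_pos[h], nchar(variants$allele[v]))]
            }
            rows[[length(rows) + 1L]] <- row
        }
    }
    if (!length(rows))
        return(data.table(gene_id = character(), region = character(),
                          rel_pos = integer(), chrom = character(),
                          pos = integer(), kind = character(),
                          ref_nt = character(), alt_nt = character(),
                          zygosity = character(), ref_aa = character(),
                          alt_aa = character(), codon_index = integer(),
                          aa_change = logical(), premature_stop = logical(),
                          lost_stop = logical(), frameshift = logical()))
    rbindlist(rows)
}

#' Genes included in structural-variant intervals
#'
#' For every gene whose genomic span overlaps a GE interval: flag 1 when
#' the whole span (min to max over all its intervals) is contained in a
#' single interval, flag 0 for a partial overlap. Non-overlapping genes
#' are omitted.
#'
#' @param ge_intervals `data.table` with chrom, start, end (0-based
#'   half-open) and optionally call.
#' @param gene_models from [load_gene_models()].
#' @return `data.table`: gene_id, flag, chrom, sv_start, sv_end, call.
#' @export
gene_extractor <- function(ge_intervals, gene_models) {
    ge <- as.data.table(ge_intervals)
    if (!"call" %in% names(ge)) ge[, call := NA_character_]
    out <- list()
    for (gm in gene_models) {
        g0 <- gm$gene_start - 1L; g1 <- gm$gene_end   # 0-based half-open
        hit <- ge[chrom == gm$chrom & start < g1 & end > g0]
        if (nrow(hit) == 0L) next
        contained <- hit[start <= g0 & end >= g1]
        best <- if (nrow(contained)) contained[1L] else hit[1L]
        out[[length(out) + 1L]] <- data.table(
            gene_id = gm$gene_id,
            flag = if (nrow(contained)) 1L else 0L,
            chrom = gm$chrom, sv_start = best$start, sv_end = best$end,
            call = best$call)
    }
    if (!length(out))
        return(data.table(gene_id = character(), flag = integer(),
                          chrom = character(), sv_start = integer(),
                          sv_end = integer(), call = character()))
    rbindlist(out)
}

#' Windowed coverage and polymorphism tracks
#'
#' Mean depth plus SNP and indel frequencies (events per bp) in adjacent
#' (`step == window`) or sliding (`step < window`) windows.
#'
#' @param pileup `rk_pileup`.
#' @param variants variant table from [call_variants()].
#' @param window window width (bp).
#' @param step step between window starts (bp), at most `window`.
#' @return `data.table`: chrom, start, end (0-based half-open), coverage,
#'   n_snp, n_indel, snp_freq, indel_freq.
#' @export
sliding_tracks <- function(pileup, variants, window = 100000L,
                           step = window) {
    assert_that(step <= window && step >= 1L, "need 1 <= step <= window")
    out <- list()
    for (ch in names(pileup$chroms)) {
        d <- pileup$chroms[[ch]]$depth
        L <- length(d)
        starts <- seq(0L, max(L - 1L, 0L), by = step)
        starts <- starts[starts < L]
        cs <- cumsum(c(0, as.numeric(d)))
        ends <- pmin(starts + window, L)
        cov <- (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
        vs <- variants[variants$chrom == ch & variants$kind == "SNP", pos]
        vi <- variants[variants$chrom == ch &
                       variants$kind %in% c("INS", "DEL"), pos]
        n_snp <- vapply(seq_along(starts), function(i)
            sum(vs > starts[i] & vs <= ends[i]), integer(1))
        n_indel <- vapply(seq_along(starts), function(i)
            sum(vi > starts[i] & vi <= ends[i]), integer(1))
        out[[ch]] <- data.table(
            chrom = ch, start = starts, end = ends, coverage = cov,
            n_snp = n_snp, n_indel = n_indel,
            snp_freq = n_snp / (ends - starts),
            indel_freq = n_indel / (ends - starts))
    }
    rbindlist(out)[]
}
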