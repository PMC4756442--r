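# Variant calling from filtered pileup evidence: depth, base-quality,
# allele-frequency and binomial-test p-value thresholds, plus the
# per-chromosome summary statistics and the 1:1 alignment comparison.

#' Variant caller configuration
#'
#' @param min_reads minimum post-filter depth for a site to be considered.
#' @param min_baseq minimum base quality (Phred); lower-quality bases are
#'   discarded before counting.
#' @param min_freq minimum variant allele frequency.
#' @param max_p significance ceiling for the binomial test.
#' @param hom_freq allele frequency at or above which a call is homozygous.
#' @param error_rate assumed per-base sequencing error rate under the null.
#' @return an object of class `rk_caller_config`.
#' @export
caller_config <- function(min_reads = 8L, min_baseq = 15L, min_freq = 0.25,
                          max_p = 0.01, hom_freq = 0.75, error_rate = 0.01) {
    assert_that(min_freq > 0 && min_freq <= hom_freq && hom_freq <= 1,
                "need 0 < min_freq <= hom_freq <= 1")
    assert_that(max_p > 0 && max_p <= 1, "need 0 < max_p <= 1")
    structure(list(min_reads = as.integer(min_reads),
                   min_baseq = as.integer(min_baseq),
                   min_freq = min_freq, max_p = max_p,
                   hom_freq = hom_freq, error_rate = error_rate),
              class = "rk_caller_config")
}

#' One-sided binomial p-value for variant support
#'
#' The probability of observing at least `alt_count` non-reference reads
#' among `depth` reads when every mismatch is a sequencing error occurring
#' independently with probability `error_rate`:
#' P\[X >= alt_count | X ~ Binomial(depth, error_rate)\].
#' Monotone decreasing in `alt_count` at fixed depth.
#'
#' @param alt_count non-reference read count (vectorised).
#' @param depth total read count (vectorised).
#' @param error_rate assumed per-base error probability.
#' @return numeric vector of tail probabilities.
#' @export
variant_p_value <- function(alt_count, depth, error_rate = 0.01) {
    assert_that(all(depth >= 1), "depth must be >= 1")
    assert_that(all(alt_count >= 0 & alt_count <= depth),
                "need 0 <= alt_count <= depth")
    pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
}

#' Call SNPs and indels from a pileup
#'
#' A site becomes a variant iff its post-filter depth is at least
#' `min_reads`, the leading non-reference allele frequency is at least
#' `min_freq`, and the binomial tail probability is at most `max_p`.
#' Zygosity is homozygous when the frequency reaches `hom_freq`. Indel
#' evidence (insertions/deletions registered at their anchor position) is
#' filtered identically, using the count of indel-supporting reads against
#' the anchor depth. At multi-allelic sites the most frequent
#' non-reference allele is tested and the runner-up is reported in the
#' `note` field.
#'
#' The base-quality filter acts when the pileup is built: pass
#' `config$min_baseq` to [pileup_from_alignments()]. A pileup built with a
#' laxer threshold triggers a warning.
#'
#' @param pileup an `rk_pileup` with allele counts.
#' @param ref named character vector of reference sequences.
#' @param config a [caller_config()].
#' @return `data.table` of variants: chrom, pos (1-based), kind
#'   (SNP/INS/DEL), ref_allele, alt_allele, allele, depth, alt_count,
#'   freq, p_value, zygosity, note.
#' @export
call_variants <- function(pileup, ref, config = caller_config()) {
    assert_that(inherits(pileup, "rk_pileup"), "expected an rk_pileup")
    if (pileup$min_baseq < config$min_baseq)
        warning(sprintf(
            "pileup was built with min_baseq %d < caller's %d; %s",
            pileup$min_baseq, config$min_baseq,
            "low-quality bases were already counted"))
    out <- list()
    for (ch in names(pileup$chroms)) {
        pc <- pileup$chroms[[ch]]
        assert_that(!is.null(pc$counts),
                    "pileup for %s lacks allele counts", ch)
        cnt <- pc$counts
        tot <- pc$depth
        cand <- which(tot >= config$min_reads)
        if (length(cand)) {
            refc <- substring(ref[[ch]], cand, cand)
            ref_i <- match(refc, BASES)
            sub <- cnt[cand, , drop = FALSE]
            known <- !is.na(ref_i)
            alt_cnt_m <- sub
            alt_cnt_m[cbind(which(known), ref_i[known])] <- -1L
            alt_i <- max.col(alt_cnt_m, ties.method = "first")
            alt_n <- sub[cbind(seq_along(cand), alt_i)]
            freq <- alt_n / tot[cand]
            keep <- known & freq >= config$min_freq & alt_n > 0L
            if (any(keep)) {
                pv <- variant_p_value(alt_n[keep], tot[cand][keep],
                                      config$error_rate)
                keep2 <- which(keep)[pv <= config$max_p]
                pv <- pv[pv <= config$max_p]
                if (length(keep2)) {
                    # runner-up allele for the note field
                    run_m <- alt_cnt_m[keep2, , drop = FALSE]
                    run_m[cbind(seq_along(keep2), alt_i[keep2])] <- -1L
                    run_i <- max.col(run_m, ties.method = "first")
                    run_n <- sub[cbind(keep2, run_i)]
                    out[[paste0(ch, ".snp")]] <- data.table(
                        chrom = ch, pos = cand[keep2], kind = "SNP",
                        ref_allele = refc[keep2],
                        alt_allele = BASES[alt_i[keep2]],
                        allele = BASES[alt_i[keep2]],
                        depth = tot[cand][keep2], alt_count = alt_n[keep2],
                        freq = freq[keep2], p_value = pv,
                        zygosity = ifelse(freq[keep2] >= config$hom_freq,
                                          "hom", "het"),
                        note = ifelse(run_n > 0L,
                                      paste0("multiallelic:",
                                             BASES[run_i], ":", run_n), ""))
                }
            }
        }
        out[[paste0(ch, ".ind")]] <- call_indels_chrom(pc, ref[[ch]], ch,
                                                       config)
    }
    res <- rbindlist(out, use.names = TRUE)
    if (nrow(res) == 0L) return(empty_variants())
    setorder(res, chrom, pos)
    res[]
}

empty_variants <- function() {
    data.table(chrom = character(), pos = integer(), kind = character(),
               ref_allele = character(), alt_allele = character(),
               allele = character(), depth = integer(),
               alt_count = integer(), freq = numeric(), p_value = numeric(),
               zygosity = character(), note = character())
}

call_indels_chrom <- function(pc, refseq, ch, config) {
    ev <- rbind(
        if (nrow(pc$ins)) pc$ins[, .(pos, kind = "INS", allele, count)]
        else NULL,
        if (nrow(pc$del)) pc$del[, .(pos, kind = "DEL",
                                     allele = substring(refseq, pos + 1L,
                                                        pos + len),
                                     count)]
        else NULL)
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    # keep the best-supported allele per anchor position
    setorder(ev, pos, -count)
    ev <- ev[, .SD[1L], by = .(pos, kind)]
    ev[, depth := pc$depth[pos]]
    ev <- ev[depth >= config$min_reads]
    if (nrow(ev) == 0L) return(NULL)
    ev[, freq := pmin(count / depth, 1)]
    ev <- ev[freq >= config$min_freq]
    if (nrow(ev) == 0L) return(NULL)
    ev[, p_value := variant_p_value(pmin(count, depth), depth,
                                    config$error_rate)]
    ev <- ev[p_value <= config$max_p]
    if (nrow(ev) == 0L) return(NULL)
    ev[, .(chrom = ch, pos, kind,
           ref_allele = ifelse(kind == "DEL", allele, ""),
           alt_allele = ifelse(kind == "INS", allele, ""),
           allele, depth, alt_count = count, freq, p_value,
           zygosity = ifelse(freq >= config$hom_freq, "hom", "het"),
           note = "")]
}

#' Summary statistics of a pileup
#'
#' Per chromosome and genome-wide: percentage of non-covered positions,
#' SNP and indel frequencies per covered bp, mean depth over covered G|C
#' versus A|T reference positions, and the base composition (reference
#' and consensus) at SNP-flagged sites.
#'
#' @param records pileup records table (covered positions only), as from
#'   [pileup_records()] or [read_pileup_folder()].
#' @param ref named character vector of reference sequences; every
#'   chromosome present in `records` must exist here.
#' @return list with `per_chrom` (`data.table`) and `genome` (one-row
#'   `data.table`), plus `polymorphic_base_freqs` tables.
#' @export
summarize_pileup <- function(records, ref) {
    records <- as.data.table(records)
    miss <- setdiff(unique(records$chrom), names(ref))
    assert_that(length(miss) == 0L,
                "chromosome %s absent from reference", miss[1L])
    per <- records[, {
        L <- nchar(ref[[.BY$chrom]])
        gc <- ref_base %in% c("G", "C")
        .(length_bp = L,
          covered = .N,
          pct_noncovered = 100 * (1 - .N / L),
          snp_freq = sum(snp_flag) / .N,
          indel_freq = sum(indel_flag) / .N,
          gc_cov = if (any(gc)) mean(depth[gc]) else NA_real_,
          at_cov = if (any(!gc)) mean(depth[!gc]) else NA_real_)
    }, by = chrom]
    tot_len <- sum(nchar(ref[unique(records$chrom)]))
    gcg <- records$ref_base %in% c("G", "C")
    genome <- data.table(
        length_bp = tot_len, covered = nrow(records),
        pct_noncovered = 100 * (1 - nrow(records) / tot_len),
        snp_freq = sum(records$snp_flag) / nrow(records),
        indel_freq = sum(records$indel_flag) / nrow(records),
        gc_cov = if (any(gcg)) mean(records$depth[gcg]) else NA_real_,
        at_cov = if (any(!gcg)) mean(records$depth[!gcg]) else NA_real_)
    poly <- records[snp_flag == TRUE]
    freqs <- function(x) {
        t <- table(factor(x, levels = c(BASES, setdiff(unique(x), BASES))))
        if (sum(t) == 0) return(t)
        t / sum(t)
    }
    list(per_chrom = per[], genome = genome,
         polymorphic_base_freqs = list(ref = freqs(poly$ref_base),
                                       consensus = freqs(poly$tg_base)))
}

#' Compare two variant sets from the same reference
#'
#' Variants are identical when chrom, pos, kind and allele all match.
#' The three returned partitions are disjoint and exhaustive.
#'
#' @param variants_a,variants_b variant tables from [call_variants()].
#' @return list with `common`, `unique_a`, `unique_b`.
#' @export
compare_pileups <- function(variants_a, variants_b) {
    a <- as.data.table(variants_a); b <- as.data.table(variants_b)
    key_of <- function(x) paste(x$chrom, x$pos, x$kind, x$allele, sep = "\r")
    ka <- key_of(a); kb <- key_of(b)
    list(common = a[ka %in% kb],
         unique_a = a[!ka %in% kb],
         unique_b = b[!kb %in% ka])
}
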