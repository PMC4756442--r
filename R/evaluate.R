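# Evaluation against a simulation truth set: PPV and sensitivity for
# point variants, base-level PPV/sensitivity for structural variants,
# breakpoint-error distributions and detected-vs-expected copy-number
# regression.

#' Evaluate called point variants against the truth set
#'
#' A SNP call is correct iff (chrom, pos, alt allele) matches a truth SNP
#' exactly; an indel call must match (chrom, kind, allele) with a +/-1 bp
#' positional tolerance (left/right-alignment ambiguity). PPV is the
#' fraction of calls that are correct; sensitivity the fraction of truth
#' variants recovered.
#'
#' @param calls variant table ([call_variants()] layout).
#' @param truth truth object (or a list with `snps` and `indels`).
#' @param kind evaluate "SNP", "indel" or "all".
#' @return list: ppv, sensitivity, n_called, n_correct, n_truth.
#' @export
eval_point_variants <- function(calls, truth, kind = c("all", "SNP",
                                                       "indel")) {
    kind <- match.arg(kind)
    calls <- as.data.table(calls)
    tr_snp <- as.data.table(truth$snps)
    tr_ind <- as.data.table(truth$indels)
    if (kind == "SNP") {
        calls <- calls[calls$kind == "SNP"]; tr_ind <- tr_ind[0]
    }
    if (kind == "indel") {
        calls <- calls[calls$kind %in% c("INS", "DEL")]; tr_snp <- tr_snp[0]
    }
    csnp <- calls[calls$kind == "SNP"]
    cind <- calls[calls$kind %in% c("INS", "DEL")]
    snp_key <- function(x, alt) paste(x$chrom, x$pos, alt, sep = "\r")
    cor_snp <- snp_key(csnp, csnp$alt_allele) %in% snp_key(tr_snp, tr_snp$alt)
    ind_match <- function(a, b) {
        # +/- 1 bp tolerance on the anchor position
        keys_b <- c(paste(b$chrom, b$pos, b$kind, b$allele, sep = "\r"),
                    paste(b$chrom, b$pos - 1L, b$kind, b$allele, sep = "\r"),
                    paste(b$chrom, b$pos + 1L, b$kind, b$allele, sep = "\r"))
        paste(a$chrom, a$pos, a$kind, a$allele, sep = "\r") %in% keys_b
    }
    cor_ind <- ind_match(cind, tr_ind)
    n_called <- nrow(csnp) + nrow(cind)
    n_correct <- sum(cor_snp) + sum(cor_ind)
    # sensitivity counts truth entries recovered (deduplicated)
    rec_snp <- snp_key(tr_snp, tr_snp$alt) %in% snp_key(csnp, csnp$alt_allele)
    rec_ind <- ind_match(tr_ind, cind)
    n_truth <- nrow(tr_snp) + nrow(tr_ind)
    list(ppv = if (n_called > 0) n_correct / n_called else NA_real_,
         sensitivity = if (n_truth > 0)
             (sum(rec_snp) + sum(rec_ind)) / n_truth else NA_real_,
         n_called = n_called, n_correct = n_correct, n_truth = n_truth)
}

#' Base-level PPV and sensitivity of structural-variant calls
#'
#' Intervals within each set are unioned first; PPV is the fraction of
#' called bases falling inside genuine variant bases, sensitivity the
#' fraction of genuine variant bases covered by calls. Symmetric under
#' swapping the two sets (with ppv and sensitivity exchanged).
#'
#' @param called,truth `data.table`s with chrom, start, end (0-based
#'   half-open).
#' @return list: ppv, sensitivity, called_bases, truth_bases,
#'   intersect_bases.
#' @export
eval_sv_bases <- function(called, truth) {
    rl <- function(x) {
        x <- as.data.table(x)
        if (nrow(x) == 0L) return(NULL)
        lapply(split(x, x$chrom), function(s)
            IRanges::reduce(IRanges::IRanges(s$start + 1L, s$end)))
    }
    a <- rl(called); b <- rl(truth)
    width_of <- function(l) if (is.null(l)) 0 else
        sum(vapply(l, function(r) sum(IRanges::width(r)), numeric(1)))
    inter <- 0
    for (ch in intersect(names(a), names(b)))
        inter <- inter + sum(IRanges::width(
            IRanges::intersect(a[[ch]], b[[ch]])))
    ca <- width_of(a); tb <- width_of(b)
    list(ppv = if (ca > 0) inter / ca else NA_real_,
         sensitivity = if (tb > 0) inter / tb else NA_real_,
         called_bases = ca, truth_bases = tb, intersect_bases = inter)
}

#' Breakpoint-error distribution of deletion calls
#'
#' Each call is matched to the truth deletion with which it shares at
#' least 50 % reciprocal overlap (the best such partner); the signed
#' start and end differences (called - true) are pooled and summarised by
#' the median and the 10th/90th percentiles. Unmatched calls are
#' excluded here (they are false positives in the base-level metrics).
#'
#' @param calls deletion calls with chrom, start, end (0-based half-open).
#' @param truth truth deletions (chrom, start, end).
#' @param min_reciprocal minimum reciprocal overlap for matching.
#' @return list: errors (signed bp), median, q10, q90, n_matched.
#' @export
breakpoint_error_stats <- function(calls, truth, min_reciprocal = 0.5) {
    calls <- as.data.table(calls); truth <- as.data.table(truth)
    errors <- integer(0); n_matched <- 0L
    for (i in seq_len(nrow(calls))) {
        tr <- truth[chrom == calls$chrom[i]]
        if (nrow(tr) == 0L) next
        ov <- pmin(tr$end, calls$end[i]) - pmax(tr$start, calls$start[i])
        rec <- pmin(ov / (tr$end - tr$start),
                    ov / (calls$end[i] - calls$start[i]))
        j <- which.max(rec)
        if (rec[j] >= min_reciprocal) {
            n_matched <- n_matched + 1L
            errors <- c(errors, calls$start[i] - tr$start[j],
                        calls$end[i] - tr$end[j])
        }
    }
    if (!length(errors))
        return(list(errors = integer(0), median = NA_real_, q10 = NA_real_,
                    q90 = NA_real_, n_matched = 0L))
    list(errors = errors, median = median(errors),
         q10 = unname(quantile(errors, 0.10, type = 1)),
         q90 = unname(quantile(errors, 0.90, type = 1)),
         n_matched = n_matched)
}

#' Ordinary-least-squares slope of detected on expected copy number
#'
#' @param detected,expected paired numeric vectors (n >= 2).
#' @return the OLS slope.
#' @export
copy_number_slope <- function(detected, expected) {
    assert_that(length(detected) == length(expected) &&
                length(detected) >= 2L, "need >= 2 paired values")
    assert_that(stats::var(expected) > 0,
                "expected copy numbers have zero variance")
    unname(coef(lm(detected ~ expected))[2L])
}
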