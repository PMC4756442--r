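# Depth-of-coverage CNV and PAV detection: windowed target/reference
# coverage ratios, changepoint segmentation into rho-homogeneous runs,
# normalization, explicit copy-number loss/gain inequalities, smoothing
# and zero-coverage (PAV) reporting.

#' Average coverage over informative positions
#'
#' The genome-wide mean depth computed over positions with depth > 0
#' only, for either a pileup object, a records table or a pileup folder.
#'
#' @param pileup `rk_pileup`, pileup records `data.table`, or the path of
#'   a pileup folder.
#' @return mean depth (scalar).
#' @export
average_coverage <- function(pileup) {
    if (is.character(pileup)) pileup <- read_pileup_folder(pileup)
    if (inherits(pileup, "rk_pileup")) {
        tot <- 0; n <- 0
        for (pc in pileup$chroms) {
            d <- pc$depth[pc$depth > 0L]
            tot <- tot + sum(as.numeric(d)); n <- n + length(d)
        }
    } else {
        d <- pileup$depth[pileup$depth > 0L]
        tot <- sum(as.numeric(d)); n <- length(d)
    }
    assert_that(n > 0, "no covered position in pileup")
    tot / n
}

#' Genome-wide coverage profile of the target/reference pair
#'
#' @param tg_pileup,rg_pileup target- and reference-alignment pileups.
#' @return list with `tg_av_cov` and `rg_av_cov`.
#' @export
genome_profile <- function(tg_pileup, rg_pileup) {
    list(tg_av_cov = average_coverage(tg_pileup),
         rg_av_cov = average_coverage(rg_pileup))
}

#' Windowed coverage ratio rho along the chromosomes
#'
#' Adjacent non-overlapping windows of `window_size` bp tile each
#' chromosome; per-window mean depths are computed over all positions in
#' the window (uncovered positions count as depth 0). rho is the ratio of
#' the target to the reference window coverage, undefined (NA) when the
#' reference window has zero coverage. Windows with target coverage 0 but
#' reference coverage > 0 are flagged as zero-coverage seeds (potential
#' PAVs).
#'
#' @param rg_pileup,tg_pileup reference and target pileups (`rk_pileup`);
#'   both must cover the same chromosomes.
#' @param window_size window width in bp (default 50).
#' @return `data.table` with columns chrom, win, start, end (0-based
#'   half-open), rg_cov, tg_cov, rho, zero_cov.
#' @export
window_coverages <- function(rg_pileup, tg_pileup, window_size = 50L) {
    assert_that(window_size >= 1L, "window_size must be >= 1")
    out <- list()
    for (ch in names(rg_pileup$chroms)) {
        rg <- rg_pileup$chroms[[ch]]$depth
        tg <- tg_pileup$chroms[[ch]]$depth %||% integer(length(rg))
        L <- length(rg)
        n <- ceiling(L / window_size)
        wmean <- function(d) {
            pad <- n * window_size - L
            m <- matrix(c(as.numeric(d), numeric(pad)), nrow = window_size)
            s <- colSums(m)
            wd <- rep(window_size, n)
            if (pad > 0) wd[n] <- window_size - pad
            s / wd
        }
        rg_w <- wmean(rg); tg_w <- wmean(tg)
        start <- (seq_len(n) - 1L) * window_size
        out[[ch]] <- data.table(
            chrom = ch, win = seq_len(n), start = start,
            end = pmin(start + window_size, L),
            rg_cov = rg_w, tg_cov = tg_w,
            rho = ifelse(rg_w > 0, tg_w / rg_w, NA_real_),
            zero_cov = tg_w == 0 & rg_w > 0)
    }
    rbindlist(out)[]
}

#' Segment the rho series into homogeneous runs
#'
#' Recursive binary changepoint search on the windows with defined rho: at
#' each step the split maximising the pooled-variance two-sample t
#' statistic is accepted when its permutation p-value is below `alpha`
#' (`nperm` label permutations). Segments shorter than `min_windows` are
#' then merged into the neighbour whose mean rho is closer. Windows with
#' undefined rho (reference coverage 0) are excluded; the output tiles the
#' defined-rho territory.
#'
#' @param windows window table from [window_coverages()].
#' @param min_windows minimum number of windows per segment (default 4).
#' @param nperm number of permutations per split test.
#' @param alpha significance level for accepting a split.
#' @return `data.table` of segments: chrom, start, end (0-based
#'   half-open), n_windows, rho_seg, tg_seg_cov, rg_seg_cov.
#' @export
segment_rho <- function(windows, min_windows = 4L, nperm = 1000L,
                        alpha = 0.01) {
    out <- list()
    for (ch in unique(windows$chrom)) {
        w <- windows[chrom == ch & !is.na(rho)]
        if (nrow(w) == 0L) next
        x_nat <- w$rho
        # The changepoint search runs on the winsorised log2 ratio: the
        # raw ratio is heavy-tailed (low-coverage windows of either
        # genome), which the log transform symmetrises and clamping at
        # median +- 3 MAD tames -- isolated outlier windows stop driving
        # spurious arcs, while multi-window events keep a clear plateau.
        # Reported segment statistics stay on the natural scale.
        x <- log2(pmax(x_nat, 0.05))
        med <- stats::median(x); madv <- stats::mad(x)
        if (madv > 0) x <- pmin(pmax(x, med - 3 * madv), med + 3 * madv)
        bounds <- cbs_recurse(x, nperm, alpha, ess_scale_of(x))
        segs <- data.table(lo = bounds$lo, hi = bounds$hi)
        segs <- refine_boundaries(segs, x)
        segs <- merge_short_segments(segs, x, min_windows)
        out[[ch]] <- segs[, .(
            chrom = ch,
            start = w$start[lo], end = w$end[hi],
            n_windows = hi - lo + 1L,
            rho_seg = vapply(seq_len(.N),
                             function(i) mean(x_nat[lo[i]:hi[i]]),
                             numeric(1)),
            tg_seg_cov = vapply(seq_len(.N),
                                function(i) mean(w$tg_cov[lo[i]:hi[i]]),
                                numeric(1)),
            rg_seg_cov = vapply(seq_len(.N),
                                function(i) mean(w$rg_cov[lo[i]:hi[i]]),
                                numeric(1)))]
    }
    assert_that(length(out) > 0L, "no window with defined rho")
    rbindlist(out)[]
}

# Effective-sample-size deflation factor for the split statistic under
# serially correlated window noise. Reads longer than the window couple
# *adjacent* windows only (a read cannot span two window boundaries),
# so the noise is MA(1): lag-1 correlation r1, zero beyond. Then
# var(x_i - x_{i-1}) = 2 s^2 (1 - r1) and var(x_i - x_{i-2}) = 2 s^2,
# giving r1 = 1 - (q1/q2)^2 from the lower quartiles of the absolute
# differences (quantiles are insensitive to the sparse outlier
# differences at true changepoints). The variance of a window-mean is
# inflated by ~ (1 + 2 r1), so the observed max-t is multiplied by
# sqrt(1 / (1 + 2 r1)) before comparison with the iid permutation null.
ess_scale_of <- function(x) {
    n <- length(x)
    if (n < 50L) return(1)
    q1 <- stats::quantile(abs(diff(x)), 0.25, names = FALSE)
    q2 <- stats::quantile(abs(diff(x, lag = 2L)), 0.25, names = FALSE)
    if (q1 <= 0 || q2 <= 0) return(1)
    r1 <- min(max(1 - (q1 / q2)^2, 0), 0.45)
    sqrt(1 / (1 + 2 * r1))
}

# recursive binary segmentation; returns segment index bounds (1-based,
# inclusive) into the series
cbs_recurse <- function(x, nperm, alpha, ess = 1) {
    n <- length(x)
    if (n < 4L) return(list(lo = 1L, hi = n))
    stack <- list(c(1L, n))
    lo <- integer(0); hi <- integer(0)
    while (length(stack)) {
        seg <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- seg[1L]; b <- seg[2L]
        res <- cbs_scan_cpp(x[a:b], 2L, nperm, alpha, ess)
        if (res$split > 0L) {
            stack[[length(stack) + 1L]] <- c(a, a + res$split - 1L)
            stack[[length(stack) + 1L]] <- c(a + res$split, b)
        } else {
            lo <- c(lo, a); hi <- c(hi, b)
        }
    }
    ord <- order(lo)
    list(lo = lo[ord], hi = hi[ord])
}

# polish each internal boundary to the exact SSE-minimising split of the
# two adjacent segments (the recursive scan can land a few windows off
# when neighbouring segments have unequal variance)
refine_boundaries <- function(segs, x) {
    if (nrow(segs) <= 1L) return(segs)
    cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
    sse2 <- function(a, b, m) {
        # split after index m: [a..m] vs [m+1..b]
        n1 <- m - a + 1; n2 <- b - m
        s1 <- cs[m + 1L] - cs[a]; s2 <- cs[b + 1L] - cs[m + 1L]
        (cs2[m + 1L] - cs2[a]) - s1^2 / n1 +
            (cs2[b + 1L] - cs2[m + 1L]) - s2^2 / n2
    }
    for (i in seq_len(nrow(segs) - 1L)) {
        a <- segs$lo[i]; b <- segs$hi[i + 1L]
        cur <- segs$hi[i]
        mids <- max(a, cur - 50L):min(b - 1L, cur + 50L)
        best <- mids[which.min(vapply(mids, function(m) sse2(a, b, m),
                                      numeric(1)))]
        segs$hi[i] <- best
        segs$lo[i + 1L] <- best + 1L
    }
    segs
}

merge_short_segments <- function(segs, x, min_windows) {
    repeat {
        len <- segs$hi - segs$lo + 1L
        if (nrow(segs) <= 1L || all(len >= min_windows)) break
        i <- which.min(ifelse(len < min_windows, len, NA_integer_))
        mu <- function(j) mean(x[segs$lo[j]:segs$hi[j]])
        mi <- mu(i)
        cand <- c(if (i > 1L) i - 1L, if (i < nrow(segs)) i + 1L)
        j <- cand[which.min(vapply(cand, function(j) abs(mu(j) - mi),
                                   numeric(1)))]
        a <- min(i, j); b <- max(i, j)
        segs$hi[a] <- segs$hi[b]
        segs <- segs[-b]
    }
    segs
}

#' Merge adjacent segments with similar rho (smoothing)
#'
#' Adjacent segments whose mean rho values differ by less than
#' `sd_mult` pooled within-segment window-rho standard deviations are
#' merged; the pass repeats until the segmentation is stable. Both the
#' smoothed and unsmoothed segment lists are normally carried downstream,
#' and loss/gain calling is run on each.
#'
#' @param segments segment table from [segment_rho()].
#' @param windows the window table the segments were computed from.
#' @param sd_mult merge threshold in pooled-SD units (default 3).
#' @return smoothed segment `data.table` in the same layout.
#' @export
smooth_segments <- function(segments, windows, sd_mult = 3) {
    segs <- as.data.table(segments)
    wd <- windows[!is.na(rho)]
    # pooled within-segment window-rho SD
    res <- numeric(0)
    for (i in seq_len(nrow(segs))) {
        r <- wd[chrom == segs$chrom[i] & start >= segs$start[i] &
                end <= segs$end[i], rho]
        res <- c(res, r - mean(r))
    }
    s <- if (length(res) > 1L) sd(res) else 0
    thr <- max(sd_mult * s, 1e-9)   # identical segments merge even noise-free
    repeat {
        if (nrow(segs) <= 1L) break
        adj <- which(segs$chrom[-1L] == segs$chrom[-nrow(segs)] &
                     abs(segs$rho_seg[-1L] - segs$rho_seg[-nrow(segs)]) <
                         thr)
        if (!length(adj)) break
        i <- adj[1L]                       # merge i and i+1
        n1 <- segs$n_windows[i]; n2 <- segs$n_windows[i + 1L]
        wmean <- function(a, b) (a * n1 + b * n2) / (n1 + n2)
        segs$end[i] <- segs$end[i + 1L]
        segs$rho_seg[i] <- wmean(segs$rho_seg[i], segs$rho_seg[i + 1L])
        segs$tg_seg_cov[i] <- wmean(segs$tg_seg_cov[i],
                                    segs$tg_seg_cov[i + 1L])
        segs$rg_seg_cov[i] <- wmean(segs$rg_seg_cov[i],
                                    segs$rg_seg_cov[i + 1L])
        segs$n_windows[i] <- n1 + n2
        segs <- segs[-(i + 1L)]
    }
    segs[]
}

#' Classify segments as loss, gain, neutral or zero coverage
#'
#' Computes, per segment j, the normalized ratio
#' rho_segNorm(j) = rho_seg(j) * RG_avCov / TG_avCov and the copy numbers
#' TG_segCopy(j) = TG_segCov(j)/TG_avCov and
#' RG_segCopy(j) = RG_segCov(j)/RG_avCov. A segment is called lost when
#' rho_segNorm(j) <= 1 - 0.5/RG_segCopy(j) and gained when
#' rho_segNorm(j) >= 1 + 0.5/RG_segCopy(j) (the half-copy margin reflects
#' the loss or gain of a single homologous copy in a diploid). Segments
#' with target coverage 0 are reported as zero_coverage; segments with
#' reference copy number 0 are deferred to the PAV/reference-gap logic
#' (call NA).
#'
#' @param segments segment table from [segment_rho()] or
#'   [smooth_segments()].
#' @param profile coverage profile from [genome_profile()].
#' @return the segment table with added columns rho_seg_norm, tg_copy,
#'   rg_copy, tg_copy_rounded, call.
#' @export
call_segments <- function(segments, profile) {
    assert_that(profile$tg_av_cov > 0 && profile$rg_av_cov > 0,
                "average coverages must be positive")
    segs <- as.data.table(segments)
    segs[, rho_seg_norm := rho_seg * profile$rg_av_cov / profile$tg_av_cov]
    segs[, tg_copy := tg_seg_cov / profile$tg_av_cov]
    segs[, rg_copy := rg_seg_cov / profile$rg_av_cov]
    segs[, tg_copy_rounded := round(2 * tg_copy) / 2]
    segs[, call := "neutral"]
    segs[rg_copy > 0 & rho_seg_norm <= 1 - 0.5 / rg_copy, call := "loss"]
    segs[rg_copy > 0 & rho_seg_norm >= 1 + 0.5 / rg_copy, call := "gain"]
    segs[tg_seg_cov == 0, call := "zero_coverage"]
    segs[rg_copy == 0, call := NA_character_]
    segs[]
}

#' Assemble the CNV report: size-filtered calls and PAV intervals
#'
#' Loss/gain segments shorter than `min_sv_size` are suppressed. Runs of
#' adjacent zero-coverage windows are merged into PAV intervals. The
#' combined interval list (chrom, start, end, call) is the GE file
#' consumed by [gene_extractor()].
#'
#' @param segments called segment table from [call_segments()] (or a
#'   rbind of the unsmoothed and smoothed calls; duplicated intervals are
#'   collapsed).
#' @param windows window table (supplies the zero-coverage seeds).
#' @param min_sv_size minimum loss/gain size in bp.
#' @return list with `cnv` (loss/gain calls), `pav` (zero-coverage
#'   intervals) and `ge` (their union with a call column).
#' @export
report_cnv <- function(segments, windows, min_sv_size = 500L) {
    segs <- as.data.table(segments)
    cnv <- unique(segs[call %in% c("loss", "gain") &
                       (end - start) >= min_sv_size],
                  by = c("chrom", "start", "end", "call"))
    zw <- windows[zero_cov == TRUE][order(chrom, start)]
    pav <- if (nrow(zw)) {
        zw[, grp := cumsum(c(1L, (chrom[-1L] != chrom[-.N]) |
                                  (start[-1L] != end[-.N])))]
        zw[, .(start = min(start), end = max(end)), by = .(chrom, grp)][
            , .(chrom, start, end, call = "zero_coverage")]
    } else {
        data.table(chrom = character(), start = integer(),
                   end = integer(), call = character())
    }
    ge <- rbind(cnv[, .(chrom, start, end, call)], pav)
    setorder(ge, chrom, start)
    list(cnv = cnv[], pav = pav[], ge = ge[])
}

#' Run the whole coverage analysis
#'
#' Windowing, segmentation, smoothing, loss/gain calling on both the
#' unsmoothed and smoothed segmentations, size filtering and PAV
#' reporting in one call.
#'
#' @param tg_pileup,rg_pileup target and reference pileups.
#' @param window_size window width in bp.
#' @param min_windows minimum windows per segment.
#' @param min_sv_size minimum reported loss/gain size in bp.
#' @param nperm,alpha split-test parameters (see [segment_rho()]).
#' @param sd_mult smoothing threshold (see [smooth_segments()]).
#' @return list with `windows`, `profile`, `segments` (unsmoothed,
#'   called), `segments_smoothed`, and the [report_cnv()] outputs `cnv`,
#'   `pav`, `ge`.
#' @export
coverage_analysis <- function(tg_pileup, rg_pileup, window_size = 50L,
                              min_windows = 4L, min_sv_size = 500L,
                              nperm = 1000L, alpha = 0.01, sd_mult = 3) {
    profile <- genome_profile(tg_pileup, rg_pileup)
    windows <- window_coverages(rg_pileup, tg_pileup, window_size)
    segs <- segment_rho(windows, min_windows, nperm, alpha)
    segs_sm <- smooth_segments(segs, windows, sd_mult)
    called <- call_segments(segs, profile)
    called_sm <- call_segments(segs_sm, profile)
    rep <- report_cnv(rbind(called, called_sm), windows, min_sv_size)
    list(windows = windows, profile = profile, segments = called,
         segments_smoothed = called_sm, cnv = rep$cnv, pav = rep$pav,
         ge = rep$ge)
}
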