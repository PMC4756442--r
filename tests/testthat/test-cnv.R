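# helper: depth-only pileup from a vector (one chromosome)
depth_pileup <- function(depth, chrom = "c1") {
    structure(list(chroms = stats::setNames(list(list(
        depth = as.integer(depth), counts = NULL,
        ins = data.table(pos = integer(), allele = character(),
                         count = integer()),
        del = data.table(pos = integer(), len = integer(),
                         count = integer()))), chrom),
        min_baseq = 0L), class = "rk_pileup")
}

test_that("average coverage uses informative positions only", {
    expect_equal(average_coverage(depth_pileup(c(0, 0, 10, 10))), 10)
    expect_equal(average_coverage(depth_pileup(rep(7, 50))), 7)
    expect_equal(average_coverage(depth_pileup(1:100)), 50.5)
    expect_error(average_coverage(depth_pileup(rep(0, 5))), "covered")
})

test_that("window coverages compute rho with division guards", {
    tg <- depth_pileup(rep(20L, 200)); rg <- depth_pileup(rep(10L, 200))
    w <- window_coverages(rg, tg, 50L)
    expect_equal(nrow(w), 4L)
    expect_true(all(w$rho == 2))
    expect_false(any(w$zero_cov))

    tg0 <- depth_pileup(c(rep(0L, 50), rep(12L, 150)))
    rg12 <- depth_pileup(rep(12L, 200))
    w2 <- window_coverages(rg12, tg0, 50L)
    expect_true(w2$zero_cov[1])
    expect_equal(w2$rho[1], 0)

    rg0 <- depth_pileup(c(rep(0L, 50), rep(10L, 150)))
    w3 <- window_coverages(rg0, tg, 50L)
    expect_true(is.na(w3$rho[1]))          # excluded from segmentation
    # uncovered tail positions dilute the window mean
    tgp <- depth_pileup(c(rep(10L, 175), rep(0L, 25)))
    w4 <- window_coverages(rg12, tgp, 50L)
    expect_equal(w4$tg_cov[4], 10 * 25 / 50)
})

test_that("segmentation recovers changepoints like the SSE oracle", {
    mkwin <- function(rho) data.table(
        chrom = "c1", win = seq_along(rho),
        start = (seq_along(rho) - 1L) * 50L, end = seq_along(rho) * 50L,
        rg_cov = 10, tg_cov = 10 * rho, rho = rho, zero_cov = FALSE)

    # constant series: one segment
    s <- segment_rho(mkwin(rep(1, 30)), nperm = 200L)
    expect_equal(nrow(s), 1L)
    expect_equal(s$n_windows, 30L)

    # clean step: boundary matches the exhaustive SSE-minimising oracle
    x <- c(rep(1, 4), rep(2, 4))
    s2 <- segment_rho(mkwin(x), min_windows = 2L, nperm = 500L)
    orc <- sse_oracle_segments(x, 1L)
    expect_equal(s2$n_windows, orc$hi - orc$lo + 1L)
    expect_equal(s2$start / 50L + 1L, orc$lo)

    # noisy series with <= 2 changepoints, <= 30 windows
    set.seed(91)
    for (rep_i in 1:4) {
        n <- sample(18:30, 1)
        cp <- sort(sample(5:(n - 5), 2))
        while (diff(cp) < 4) cp <- sort(sample(5:(n - 5), 2))
        mu <- c(1, 2.5, 0.6)
        x <- numeric(n)
        x[1:cp[1]] <- mu[1]
        x[(cp[1] + 1):cp[2]] <- mu[2]
        x[(cp[2] + 1):n] <- mu[3]
        x <- x + rnorm(n, 0, 0.04)
        s3 <- segment_rho(mkwin(x), min_windows = 2L, nperm = 500L)
        orc <- sse_oracle_segments(x, 2L)
        expect_equal(s3$start / 50L + 1L, orc$lo)
        expect_equal(s3$end / 50L, orc$hi)
    }
})

test_that("pure-noise series rarely splits at alpha 0.01", {
    mkwin <- function(rho) data.table(
        chrom = "c1", win = seq_along(rho),
        start = (seq_along(rho) - 1L) * 50L, end = seq_along(rho) * 50L,
        rg_cov = 10, tg_cov = 10 * rho, rho = rho, zero_cov = FALSE)
    set.seed(17)
    one_seg <- 0L
    for (i in 1:20) {
        x <- rnorm(200, 1, 0.05)
        s <- segment_rho(mkwin(x), nperm = 500L)
        if (nrow(s) == 1L) one_seg <- one_seg + 1L
    }
    expect_gte(one_seg, 18L)
})

test_that("short segments merge into the closer neighbour", {
    mkwin <- function(rho) data.table(
        chrom = "c1", win = seq_along(rho),
        start = (seq_along(rho) - 1L) * 50L, end = seq_along(rho) * 50L,
        rg_cov = 10, tg_cov = 10 * rho, rho = rho, zero_cov = FALSE)
    # a clear 2-window spike cannot stand alone with min_windows = 4
    x <- c(rep(1, 10), rep(5, 2), rep(1.2, 10))
    s <- segment_rho(mkwin(x), min_windows = 4L, nperm = 500L)
    expect_true(all(s$n_windows >= 4L))
})

test_that("smoothing merges similar neighbours to a fixed point", {
    seg <- function(start, end, n, rho) data.table(
        chrom = "c1", start = start, end = end, n_windows = n,
        rho_seg = rho, tg_seg_cov = 10 * rho, rg_seg_cov = 10)
    set.seed(44)
    rho_w <- c(rep(1, 10), rep(1.02, 10), rep(1.01, 10)) + rnorm(30, 0, 0.05)
    win <- data.table(chrom = "c1", win = 1:30, start = (0:29) * 50L,
                      end = (1:30) * 50L, rg_cov = 10,
                      tg_cov = 10 * rho_w, rho = rho_w, zero_cov = FALSE)
    segs <- rbind(seg(0L, 500L, 10L, 1), seg(500L, 1000L, 10L, 1.02),
                  seg(1000L, 1500L, 10L, 1.01))
    sm <- smooth_segments(segs, win)
    expect_equal(nrow(sm), 1L)             # chain collapses when stable
    expect_equal(sm$n_windows, 30L)

    # identical rho always merges; 20 SD apart never does
    win2 <- copy(win)[, rho := rho + rnorm(30, 0, 0.05)]
    segs2 <- rbind(seg(0L, 500L, 10L, 1), seg(500L, 1000L, 10L, 2))
    expect_equal(nrow(smooth_segments(segs2, win2)), 2L)
    segs3 <- rbind(seg(0L, 500L, 10L, 1), seg(500L, 1000L, 10L, 1))
    expect_equal(nrow(smooth_segments(segs3, win2)), 1L)
})

test_that("loss/gain inequalities match direct substitution", {
    profile <- list(tg_av_cov = 10, rg_av_cov = 10)
    seg <- function(rho_norm, rg_copy) data.table(
        chrom = "c1", start = 0L, end = 1000L, n_windows = 20L,
        rho_seg = rho_norm,                 # profile ratio is 1
        tg_seg_cov = rho_norm * rg_copy * 10, rg_seg_cov = rg_copy * 10)
    # RG copy 1: loss at <= 0.5, gain at >= 1.5
    expect_equal(call_segments(seg(0.50, 1), profile)$call, "loss")
    expect_equal(call_segments(seg(0.51, 1), profile)$call, "neutral")
    expect_equal(call_segments(seg(1.50, 1), profile)$call, "gain")
    expect_equal(call_segments(seg(1.49, 1), profile)$call, "neutral")
    # RG copy 2: thresholds 0.75 / 1.25; the worked example 0.74 is lost
    expect_equal(call_segments(seg(0.74, 2), profile)$call, "loss")
    expect_equal(call_segments(seg(1.24, 2), profile)$call, "neutral")
    # zero target coverage
    expect_equal(call_segments(seg(0, 1), profile)$call, "zero_coverage")
    # loss and gain can never both hold: sweep a grid
    for (rc in c(0.5, 1, 2, 4)) for (rn in seq(0, 3, by = 0.1)) {
        cl <- call_segments(seg(rn, rc), profile)$call
        loss <- rn <= 1 - 0.5 / rc
        gain <- rn >= 1 + 0.5 / rc
        expect_false(loss && gain)
        if (rn > 0)
            expect_equal(cl, if (loss) "loss" else if (gain) "gain"
                         else "neutral")
    }
})

test_that("balanced genomes stay neutral and TG scaling is invariant", {
    set.seed(5)
    depth <- rep(10L, 5000) + sample(-2:2, 5000, TRUE)
    tg <- depth_pileup(depth); rg <- depth_pileup(depth)
    prof <- genome_profile(tg, rg)
    w <- window_coverages(rg, tg, 50L)
    s <- call_segments(segment_rho(w, nperm = 300L), prof)
    expect_true(all(s$call == "neutral"))
    expect_true(all(abs(s$rho_seg_norm - 1) < 1e-9))

    # multiply TG depths by 3: rho scales, normalized calls do not change
    tg3 <- depth_pileup(depth * 3L)
    prof3 <- genome_profile(tg3, rg)
    w3 <- window_coverages(rg, tg3, 50L)
    s3 <- call_segments(segment_rho(w3, nperm = 300L), prof3)
    expect_equal(s3$rho_seg, 3 * s$rho_seg)
    expect_equal(s3$rho_seg_norm, s$rho_seg_norm)
    expect_identical(s3$call, s$call)
})

test_that("CNV report filters by size and merges PAV windows", {
    win <- data.table(chrom = "c1", win = 1:40, start = (0:39) * 50L,
                      end = (1:40) * 50L, rg_cov = 10, tg_cov = 10,
                      rho = 1, zero_cov = FALSE)
    win[10:21, `:=`(tg_cov = 0, rho = 0, zero_cov = TRUE)]
    segs <- data.table(chrom = "c1",
                       start = c(0L, 1000L), end = c(400L, 1800L),
                       n_windows = c(8L, 16L), rho_seg = c(3, 3),
                       tg_seg_cov = c(30, 30), rg_seg_cov = c(10, 10),
                       rho_seg_norm = c(3, 3), tg_copy = c(3, 3),
                       rg_copy = c(1, 1), tg_copy_rounded = c(3, 3),
                       call = c("gain", "gain"))
    rep <- report_cnv(segs, win, min_sv_size = 500L)
    expect_equal(nrow(rep$cnv), 1L)        # 400-bp gain suppressed
    expect_equal(rep$cnv$start, 1000L)
    # 12 consecutive zero-coverage 50-bp windows merge into one 600-bp PAV
    expect_equal(nrow(rep$pav), 1L)
    expect_equal(rep$pav$end - rep$pav$start, 600L)
    # empty call set still yields a valid (zero-row) report
    rep0 <- report_cnv(segs[0], win[zero_cov == FALSE], 500L)
    expect_equal(nrow(rep0$cnv), 0L)
    expect_equal(nrow(rep0$ge), 0L)
})
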