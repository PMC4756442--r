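# Shared fixtures and independent oracles, built in code at test time.

library(data.table)

# deterministic toy genome
toy_genome <- function(len = 10000L, n_chrom = 1L, seed = 42L,
                       gc = 0.5) {
    random_genome(stats::setNames(rep(as.integer(len), n_chrom),
                                  paste0("c", seq_len(n_chrom))),
                  gc = gc, seed = seed)
}

# hand-built alignment row(s)
make_aln <- function(qname = "r1", flag = 99L, chrom = "c1", pos = 1L,
                     cigar = "70M", seq = strrep("A", 70L),
                     qual = strrep("I", 70L), mchrom = chrom,
                     mpos = pos, tlen = 0L, mapq = 60L) {
    data.table(qname = qname, flag = flag, chrom = chrom, pos = pos,
               mapq = mapq, cigar = cigar, mchrom = mchrom, mpos = mpos,
               tlen = tlen, seq = seq, qual = qual,
               unmapped = bitwAnd(flag, 4L) != 0L,
               secondary = bitwAnd(flag, 256L) != 0L)
}

# brute-force binomial upper tail by direct pmf summation
binom_tail_oracle <- function(k, n, p) {
    if (k <= 0) return(1)
    sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
               numeric(1)))
}

# exhaustive SSE-minimising segmentation of a series into <= k segments;
# returns 1-based inclusive segment bounds of the best model by SSE with
# the given number of changepoints
sse_oracle_segments <- function(x, n_changepoints) {
    n <- length(x)
    sse <- function(lo, hi) {
        v <- x[lo:hi]; sum((v - mean(v))^2)
    }
    if (n_changepoints == 0L)
        return(data.table(lo = 1L, hi = n))
    if (n_changepoints == 1L) {
        best <- NULL; bs <- Inf
        for (i in 1:(n - 1L)) {
            s <- sse(1L, i) + sse(i + 1L, n)
            if (s < bs) { bs <- s; best <- i }
        }
        return(data.table(lo = c(1L, best + 1L), hi = c(best, n)))
    }
    best <- NULL; bs <- Inf
    for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) {
        s <- sse(1L, i) + sse(i + 1L, j) + sse(j + 1L, n)
        if (s < bs) { bs <- s; best <- c(i, j) }
    }
    data.table(lo = c(1L, best[1L] + 1L, best[2L] + 1L),
               hi = c(best, n))
}

# quadratic-time affine-gap Smith-Waterman score oracle (scores only),
# independent of the package's traceback implementation
sw_score_oracle <- function(q, s, match = 1, mismatch = -2,
                            gap_open = -5, gap_ext = -2) {
    m <- nchar(q); n <- nchar(s)
    qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
    H <- matrix(0, m + 1, n + 1)
    E <- matrix(-Inf, m + 1, n + 1)
    F <- matrix(-Inf, m + 1, n + 1)
    best <- 0
    for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
        E[i, j] <- max(H[i, j - 1] + gap_open + gap_ext,
                       E[i, j - 1] + gap_ext)
        F[i, j] <- max(H[i - 1, j] + gap_open + gap_ext,
                       F[i - 1, j] + gap_ext)
        sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N") match
               else mismatch
        H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
        best <- max(best, H[i, j])
    }
    best
}

# mutate one base of a string
subst_base <- function(s, pos, base) {
    substr(s, pos, pos) <- base
    s
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# per-base membership oracle for interval PPV/sensitivity
sv_bases_oracle <- function(called, truth, len) {
    inset <- function(iv) {
        v <- logical(len)
        for (i in seq_len(nrow(iv)))
            if (iv$end[i] > iv$start[i])
                v[(iv$start[i] + 1L):iv$end[i]] <- TRUE
        v
    }
    a <- inset(called); b <- inset(truth)
    list(ppv = sum(a & b) / sum(a), sensitivity = sum(a & b) / sum(b))
}

# translate a full CDS with Biostrings (independent of the package's
# codon table)
translate_cds <- function(cds) {
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       if.fuzzy.codon = "X"))
}
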