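# Structural-variant genome and read simulator with a truth-driven oracle
# aligner. Generates rearranged genomes (deletions, tandem duplications),
# point-mutated haplotype pairs, paired-end reads with a ramped per-base
# error model, oracle alignments in SAM form and pileups, together with a
# complete truth set for downstream evaluation.

#' Simulation configuration
#'
#' @param coverage fold coverage of the simulated genome.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert-size distribution (bp). The default
#'   300 +/- 30 bp is a typical Illumina paired-end library.
#' @param err_min,err_max per-base substitution error probabilities,
#'   ramped linearly from the 5' to the 3' end of each read.
#' @param snp_rate,indel_rate per-bp point-mutation probabilities.
#' @param n_del,n_dup number of large deletions / tandem duplications.
#' @param sv_size structural-variant size in bp.
#' @param max_dups maximum number of extra tandem copies per duplication;
#'   the actual count is uniform on 1..max_dups.
#' @param min_sv_gap minimum gap enforced between placed events (bp), so
#'   that neighbouring events produce separable signals.
#' @param seed integer seed consumed by every stochastic operation that
#'   receives this configuration.
#' @return an object of class `rk_sim_config`.
#' @export
sim_config <- function(coverage = 10, read_len = 70L, insert_mean = 300,
                       insert_sd = 30, err_min = 1e-4, err_max = 0.01,
                       snp_rate = 0, indel_rate = 0, n_del = 0L, n_dup = 0L,
                       sv_size = 2000L, max_dups = 10L, min_sv_gap = 2000L,
                       seed = NULL) {
    assert_that(err_min >= 0 && err_min <= err_max && err_max < 0.5,
                "need 0 <= err_min <= err_max < 0.5")
    assert_that(snp_rate >= 0 && snp_rate <= 0.1 &&
                indel_rate >= 0 && indel_rate <= 0.1,
                "mutation rates must lie in [0, 0.1]")
    assert_that(insert_mean > 2 * read_len,
                "insert_mean must exceed twice the read length")
    structure(list(coverage = coverage, read_len = as.integer(read_len),
                   insert_mean = insert_mean, insert_sd = insert_sd,
                   err_min = err_min, err_max = err_max,
                   snp_rate = snp_rate, indel_rate = indel_rate,
                   n_del = as.integer(n_del), n_dup = as.integer(n_dup),
                   sv_size = as.integer(sv_size),
                   max_dups = as.integer(max_dups),
                   min_sv_gap = as.integer(min_sv_gap), seed = seed),
              class = "rk_sim_config")
}

#' Generate a random genome
#'
#' @param chrom_lens named integer vector of chromosome lengths.
#' @param gc GC content.
#' @param seed optional seed.
#' @return named character vector of uppercase sequences.
#' @export
random_genome <- function(chrom_lens, gc = 0.36, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(names(chrom_lens)))
        names(chrom_lens) <- paste0("chr", seq_along(chrom_lens))
    pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    codes <- utf8ToInt("ACGT")
    out <- vapply(chrom_lens, function(L)
        intToUtf8(codes[sample.int(4L, L, replace = TRUE, prob = pr)]),
        character(1))
    names(out) <- names(chrom_lens)
    out
}

new_truth <- function() {
    list(snps = data.table(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           zygosity = character()),
         indels = data.table(chrom = character(), pos = integer(),
                             kind = character(), allele = character(),
                             len = integer(), zygosity = character()),
         deletions = data.table(chrom = character(), start = integer(),
                                end = integer()),
         duplications = data.table(chrom = character(), start = integer(),
                                   end = integer(), extra_copies = integer()),
         maps = list())
}

#' Simulate a rearranged genome with deletions and tandem duplications
#'
#' Events are placed uniformly (chromosome chosen proportional to length),
#' rejecting placements that overlap or come within `min_sv_gap` of an
#' already placed event, with a bounded number of retries. Each deletion
#' excises its interval; each duplication inserts k extra tandem copies,
#' k uniform on 1..`max_dups`. The returned truth set records
#' reference-coordinate intervals (0-based half-open) and the block map
#' from target to reference coordinates used by [oracle_align()].
#'
#' @param ref named character vector of reference sequences.
#' @param config an [sim_config()] object (`n_del`, `n_dup`, `sv_size`,
#'   `max_dups`, `seed` are used).
#' @return list with elements `target` (named character vector), `truth`
#'   and `map`.
#' @export
simulate_rearranged_genome <- function(ref, config) {
    if (!is.null(config$seed)) set.seed(config$seed)
    lens <- nchar(ref)
    assert_that(any(lens >= config$sv_size),
                "no chromosome can hold an event of %d bp", config$sv_size)
    n_ev <- config$n_del + config$n_dup
    types <- c(rep("del", config$n_del), rep("dup", config$n_dup))
    placed <- data.table(chrom = character(), start = integer(),
                         end = integer(), type = character(),
                         extra = integer())
    ok_chr <- names(ref)[lens >= config$sv_size + 2L]
    budget <- 200L * max(n_ev, 1L)
    for (tp in types) {
        put <- FALSE
        while (budget > 0L) {
            budget <- budget - 1L
            ch <- if (length(ok_chr) == 1L) ok_chr else
                sample(ok_chr, 1L, prob = lens[ok_chr])
            s <- floor(runif(1, 1, lens[ch] - config$sv_size)) # 0-based
            e <- s + config$sv_size
            near <- placed[chrom == ch &
                           start < e + config$min_sv_gap &
                           end > s - config$min_sv_gap]
            if (nrow(near) == 0L) {
                k <- if (tp == "dup") sample.int(config$max_dups, 1L) else 0L
                placed <- rbind(placed, data.table(
                    chrom = ch, start = as.integer(s), end = as.integer(e),
                    type = tp, extra = k))
                put <- TRUE
                break
            }
        }
        if (!put) stopf("event placement retry budget exhausted")
    }
    truth <- new_truth()
    truth$deletions <- placed[type == "del", .(chrom, start, end)]
    truth$duplications <- placed[type == "dup",
                                 .(chrom, start, end, extra_copies = extra)]
    # build target sequence and block map per chromosome
    target <- character(0)
    map <- list()
    for (ch in names(ref)) {
        ev <- placed[chrom == ch][order(start)]
        pieces <- data.table(r_start = integer(), len = integer())
        cur <- 0L
        for (i in seq_len(nrow(ev))) {
            if (ev$start[i] > cur)
                pieces <- rbind(pieces, data.table(r_start = cur,
                                                   len = ev$start[i] - cur))
            if (ev$type[i] == "del") {
                cur <- ev$end[i]
            } else {
                n_copies <- 1L + ev$extra[i]
                pieces <- rbind(pieces, data.table(
                    r_start = rep(ev$start[i], n_copies),
                    len = rep(ev$end[i] - ev$start[i], n_copies)))
                cur <- ev$end[i]
            }
        }
        if (cur < lens[ch])
            pieces <- rbind(pieces, data.table(r_start = cur,
                                               len = lens[ch] - cur))
        pieces[, t_start := cumsum(shift(len, fill = 0L))]
        pieces[, `:=`(chrom = ch, type = "M")]
        target[ch] <- paste(seq_slices(ref[[ch]], pieces$r_start,
                                       pieces$r_start + pieces$len),
                            collapse = "")
        map[[ch]] <- pieces[, .(chrom, t_start, len, r_start, type)]
    }
    map <- rbindlist(map)
    setattr(map, "kind", "sv")
    truth$maps$target <- map
    list(target = target, truth = truth, map = map)
}

#' Simulate point variants on a reference, producing a haplotype pair
#'
#' SNPs are drawn per site as Bernoulli(`snp_rate`) with the alternate
#' base uniform over the three non-reference bases; indels as
#' Bernoulli(`indel_rate`) with geometric length (p = 0.5, capped at 10),
#' insertions and deletions equally likely. Each variant is homozygous or
#' heterozygous with probability 1/2; heterozygous variants are applied to
#' one randomly chosen haplotype. Variants landing within 12 bp of an
#' indel anchor are thinned so truth coordinates stay unambiguous.
#'
#' @param ref named character vector of reference sequences.
#' @param config an [sim_config()] object.
#' @return list with `haplotypes` (list of two named character vectors)
#'   and `truth` (with per-haplotype block maps for the oracle aligner).
#' @export
simulate_point_variants <- function(ref, config) {
    if (!is.null(config$seed)) set.seed(config$seed)
    truth <- new_truth()
    haps <- list(hap1 = character(0), hap2 = character(0))
    maps <- list(hap1 = list(), hap2 = list())
    codes <- utf8ToInt("ACGT")
    for (ch in names(ref)) {
        L <- nchar(ref[[ch]])
        z <- utf8ToInt(ref[[ch]])
        ref_idx <- match(z, codes)          # 1..4, NA for N
        ## --- SNPs ---
        spos <- which(runif(L) < config$snp_rate)
        spos <- spos[!is.na(ref_idx[spos])]
        ## --- indels ---
        ipos <- which(runif(L) < config$indel_rate)
        ipos <- ipos[ipos > 12L & ipos < L - 15L]
        if (length(ipos) > 1L)
            ipos <- ipos[c(TRUE, diff(ipos) > 25L)]
        if (length(ipos) && length(spos)) {
            # drop SNPs too close to an indel anchor
            near <- findInterval(spos, sort(c(ipos - 12L, ipos + 12L)))
            spos <- spos[near %% 2L == 0L]
        }
        n_snp <- length(spos); n_ind <- length(ipos)
        if (n_snp) {
            alt_idx <- (ref_idx[spos] - 1L + sample.int(3L, n_snp,
                                                        replace = TRUE)) %% 4L + 1L
            szyg <- sample(c("hom", "het"), n_snp, replace = TRUE)
            shap <- sample.int(2L, n_snp, replace = TRUE)  # used when het
            truth$snps <- rbind(truth$snps, data.table(
                chrom = ch, pos = spos, ref = BASES[ref_idx[spos]],
                alt = BASES[alt_idx], zygosity = szyg))
        }
        ind <- NULL
        if (n_ind) {
            kind <- sample(c("INS", "DEL"), n_ind, replace = TRUE)
            ilen <- pmin(rgeom(n_ind, 0.5) + 1L, 10L)
            izyg <- sample(c("hom", "het"), n_ind, replace = TRUE)
            ihap <- sample.int(2L, n_ind, replace = TRUE)
            allele <- character(n_ind)
            for (i in seq_len(n_ind)) {
                allele[i] <- if (kind[i] == "INS")
                    intToUtf8(codes[sample.int(4L, ilen[i], replace = TRUE)])
                else substr(ref[[ch]], ipos[i] + 1L, ipos[i] + ilen[i])
            }
            ind <- data.table(pos = ipos, kind = kind, allele = allele,
                              len = ilen, zygosity = izyg, hap = ihap)
            truth$indels <- rbind(truth$indels, data.table(
                chrom = ch, pos = ipos, kind = kind, allele = allele,
                len = ilen, zygosity = izyg))
        }
        for (h in 1:2) {
            zz <- z
            if (n_snp) {
                use <- szyg == "hom" | shap == h
                zz[spos[use]] <- codes[alt_idx[use]]
            }
            s2 <- intToUtf8(zz)
            hind <- if (!is.null(ind)) ind[zygosity == "hom" | hap == h][order(pos)]
                    else NULL
            built <- apply_indels(s2, hind, ch)
            haps[[h]][ch] <- built$seq
            maps[[h]][[ch]] <- built$map
        }
    }
    maps <- lapply(maps, function(m) {
        mm <- rbindlist(m)
        setattr(mm, "kind", "point")
        mm
    })
    truth$maps <- maps
    list(haplotypes = haps, truth = truth)
}

# splice indels into a sequence, returning the new sequence and the
# block map (t_start/len/r_start, type M for reference-mapped pieces and
# I for inserted bases) in 0-based half-open coordinates
apply_indels <- function(seq, ind, ch) {
    L <- nchar(seq)
    if (is.null(ind) || nrow(ind) == 0L) {
        map <- data.table(chrom = ch, t_start = 0L, len = L,
                          r_start = 0L, type = "M")
        return(list(seq = seq, map = map))
    }
    pieces <- list()
    frags <- character(0)
    r_cur <- 0L; t_cur <- 0L
    for (i in seq_len(nrow(ind))) {
        a <- ind$pos[i]                      # 1-based anchor
        mlen <- a - r_cur                    # ref piece [r_cur, a)
        frags <- c(frags, substr(seq, r_cur + 1L, a))
        pieces[[length(pieces) + 1L]] <-
            data.table(chrom = ch, t_start = t_cur, len = mlen,
                       r_start = r_cur, type = "M")
        t_cur <- t_cur + mlen
        if (ind$kind[i] == "INS") {
            frags <- c(frags, ind$allele[i])
            pieces[[length(pieces) + 1L]] <-
                data.table(chrom = ch, t_start = t_cur, len = ind$len[i],
                           r_start = NA_integer_, type = "I")
            t_cur <- t_cur + ind$len[i]
            r_cur <- a
        } else {
            r_cur <- a + ind$len[i]          # skip deleted bases
        }
    }
    frags <- c(frags, substr(seq, r_cur + 1L, L))
    pieces[[length(pieces) + 1L]] <-
        data.table(chrom = ch, t_start = t_cur, len = L - r_cur,
                   r_start = r_cur, type = "M")
    list(seq = paste(frags, collapse = ""), map = rbindlist(pieces))
}

#' Simulate Illumina-style paired-end reads
#'
#' Fragment start positions are uniform; insert lengths are
#' Normal(insert_mean, insert_sd) truncated below at twice the read
#' length. The pair count is `floor(coverage * genome_len /
#' (2 * read_len))`. Per-base substitution errors ramp linearly from
#' `err_min` at the 5' end to `err_max` at the 3' end of each read; an
#' error substitutes a uniformly chosen different base and lowers the
#' recorded quality. When a list of haplotypes is supplied each fragment
#' is drawn from a randomly chosen haplotype.
#'
#' @param genome named character vector, or a list of such haplotypes
#'   sharing chromosome names.
#' @param config an [sim_config()] object.
#' @param n_pairs override the pair count (used by chunked drivers; the
#'   default derives it from the coverage).
#' @return a `data.table` of reads (two rows per pair) with columns pid,
#'   qname, src, chrom, gstart (0-based position of the read's leftmost
#'   base in the simulated genome), strand, mate, insert, seq, qual.
#' @export
simulate_paired_reads <- function(genome, config, n_pairs = NULL) {
    assert_that(config$coverage > 0, "coverage must be positive")
    if (!is.null(config$seed)) set.seed(config$seed)
    haps <- if (is.list(genome)) genome else list(genome = genome)
    if (is.null(names(haps))) names(haps) <- paste0("hap", seq_along(haps))
    rl <- config$read_len
    glen <- mean(vapply(haps, function(h) sum(nchar(h)), numeric(1)))
    if (is.null(n_pairs))
        n_pairs <- floor(config$coverage * glen / (2 * rl))
    assert_that(n_pairs >= 1, "genome too small for any read pair")

    hap_i <- sample.int(length(haps), n_pairs, replace = TRUE)
    # chromosome choice proportional to its length within the haplotype
    chrom_of <- character(n_pairs); start0 <- integer(n_pairs)
    ins <- as.integer(pmax(round(rnorm(n_pairs, config$insert_mean,
                                       config$insert_sd)), 2L * rl))
    for (hi in seq_along(haps)) {
        sel <- which(hap_i == hi)
        if (!length(sel)) next
        lens <- nchar(haps[[hi]])
        ch_i <- if (length(lens) == 1L) rep(1L, length(sel)) else
            sample.int(length(lens), length(sel), replace = TRUE,
                       prob = lens)
        chrom_of[sel] <- names(lens)[ch_i]
        Ls <- lens[ch_i]
        ins[sel] <- pmin(ins[sel], Ls)
        start0[sel] <- as.integer(floor(runif(length(sel)) *
                                        (Ls - ins[sel] + 1L)))
    }
    flip <- runif(n_pairs) < 0.5   # which mate is first-in-pair
    l_start <- start0
    r_start <- start0 + ins - rl

    reads <- data.table(
        pid = rep(seq_len(n_pairs), each = 2L),
        src = rep(names(haps)[hap_i], each = 2L),
        chrom = rep(chrom_of, each = 2L),
        gstart = as.integer(rbind(l_start, r_start)),
        strand = rep(c("+", "-"), n_pairs),
        mate = as.integer(rbind(ifelse(flip, 2L, 1L),
                                ifelse(flip, 1L, 2L))),
        insert = rep(ins, each = 2L))
    reads[, qname := sprintf("r%08d", pid)]
    # extract forward-strand slices per (src, chrom), then orient reads
    reads[, seq := ""]
    for (hi in seq_along(haps)) {
        for (ch in names(haps[[hi]])) {
            sel <- which(reads$src == names(haps)[hi] & reads$chrom == ch)
            if (!length(sel)) next
            set(reads, sel, "seq",
                seq_slices(haps[[hi]][[ch]], reads$gstart[sel],
                           reads$gstart[sel] + rl))
        }
    }
    minus <- reads$strand == "-"
    set(reads, which(minus), "seq", revcomp(reads$seq[minus]))
    prof <- seq(config$err_min, config$err_max, length.out = rl)
    inj <- inject_errors_cpp(reads$seq, prof, 33L)
    reads[, `:=`(seq = inj$seq, qual = inj$qual)]
    setattr(reads, "read_len", rl)
    reads[]
}

#' Oracle alignment of simulated reads against the reference
#'
#' Stands in for a short-read mapper: because the simulator knows every
#' read's origin, reads lying wholly inside a reference-mapped block are
#' placed at their true reference coordinates with a full-match CIGAR.
#' Reads crossing a point-indel junction receive the corresponding I/D
#' CIGAR; reads crossing a structural-variant junction (or starting inside
#' inserted sequence, or spanning more than one indel) are emitted
#' unmapped with their mate's position preserved -- exactly the reads the
#' split-read breakpoint refinement step later recovers. Reads from extra
#' duplication copies map onto the source copy, producing the coverage
#' gain signal. Template length (tlen) is computed from the mapped mate
#' positions, so pairs flanking a deletion show inflated insert sizes.
#'
#' @param reads read table from [simulate_paired_reads()].
#' @param truth truth object carrying per-source block `maps` (as built by
#'   [simulate_rearranged_genome()] / [simulate_point_variants()]), a
#'   single block map, or NULL when reads were simulated directly from the
#'   reference.
#' @param ref named character vector of reference sequences.
#' @param config an [sim_config()] object.
#' @return an alignment `data.table` in SAM field order (1-based `pos`),
#'   with logical `unmapped` / `secondary` columns; minus-strand records
#'   carry the reference-forward sequence as in SAM.
#' @export
oracle_align <- function(reads, truth, ref, config) {
    rl <- attr(reads, "read_len") %||% config$read_len
    maps <- if (is.null(truth)) NULL
            else if (is.data.table(truth)) {
                m <- list(truth); names(m) <- reads$src[1L]; m
            }
            else truth$maps
    n <- nrow(reads)
    pos0 <- rep(NA_integer_, n)
    cigar <- rep("*", n)
    full_cigar <- paste0(rl, "M")

    for (src in unique(reads$src)) {
        m <- if (!is.null(maps)) maps[[src]] else NULL
        if (is.null(m) && !is.null(maps) && length(maps) == 1L)
            m <- maps[[1L]]
        rows <- which(reads$src == src)
        if (is.null(m)) {    # identity: reads come from the reference
            pos0[rows] <- reads$gstart[rows]
            cigar[rows] <- full_cigar
            next
        }
        kind <- attr(m, "kind") %||% "sv"
        for (ch in unique(reads$chrom[rows])) {
            rr <- rows[reads$chrom[rows] == ch]
            pc <- m[chrom == ch]
            g <- reads$gstart[rr]
            pi <- findInterval(g, pc$t_start)
            fits <- pi >= 1L & pc$type[pi] == "M" &
                (g + rl) <= (pc$t_start[pi] + pc$len[pi])
            ok <- rr[fits]
            pos0[ok] <- pc$r_start[pi[fits]] + (g[fits] - pc$t_start[pi[fits]])
            cigar[ok] <- full_cigar
            if (kind == "point") {
                # junction reads: derive an indel-aware CIGAR
                jr <- which(!fits)
                for (t in jr) {
                    res <- junction_cigar(g[t], rl, pc)
                    if (!is.null(res)) {
                        pos0[rr[t]] <- res$pos0
                        cigar[rr[t]] <- res$cigar
                    }
                }
            }
        }
    }

    mapped <- !is.na(pos0)
    # SAM orientation: minus-strand sequences stored reference-forward
    seqs <- reads$seq; quals <- reads$qual
    mrev <- which(mapped & reads$strand == "-")
    seqs[mrev] <- revcomp(seqs[mrev])
    quals[mrev] <- reverse_str_cpp(quals[mrev])

    aln <- data.table(pid = reads$pid, qname = reads$qname,
                      chrom = reads$chrom, pos = pos0 + 1L,
                      mapq = ifelse(mapped, 60L, 0L), cigar = cigar,
                      seq = seqs, qual = quals, mate = reads$mate,
                      strand = reads$strand, unmapped = !mapped)
    # pair the two rows of each pid to fill mate fields and tlen
    setorder(aln, pid, mate)
    odd <- seq(1L, nrow(aln), by = 2L); even <- odd + 1L
    o <- integer(nrow(aln)); o[odd] <- even; o[even] <- odd
    aln[, `:=`(m_unmapped = unmapped[o], mchrom = chrom[o],
               mpos = pos[o], m_strand = strand[o])]
    aln[unmapped == TRUE, `:=`(chrom = mchrom, pos = mpos)]  # SAM convention
    aln[m_unmapped == TRUE, `:=`(mchrom = chrom, mpos = pos)]
    span <- integer(nrow(aln))
    span[!aln$unmapped] <- cigar_ref_span(aln$cigar[!aln$unmapped])
    both <- !aln$unmapped & !aln$m_unmapped & aln$chrom == aln$mchrom
    lo <- pmin(aln$pos, aln$mpos)
    hi_end <- pmax(aln$pos + span, aln$mpos + span[o])
    tl <- ifelse(both, hi_end - lo, 0L)
    tl_signed <- ifelse(aln$pos <= aln$mpos, tl, -tl)
    aln[, tlen := 0L]
    set(aln, which(both), "tlen", as.integer(tl_signed[both]))
    max_ins <- config$insert_mean + 4 * config$insert_sd
    proper <- both & abs(tl) <= max_ins
    aln[, flag := 1L +
          ifelse(proper, 2L, 0L) +
          ifelse(unmapped, 4L, 0L) +
          ifelse(m_unmapped, 8L, 0L) +
          ifelse(!unmapped & strand == "-", 16L, 0L) +
          ifelse(!m_unmapped & m_strand == "-", 32L, 0L) +
          ifelse(mate == 1L, 64L, 128L)]
    aln[unmapped == TRUE, `:=`(cigar = "*", mapq = 0L)]
    aln[is.na(pos), pos := 0L]
    aln[is.na(mpos), mpos := 0L]
    aln[, secondary := FALSE]
    out <- aln[, .(qname, flag, chrom, pos, mapq, cigar, mchrom, mpos,
                   tlen, seq, qual, unmapped, secondary)]
    out[]
}

# CIGAR for a read crossing point-variant junctions; NULL when the read
# cannot be represented with a single simple indel path (then unmapped)
junction_cigar <- function(g, rl, pc) {
    p <- findInterval(g, pc$t_start)
    if (p < 1L) return(NULL)
    q <- p
    while (q <= nrow(pc) && pc$t_start[q] < g + rl) q <- q + 1L
    q <- q - 1L
    idx <- p:q
    if (length(idx) > 3L) return(NULL)
    if (pc$type[p] == "I" || pc$type[q] == "I") return(NULL)
    ops <- character(0)
    pos0 <- pc$r_start[p] + (g - pc$t_start[p])
    prev_rend <- NA_integer_
    for (i in idx) {
        t0 <- max(pc$t_start[i], g)
        t1 <- min(pc$t_start[i] + pc$len[i], g + rl)
        o <- t1 - t0
        if (o <= 0L) next
        if (pc$type[i] == "I") {
            ops <- c(ops, paste0(o, "I"))
        } else {
            if (!is.na(prev_rend)) {
                gap <- pc$r_start[i] - prev_rend
                if (gap > 0L) ops <- c(ops, paste0(gap, "D"))
                if (gap < 0L) return(NULL)
            }
            ops <- c(ops, paste0(o, "M"))
            prev_rend <- pc$r_start[i] + (t1 - pc$t_start[i])
        }
    }
    # merge adjacent M ops (insertion piece not overlapped etc.)
    list(pos0 = pos0, cigar = collapse_cigar(ops))
}

collapse_cigar <- function(ops) {
    if (length(ops) <= 1L) return(paste(ops, collapse = ""))
    lens <- as.integer(sub("[MID]$", "", ops))
    typ <- substr(ops, nchar(ops), nchar(ops))
    keep_l <- integer(0); keep_t <- character(0)
    for (i in seq_along(ops)) {
        if (length(keep_t) && keep_t[length(keep_t)] == typ[i]) {
            keep_l[length(keep_l)] <- keep_l[length(keep_l)] + lens[i]
        } else {
            keep_l <- c(keep_l, lens[i]); keep_t <- c(keep_t, typ[i])
        }
    }
    paste0(keep_l, keep_t, collapse = "")
}

#' Build a pileup from mapped alignments
#'
#' Per-position depth counts aligned M bases with base quality at least
#' `min_baseq`; soft-clipped bases never contribute. With
#' `want_counts = TRUE` per-position A/C/G/T allele counts are kept
#' (needed for variant calling). Insertion (I) and deletion (D) CIGAR
#' operations register indel evidence at the reference position of the
#' preceding aligned base.
#'
#' @param aln alignment table ([oracle_align()] or [parse_sam()]).
#' @param ref named character vector of reference sequences.
#' @param min_baseq minimum base quality (Phred) for a base to count.
#' @param want_counts keep the per-base allele count matrix.
#' @param qual_offset quality ASCII offset (default Phred+33).
#' @return an object of class `rk_pileup`: per-chromosome depth vectors,
#'   optional allele counts and indel evidence tables.
#' @export
pileup_from_alignments <- function(aln, ref, min_baseq = 0L,
                                   want_counts = TRUE, qual_offset = 33L) {
    mapped <- aln[unmapped == FALSE & secondary == FALSE]
    chroms <- list()
    for (ch in names(ref)) {
        sub <- mapped[chrom == ch]
        L <- nchar(ref[[ch]])
        if (nrow(sub) == 0L) {
            chroms[[ch]] <- list(depth = integer(L), counts = NULL,
                                 ins = data.table(pos = integer(),
                                                  allele = character(),
                                                  count = integer()),
                                 del = data.table(pos = integer(),
                                                  len = integer(),
                                                  count = integer()))
            next
        }
        r <- pileup_chrom_cpp(sub$pos, sub$cigar, sub$seq, sub$qual, L,
                              as.integer(min_baseq), as.integer(qual_offset),
                              want_counts)
        chroms[[ch]] <- list(depth = r$depth, counts = r$counts,
                             ins = as.data.table(r$ins),
                             del = as.data.table(r$del))
    }
    structure(list(chroms = chroms, min_baseq = as.integer(min_baseq)),
              class = "rk_pileup")
}

#' @export
print.rk_pileup <- function(x, ...) {
    cat("<rk_pileup>", length(x$chroms), "chromosome(s)\n")
    for (ch in names(x$chroms)) {
        d <- x$chroms[[ch]]$depth
        cat(sprintf("  %s: %d bp, mean depth %.2f, covered %.1f%%\n",
                    ch, length(d), mean(d), 100 * mean(d > 0)))
    }
    invisible(x)
}

#' Convert a pileup object into compact pileup records
#'
#' One row per covered position with the reference base, the
#' target-genome consensus (IUPAC code when a non-reference allele
#' reaches `het_freq`), depth, SNP/indel evidence flags and the top
#' alternate allele count -- the exchange form stored by
#' [write_pileup_folder()].
#'
#' @param pileup an `rk_pileup` with allele counts.
#' @param ref named character vector of reference sequences.
#' @param het_freq minor-allele frequency at which the consensus becomes
#'   an ambiguity code.
#' @return `data.table` of pileup records.
#' @export
pileup_records <- function(pileup, ref, het_freq = 0.25) {
    out <- list()
    for (ch in names(pileup$chroms)) {
        pc <- pileup$chroms[[ch]]
        cov <- which(pc$depth > 0L)
        if (!length(cov)) next
        refc <- strsplit(seq_slices(ref[[ch]], 0L, nchar(ref[[ch]])),
                         "")[[1L]][cov]
        dt <- data.table(chrom = ch, pos = cov, ref_base = refc,
                         depth = pc$depth[cov])
        if (!is.null(pc$counts)) {
            cnt <- pc$counts[cov, , drop = FALSE]
            ref_i <- match(refc, BASES)
            cnt_ref <- ifelse(is.na(ref_i), 0L,
                              cnt[cbind(seq_along(cov),
                                        ifelse(is.na(ref_i), 1L, ref_i))])
            alt_cnt <- cnt
            alt_cnt[cbind(which(!is.na(ref_i)), ref_i[!is.na(ref_i)])] <- -1L
            alt_i <- max.col(alt_cnt, ties.method = "first")
            alt_n <- cnt[cbind(seq_along(cov), alt_i)]
            tot <- rowSums(cnt)
            maj_i <- max.col(cnt, ties.method = "first")
            tg <- BASES[maj_i]
            het <- alt_n > 0L & alt_n < tot & (alt_n / pmax(tot, 1L)) >= het_freq
            tg[het] <- iupac_het(BASES[maj_i[het]], BASES[alt_i[het]])
            none <- tot == 0L
            tg[none] <- refc[none]
            dt[, `:=`(tg_base = tg, alt_count = alt_n,
                      snp_flag = tg != refc)]
        } else {
            dt[, `:=`(tg_base = refc, alt_count = 0L, snp_flag = FALSE)]
        }
        ipos <- unique(c(pc$ins$pos, pc$del$pos))
        dt[, indel_flag := pos %in% ipos]
        out[[ch]] <- dt[, .(chrom, pos, ref_base, tg_base, depth,
                            snp_flag, indel_flag, alt_count)]
    }
    if (!length(out)) return(read_pileup_records_empty())
    rbindlist(out)[]
}

read_pileup_records_empty <- function() {
    data.table(chrom = character(), pos = integer(), ref_base = character(),
               tg_base = character(), depth = integer(),
               snp_flag = logical(), indel_flag = logical(),
               alt_count = integer())
}

#' Depth vector of one chromosome from a pileup object or records table
#'
#' @param pileup `rk_pileup` or pileup records `data.table`.
#' @param chrom chromosome name.
#' @param len chromosome length (required for a records table).
#' @return integer vector of per-position depth.
#' @export
pileup_depth <- function(pileup, chrom, len = NULL) {
    if (inherits(pileup, "rk_pileup")) {
        pc <- pileup$chroms[[chrom]]
        assert_that(!is.null(pc), "chromosome %s absent from pileup", chrom)
        return(pc$depth)
    }
    assert_that(!is.null(len), "len is required for records input")
    d <- integer(len)
    sub <- pileup[pileup$chrom == chrom, ]
    d[sub$pos] <- sub$depth
    d
}
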