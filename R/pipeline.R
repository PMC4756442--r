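# End-to-end drivers: the three simulation-study designs (point
# variants, large deletions, tandem duplications) and a full pipeline run
# that writes every stage artifact plus a manifest.

#' Simulation study: point-variant calling accuracy
#'
#' Generates a random genome, plants SNPs and indels on a diploid
#' haplotype pair, simulates paired-end reads with the ramped error
#' model, oracle-aligns them, builds a quality-filtered pileup, calls
#' variants and evaluates them against the truth set.
#'
#' @param genome_len genome length in bp.
#' @param coverage fold coverage.
#' @param snp_rate,indel_rate per-bp mutation rates.
#' @param seed integer seed (consumed for genome, variants and reads).
#' @param caller [caller_config()].
#' @param config optional [sim_config()] overriding read parameters.
#' @return list: eval_snp, eval_indel (from [eval_point_variants()]),
#'   calls, truth, pileup.
#' @export
study_point_variants <- function(genome_len = 5e6, coverage = 20,
                                 snp_rate = 0.001, indel_rate = 1e-4,
                                 seed = 1L, caller = caller_config(),
                                 config = NULL) {
    cfg <- config %||% sim_config(coverage = coverage, snp_rate = snp_rate,
                                  indel_rate = indel_rate, seed = seed + 1L)
    ref <- random_genome(c(chr1 = as.integer(genome_len)), seed = seed)
    pv <- simulate_point_variants(ref, cfg)
    cfg$seed <- seed + 2L
    reads <- simulate_paired_reads(pv$haplotypes, cfg)
    aln <- oracle_align(reads, pv$truth, ref, cfg)
    rm(reads)
    pile <- pileup_from_alignments(aln, ref, min_baseq = caller$min_baseq,
                                   want_counts = TRUE)
    rm(aln)
    calls <- call_variants(pile, ref, caller)
    list(eval_snp = eval_point_variants(calls, pv$truth, "SNP"),
         eval_indel = eval_point_variants(calls, pv$truth, "indel"),
         calls = calls, truth = pv$truth, pileup = pile)
}

#' Simulation study: large-deletion discovery and breakpoint precision
#'
#' Plants non-overlapping deletions in a random genome, simulates reads
#' from the rearranged target, oracle-aligns them to the reference (pairs
#' flanking a deletion become discordant; breakpoint-spanning reads stay
#' unmapped), runs the large-deletion finder and evaluates base-level
#' PPV/sensitivity plus the signed breakpoint-error distribution.
#'
#' @param genome_len,n_del,sv_size,coverage study design parameters.
#' @param seed integer seed.
#' @param config optional [sim_config()] override.
#' @return list: eval (base-level), bp (breakpoint stats), calls, truth.
#' @export
study_deletions <- function(genome_len = 1e7, n_del = 50L, sv_size = 2000L,
                            coverage = 10, seed = 1L, config = NULL) {
    cfg <- config %||% sim_config(coverage = coverage, n_del = n_del,
                                  sv_size = sv_size, seed = seed + 1L)
    ref <- random_genome(c(chr1 = as.integer(genome_len)), seed = seed)
    sim <- simulate_rearranged_genome(ref, cfg)
    cfg$seed <- seed + 2L
    reads <- simulate_paired_reads(sim$target, cfg)
    aln <- oracle_align(reads, sim$truth, ref, cfg)
    rm(reads)
    pile <- pileup_from_alignments(aln, ref, want_counts = FALSE)
    calls <- find_deletions(aln, ref, tg_pileup = pile)
    ev <- eval_sv_bases(calls[, .(chrom, start, end)], sim$truth$deletions)
    bp <- breakpoint_error_stats(calls[!is.na(refined_start),
                                       .(chrom, start, end)],
                                 sim$truth$deletions)
    list(eval = ev, bp = bp, calls = calls, truth = sim$truth)
}

#' Depth-only pileup from a chunked read simulation
#'
#' Simulates, oracle-aligns and pileups paired-end reads in chunks of
#' `chunk_pairs` pairs, accumulating per-position depth and discarding
#' each chunk's reads -- the memory-bounded path for coverage-only
#' analyses of larger genomes. One seed (from `config$seed`) governs the
#' whole stream, so the result is reproducible and independent of the
#' chunk size boundaries only up to chunking; a fixed chunk size plus
#' seed is fully deterministic.
#'
#' @param genome simulated genome (named character vector or haplotype
#'   list).
#' @param truth truth object carrying block maps (or NULL for reads from
#'   the reference itself).
#' @param ref named character vector of reference sequences.
#' @param config [sim_config()]; `config$seed` seeds the stream.
#' @param chunk_pairs pairs per chunk.
#' @return a depth-only `rk_pileup` over `ref`.
#' @export
simulated_depth_pileup <- function(genome, truth, ref, config,
                                   chunk_pairs = 250000L) {
    haps <- if (is.list(genome)) genome else list(genome = genome)
    glen <- mean(vapply(haps, function(h) sum(nchar(h)), numeric(1)))
    total <- floor(config$coverage * glen / (2 * config$read_len))
    if (!is.null(config$seed)) set.seed(config$seed)
    cfg <- config; cfg$seed <- NULL    # RNG stream continues across chunks
    depth <- lapply(ref, function(s) integer(nchar(s)))
    done <- 0L
    while (done < total) {
        k <- min(chunk_pairs, total - done)
        reads <- simulate_paired_reads(genome, cfg, n_pairs = k)
        aln <- oracle_align(reads, truth, ref, cfg)
        rm(reads)
        pile <- pileup_from_alignments(aln, ref, want_counts = FALSE)
        rm(aln)
        for (ch in names(ref))
            depth[[ch]] <- depth[[ch]] + pile$chroms[[ch]]$depth
        rm(pile)
        done <- done + k
    }
    chroms <- lapply(depth, function(d) list(
        depth = d, counts = NULL,
        ins = data.table(pos = integer(), allele = character(),
                         count = integer()),
        del = data.table(pos = integer(), len = integer(),
                         count = integer())))
    structure(list(chroms = chroms, min_baseq = 0L), class = "rk_pileup")
}

#' Simulation study: duplication (copy-number gain) detection
#'
#' Plants tandem duplications (1..max_dups extra copies) in a random
#' genome, simulates reads at the same coverage from both the rearranged
#' target and the untouched reference, builds both pileups, runs the
#' coverage analysis and evaluates base-level PPV/sensitivity of the gain
#' calls plus the OLS slope of detected segment copy number on the
#' simulated copy number.
#'
#' @param genome_len,n_dup,sv_size,coverage study design parameters.
#' @param seed integer seed.
#' @param min_sv_size minimum reported loss/gain size (bp).
#' @param window_size coverage window (bp).
#' @param config optional [sim_config()] override.
#' @return list: eval (base-level gain), cn (expected/detected pairs),
#'   slope, analysis, truth.
#' @export
study_duplications <- function(genome_len = 2e7, n_dup = 50L,
                               sv_size = 50000L, coverage = 10, seed = 1L,
                               min_sv_size = 500L, window_size = 50L,
                               config = NULL) {
    cfg <- config %||% sim_config(coverage = coverage, n_dup = n_dup,
                                  sv_size = sv_size, seed = seed + 1L)
    ref <- random_genome(c(chr1 = as.integer(genome_len)), seed = seed)
    sim <- simulate_rearranged_genome(ref, cfg)
    cfg$seed <- seed + 2L
    tg_pile <- simulated_depth_pileup(sim$target, sim$truth, ref, cfg)
    cfg$seed <- seed + 3L
    rg_pile <- simulated_depth_pileup(ref, NULL, ref, cfg)
    res <- coverage_analysis(tg_pile, rg_pile, window_size = window_size,
                             min_sv_size = min_sv_size)
    gains <- res$cnv[call == "gain"]
    ev <- eval_sv_bases(gains[, .(chrom, start, end)],
                        sim$truth$duplications[, .(chrom, start, end)])
    cn <- copy_number_pairs(res$segments, sim$truth$duplications)
    slope <- if (nrow(cn) >= 2L && stats::var(cn$expected) > 0)
        copy_number_slope(cn$detected, cn$expected) else NA_real_
    list(eval = ev, cn = cn, slope = slope, analysis = res,
         truth = sim$truth)
}

#' Pair simulated with detected copy numbers
#'
#' For each truth duplication, the gain segment with the largest overlap
#' contributes its target copy number (TG_segCopy); the expected value is
#' the simulated total copy count (1 + extra copies). Duplications
#' without an overlapping gain segment are omitted.
#'
#' @param segments called segment table.
#' @param duplications truth duplications (chrom, start, end,
#'   extra_copies).
#' @return `data.table` with expected and detected columns.
#' @export
copy_number_pairs <- function(segments, duplications) {
    segs <- as.data.table(segments)[call == "gain"]
    out <- list()
    for (i in seq_len(nrow(duplications))) {
        d <- duplications[i]
        ov <- segs[chrom == d$chrom & start < d$end & end > d$start]
        if (nrow(ov) == 0L) next
        ov[, olap := pmin(end, d$end) - pmax(start, d$start)]
        best <- ov[which.max(olap)]
        out[[length(out) + 1L]] <- data.table(
            chrom = d$chrom, start = d$start, end = d$end,
            expected = d$extra_copies + 1L, detected = best$tg_copy)
    }
    if (!length(out))
        return(data.table(chrom = character(), start = integer(),
                          end = integer(), expected = integer(),
                          detected = numeric()))
    rbindlist(out)
}

#' Run the full simulated pipeline and write every stage artifact
#'
#' Simulates a rearranged, point-mutated genome, reads, alignments and
#' pileups, then runs variant calling, the coverage analysis and the
#' large-deletion finder, writing TSV reports, a GE interval file and a
#' JSON manifest (parameters, seed, output files with MD5 checksums)
#' under `output_dir`. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param output_dir output directory (created).
#' @param genome_len genome length (bp).
#' @param coverage fold coverage.
#' @param n_del,n_dup,sv_size structural-variant design.
#' @param snp_rate,indel_rate point-variant design.
#' @param seed integer seed.
#' @param caller [caller_config()].
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(output_dir, genome_len = 2e5, coverage = 10,
                         n_del = 2L, n_dup = 2L, sv_size = 5000L,
                         snp_rate = 5e-4, indel_rate = 5e-5, seed = 1L,
                         caller = caller_config()) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- sim_config(coverage = coverage, n_del = n_del, n_dup = n_dup,
                      sv_size = sv_size, snp_rate = snp_rate,
                      indel_rate = indel_rate, seed = seed + 1L)
    ref <- random_genome(c(chr1 = as.integer(genome_len)), seed = seed)
    sv <- simulate_rearranged_genome(ref, cfg)
    cfg$seed <- seed + 2L
    reads <- simulate_paired_reads(sv$target, cfg)
    aln <- oracle_align(reads, sv$truth, ref, cfg)
    tg_pile <- pileup_from_alignments(aln, ref,
                                      min_baseq = caller$min_baseq,
                                      want_counts = TRUE)
    cfg$seed <- seed + 3L
    rg_reads <- simulate_paired_reads(ref, cfg)
    rg_aln <- oracle_align(rg_reads, NULL, ref, cfg)
    rg_pile <- pileup_from_alignments(rg_aln, ref, want_counts = FALSE)

    variants <- call_variants(tg_pile, ref, caller)
    cov <- coverage_analysis(tg_pile, rg_pile, min_sv_size = 500L)
    dels <- find_deletions(aln, ref, tg_pileup = tg_pile)

    paths <- c(ref = "ref.fa", target = "target.fa", sam = "alignments.sam",
               variants = "variants.tsv", segments = "segments.tsv",
               cnv = "cnv_calls.tsv", pav = "pav.tsv", ge = "regions.ge",
               deletions = "deletions.tsv", truth_del = "truth_deletions.tsv",
               truth_dup = "truth_duplications.tsv")
    paths <- vapply(paths, function(p) file.path(output_dir, p),
                    character(1))
    write_fasta(ref, paths["ref"])
    write_fasta(sv$target, paths["target"])
    write_sam(aln, paths["sam"], ref)
    write_report(variants, paths["variants"])
    write_report(cov$segments, paths["segments"])
    write_report(cov$cnv, paths["cnv"])
    write_report(cov$pav, paths["pav"])
    write_report(cov$ge, paths["ge"])
    write_report(dels, paths["deletions"])
    write_report(sv$truth$deletions, paths["truth_del"])
    write_report(sv$truth$duplications, paths["truth_dup"])
    write_pileup_folder(pileup_records(tg_pile, ref),
                        file.path(output_dir, "pileup_tg"))

    manifest <- list(
        parameters = list(genome_len = genome_len, coverage = coverage,
                          n_del = n_del, n_dup = n_dup, sv_size = sv_size,
                          snp_rate = snp_rate, indel_rate = indel_rate,
                          seed = seed),
        files = lapply(stats::setNames(nm = names(paths)), function(k)
            list(path = basename(paths[[k]]),
                 md5 = unname(tools::md5sum(paths[[k]])))))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
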