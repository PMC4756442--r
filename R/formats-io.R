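# Readers and writers for the formats the toolkit consumes and produces:
# FASTA, minimal SAM, the compact per-chromosome pileup folder, samtools
# pileup, GFF3 gene models and TSV reports. All coordinate-convention
# conversions live here.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; the header token before the first whitespace
#' becomes the name. Duplicated headers and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
    assert_that(file.exists(path), "FASTA file not found: %s", path)
    ss <- Biostrings::readBStringSet(path)
    assert_that(length(ss) > 0L, "empty FASTA file: %s", path)
    nm <- sub("\\s.*$", "", names(ss))
    assert_that(!anyDuplicated(nm), "duplicate FASTA header in %s", path)
    out <- toupper(as.character(ss))
    names(out) <- nm
    out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(x, path, width = 70L) {
    assert_that(!is.null(names(x)), "sequences must be named")
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(x)) {
        writeLines(paste0(">", names(x)[i]), con)
        s <- x[[i]]
        starts <- seq(1L, max(nchar(s), 1L), by = width)
        writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                   con)
    }
    invisible(path)
}

SAM_COLS <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
              "mchrom", "mpos", "tlen", "seq", "qual")

#' Parse a plain-text SAM file into an alignment table
#'
#' Header lines (starting with `@`) are skipped. Each alignment line
#' becomes one row with the eleven mandatory SAM fields; optional tags are
#' dropped. Records with fewer than 11 tab-separated fields raise an error
#' naming the line, as does an unsupported CIGAR operation or a CIGAR whose
#' query span disagrees with the sequence length.
#'
#' @param path path to a SAM file.
#' @return a `data.table` with columns qname, flag, chrom, pos, mapq,
#'   cigar, mchrom, mpos, tlen, seq, qual plus derived logical columns
#'   `unmapped` and `secondary`.
#' @export
parse_sam <- function(path) {
    lines <- readLines(path)
    body <- which(!startsWith(lines, "@"))
    if (!length(body)) {
        return(empty_alignments())
    }
    parts <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 11L)) {
        bad <- body[which(nf < 11L)[1L]]
        stopf("SAM line %d has %d fields (11 required)", bad, min(nf))
    }
    mat <- vapply(parts, function(p) p[1:11], character(11L))
    aln <- data.table(
        qname = mat[1L, ], flag = as.integer(mat[2L, ]), chrom = mat[3L, ],
        pos = as.integer(mat[4L, ]), mapq = as.integer(mat[5L, ]),
        cigar = mat[6L, ], mchrom = mat[7L, ], mpos = as.integer(mat[8L, ]),
        tlen = as.integer(mat[9L, ]), seq = toupper(mat[10L, ]),
        qual = mat[11L, ])
    aln[mchrom == "=", mchrom := chrom]
    aln[, unmapped := bitwAnd(flag, 4L) != 0L]
    aln[, secondary := bitwAnd(flag, 256L) != 0L]
    chk <- aln[!unmapped & cigar != "*" & seq != "*"]
    if (nrow(chk)) {
        qs <- cigar_query_span(chk$cigar)  # errors on unknown ops
        bad <- which(qs != nchar(chk$seq))
        if (length(bad))
            stopf("CIGAR span %d disagrees with sequence length %d for read %s",
                  qs[bad[1L]], nchar(chk$seq[bad[1L]]), chk$qname[bad[1L]])
    }
    aln[]
}

empty_alignments <- function() {
    data.table(qname = character(), flag = integer(), chrom = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               mchrom = character(), mpos = integer(), tlen = integer(),
               seq = character(), qual = character(),
               unmapped = logical(), secondary = logical())
}

#' Write an alignment table as plain-text SAM
#'
#' @param aln alignment table as produced by [parse_sam()] or
#'   [oracle_align()].
#' @param path output file.
#' @param ref optional named character vector of reference sequences used
#'   to emit `@SQ` header lines.
#' @export
write_sam <- function(aln, path, ref = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unsorted", con)
    if (!is.null(ref))
        writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)), con)
    if (nrow(aln)) {
        writeLines(do.call(paste, c(as.list(
            aln[, .(qname, flag, chrom, pos, mapq, cigar, mchrom, mpos,
                    tlen, seq, qual)]), sep = "\t")), con)
    }
    invisible(path)
}

PILEUP_HEADER <- "#pos\tref\ttg\tdepth\tsnp\tindel\talt"

#' Write pileup records as a compact per-chromosome pileup folder
#'
#' One TSV per chromosome, named `<chrom>.pileup.tsv`, with the documented
#' header line `#pos\\tref\\ttg\\tdepth\\tsnp\\tindel\\talt`. Positions are
#' 1-based; only covered positions are stored, so a chromosome with no
#' coverage has no file and is treated as zero coverage everywhere by the
#' reader. Round-trips losslessly through [read_pileup_folder()].
#'
#' @param records a `data.table` with columns chrom, pos, ref_base,
#'   tg_base, depth, snp_flag, indel_flag, alt_count, sorted by
#'   (chrom, pos).
#' @param out_dir output directory (created if needed).
#' @export
write_pileup_folder <- function(records, out_dir) {
    need <- c("chrom", "pos", "ref_base", "tg_base", "depth",
              "snp_flag", "indel_flag", "alt_count")
    assert_that(all(need %in% names(records)),
                "pileup records need columns: %s", paste(need, collapse = ", "))
    records <- as.data.table(records)
    ord <- records[, all(diff(pos) > 0), by = chrom]
    assert_that(all(ord$V1), "pileup records must be sorted by (chrom, pos)")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ch in unique(records$chrom)) {
        f <- file.path(out_dir, paste0(ch, ".pileup.tsv"))
        sub <- records[chrom == ch]
        con <- file(f, "w")
        writeLines(PILEUP_HEADER, con)
        close(con)
        fwrite(sub[, .(pos, ref_base, tg_base, depth,
                       snp = as.integer(snp_flag),
                       indel = as.integer(indel_flag), alt = alt_count)],
               f, sep = "\t", append = TRUE, col.names = FALSE)
    }
    invisible(out_dir)
}

#' Read a compact pileup folder back into a records table
#'
#' @param dir folder written by [write_pileup_folder()].
#' @return `data.table` of pileup records (covered positions only).
#' @export
read_pileup_folder <- function(dir) {
    files <- sort(list.files(dir, pattern = "\\.pileup\\.tsv$",
                             full.names = TRUE))
    assert_that(length(files) > 0L, "no .pileup.tsv files in %s", dir)
    out <- rbindlist(lapply(files, function(f) {
        ch <- sub("\\.pileup\\.tsv$", "", basename(f))
        dt <- fread(f, sep = "\t", skip = 1L,
                    col.names = c("pos", "ref_base", "tg_base", "depth",
                                  "snp", "indel", "alt"),
                    colClasses = list(character = 2:3))
        dt[, .(chrom = ch, pos, ref_base, tg_base, depth,
               snp_flag = snp == 1L, indel_flag = indel == 1L,
               alt_count = alt)]
    }))
    out[]
}

#' Read a classic 6-column samtools pileup file
#'
#' Parses the read-base string (match/mismatch symbols, `^`/`$` markers and
#' `+n`/`-n` indel insertions) into per-position depth and top alternate
#' allele counts, producing the same records table the compact folder uses.
#'
#' @param path samtools pileup file (chrom, pos, ref, depth, bases, quals).
#' @param min_baseq minimum base quality (Phred) for a base to count.
#' @param qual_offset ASCII offset of the quality encoding (33 = Phred+33).
#' @return `data.table` of pileup records.
#' @export
read_samtools_pileup <- function(path, min_baseq = 0L, qual_offset = 33L) {
    dt <- fread(path, sep = "\t", header = FALSE,
                col.names = c("chrom", "pos", "ref_base", "depth",
                              "bases", "quals"),
                colClasses = list(character = c(1, 3, 5, 6)))
    recs <- dt[, parse_pileup_bases(ref_base, bases, quals,
                                    min_baseq, qual_offset),
               by = .(chrom, pos)]
    recs[]
}

# decode one samtools pileup base column entry
parse_pileup_bases <- function(ref, bases, quals, min_baseq, qual_offset) {
    ref <- toupper(ref)
    s <- strsplit(bases, "")[[1]]
    q <- utf8ToInt(quals) - qual_offset
    calls <- character(0)
    indel <- FALSE
    i <- 1L; qi <- 1L
    while (i <= length(s)) {
        c <- s[i]
        if (c == "^") { i <- i + 2L; next }       # start marker + mapq char
        if (c == "$") { i <- i + 1L; next }
        if (c %in% c("+", "-")) {                  # indel descriptor
            j <- i + 1L
            while (j <= length(s) && grepl("[0-9]", s[j])) j <- j + 1L
            n <- as.integer(paste(s[(i + 1L):(j - 1L)], collapse = ""))
            i <- j + n
            indel <- TRUE
            next
        }
        b <- switch(toupper(c), "." = ref, "," = ref, toupper(c))
        if (b %in% c(BASES, "N", "*")) {
            if (b != "*" && qi <= length(q) && q[qi] >= min_baseq)
                calls <- c(calls, b)
            qi <- qi + 1L
        }
        i <- i + 1L
    }
    calls <- calls[calls != "N"]
    dp <- length(calls)
    if (dp == 0L)
        return(list(ref_base = ref, tg_base = ref, depth = 0L,
                    snp_flag = FALSE, indel_flag = indel, alt_count = 0L))
    tab <- table(factor(calls, levels = BASES))
    alt_tab <- tab[setdiff(BASES, ref)]
    alt_n <- if (length(alt_tab)) max(alt_tab) else 0L
    alt_b <- if (alt_n > 0L) names(alt_tab)[which.max(alt_tab)] else ref
    maj <- names(tab)[which.max(tab)]
    tg <- if (alt_n > 0L && alt_n < dp && alt_n / dp >= 0.25)
        iupac_het(maj, alt_b) else maj
    list(ref_base = ref, tg_base = tg, depth = dp,
         snp_flag = tg != ref, indel_flag = indel,
         alt_count = as.integer(alt_n))
}

#' Write a TSV report with a one-line schema header
#'
#' @param dt a data.frame/data.table.
#' @param path output file.
#' @export
write_report <- function(dt, path) {
    con <- file(path, "w")
    writeLines(paste0("#", paste(names(dt), collapse = "\t")), con)
    close(con)
    fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
    invisible(path)
}

#' Read a TSV report written by [write_report()]
#' @param path report file.
#' @return `data.table`.
#' @export
read_report <- function(path) {
    lines <- readLines(path)
    hdr <- strsplit(sub("^#", "", lines[1L]), "\t")[[1]]
    if (length(lines) < 2L)
        return(as.data.table(stats::setNames(rep(list(logical(0)),
                                                 length(hdr)), hdr)))
    dt <- fread(path, sep = "\t", skip = 1L, header = FALSE)
    setnames(dt, hdr)
    dt[]
}
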