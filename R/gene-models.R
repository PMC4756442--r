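# Gene models: GFF3 + spliced CDS/UTR sequences, the input to the
# transcript-consequence annotator.

#' Load gene models from GFF3 with matching CDS/UTR FASTA
#'
#' Builds one model per gene from `gene`, `mRNA`, `CDS`,
#' `five_prime_UTR` and `three_prime_UTR` features (first mRNA per gene).
#' Interval lists are sorted 5'->3' in strand orientation and carry GFF3's
#' 1-based inclusive coordinates. The spliced, strand-oriented sequences
#' are taken from the FASTA files: the CDS FASTA is keyed by gene or
#' transcript id; the UTR FASTA uses headers `<id>.5utr` and `<id>.3utr`.
#' A gene whose id is missing from the CDS FASTA is skipped with a
#' warning; a gene whose CDS interval lengths disagree with its sequence
#' is kept but flagged (`ok = FALSE`) and consequence prediction on it is
#' suppressed. A CDS length that is not a multiple of 3 (partial
#' annotation) is flagged the same way.
#'
#' @param gff3_path GFF3 annotation file.
#' @param cds_fasta FASTA of spliced CDS sequences.
#' @param utr_fasta FASTA of spliced UTR sequences (optional).
#' @return a list of gene models (class `rk_gene_models`); each element
#'   has fields gene_id, chrom, strand, cds_intervals, utr5_intervals,
#'   utr3_intervals, cds_seq, utr5_seq, utr3_seq, ok, note.
#' @export
load_gene_models <- function(gff3_path, cds_fasta, utr_fasta = NULL) {
    gff <- read_gff3(gff3_path)
    cds_seqs <- read_fasta(cds_fasta)
    utr_seqs <- if (!is.null(utr_fasta) && file.exists(utr_fasta))
        read_fasta(utr_fasta) else character(0)

    genes <- gff[type == "gene"]
    mrna <- gff[type == "mRNA"]
    models <- list()
    for (k in seq_len(nrow(genes))) {
        gid <- genes$id[k]
        tx <- mrna[parent == gid]
        txid <- if (nrow(tx)) tx$id[1L] else gid
        feats <- gff[parent %in% c(gid, txid)]
        cds_iv <- feats[type == "CDS", .(start, end)]
        u5_iv <- feats[type == "five_prime_UTR", .(start, end)]
        u3_iv <- feats[type == "three_prime_UTR", .(start, end)]
        if (nrow(cds_iv) == 0L) next
        strand <- genes$strand[k]
        sort_iv <- function(iv) {
            if (!nrow(iv)) return(iv)
            iv[order(if (strand == "-") -start else start)]
        }
        cds_iv <- sort_iv(cds_iv); u5_iv <- sort_iv(u5_iv)
        u3_iv <- sort_iv(u3_iv)
        seq_key <- if (gid %in% names(cds_seqs)) gid
                   else if (txid %in% names(cds_seqs)) txid else NA_character_
        if (is.na(seq_key)) {
            warning(sprintf("gene %s missing from CDS FASTA; skipped", gid))
            next
        }
        cds_seq <- cds_seqs[[seq_key]]
        len_iv <- sum(cds_iv$end - cds_iv$start + 1L)
        ok <- TRUE; note <- ""
        if (len_iv != nchar(cds_seq)) {
            ok <- FALSE
            note <- sprintf("CDS interval length %d != sequence length %d",
                            len_iv, nchar(cds_seq))
        } else if (nchar(cds_seq) %% 3L != 0L) {
            ok <- FALSE
            note <- "CDS length not a multiple of 3 (partial annotation)"
        }
        u5_key <- paste0(seq_key, ".5utr"); u3_key <- paste0(seq_key, ".3utr")
        models[[gid]] <- list(
            gene_id = gid, chrom = genes$chrom[k], strand = strand,
            gene_start = genes$start[k], gene_end = genes$end[k],
            cds_intervals = cds_iv, utr5_intervals = u5_iv,
            utr3_intervals = u3_iv,
            cds_seq = cds_seq,
            utr5_seq = if (u5_key %in% names(utr_seqs)) utr_seqs[[u5_key]]
                       else NA_character_,
            utr3_seq = if (u3_key %in% names(utr_seqs)) utr_seqs[[u3_key]]
                       else NA_character_,
            ok = ok, note = note)
    }
    structure(models, class = "rk_gene_models")
}

# minimal tabular view of a GFF3 file; uses rtracklayer when available,
# otherwise falls back to reading the 9-column text directly
read_gff3 <- function(path) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
        g <- as.data.table(rtracklayer::readGFF(
            path, columns = c("seqid", "start", "end", "strand", "type"),
            tags = c("ID", "Parent")))
        g[, parent := vapply(Parent, function(p)
            if (length(p)) p[[1L]] else NA_character_, character(1))]
        out <- g[, .(chrom = as.character(seqid), start = as.integer(start),
                     end = as.integer(end), strand = as.character(strand),
                     type = as.character(type), id = as.character(ID),
                     parent)]
    } else {
        lines <- readLines(path)
        lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
        f <- tstrsplit(lines, "\t", fixed = TRUE)
        attr_get <- function(a, key) {
            r <- regexpr(paste0("(^|;)", key, "=[^;]+"), a)
            out <- rep(NA_character_, length(a))
            hit <- r != -1L
            out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(a, r))
            out
        }
        attrs <- f[[9L]]
        out <- data.table(chrom = f[[1L]], start = as.integer(f[[4L]]),
                          end = as.integer(f[[5L]]), strand = f[[7L]],
                          type = f[[3L]],
                          id = attr_get(attrs, "ID"),
                          parent = attr_get(attrs, "Parent"))
    }
    out[]
}
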