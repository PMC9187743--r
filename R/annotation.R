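# Per-gene annotation: principal transcript selection, lengths, GC content,
# and the expression filter applied before any length analysis.

#' Read transcript models from a GTF file
#'
#' Parses exon and CDS records into one row per transcript. Genomic
#' coordinates are converted from the 1-based inclusive GTF convention to the
#' 0-based half-open convention used throughout the package. The coding start
#' is the genomic coordinate of the first CDS base in transcription order
#' (leftmost CDS base on `+`, rightmost on `-`).
#'
#' @param path path to a GTF file with `exon` (and optionally `CDS`) features
#'   carrying `transcript_id` and `gene_id` attributes.
#' @return a `data.frame` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end` (0-based half-open span), `coding_start`
#'   (0-based, `NA` for non-coding), `cds_length`, `exonic_length`,
#'   `utr5_annot` (annotated transcript-start to coding-start distance in
#'   transcript coordinates) and `utr3_length`.
#' @export
readGtfModels <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    transcriptModelsFromRanges(gr)
}

#' Build a transcript-model table from annotation ranges
#'
#' @param gr a `GRanges` with metadata columns `type` (`"exon"`/`"CDS"`),
#'   `transcript_id` and `gene_id`, using 1-based inclusive coordinates as
#'   returned by [rtracklayer::import()].
#' @return see [readGtfModels()].
#' @export
transcriptModelsFromRanges <- function(gr) {
    keep <- as.character(gr$type) %in% c("exon", "CDS")
    gr <- gr[keep]
    if (length(gr) == 0L) {
        return(data.frame(
            transcript_id = character(), gene_id = character(),
            chrom = character(), strand = character(),
            tx_start = integer(), tx_end = integer(),
            coding_start = integer(), cds_length = integer(),
            exonic_length = integer(), utr5_annot = integer(),
            utr3_length = integer()
        ))
    }
    if (is.null(gr$transcript_id) || is.null(gr$gene_id) ||
        anyNA(gr$transcript_id) || anyNA(gr$gene_id))
        stop("annotation records must carry transcript_id and gene_id")
    df <- data.frame(
        transcript_id = as.character(gr$transcript_id),
        gene_id = as.character(gr$gene_id),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        strand = as.character(GenomicRanges::strand(gr)),
        type = as.character(gr$type),
        start0 = GenomicRanges::start(gr) - 1L,   # 0-based half-open
        end0 = GenomicRanges::end(gr),
        stringsAsFactors = FALSE
    )
    per_tx <- split(df, df$transcript_id)
    rows <- lapply(per_tx, function(d) {
        ex <- d[d$type == "exon", , drop = FALSE]
        if (nrow(ex) == 0L) ex <- d   # CDS-only annotation
        cds <- d[d$type == "CDS", , drop = FALSE]
        strand <- ex$strand[1L]
        tx_start <- min(ex$start0)
        tx_end <- max(ex$end0)
        exonic_length <- sum(ex$end0 - ex$start0)
        if (nrow(cds) > 0L) {
            cds_length <- sum(cds$end0 - cds$start0)
            coding_start <- if (strand == "+") min(cds$start0)
                else max(cds$end0) - 1L
            # exonic bases strictly upstream of the coding start,
            # in transcription order
            utr5_annot <- if (strand == "+") {
                sum(pmax(0L, pmin(ex$end0, coding_start) - ex$start0))
            } else {
                sum(pmax(0L, ex$end0 - pmax(ex$start0, coding_start + 1L)))
            }
            utr3_length <- exonic_length - utr5_annot - cds_length
        } else {
            cds_length <- 0L
            coding_start <- NA_integer_
            utr5_annot <- NA_integer_
            utr3_length <- NA_integer_
        }
        data.frame(
            transcript_id = ex$transcript_id[1L], gene_id = ex$gene_id[1L],
            chrom = ex$chrom[1L], strand = strand,
            tx_start = tx_start, tx_end = tx_end,
            coding_start = coding_start, cds_length = cds_length,
            exonic_length = exonic_length, utr5_annot = utr5_annot,
            utr3_length = utr3_length, stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Read a transcript abundance table
#'
#' @param path TSV with columns `transcript_id`, `gene_id`, `tpm` and
#'   optionally `fpkm`.
#' @return a `data.frame`.
#' @export
readAbundance <- function(path) {
    df <- .readTsv(path)
    required <- c("transcript_id", "gene_id", "tpm")
    missing_cols <- setdiff(required, colnames(df))
    if (length(missing_cols) > 0L)
        stop("abundance table is missing column(s): ",
            paste(missing_cols, collapse = ", "))
    df
}

#' Read CDS sequences from a FASTA file
#'
#' @param path FASTA of coding sequences named by transcript id.
#' @return a [Biostrings::DNAStringSet].
#' @export
readCdsFasta <- function(path) {
    Biostrings::readDNAStringSet(path)
}

#' Select each gene's principal (most abundant) transcript
#'
#' For every gene, returns the transcript with the maximal TPM in the
#' reference tissue. Ties (including all-zero genes) resolve to the
#' lexicographically smallest transcript id, so the choice is deterministic.
#'
#' @param abundance `data.frame` with columns `transcript_id`, `gene_id`,
#'   `tpm`. Every transcript must map to exactly one gene.
#' @return named character vector: `gene_id -> transcript_id`.
#' @examples
#' ab <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g",
#'                  tpm = c(5, 9.2))
#' selectPrincipalTranscript(ab)
#' @export
selectPrincipalTranscript <- function(abundance) {
    required <- c("transcript_id", "gene_id", "tpm")
    missing_cols <- setdiff(required, colnames(abundance))
    if (length(missing_cols) > 0L)
        stop("abundance table is missing column(s): ",
            paste(missing_cols, collapse = ", "))
    tx <- as.character(abundance$transcript_id)
    gid <- as.character(abundance$gene_id)
    tpm <- abundance$tpm
    if (anyNA(tx) || anyNA(gid) || any(gid == "") || any(tx == ""))
        stop("every transcript must map to exactly one gene")
    if (anyDuplicated(tx)) {
        n_genes <- vapply(split(gid, tx), function(g) length(unique(g)),
            integer(1))
        if (any(n_genes > 1L))
            stop("transcript(s) mapped to multiple genes: ",
                paste(names(n_genes)[n_genes > 1L], collapse = ", "))
        stop("duplicated transcript_id in abundance table")
    }
    if (any(is.na(tpm)) || any(tpm < 0))
        stop("abundances must be non-negative")
    # order by gene, then descending tpm, then transcript id: first row per
    # gene is the principal transcript under the documented tie-break
    o <- order(gid, -tpm, tx, method = "radix")
    first <- !duplicated(gid[o])
    ans <- tx[o][first]
    names(ans) <- gid[o][first]
    ans[order(names(ans))]
}

#' GC fraction of coding sequences
#'
#' Computes (G + C) / (A + C + G + T) case-insensitively; `N` bases are
#' excluded from both numerator and denominator. An all-N (or empty after
#' exclusion) sequence yields `NA`, not zero.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet].
#' @return numeric vector of fractions in `[0, 1]` (or `NA`).
#' @examples
#' computeGC(c("ATGC", "GGGG", "NNNN"))
#' @export
computeGC <- function(sequences) {
    if (!methods::is(sequences, "DNAStringSet")) {
        sequences <- as.character(sequences)
        if (any(nchar(sequences) == 0L))
            stop("sequences must be non-empty")
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    } else if (any(Biostrings::width(sequences) == 0L)) {
        stop("sequences must be non-empty")
    }
    freq <- Biostrings::alphabetFrequency(sequences, baseOnly = TRUE)
    acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
    denom <- rowSums(acgt)
    ans <- (acgt[, "G"] + acgt[, "C"]) / denom
    ans[denom == 0] <- NA_real_
    unname(ans)
}

#' Build the per-gene annotation table
#'
#' Resolves the principal transcript per gene, attaches its lengths and the
#' GC content of its CDS, and carries that transcript's TPM/FPKM. Genes whose
#' CDS sequence is absent from `cdsSeqs`, or whose sequence length disagrees
#' with the annotated CDS length, are flagged (`flagged = TRUE`) and kept so
#' the pipeline can continue.
#'
#' @param models transcript-model table from [readGtfModels()].
#' @param abundance abundance table (see [readAbundance()]); FPKM optional.
#' @param cdsSeqs optional `DNAStringSet` of CDS sequences named by
#'   transcript id (gene ids also accepted).
#' @param useAnnotatedUtr5 logical; if `TRUE`, `utr5_length` is filled with
#'   the annotated transcript-start to coding-start distance so length
#'   analyses can run without CAGE data. Default leaves it `NA` for the
#'   CAGE-based caller ([callAllTss()]) to fill.
#' @return a [GeneAnnotation-class] with extra columns `gene_length`
#'   (genomic span of the principal transcript) and `flagged`.
#' @export
buildGeneTable <- function(models, abundance, cdsSeqs = NULL,
                           useAnnotatedUtr5 = FALSE) {
    principal <- selectPrincipalTranscript(abundance)
    empty <- data.frame(
        gene_id = character(), principal_transcript = character(),
        transcript_length = integer(), cds_length = integer(),
        utr5_length = integer(), utr3_length = integer(),
        gc_cds = numeric(), tpm = numeric(), fpkm = numeric(),
        gene_length = integer(), flagged = logical()
    )
    if (nrow(models) == 0L || length(principal) == 0L)
        return(GeneAnnotation(empty))
    idx <- match(unname(principal), models$transcript_id)
    if (anyNA(idx))
        stop("principal transcript not resolvable in the model table for ",
            "gene(s): ", paste(names(principal)[is.na(idx)], collapse = ", "))
    m <- models[idx, , drop = FALSE]
    ab_idx <- match(unname(principal), as.character(abundance$transcript_id))
    fpkm <- if ("fpkm" %in% colnames(abundance)) abundance$fpkm[ab_idx]
        else rep(NA_real_, length(ab_idx))
    ann <- data.frame(
        gene_id = names(principal),
        principal_transcript = unname(principal),
        transcript_length = m$exonic_length,
        cds_length = m$cds_length,
        utr5_length = if (useAnnotatedUtr5) m$utr5_annot else NA_integer_,
        utr3_length = m$utr3_length,
        gc_cds = NA_real_,
        tpm = abundance$tpm[ab_idx],
        fpkm = fpkm,
        gene_length = m$tx_end - m$tx_start,
        flagged = FALSE,
        stringsAsFactors = FALSE
    )
    if (!is.null(cdsSeqs)) {
        seq_idx <- match(ann$principal_transcript, names(cdsSeqs))
        seq_idx[is.na(seq_idx)] <-
            match(ann$gene_id, names(cdsSeqs))[is.na(seq_idx)]
        found <- !is.na(seq_idx)
        if (any(found))
            ann$gc_cds[found] <- computeGC(cdsSeqs[seq_idx[found]])
        ann$flagged[!found] <- TRUE
        if (any(!found))
            warning(sum(!found), " gene(s) without a CDS sequence were flagged")
        mismatch <- found &
            Biostrings::width(cdsSeqs)[seq_idx] != ann$cds_length
        mismatch[is.na(mismatch)] <- FALSE
        if (any(mismatch)) {
            warning(sum(mismatch),
                " gene(s) with CDS sequence length inconsistent with the ",
                "annotated CDS length were flagged")
            ann$flagged[mismatch] <- TRUE
        }
    }
    GeneAnnotation(ann)
}

#' Filter to confidently expressed genes
#'
#' Keeps genes whose expression is strictly greater than the threshold
#' (default > 2 FPKM, the high-confidence expression cutoff applied before
#' all length analyses).
#'
#' @param ann a [GeneAnnotation-class].
#' @param threshold expression cutoff (strict `>`).
#' @param measure which column to filter on, `"fpkm"` (default) or `"tpm"`.
#' @return the filtered [GeneAnnotation-class].
#' @export
filterExpressed <- function(ann, threshold = 2, measure = c("fpkm", "tpm")) {
    measure <- match.arg(measure)
    .assertScalarNumber(threshold, "threshold", lo = 0)
    v <- ann[[measure]]
    if (all(is.na(v)))
        stop("column '", measure, "' is not populated")
    keep <- !is.na(v) & v > threshold
    ann[keep, , drop = FALSE]
}

#' Write a gene annotation table to TSV
#'
#' Columns are emitted in the fixed documented order; extra columns follow.
#'
#' @param ann a [GeneAnnotation-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneTable <- function(ann, path) {
    df <- as.data.frame(ann)
    df <- df[, union(.GENE_ANNOTATION_COLS, colnames(df)), drop = FALSE]
    .writeTsv(df, path)
}
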