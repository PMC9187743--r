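# CAGE-pileup transcription start site calling and 5'UTR assignment.
#
# Coordinates are 0-based genomic positions throughout. "Upstream" and
# "downstream" are in transcription order: upstream means a smaller genomic
# coordinate on '+' and a larger one on '-'.

.TSS_STATUSES <- c("called", "excluded_long_utr", "excluded_downstream",
    "no_signal")

# Pull pileup counts for one chrom/strand as a position -> count lookup.
.trackCounts <- function(track, chrom, strand) {
    gr <- pileupPositions(track)
    sel <- as.character(GenomicRanges::seqnames(gr)) == chrom &
        as.character(GenomicRanges::strand(gr)) == strand
    gr <- gr[sel]
    list(pos = GenomicRanges::start(gr) - 1L, count = gr$score)
}

#' Call the transcription start site of one gene from a CAGE pileup
#'
#' Scans from `windowUpstream` bases upstream of the earliest transcript
#' start (in transcription order) down to, but excluding, the most
#' downstream coding start of the gene's transcripts, and returns the
#' position carrying the greatest 5'-end read pile-up. Ties resolve to the
#' position closest to the coding start (most downstream on the gene
#' strand), giving the shortest 5'UTR. A window with no reads yields `NA`.
#'
#' @param geneModels transcript-model rows (see [readGtfModels()]) for a
#'   single gene; all transcripts must share the gene's strand and have a
#'   coding start.
#' @param track a [CageTrack-class] whose strand matches the gene's.
#' @param windowUpstream scan distance upstream of the earliest transcript
#'   start, in nucleotides (default 1000).
#' @return a list with `position` (0-based genomic coordinate or `NA`) and
#'   `height` (read count at that position, `NA` when no signal).
#' @export
callTss <- function(geneModels, track, windowUpstream = 1000L) {
    if (nrow(geneModels) == 0L)
        stop("empty transcript list")
    strand <- unique(geneModels$strand)
    if (length(strand) != 1L || !strand %in% c("+", "-"))
        stop("all transcripts of a gene must share one strand")
    chrom <- unique(geneModels$chrom)
    if (length(chrom) != 1L)
        stop("all transcripts of a gene must share one chromosome")
    if (anyNA(geneModels$coding_start))
        stop("all transcripts must have a coding start")
    cnt <- .trackCounts(track, chrom, strand)
    if (strand == "+") {
        scan_from <- min(geneModels$tx_start) - as.integer(windowUpstream)
        scan_to <- max(geneModels$coding_start)   # exclusive
        in_win <- cnt$pos >= scan_from & cnt$pos < scan_to
    } else {
        # earliest start in transcription order is the rightmost base
        scan_from <- max(geneModels$tx_end) - 1L + as.integer(windowUpstream)
        scan_to <- min(geneModels$coding_start)   # exclusive
        in_win <- cnt$pos <= scan_from & cnt$pos > scan_to
    }
    pos <- cnt$pos[in_win]
    count <- cnt$count[in_win]
    keep <- count > 0L
    pos <- pos[keep]
    count <- count[keep]
    if (length(pos) == 0L)
        return(list(position = NA_integer_, height = NA_integer_))
    top <- count == max(count)
    cand <- pos[top]
    position <- if (strand == "+") max(cand) else min(cand)
    list(position = position, height = max(count))
}

#' Assign a 5'UTR from a called TSS
#'
#' Among transcripts whose coding start lies strictly downstream of the TSS
#' (strand-aware), picks the one with the smallest TSS-to-coding-start
#' distance; that distance is the 5'UTR length. A TSS at or downstream of
#' any transcript's coding start is excluded (`excluded_downstream`; a 0-nt
#' 5'UTR counts as excluded), and a 5'UTR longer than 500 nt is excluded
#' (`excluded_long_utr`).
#'
#' @param tss 0-based genomic TSS position, or `NA` for no signal.
#' @param geneModels transcript-model rows for the gene (see [callTss()]).
#' @param maxUtr5 exclusion threshold on the 5'UTR length (default 500 nt).
#' @return a one-row `data.frame` with `tss_position`, `chosen_transcript`,
#'   `utr5_length` and `status` (one of `called`, `excluded_long_utr`,
#'   `excluded_downstream`, `no_signal`).
#' @export
assignUtr5 <- function(tss, geneModels, maxUtr5 = 500L) {
    out <- data.frame(
        tss_position = NA_integer_, chosen_transcript = NA_character_,
        utr5_length = NA_integer_, status = "no_signal",
        stringsAsFactors = FALSE
    )
    if (length(tss) != 1L || is.na(tss))
        return(out)
    strand <- geneModels$strand[1L]
    dist <- if (strand == "+") geneModels$coding_start - tss
        else tss - geneModels$coding_start
    out$tss_position <- as.integer(tss)
    if (min(dist) <= 0L) {
        out$status <- "excluded_downstream"
        return(out)
    }
    pick <- which.min(dist)
    out$chosen_transcript <- geneModels$transcript_id[pick]
    out$utr5_length <- as.integer(dist[pick])
    out$status <- if (dist[pick] > maxUtr5) "excluded_long_utr" else "called"
    out
}

#' Call TSS and 5'UTR for every gene
#'
#' Applies [callTss()] then [assignUtr5()] per gene and tabulates outcomes.
#'
#' @param models transcript-model table covering all genes.
#' @param track a [CageTrack-class].
#' @param windowUpstream see [callTss()].
#' @param maxUtr5 see [assignUtr5()].
#' @return a list with `calls` (a `data.frame`: `gene_id`, `tss_position`,
#'   `pileup_height`, `chosen_transcript`, `utr5_length`, `status`) and
#'   `summary` (named integer counts per status, summing to the gene count).
#' @export
callAllTss <- function(models, track, windowUpstream = 1000L,
                       maxUtr5 = 500L) {
    per_gene <- split(models, models$gene_id)
    rows <- lapply(names(per_gene), function(gid) {
        gm <- per_gene[[gid]]
        hit <- callTss(gm, track, windowUpstream = windowUpstream)
        call <- assignUtr5(hit$position, gm, maxUtr5 = maxUtr5)
        cbind(
            data.frame(gene_id = gid, stringsAsFactors = FALSE),
            call[, "tss_position", drop = FALSE],
            data.frame(pileup_height = hit$height),
            call[, c("chosen_transcript", "utr5_length", "status")]
        )
    })
    calls <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
        gene_id = character(), tss_position = integer(),
        pileup_height = integer(), chosen_transcript = character(),
        utr5_length = integer(), status = character()
    )
    rownames(calls) <- NULL
    summary <- vapply(.TSS_STATUSES, function(s) sum(calls$status == s),
        integer(1))
    list(calls = calls, summary = summary)
}

#' Fill CAGE-derived 5'UTR lengths into a gene annotation
#'
#' @param ann a [GeneAnnotation-class].
#' @param calls the `calls` element of [callAllTss()].
#' @return the annotation with `utr5_length` set for genes whose status is
#'   `called` (other genes keep their existing value).
#' @export
applyTssCalls <- function(ann, calls) {
    called <- calls[calls$status == "called", , drop = FALSE]
    idx <- match(ann$gene_id, called$gene_id)
    hit <- !is.na(idx)
    utr5 <- ann$utr5_length
    utr5[hit] <- called$utr5_length[idx[hit]]
    df <- as(ann, "DFrame", strict = TRUE)
    df$utr5_length <- utr5
    GeneAnnotation(df)
}

#' Read strand-specific CAGE pileups from bedGraph files
#'
#' Each file holds per-base (or run-length) 5'-end read counts for one
#' strand; spans wider than one base are expanded to per-base anchors.
#'
#' @param plusPath bedGraph for the `+` strand (or `NULL`).
#' @param minusPath bedGraph for the `-` strand (or `NULL`).
#' @return a [CageTrack-class] combining both strands.
#' @export
readCageBedGraph <- function(plusPath = NULL, minusPath = NULL) {
    expand_one <- function(path, strand) {
        if (is.null(path)) return(NULL)
        gr <- rtracklayer::import(path, format = "bedGraph")
        gr <- gr[gr$score > 0]
        if (length(gr) == 0L) return(NULL)
        w <- GenomicRanges::width(gr)
        pos <- unlist(lapply(seq_along(gr), function(i) {
            seq.int(GenomicRanges::start(gr)[i],
                length.out = w[i]) - 1L
        }))
        data.frame(
            chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
            strand = strand, pos = pos,
            count = rep(as.integer(round(gr$score)), w),
            stringsAsFactors = FALSE
        )
    }
    parts <- rbind(expand_one(plusPath, "+"), expand_one(minusPath, "-"))
    if (is.null(parts))
        return(CageTrack())
    CageTrack(parts$chrom, parts$strand, parts$pos, parts$count)
}

#' Write TSS calls as BED6 and TSV
#'
#' The BED file holds one width-1 interval per called TSS with the gene id
#' as name and the pileup height as score.
#'
#' @param calls the `calls` element of [callAllTss()].
#' @param models transcript-model table (for chrom/strand lookup).
#' @param bedPath,tsvPath output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
writeTssCalls <- function(calls, models, bedPath = NULL, tsvPath = NULL) {
    if (!is.null(tsvPath))
        .writeTsv(calls, tsvPath)
    if (!is.null(bedPath)) {
        called <- calls[calls$status == "called", , drop = FALSE]
        idx <- match(called$gene_id, models$gene_id)
        bed <- data.frame(
            chrom = models$chrom[idx],
            start = called$tss_position,
            end = called$tss_position + 1L,
            name = called$gene_id,
            score = called$pileup_height,
            strand = models$strand[idx]
        )
        utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
    }
    invisible(c(bed = bedPath, tsv = tsvPath))
}
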