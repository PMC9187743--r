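#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors DFrame SimpleList
#' @importClassesFrom GenomicRanges GRanges
NULL

.GENE_ANNOTATION_COLS <- c(
    "gene_id", "principal_transcript", "transcript_length", "cds_length",
    "utr5_length", "utr3_length", "gc_cds", "tpm", "fpkm"
)

.DE_TABLE_COLS <- c("gene_id", "log2fc", "stat", "pvalue", "padj")

#' Per-gene annotation table
#'
#' A `DFrame` subclass holding one row per gene for the principal (most
#' abundant) transcript: transcript/CDS/UTR lengths in nucleotides, the GC
#' fraction of the CDS, and abundance (TPM and FPKM). `utr5_length` may be
#' `NA` until a CAGE-based transcription start site has been assigned (or the
#' annotated fallback requested). Extra columns (for example `gene_length`,
#' the genomic span of the principal transcript, or `flagged`) are allowed.
#'
#' @slot .Data inherited `DFrame` representation.
#' @seealso [buildGeneTable()], [filterExpressed()]
#' @export
setClass("GeneAnnotation", contains = "DFrame")

setValidity("GeneAnnotation", function(object) {
    missing_cols <- setdiff(.GENE_ANNOTATION_COLS, colnames(object))
    if (length(missing_cols) > 0L)
        return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(object$gene_id))
        return("gene_id values must be unique")
    gc <- object$gc_cds
    if (any(!is.na(gc) & (gc < 0 | gc > 1)))
        return("gc_cds must lie in [0, 1]")
    len_cols <- c("transcript_length", "cds_length", "utr5_length", "utr3_length")
    for (cc in len_cols) {
        v <- object[[cc]]
        if (any(!is.na(v) & v < 0)) return(paste(cc, "must be non-negative"))
    }
    bad <- !is.na(object$transcript_length) & !is.na(object$cds_length) &
        object$transcript_length < object$cds_length
    if (any(bad))
        return("transcript_length must be >= cds_length")
    TRUE
})

#' Construct a GeneAnnotation
#'
#' @param table a `data.frame` or `DFrame` with columns `gene_id`,
#'   `principal_transcript`, `transcript_length`, `cds_length`, `utr5_length`,
#'   `utr3_length`, `gc_cds`, `tpm`, `fpkm` (additional columns are kept).
#' @return a [GeneAnnotation-class] object.
#' @examples
#' ann <- GeneAnnotation(data.frame(
#'     gene_id = "g1", principal_transcript = "t1", transcript_length = 1500,
#'     cds_length = 900, utr5_length = 100, utr3_length = 500,
#'     gc_cds = 0.45, tpm = 12, fpkm = 10
#' ))
#' @export
GeneAnnotation <- function(table) {
    ans <- new("GeneAnnotation", DataFrame(table, row.names = NULL))
    validObject(ans)
    ans
}

#' Differential-expression result table for one contrast
#'
#' A `DFrame` subclass with one row per gene: `gene_id`, `log2fc` (moderated
#' log2 fold change as produced by e.g. DESeq2 or a limma effect size),
#' `stat` (test statistic), `pvalue` and `padj` (adjusted p, possibly `NA`
#' where independent filtering removed the gene). The contrast name is kept
#' in a slot.
#'
#' @slot contrastName single string naming the contrast.
#' @seealso [readDeTable()], [significantSet()]
#' @export
setClass("DifferentialTable",
    contains = "DFrame",
    representation(contrastName = "character")
)

setValidity("DifferentialTable", function(object) {
    missing_cols <- setdiff(.DE_TABLE_COLS, colnames(object))
    if (length(missing_cols) > 0L)
        return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(object$gene_id))
        return("gene_id values must be unique")
    p <- object$pvalue
    if (any(!is.na(p) & (p < 0 | p > 1)))
        return("pvalue must lie in [0, 1]")
    pa <- object$padj
    if (any(!is.na(pa) & (pa < 0 | pa > 1)))
        return("padj must lie in [0, 1]")
    if (length(object@contrastName) != 1L)
        return("contrastName must be a single string")
    TRUE
})

#' Construct a DifferentialTable
#'
#' @param table a `data.frame` or `DFrame` with columns `gene_id`, `log2fc`,
#'   `stat`, `pvalue`, `padj`. A missing `padj` or `stat` column is filled
#'   with `NA`.
#' @param contrast name of the contrast (e.g. `"KO_vs_WT_TRAP"`).
#' @return a [DifferentialTable-class] object.
#' @export
DifferentialTable <- function(table, contrast = "contrast") {
    table <- DataFrame(table, row.names = NULL)
    for (cc in c("stat", "padj"))
        if (!cc %in% colnames(table)) table[[cc]] <- NA_real_
    table <- table[, union(.DE_TABLE_COLS, colnames(table))]
    ans <- new("DifferentialTable", table, contrastName = as.character(contrast))
    validObject(ans)
    ans
}

#' Named collection of gene sets
#'
#' A `SimpleList` subclass whose elements are character vectors of gene ids,
#' named by set/term id (as read from a GMT file).
#'
#' @seealso [readGmt()], [sizeFilterSets()], [pruneRedundantTerms()]
#' @export
setClass("GeneSetCollection", contains = "SimpleList")

setValidity("GeneSetCollection", function(object) {
    if (length(object) > 0L) {
        if (is.null(names(object)) || any(names(object) == ""))
            return("all gene sets must be named")
        if (anyDuplicated(names(object)))
            return("gene set names must be unique")
        if (!all(vapply(object, is.character, logical(1))))
            return("gene sets must be character vectors")
    }
    TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids. Duplicate members
#'   within a set are removed.
#' @return a [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(rp = c("g1", "g2"), syn = c("g2", "g3")))
#' @export
GeneSetCollection <- function(sets = list()) {
    sets <- lapply(sets, function(x) unique(as.character(x)))
    ans <- as(SimpleList(sets), "GeneSetCollection")
    validObject(ans)
    ans
}

#' Strand-specific CAGE 5'-end pileup track
#'
#' Wraps a `GRanges` of width-1 positions (0-based positions are stored as
#' 1-based `GRanges` starts) with integer 5'-end read counts in `score` and
#' the read strand set. Positions with zero counts need not be stored.
#'
#' @slot positions `GRanges` of width-1 anchors with integer `score`.
#' @seealso [readCageBedGraph()], [callTss()]
#' @export
setClass("CageTrack", representation(positions = "GRanges"))

setValidity("CageTrack", function(object) {
    gr <- object@positions
    if (length(gr) > 0L) {
        if (!all(GenomicRanges::width(gr) == 1L))
            return("all pileup anchors must have width 1")
        sc <- gr$score
        if (is.null(sc) || any(is.na(sc)) || any(sc < 0) ||
            any(sc != round(sc)))
            return("score must hold non-negative integer counts")
        if (any(GenomicRanges::strand(gr) == "*"))
            return("pileup anchors must be stranded")
    }
    TRUE
})

#' Construct a CageTrack
#'
#' @param chrom character vector of chromosome names.
#' @param strand character vector of `"+"`/`"-"`.
#' @param pos integer vector of 0-based positions of the read 5' ends.
#' @param count integer vector of read counts (> 0 entries suffice).
#' @return a [CageTrack-class] object.
#' @examples
#' trk <- CageTrack("chr1", "+", pos = c(980L, 1005L), count = c(7L, 3L))
#' @export
CageTrack <- function(chrom = character(), strand = character(),
                      pos = integer(), count = integer()) {
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = as.integer(pos) + 1L, width = 1L),
        strand = strand,
        score = as.integer(count)
    )
    ans <- new("CageTrack", positions = gr)
    validObject(ans)
    ans
}

#' @describeIn GeneAnnotation-class number of genes
#' @param x,object a GeneAnnotation
#' @export
setMethod("show", "GeneAnnotation", function(object) {
    cat(sprintf("GeneAnnotation with %d genes\n", nrow(object)))
    callNextMethod()
})

setMethod("show", "DifferentialTable", function(object) {
    cat(sprintf("DifferentialTable '%s' with %d genes\n",
        object@contrastName, nrow(object)))
    callNextMethod()
})

setMethod("show", "GeneSetCollection", function(object) {
    sizes <- lengths(object)
    cat(sprintf("GeneSetCollection with %d sets", length(object)))
    if (length(object) > 0L)
        cat(sprintf(" (sizes %d-%d)", min(sizes), max(sizes)))
    cat("\n")
})

setMethod("show", "CageTrack", function(object) {
    gr <- object@positions
    cat(sprintf(
        "CageTrack: %d non-zero positions, %d reads, strands {%s}\n",
        length(gr), sum(gr$score),
        paste(unique(as.character(GenomicRanges::strand(gr))), collapse = ",")
    ))
})
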