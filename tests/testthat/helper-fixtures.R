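# Small fixtures built in code.

# Two-gene annotation: g1 on '+' with two exons, g2 on '-' single exon.
# Hand-derived values:
#   g1/t1: exons [100,200)+[300,400), CDS [150,200)+[300,350)
#          exonic 200, cds 100, coding_start0 150, utr5 50, utr3 50
#   g2/t2: exon [1000,1100), CDS [1020,1080)
#          exonic 100, cds 60, coding_start0 1079, utr5 20, utr3 20
toyGtfLines <- function() {
    f <- function(chrom, src, type, start1, end1, strand, tx, gene) {
        sprintf(
            "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            chrom, src, type, start1, end1, strand, gene, tx)
    }
    c(
        f("chr1", "toy", "exon", 101, 200, "+", "t1", "g1"),
        f("chr1", "toy", "exon", 301, 400, "+", "t1", "g1"),
        f("chr1", "toy", "CDS", 151, 200, "+", "t1", "g1"),
        f("chr1", "toy", "CDS", 301, 350, "+", "t1", "g1"),
        f("chr1", "toy", "exon", 1001, 1100, "-", "t2", "g2"),
        f("chr1", "toy", "CDS", 1021, 1080, "-", "t2", "g2")
    )
}

writeToyGtf <- function(path = tempfile(fileext = ".gtf")) {
    writeLines(toyGtfLines(), path)
    path
}

# Single-transcript model rows for TSS tests (0-based half-open).
makeModel <- function(transcript_id, gene_id, strand, tx_start, tx_end,
                      coding_start, chrom = "chr1") {
    data.frame(
        transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
        strand = strand, tx_start = tx_start, tx_end = tx_end,
        coding_start = coding_start,
        cds_length = 90L, exonic_length = tx_end - tx_start,
        utr5_annot = NA_integer_, utr3_length = NA_integer_,
        stringsAsFactors = FALSE
    )
}

makeDe <- function(gene_id, log2fc, pvalue = NULL, padj = NULL,
                   contrast = "test") {
    n <- length(gene_id)
    if (is.null(pvalue)) pvalue <- rep(0.5, n)
    if (is.null(padj)) padj <- rep(NA_real_, n)
    DifferentialTable(data.frame(
        gene_id = gene_id, log2fc = log2fc, stat = log2fc,
        pvalue = pvalue, padj = padj, stringsAsFactors = FALSE
    ), contrast = contrast)
}

makeAnn <- function(gene_id, cds_length, gene_length = NULL,
                    fpkm = NULL, tpm = NULL) {
    n <- length(gene_id)
    if (is.null(gene_length)) gene_length <- cds_length * 10L
    if (is.null(fpkm)) fpkm <- rep(10, n)
    if (is.null(tpm)) tpm <- rep(10, n)
    GeneAnnotation(data.frame(
        gene_id = gene_id, principal_transcript = paste0(gene_id, ".t1"),
        transcript_length = cds_length + 200L, cds_length = cds_length,
        utr5_length = rep(100L, n), utr3_length = rep(100L, n),
        gc_cds = rep(0.5, n), tpm = tpm, fpkm = fpkm,
        gene_length = gene_length, stringsAsFactors = FALSE
    ))
}
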