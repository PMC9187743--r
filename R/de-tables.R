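# Ingestion of differential-expression / proteome result tables and the
# cross-table operations: TRAP/total ratios, significance sets, consistent
# direction genes, contrast correlation, hypergeometric overlaps.

#' Read a differential-expression result table
#'
#' Expects a TSV with columns `gene_id`, `log2fc`, `pvalue` and optionally
#' `stat` and `padj` (absent optional columns are filled with `NA`). Rows
#' with unparseable numeric fields are dropped with a message.
#'
#' @param path TSV path.
#' @param contrast contrast name stored in the returned object.
#' @return a [DifferentialTable-class].
#' @export
readDeTable <- function(path, contrast = basename(path)) {
    df <- .readTsv(path)
    required <- c("gene_id", "log2fc", "pvalue")
    missing_cols <- setdiff(required, colnames(df))
    if (length(missing_cols) > 0L)
        stop("differential table is missing column(s): ",
            paste(missing_cols, collapse = ", "))
    for (cc in c("log2fc", "stat", "pvalue", "padj")) {
        if (cc %in% colnames(df) && !is.numeric(df[[cc]]))
            df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    }
    bad <- is.na(df$log2fc) | is.na(df$pvalue)
    if (any(bad)) {
        message("dropped ", sum(bad), " row(s) with unparseable numerics")
        df <- df[!bad, , drop = FALSE]
    }
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    if (length(dup) > 0L)
        stop("duplicated gene_id in differential table: ",
            paste(utils::head(dup, 10L), collapse = ", "))
    DifferentialTable(df, contrast = contrast)
}

#' Per-gene TRAP over total count ratios
#'
#' For each matched TRAP/total sample pair, divides the (normalized) TRAP
#' count by the total count, gene by gene. Pairs where the total count is
#' zero yield `NA` for that gene.
#'
#' @param trap,total numeric matrices (genes x samples) with identical
#'   rownames; non-negative normalized counts.
#' @param pairing `data.frame` with columns `trap` and `total` naming the
#'   matched columns of each matrix. Defaults to positional pairing when the
#'   two matrices have the same number of columns.
#' @return matrix of ratios, one column per pair (named after the TRAP
#'   sample).
#' @export
trapOverTotal <- function(trap, total, pairing = NULL) {
    if (!identical(rownames(trap), rownames(total)))
        stop("trap and total matrices must share identical rownames")
    if (is.null(pairing)) {
        if (ncol(trap) != ncol(total))
            stop("without 'pairing', trap and total need equal column counts")
        pairing <- data.frame(trap = colnames(trap), total = colnames(total))
    }
    bad_t <- setdiff(pairing$trap, colnames(trap))
    bad_n <- setdiff(pairing$total, colnames(total))
    if (length(bad_t) > 0L || length(bad_n) > 0L)
        stop("unmatched sample(s) in pairing: ",
            paste(c(bad_t, bad_n), collapse = ", "))
    if (any(trap < 0) || any(total < 0))
        stop("counts must be non-negative")
    ratio <- trap[, pairing$trap, drop = FALSE] /
        total[, pairing$total, drop = FALSE]
    ratio[total[, pairing$total, drop = FALSE] == 0] <- NA_real_
    colnames(ratio) <- pairing$trap
    ratio
}

#' Significantly regulated gene set
#'
#' Genes with adjusted p strictly below `alphaAdj` (missing `padj`, as left
#' by DESeq2 independent filtering, counts as non-significant) and a fold
#' change matching `direction`.
#'
#' @param de a [DifferentialTable-class].
#' @param alphaAdj adjusted-p threshold (strict `<`; default 0.1, the
#'   standard DESeq2 FDR cutoff).
#' @param direction `"both"`, `"up"` (log2fc > 0) or `"down"` (log2fc < 0).
#' @return character vector of gene ids.
#' @export
significantSet <- function(de, alphaAdj = 0.1,
                           direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    .assertScalarNumber(alphaAdj, "alphaAdj", lo = 0, hi = 1)
    keep <- !is.na(de$padj) & de$padj < alphaAdj
    keep <- keep & switch(direction,
        both = TRUE,
        up = de$log2fc > 0,
        down = de$log2fc < 0
    )
    de$gene_id[keep]
}

#' Genes regulated in the same direction in every table
#'
#' Restricted to genes present in all tables; `up` holds genes with
#' log2fc > 0 in every table, `down` those with log2fc < 0 in every table.
#'
#' @param tables list of two or more [DifferentialTable-class] objects
#'   (e.g. the per-pair TRAP/total ratios of one experiment fitted
#'   pair-wise).
#' @return list with disjoint character vectors `up` and `down`.
#' @export
consistentDirectionGenes <- function(tables) {
    if (length(tables) < 2L)
        stop("need at least two tables")
    shared <- Reduce(intersect, lapply(tables, geneIds))
    signs <- vapply(tables, function(tt) {
        tt$log2fc[match(shared, tt$gene_id)]
    }, numeric(length(shared)))
    if (length(shared) == 1L) signs <- matrix(signs, nrow = 1L)
    list(
        up = shared[rowSums(signs > 0) == length(tables)],
        down = shared[rowSums(signs < 0) == length(tables)]
    )
}

#' Pearson correlation of log2 fold changes between two contrasts
#'
#' @param tableA,tableB [DifferentialTable-class] objects.
#' @param genes optional gene subset (default: genes shared by both tables).
#' @return list with `r`, `pvalue` (two-sided) and `n`. Zero variance in
#'   either vector yields `r = NA` with a warning.
#' @export
correlateContrasts <- function(tableA, tableB, genes = NULL) {
    shared <- intersect(geneIds(tableA), geneIds(tableB))
    if (!is.null(genes)) shared <- intersect(shared, genes)
    if (length(shared) < 3L)
        stop("need at least 3 shared genes")
    x <- tableA$log2fc[match(shared, tableA$gene_id)]
    y <- tableB$log2fc[match(shared, tableB$gene_id)]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero variance in one of the fold-change vectors")
        return(list(r = NA_real_, pvalue = NA_real_, n = length(shared)))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(shared))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail test of the observed overlap: `p = P[X >= k]` with
#' `X ~ Hypergeometric(universe, |A|, |B|)`.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universe either a character vector containing both sets, or a
#'   single integer universe size (then the sets are assumed to lie within
#'   it).
#' @return list with `overlap`, `pvalue`, `setA`, `setB` and `universe`
#'   sizes.
#' @export
overlapTest <- function(setA, setB, universe) {
    setA <- unique(as.character(setA))
    setB <- unique(as.character(setB))
    if (is.character(universe)) {
        universe <- unique(universe)
        if (length(setdiff(setA, universe)) > 0L ||
            length(setdiff(setB, universe)) > 0L)
            stop("both sets must lie within the universe")
        n_universe <- length(universe)
    } else {
        n_universe <- as.integer(universe)
        if (length(setA) > n_universe || length(setB) > n_universe)
            stop("both sets must lie within the universe")
    }
    k <- length(intersect(setA, setB))
    p <- stats::phyper(k - 1L, length(setA), n_universe - length(setA),
        length(setB), lower.tail = FALSE)
    list(overlap = k, pvalue = p, setA = length(setA), setB = length(setB),
        universe = n_universe)
}
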