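# CDS-length translation-bias framework: length bins with KS tests, top-N
# up/down length comparisons, length-ranked gene-set analysis, and the
# CDS-vs-gene-length threshold classification.

#' Bin genes by CDS length
#'
#' Default bins are <1 kb, 1-2 kb, 2-4 kb and >4 kb, half-open on the right
#' (`[lo, hi)`), so a 1000-nt CDS falls in the 1-2 kb bin. Genes with a
#' missing CDS length are excluded with a message.
#'
#' @param ann a [GeneAnnotation-class] (or any table with `gene_id` and
#'   `cds_length`).
#' @param edges increasing bin edges in nt, starting at 0 and ending at
#'   `Inf`.
#' @return `data.frame` with `gene_id`, `cds_length` and `bin` (ordered
#'   factor labelled e.g. `"<1kb"`, `"1-2kb"`, `"2-4kb"`, `">4kb"`).
#' @export
binByCdsLength <- function(ann, edges = c(0, 1000, 2000, 4000, Inf)) {
    if (is.unsorted(edges, strictly = TRUE) || edges[1] != 0 ||
        !is.infinite(edges[length(edges)]))
        stop("'edges' must increase strictly from 0 to Inf")
    len <- ann[["cds_length"]]
    gid <- ann[["gene_id"]]
    drop <- is.na(len)
    if (any(drop)) {
        message("excluded ", sum(drop), " gene(s) with missing CDS length")
        len <- len[!drop]
        gid <- gid[!drop]
    }
    kb <- function(x) {
        ifelse(is.infinite(x), "", sub("\\.?0*$", "", sprintf("%.1f", x / 1000)))
    }
    n_bins <- length(edges) - 1L
    labels <- character(n_bins)
    labels[1] <- paste0("<", kb(edges[2]), "kb")
    labels[n_bins] <- paste0(">", kb(edges[n_bins]), "kb")
    if (n_bins > 2L)
        labels[2:(n_bins - 1L)] <- paste0(kb(edges[2:(n_bins - 1L)]), "-",
            kb(edges[3:n_bins]), "kb")
    bin <- cut(len, breaks = edges, labels = labels, right = FALSE,
        include.lowest = FALSE, ordered_result = TRUE)
    data.frame(gene_id = gid, cds_length = len, bin = bin,
        stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `d` is the supremum of the absolute ECDF difference; the p-value is the
#' two-sided asymptotic Kolmogorov approximation, as used to compare fold
#' change distributions between the shortest and longest CDS bins.
#'
#' @param x,y numeric samples (each at least `minN` values).
#' @param minN minimum sample size (default 2).
#' @return list with `d` and `pvalue`.
#' @export
ksTwoSample <- function(x, y, minN = 2L) {
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < minN || length(y) < minN)
        stop("both samples need at least ", minN, " values")
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    list(d = unname(kt$statistic), pvalue = kt$p.value)
}

#' Top-N length comparison of up- and downregulated genes
#'
#' Selects the `n` most up- and the `n` most downregulated genes of a
#' contrast and compares their log2(CDS length) against the whole detected
#' universe (and against each other) with two-sample z tests. A negative
#' up-vs-all z means the upregulated population is shorter than average.
#'
#' @param de a [DifferentialTable-class].
#' @param ann a [GeneAnnotation-class]; only genes present in both are used.
#' @param n genes per tail (default 500).
#' @param rankBy `"log2fc"` (top/bottom of the fold-change ranking) or
#'   `"pvalue_signed"` (most significant genes separately within each fold
#'   change sign).
#' @param logScale compare `log2(cds_length)` (default, matching how length
#'   distributions are plotted) or raw lengths.
#' @return `data.frame` with one row per comparison (`up_vs_all`,
#'   `down_vs_all`, `up_vs_down`): `z`, `pvalue`, `n_group`, `n_reference`,
#'   `mean_group`, `mean_reference`. The reference for the `*_vs_all` rows
#'   is the whole universe including the selected tails.
#' @export
topNLengthComparison <- function(de, ann, n = 500L,
                                 rankBy = c("log2fc", "pvalue_signed"),
                                 logScale = TRUE) {
    rankBy <- match.arg(rankBy)
    shared <- intersect(geneIds(de), geneIds(ann))
    if (length(shared) < 2L * n)
        stop("universe (", length(shared), ") smaller than 2*n; ",
            "use a smaller n")
    lfc <- de$log2fc[match(shared, de$gene_id)]
    pval <- de$pvalue[match(shared, de$gene_id)]
    len <- ann$cds_length[match(shared, ann$gene_id)]
    ok <- !is.na(len) & len > 0
    shared <- shared[ok]; lfc <- lfc[ok]; pval <- pval[ok]; len <- len[ok]
    if (length(shared) < 2L * n)
        stop("universe after removing missing lengths smaller than 2*n")
    lenv <- if (logScale) log2(len) else len
    if (rankBy == "log2fc") {
        o <- order(-lfc, shared, method = "radix")
        up_idx <- o[seq_len(n)]
        down_idx <- rev(o)[seq_len(n)]
    } else {
        up_pool <- which(lfc > 0)
        down_pool <- which(lfc < 0)
        if (length(up_pool) < n || length(down_pool) < n)
            stop("fewer than n genes in one fold-change sign")
        up_idx <- up_pool[order(pval[up_pool], shared[up_pool],
            method = "radix")][seq_len(n)]
        down_idx <- down_pool[order(pval[down_pool], shared[down_pool],
            method = "radix")][seq_len(n)]
    }
    cmp <- function(gi, ref, label) {
        zt <- twoSampleZ(lenv[gi], lenv[ref])
        data.frame(
            comparison = label, z = zt$z, pvalue = zt$pvalue,
            n_group = zt$nx, n_reference = zt$ny,
            mean_group = mean(lenv[gi]), mean_reference = mean(lenv[ref]),
            stringsAsFactors = FALSE
        )
    }
    all_idx <- seq_along(shared)
    out <- rbind(
        cmp(up_idx, all_idx, "up_vs_all"),
        cmp(down_idx, all_idx, "down_vs_all"),
        cmp(up_idx, down_idx, "up_vs_down")
    )
    rownames(out) <- NULL
    out
}

#' Length-ranked gene-set analysis
#'
#' Ranks the detected universe by CDS length and runs the mean-rank gene-set
#' statistic in two orientations - top rank given to the shortest gene, and
#' top rank given to the longest gene - over sets of 20-50 members (after
#' intersection with the universe). Reports the top terms per orientation
#' sorted by p-value then enrichment magnitude.
#'
#' @param ann a [GeneAnnotation-class].
#' @param sets a [GeneSetCollection-class].
#' @param minSize,maxSize set-size filter (defaults 20 and 50).
#' @param nPerm permutations per set.
#' @param seed master seed.
#' @param topN how many top terms to report per orientation (default 7).
#' @return list with `shortest_first` and `longest_first`: each a
#'   `data.frame` of the top terms, plus `full` holding both complete
#'   result tables.
#' @export
lengthRankedGsa <- function(ann, sets, minSize = 20L, maxSize = 50L,
                            nPerm = 1000L, seed = NULL, topN = 7L) {
    len <- ann$cds_length
    names(len) <- ann$gene_id
    len <- len[!is.na(len) & len > 0]
    run <- function(orientation, offset) {
        runSetStats(len, sets, method = "mean_rank", minSize = minSize,
            maxSize = maxSize, nPerm = nPerm,
            seed = if (is.null(seed)) NULL else childSeed(seed, offset),
            orientation = orientation)
    }
    # ascending: smallest length at rank 1 = shortest-first
    short_first <- run("ascending", 1L)
    long_first <- run("descending", 2L)
    list(
        shortest_first = utils::head(short_first, topN),
        longest_first = utils::head(long_first, topN),
        full = list(shortest_first = short_first, longest_first = long_first)
    )
}

#' CDS-length versus gene-length classification table
#'
#' Cross-tabulates a gene set by CDS length and genomic gene length against
#' fixed thresholds: `log2(CDS length) = 11` (2048 nt) and
#' `log2(gene length) = 16` (65536 nt), `>=` on the high side. Used to ask
#' whether the CDS, and not the gene span, carries a length effect.
#'
#' @param ann a [GeneAnnotation-class] carrying a `gene_length` column.
#' @param geneSet character vector of gene ids (default: all genes).
#' @param cdsThreshold,geneThreshold thresholds in nt.
#' @return 2x2 integer matrix with rows `cds_short`/`cds_long` and columns
#'   `gene_short`/`gene_long`.
#' @export
lengthGroupTable <- function(ann, geneSet = NULL,
                             cdsThreshold = 2^11, geneThreshold = 2^16) {
    if (!"gene_length" %in% colnames(ann))
        stop("annotation must carry a 'gene_length' column")
    keep <- if (is.null(geneSet)) rep(TRUE, nrow(ann))
        else ann$gene_id %in% geneSet
    keep <- keep & !is.na(ann$cds_length) & !is.na(ann$gene_length)
    cds_long <- ann$cds_length[keep] >= cdsThreshold
    gene_long <- ann$gene_length[keep] >= geneThreshold
    out <- matrix(c(
        sum(!cds_long & !gene_long), sum(!cds_long & gene_long),
        sum(cds_long & !gene_long), sum(cds_long & gene_long)
    ), nrow = 2L, byrow = TRUE,
        dimnames = list(c("cds_short", "cds_long"),
            c("gene_short", "gene_long")))
    out
}

#' Binned fold-change report
#'
#' Summarises the log2 fold change distribution per CDS-length bin and runs
#' the KS test between the shortest and longest bins.
#'
#' @param de a [DifferentialTable-class].
#' @param ann a [GeneAnnotation-class].
#' @param edges bin edges (see [binByCdsLength()]).
#' @return list with `per_bin` (`data.frame`: bin, n, median/mean log2fc)
#'   and `ks_extreme` (the [ksTwoSample()] result for first vs last bin).
#' @export
lengthBinReport <- function(de, ann, edges = c(0, 1000, 2000, 4000, Inf)) {
    shared <- intersect(geneIds(de), geneIds(ann))
    sub <- ann[match(shared, ann$gene_id), , drop = FALSE]
    bins <- binByCdsLength(sub, edges)
    lfc <- de$log2fc[match(bins$gene_id, de$gene_id)]
    per_bin <- do.call(rbind, lapply(levels(bins$bin), function(b) {
        v <- lfc[bins$bin == b]
        data.frame(bin = b, n = length(v),
            median_log2fc = stats::median(v), mean_log2fc = mean(v),
            stringsAsFactors = FALSE)
    }))
    first_bin <- levels(bins$bin)[1]
    last_bin <- levels(bins$bin)[length(levels(bins$bin))]
    ks <- ksTwoSample(lfc[bins$bin == first_bin], lfc[bins$bin == last_bin])
    list(per_bin = per_bin, ks_extreme = ks)
}
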