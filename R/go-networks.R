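# GO-term sign-imbalance z scores, population comparison against the
# all-term null, redundancy pruning, term-network construction and
# edge-betweenness clustering.

#' Sign-imbalance z score for one functional term
#'
#' `z = (n_up - n_down) / sqrt(n_total)` where `n_total` is the number of
#' the term's genes detected in the contrast. With
#' `classification = "sign"` (default), up/down membership is the sign of
#' the log2 fold change (genes with exactly zero fold change count in
#' neither group); with `"significance"`, only genes with `padj < alpha`
#' are counted as up/down, the rest contribute only to `n_total`.
#'
#' @param termGenes character vector of the term's gene ids.
#' @param de a [DifferentialTable-class].
#' @param classification `"sign"` or `"significance"`.
#' @param alpha adjusted-p threshold for the significance mode.
#' @return one-row `data.frame`: `n_up`, `n_down`, `n_total`, `z` (`NA`
#'   when the term has no detected genes).
#' @export
termZScore <- function(termGenes, de,
                       classification = c("sign", "significance"),
                       alpha = 0.1) {
    classification <- match.arg(classification)
    idx <- match(intersect(termGenes, geneIds(de)), de$gene_id)
    n_total <- length(idx)
    if (n_total == 0L) {
        return(data.frame(n_up = NA_integer_, n_down = NA_integer_,
            n_total = 0L, z = NA_real_))
    }
    lfc <- de$log2fc[idx]
    counted <- if (classification == "sign") {
        rep(TRUE, n_total)
    } else {
        padj <- de$padj[idx]
        !is.na(padj) & padj < alpha
    }
    n_up <- sum(counted & lfc > 0)
    n_down <- sum(counted & lfc < 0)
    data.frame(n_up = n_up, n_down = n_down, n_total = n_total,
        z = (n_up - n_down) / sqrt(n_total))
}

#' Sign-imbalance z scores for a collection of terms
#'
#' @param sets a [GeneSetCollection-class].
#' @inheritParams termZScore
#' @return `data.frame` with `term_id`, `n_up`, `n_down`, `n_total`, `z`.
#' @export
termZScores <- function(sets, de,
                        classification = c("sign", "significance"),
                        alpha = 0.1) {
    classification <- match.arg(classification)
    rows <- lapply(names(sets), function(nm) {
        cbind(data.frame(term_id = nm, stringsAsFactors = FALSE),
            termZScore(sets[[nm]], de, classification, alpha))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Compare target-term z scores against the all-term null distribution
#'
#' A two-sample z test of the target terms' sign-imbalance scores against
#' the scores of all terms detected in the comparison, asking whether the
#' target family (e.g. the LTD-downregulated terms) is shifted as a
#' population.
#'
#' @param targetZ numeric vector of target-term z scores.
#' @param allZ numeric vector of all-term z scores (the null population).
#' @return list with `z`, `pvalue`, `nx`, `ny` (see [twoSampleZ()]).
#' @export
zscorePopulationTest <- function(targetZ, allZ) {
    twoSampleZ(targetZ, allZ)
}

#' Remove redundant terms sharing most of their genes
#'
#' For any pair whose overlap fraction `|A n B| / min(|A|, |B|)` is at
#' least `overlapFraction`, the smaller term (lexicographically later on a
#' size tie) is removed. Pairs are scanned greedily by descending overlap
#' fraction (ties by term id), so the result is deterministic; no surviving
#' pair violates the criterion, and pruning is idempotent.
#'
#' @param sets a [GeneSetCollection-class].
#' @param overlapFraction threshold (default 0.9).
#' @return list with `sets` (the pruned [GeneSetCollection-class]) and
#'   `removed` (`data.frame`: removed term, the term kept, the overlap
#'   fraction).
#' @export
pruneRedundantTerms <- function(sets, overlapFraction = 0.9) {
    nms <- names(sets)
    n <- length(nms)
    removed <- data.frame(removed = character(), kept = character(),
        overlap_fraction = numeric(), stringsAsFactors = FALSE)
    if (n < 2L)
        return(list(sets = sets, removed = removed))
    pairs <- utils::combn(n, 2L)
    frac <- apply(pairs, 2L, function(ij) {
        a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
        length(intersect(a, b)) / min(length(a), length(b))
    })
    hit <- which(frac >= overlapFraction)
    if (length(hit) > 0L) {
        a_id <- nms[pairs[1L, hit]]
        b_id <- nms[pairs[2L, hit]]
        key_a <- pmin(a_id, b_id)
        key_b <- pmax(a_id, b_id)
        o <- order(-frac[hit], key_a, key_b, method = "radix")
        alive <- stats::setNames(rep(TRUE, n), nms)
        for (k in o) {
            a <- a_id[k]; b <- b_id[k]
            if (!alive[[a]] || !alive[[b]]) next
            la <- length(sets[[a]]); lb <- length(sets[[b]])
            # drop the smaller set; on a size tie the lexicographically
            # later term id goes
            drop <- if (la < lb) a
                else if (lb < la) b
                else max(a, b)
            alive[[drop]] <- FALSE
            removed <- rbind(removed, data.frame(
                removed = drop, kept = if (drop == a) b else a,
                overlap_fraction = frac[hit][k], stringsAsFactors = FALSE))
        }
        sets <- GeneSetCollection(as.list(sets)[names(alive)[alive]])
    }
    list(sets = sets, removed = removed)
}

#' Build a term-similarity network
#'
#' Nodes are term ids; an undirected edge joins two terms sharing at least
#' one gene, weighted by the shared-gene count. Optional per-term
#' annotations (e.g. z scores) become node attributes.
#'
#' @param sets a (typically pruned) [GeneSetCollection-class].
#' @param annotations optional `data.frame` with a `term_id` column;
#'   remaining columns become vertex attributes.
#' @return an [igraph::igraph] graph.
#' @export
buildTermNetwork <- function(sets, annotations = NULL) {
    nms <- names(sets)
    n <- length(nms)
    edges <- NULL
    if (n >= 2L) {
        pairs <- utils::combn(n, 2L)
        w <- apply(pairs, 2L, function(ij) {
            length(intersect(sets[[ij[1]]], sets[[ij[2]]]))
        })
        keep <- w >= 1L
        if (any(keep))
            edges <- data.frame(
                from = nms[pairs[1L, keep]], to = nms[pairs[2L, keep]],
                weight = w[keep], stringsAsFactors = FALSE)
    }
    g <- if (is.null(edges)) {
        igraph::make_empty_graph(n = 0, directed = FALSE)
    } else {
        igraph::graph_from_data_frame(edges, directed = FALSE,
            vertices = data.frame(name = nms))
    }
    if (is.null(edges))
        g <- igraph::add_vertices(g, n, name = nms)
    if (!is.null(annotations)) {
        idx <- match(igraph::V(g)$name, annotations$term_id)
        for (cc in setdiff(colnames(annotations), "term_id"))
            g <- igraph::set_vertex_attr(g, cc, value = annotations[[cc]][idx])
    }
    g
}

#' Cluster a term network by edge betweenness
#'
#' Girvan-Newman edge-betweenness community detection with the hierarchy cut
#' at maximal modularity; isolated terms form singleton clusters.
#'
#' @param network an [igraph::igraph] graph from [buildTermNetwork()].
#' @return named integer vector of cluster labels (names are term ids).
#' @export
clusterTerms <- function(network) {
    if (igraph::vcount(network) == 0L)
        return(stats::setNames(integer(0), character(0)))
    # igraph selects the hierarchy cut with the highest modularity and says
    # so in a warning; that is precisely the documented behaviour here
    comm <- suppressWarnings(igraph::cluster_edge_betweenness(network,
        weights = igraph::E(network)$weight, directed = FALSE))
    stats::setNames(as.integer(igraph::membership(comm)),
        igraph::V(network)$name)
}

#' Write a term network as edge-list and membership TSVs
#'
#' @param network an [igraph::igraph] graph.
#' @param clusters named cluster labels from [clusterTerms()].
#' @param edgePath,membershipPath,graphmlPath output paths (any may be
#'   `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
writeTermNetwork <- function(network, clusters = NULL, edgePath = NULL,
                             membershipPath = NULL, graphmlPath = NULL) {
    if (!is.null(edgePath)) {
        el <- igraph::as_data_frame(network, what = "edges")
        colnames(el)[1:2] <- c("term_a", "term_b")
        .writeTsv(el, edgePath)
    }
    if (!is.null(membershipPath) && !is.null(clusters)) {
        .writeTsv(data.frame(term_id = names(clusters),
            cluster = unname(clusters)), membershipPath)
    }
    if (!is.null(graphmlPath))
        igraph::write_graph(network, graphmlPath, format = "graphml")
    invisible(c(edges = edgePath, membership = membershipPath,
        graphml = graphmlPath))
}
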