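# Gene-set statistics: unweighted running-sum enrichment score with a
# permutation null, mean-rank gene-set analysis, two-sample z tests against
# the whole population or size-matched random sets, and BH adjustment.

#' Order genes by a ranking metric
#'
#' Returns gene ids ordered so that rank 1 is the top of the list. With
#' `orientation = "descending"` (the default, used for fold-change ranking)
#' the largest metric is at the top; `"ascending"` puts the smallest first
#' (e.g. shortest-CDS-first length ranking). Ties are broken by gene id so
#' the ordering is deterministic.
#'
#' @param metric named numeric vector (names are gene ids).
#' @param orientation `"descending"` or `"ascending"`.
#' @return character vector of gene ids, top of the list first.
#' @export
rankGenes <- function(metric, orientation = c("descending", "ascending")) {
    orientation <- match.arg(orientation)
    if (is.null(names(metric)) || anyNA(names(metric)))
        stop("'metric' must be named by gene id")
    key <- if (orientation == "descending") -metric else metric
    names(metric)[order(key, names(metric), method = "radix")]
}

#' Midranks of a ranking metric
#'
#' Rank values with 1 = top of the list; tied metric values receive their
#' midrank, the standard nonparametric convention used by the mean-rank
#' statistic.
#'
#' @inheritParams rankGenes
#' @return named numeric vector of ranks.
#' @export
geneRanks <- function(metric, orientation = c("descending", "ascending")) {
    orientation <- match.arg(orientation)
    key <- if (orientation == "descending") -metric else metric
    r <- rank(key, ties.method = "average")
    names(r) <- names(metric)
    r
}

#' Running-sum enrichment score
#'
#' Walks the ranked list accumulating `+sqrt((N - G)/G)` at each gene in the
#' set (a hit) and `-sqrt(G/(N - G))` at each gene absent from it, where `N`
#' is the list length and `G` the number of set members found in the list.
#' The enrichment score is the running sum's deviation of maximal absolute
#' value, signed: positive when the set concentrates at the top of the list.
#' In the degenerate case where the extreme positive and negative excursions
#' tie exactly in magnitude the score is reported as 0, the only convention
#' under which reversing the list always negates the score.
#'
#' @param ranked character vector of gene ids ordered top-first (see
#'   [rankGenes()]).
#' @param set character vector of gene ids; must intersect the list but not
#'   cover it entirely.
#' @return single numeric enrichment score.
#' @examples
#' gseaES(c("a", "b", "c", "d"), set = c("a", "b"))  # 2
#' @export
gseaES <- function(ranked, set) {
    hit <- ranked %in% set
    N <- length(ranked)
    G <- sum(hit)
    if (G == 0L)
        stop("gene set is disjoint from the ranked list")
    if (G == N)
        stop("gene set covers the entire ranked list")
    steps <- ifelse(hit, sqrt((N - G) / G), -sqrt(G / (N - G)))
    rs <- cumsum(steps)
    .signedExtreme(max(rs), min(rs))
}

# Signed deviation of maximal absolute value; a magnitude tie between the
# positive and negative excursions (within floating-point slack) yields 0,
# the antisymmetric convention.
.signedExtreme <- function(mx, mn) {
    tol <- 1e-9 * max(abs(mx), abs(mn), 1)
    if (abs(mx + mn) <= tol) 0 else if (mx > -mn) mx else mn
}

# Enrichment score recomputed from sorted hit positions only: the running
# sum is piecewise linear, so its extrema occur at hit positions (candidate
# maxima) and just before each hit (candidate minima). O(G log G) per
# permutation instead of O(N).
.esFromHitPositions <- function(hitpos, N) {
    G <- length(hitpos)
    hs <- sqrt((N - G) / G)
    ms <- sqrt(G / (N - G))
    p <- sort.int(hitpos)
    j <- seq_len(G)
    at_hit <- j * hs - (p - j) * ms          # value at each hit
    before_hit <- at_hit - hs                # value just before each hit
    cand <- c(at_hit, before_hit, 0)         # 0 = the end of the walk
    .signedExtreme(max(cand), min(cand))
}

#' Permutation null for the enrichment score
#'
#' Scrambles gene labels `nPerm` times (equivalently, places the set's `G`
#' hits at uniformly random list positions), recomputes the enrichment
#' score, and reports an add-one two-sided permutation p-value for the
#' observed score: `p = (1 + #{|null| >= |observed|}) / (nPerm + 1)`, which
#' can never reach zero.
#'
#' @param N ranked-list length.
#' @param G number of set members in the list (`0 < G < N`).
#' @param observed observed enrichment score.
#' @param nPerm number of permutations (default 1000; at least 100).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `null` (numeric vector of permuted scores) and
#'   `pvalue`.
#' @export
permutationNull <- function(N, G, observed, nPerm = 1000L, seed = NULL) {
    if (G <= 0L || G >= N)
        stop("need 0 < G < N")
    if (nPerm < 100L)
        stop("nPerm must be at least 100")
    .setSeedIfGiven(seed)
    null <- vapply(seq_len(nPerm), function(i) {
        .esFromHitPositions(sample.int(N, G), N)
    }, numeric(1))
    p <- (1 + sum(abs(null) >= abs(observed))) / (nPerm + 1)
    list(null = null, pvalue = p)
}

.setStatRow <- function(set_name, set_size, statistic_type, observed,
                        null, pvalue) {
    data.frame(
        set_name = set_name, set_size = set_size,
        statistic_type = statistic_type, observed = observed,
        null_mean = mean(null), null_sd = stats::sd(null),
        p_nominal = pvalue, p_adjusted = NA_real_,
        direction = if (statistic_type == "mean_rank") {
            # smaller mean rank than expected = concentrated at the top
            if (observed <= mean(null)) "up" else "down"
        } else {
            if (observed >= 0) "up" else "down"
        },
        stringsAsFactors = FALSE
    )
}

#' Enrichment-score test for one gene set
#'
#' Computes [gseaES()] on the ranked list and its permutation p-value via
#' [permutationNull()].
#'
#' @inheritParams gseaES
#' @inheritParams permutationNull
#' @return one-row `data.frame`: `set_name`, `set_size`, `statistic_type`
#'   (`"ES"`), `observed`, `null_mean`, `null_sd`, `p_nominal`,
#'   `p_adjusted` (`NA` until adjusted across a family), `direction`.
#' @export
gseaTest <- function(ranked, set, nPerm = 1000L, seed = NULL,
                     setName = "set") {
    es <- gseaES(ranked, set)
    G <- sum(ranked %in% set)
    pn <- permutationNull(length(ranked), G, es, nPerm = nPerm, seed = seed)
    .setStatRow(setName, G, "ES", es, pn$null, pn$pvalue)
}

#' Mean-rank gene-set analysis
#'
#' The observed statistic is the mean midrank of the set's members in the
#' ranked universe; the null is the mean rank of `nPerm` random same-size
#' gene draws without replacement. The two-sided add-one p-value compares
#' deviations from the exact exchangeable expectation `(N + 1)/2`:
#' `p = (1 + #{|null - (N+1)/2| >= |obs - (N+1)/2|}) / (nPerm + 1)`.
#' Direction is `"up"` when the set sits higher in the list (smaller mean
#' rank) than expected.
#'
#' @param metric named numeric vector of the ranking metric (e.g. log2 fold
#'   change), names are gene ids; the universe is `names(metric)`.
#' @param set character vector of set member gene ids.
#' @param orientation passed to [geneRanks()]; the default `"descending"`
#'   puts the largest metric at rank 1.
#' @inheritParams permutationNull
#' @param setName label for the output row.
#' @return one-row `data.frame` as in [gseaTest()] with `statistic_type
#'   = "mean_rank"`.
#' @export
gsaMeanRank <- function(metric, set, nPerm = 1000L, seed = NULL,
                        orientation = c("descending", "ascending"),
                        setName = "set") {
    orientation <- match.arg(orientation)
    ranks <- geneRanks(metric, orientation)
    in_set <- names(ranks) %in% set
    G <- sum(in_set)
    N <- length(ranks)
    if (G == 0L)
        stop("gene set is disjoint from the universe")
    if (G >= N)
        stop("gene set covers the entire universe")
    if (nPerm < 100L)
        stop("nPerm must be at least 100")
    .setSeedIfGiven(seed)
    observed <- mean(ranks[in_set])
    rank_values <- unname(ranks)
    null <- vapply(seq_len(nPerm), function(i) {
        mean(rank_values[sample.int(N, G)])
    }, numeric(1))
    center <- (N + 1) / 2
    p <- (1 + sum(abs(null - center) >= abs(observed - center))) / (nPerm + 1)
    .setStatRow(setName, G, "mean_rank", observed, null, p)
}

#' Two-sample z test
#'
#' `z = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with sample
#' variances and a two-sided normal p-value, the large-sample test used to
#' compare a gene set's fold changes against a reference population. Two
#' zero-variance groups with equal means give `z = 0`.
#'
#' @param x values in the set.
#' @param y reference values.
#' @return list with `z`, `pvalue`, `nx`, `ny`.
#' @export
twoSampleZ <- function(x, y) {
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("both groups need at least 2 values")
    se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
    z <- if (se2 == 0) {
        if (mean(x) == mean(y)) 0 else stop("zero variance with unequal means")
    } else {
        (mean(x) - mean(y)) / sqrt(se2)
    }
    list(z = z, pvalue = 2 * stats::pnorm(-abs(z)),
        nx = length(x), ny = length(y))
}

#' Size-matched random reference sets
#'
#' Draws `nDraws` random gene sets of the same size as `set` from the
#' detected universe and returns both the pooled values (a reference for
#' [twoSampleZ()]) and the per-draw means (an empirical null for the set
#' mean). With `stratum` given (e.g. a CDS-length tercile factor), each draw
#' matches the set's per-stratum composition, which is how a length-matched
#' control for a short-transcript set such as the ribosomal proteins is
#' built.
#'
#' @param values named numeric vector over all detected genes.
#' @param set character vector of set member gene ids.
#' @param nDraws number of random sets (default 1000).
#' @param seed optional RNG seed.
#' @param stratum optional factor aligned with `values` for stratified
#'   (e.g. length-matched) draws.
#' @return list with `pooled` (numeric vector of all drawn values),
#'   `draw_means` (numeric vector, one mean per draw) and `set_values`.
#' @export
sizeMatchedReference <- function(values, set, nDraws = 1000L, seed = NULL,
                                 stratum = NULL) {
    if (is.null(names(values)))
        stop("'values' must be named by gene id")
    in_set <- names(values) %in% set
    G <- sum(in_set)
    if (G == 0L || G >= length(values))
        stop("need 0 < |set| < number of detected genes")
    .setSeedIfGiven(seed)
    v <- unname(values)
    if (is.null(stratum)) {
        draws <- replicate(nDraws, v[sample.int(length(v), G)])
    } else {
        stratum <- as.factor(stratum)
        if (length(stratum) != length(values))
            stop("'stratum' must align with 'values'")
        per_stratum <- table(stratum[in_set])
        idx_by_stratum <- split(seq_along(v), stratum)
        draws <- replicate(nDraws, {
            unlist(lapply(names(per_stratum), function(s) {
                k <- per_stratum[[s]]
                if (k == 0L) return(numeric(0))
                pool <- idx_by_stratum[[s]]
                v[pool[sample.int(length(pool), k)]]
            }), use.names = FALSE)
        })
    }
    draws <- matrix(draws, nrow = G)
    list(
        pooled = as.numeric(draws),
        draw_means = colMeans(draws),
        set_values = values[in_set]
    )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, capped at 1) used to correct gene-set
#' nominal p-values across a family.
#'
#' @param p numeric vector of nominal p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
adjustFdr <- function(p) {
    if (any(!is.na(p) & (p < 0 | p > 1)))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Run a gene-set statistic over a collection
#'
#' Applies [gseaTest()] or [gsaMeanRank()] to every set in the collection
#' (intersected with the universe first) and BH-adjusts the nominal
#' p-values across the family.
#'
#' @param metric named numeric ranking metric over the detected universe.
#' @param sets a [GeneSetCollection-class].
#' @param method `"mean_rank"` or `"gsea"`.
#' @param minSize,maxSize set-size filter applied after intersecting each
#'   set with the universe (sets outside the range are skipped).
#' @param nPerm permutations per set.
#' @param seed master seed; each set receives a derived child seed so any
#'   single result can be regenerated independently.
#' @param orientation see [geneRanks()].
#' @return `data.frame` of result rows (one per retained set) with
#'   `p_adjusted` filled in, sorted by `p_nominal` then by decreasing
#'   enrichment magnitude.
#' @export
runSetStats <- function(metric, sets, method = c("mean_rank", "gsea"),
                        minSize = 1L, maxSize = Inf, nPerm = 1000L,
                        seed = NULL,
                        orientation = c("descending", "ascending")) {
    method <- match.arg(method)
    orientation <- match.arg(orientation)
    universe <- names(metric)
    kept <- lapply(as.list(sets), function(s) intersect(s, universe))
    sizes <- lengths(kept)
    keep <- sizes >= minSize & sizes <= maxSize & sizes < length(universe)
    kept <- kept[keep]
    if (length(kept) == 0L) {
        warning("no gene sets survive the size filter")
        return(data.frame(
            set_name = character(), set_size = integer(),
            statistic_type = character(), observed = numeric(),
            null_mean = numeric(), null_sd = numeric(),
            p_nominal = numeric(), p_adjusted = numeric(),
            direction = character(), stringsAsFactors = FALSE
        ))
    }
    ranked <- rankGenes(metric, orientation)
    rows <- lapply(seq_along(kept), function(i) {
        s <- kept[[i]]
        child <- if (is.null(seed)) NULL else childSeed(seed, i)
        if (method == "gsea")
            gseaTest(ranked, s, nPerm = nPerm, seed = child,
                setName = names(kept)[i])
        else
            gsaMeanRank(metric, s, nPerm = nPerm, seed = child,
                orientation = orientation, setName = names(kept)[i])
    })
    res <- do.call(rbind, rows)
    res$p_adjusted <- adjustFdr(res$p_nominal)
    dev <- if (method == "gsea") abs(res$observed)
        else abs(res$observed - (length(universe) + 1) / 2)
    res <- res[order(res$p_nominal, -dev), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member gene ids.
#'
#' @param path GMT path.
#' @return a [GeneSetCollection-class] (descriptions in
#'   `metadata()$description`).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, integer(1)) < 3L
    if (any(short))
        stop("malformed GMT line(s): ", paste(which(short), collapse = ", "))
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- vapply(fields, `[`, character(1), 1L)
    gsc <- GeneSetCollection(sets)
    metadata(gsc)$description <- stats::setNames(
        vapply(fields, `[`, character(1), 2L), names(sets))
    gsc
}

#' Write a GeneSetCollection as GMT
#'
#' @param sets a [GeneSetCollection-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGmt <- function(sets, path) {
    desc <- metadata(sets)$description
    lines <- vapply(names(sets), function(nm) {
        d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
        paste(c(nm, d, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Filter a collection by set size within a universe
#'
#' Intersects each set with the universe and keeps sets whose resulting
#' size lies in `[minSize, maxSize]`.
#'
#' @param sets a [GeneSetCollection-class].
#' @param universe character vector of detected gene ids.
#' @param minSize,maxSize inclusive size bounds.
#' @return a filtered [GeneSetCollection-class] with intersected members.
#' @export
sizeFilterSets <- function(sets, universe, minSize = 20L, maxSize = 50L) {
    kept <- lapply(as.list(sets), function(s) intersect(s, universe))
    sizes <- lengths(kept)
    GeneSetCollection(kept[sizes >= minSize & sizes <= maxSize])
}

#' Write gene-set statistic results to TSV
#'
#' @param results `data.frame` from [runSetStats()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSetStats <- function(results, path) {
    .writeTsv(results, path)
}
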