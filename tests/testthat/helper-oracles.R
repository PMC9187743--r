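# Independent brute-force oracles. These deliberately use naive loops and
# enumeration, not the package's code paths.

# Running-sum enrichment score by explicit walk down the list.
oracleGseaES <- function(ranked, set) {
    N <- length(ranked)
    G <- sum(ranked %in% set)
    rs <- 0
    mx <- 0
    mn <- 0
    for (g in ranked) {
        rs <- rs + if (g %in% set) sqrt((N - G) / G) else -sqrt(G / (N - G))
        if (rs > mx) mx <- rs
        if (rs < mn) mn <- rs
    }
    tol <- 1e-9 * max(abs(mx), abs(mn), 1)
    if (abs(mx + mn) <= tol) 0 else if (mx > -mn) mx else mn
}

# Two-sample KS statistic as the sup of |ECDF_x - ECDF_y| over all pooled
# evaluation points.
oracleKsD <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    dmax <- 0
    for (t in pts) {
        d <- abs(mean(x <= t) - mean(y <= t))
        if (d > dmax) dmax <- d
    }
    dmax
}

# Upper-tail hypergeometric p by summing the pmf from the observed overlap.
oracleHyperP <- function(k, sizeA, sizeB, universe) {
    upper <- min(sizeA, sizeB)
    if (k > upper) return(0)
    js <- k:upper
    sum(choose(sizeA, js) * choose(universe - sizeA, sizeB - js)) /
        choose(universe, sizeB)
}

# Sign-imbalance z from raw fold changes.
oracleTermZ <- function(lfc) {
    (sum(lfc > 0) - sum(lfc < 0)) / sqrt(length(lfc))
}

# Half-open binning by linear scan.
oracleBinLabel <- function(len, edges) {
    vapply(len, function(l) {
        for (i in seq_len(length(edges) - 1L)) {
            if (l >= edges[i] && l < edges[i + 1L]) return(i)
        }
        NA_integer_
    }, integer(1))
}

# Two-sample z by the textbook formula, computed step by step.
oracleTwoSampleZ <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    vx <- sum((x - mx)^2) / (length(x) - 1)
    vy <- sum((y - my)^2) / (length(y) - 1)
    (mx - my) / sqrt(vx / length(x) + vy / length(y))
}

# Exhaustive two-sided mean-rank p over all C(N, G) subsets, centred on
# (N + 1)/2.
oracleMeanRankExactP <- function(ranks, setRanks) {
    N <- length(ranks)
    G <- length(setRanks)
    center <- (N + 1) / 2
    obs_dev <- abs(mean(setRanks) - center)
    combos <- utils::combn(ranks, G)
    devs <- abs(colMeans(combos) - center)
    mean(devs >= obs_dev - 1e-12)
}
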