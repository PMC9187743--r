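test_that("running-sum ES matches the step formula and a naive oracle", {
    ranked <- c("a", "b", "c", "d")
    expect_equal(gseaES(ranked, c("a", "b")), 2)          # 2*sqrt(2/2)
    expect_equal(gseaES(ranked, c("c", "d")), -2)         # bottom mirror
    expect_error(gseaES(ranked, c("zz")), "disjoint")
    expect_error(gseaES(ranked, ranked), "entire")

    set.seed(31)
    for (rep in 1:40) {
        genes <- sprintf("g%02d", 1:50)
        ranked <- sample(genes)
        set <- sample(genes, 8)
        expect_equal(gseaES(ranked, set), oracleGseaES(ranked, set),
            tolerance = 1e-12)
    }
})

test_that("reversing the ranked list negates the ES", {
    set.seed(32)
    for (rep in 1:30) {
        genes <- sprintf("g%02d", 1:40)
        ranked <- sample(genes)
        set <- sample(genes, sample(3:12, 1))
        expect_equal(gseaES(rev(ranked), set), -gseaES(ranked, set),
            tolerance = 1e-12)
    }
})

test_that("permutation null is reproducible and floors at 1/(n+1)", {
    a <- permutationNull(100, 10, observed = 5, nPerm = 200, seed = 5)
    b <- permutationNull(100, 10, observed = 5, nPerm = 200, seed = 5)
    expect_identical(a$null, b$null)
    # an observed value far outside the null support
    far <- permutationNull(100, 10, observed = 1e6, nPerm = 200, seed = 5)
    expect_equal(far$pvalue, 1 / 201)
    expect_error(permutationNull(10, 10, 1), "G < N")
    expect_error(permutationNull(100, 5, 1, nPerm = 10), "at least 100")

    # the fast hit-position ES recomputation agrees with the full walk
    set.seed(33)
    for (rep in 1:30) {
        N <- sample(20:60, 1)
        G <- sample(3:10, 1)
        hits <- sample.int(N, G)
        ranked <- sprintf("g%02d", 1:N)
        set <- ranked[hits]
        expect_equal(riboshift:::.esFromHitPositions(hits, N),
            oracleGseaES(ranked, set), tolerance = 1e-12)
    }
})

test_that("mean-rank GSA recovers planted sets and matches enumeration", {
    metric <- setNames(seq(1000, 1, length.out = 1000),
        sprintf("g%04d", 1:1000))
    res <- gsaMeanRank(metric, names(metric)[1:3], nPerm = 500, seed = 3)
    expect_equal(res$observed, 2)
    expect_equal(res$p_nominal, 1 / 501)
    expect_equal(res$direction, "up")
    # null mean close to the exchangeable expectation (N + 1)/2
    expect_lt(abs(res$null_mean - 500.5),
        3 * res$null_sd / sqrt(500) * 5 + 5)

    # exhaustive oracle at N = 10, G = 3
    set.seed(34)
    metric <- setNames(rnorm(10), paste0("g", 1:10))
    for (rep in 1:10) {
        set <- sample(names(metric), 3)
        got <- gsaMeanRank(metric, set, nPerm = 2000, seed = rep)
        ranks <- rank(-metric, ties.method = "average")
        exact <- oracleMeanRankExactP(unname(ranks),
            unname(ranks[names(ranks) %in% set]))
        # sampled add-one p within Monte-Carlo error of the exact p
        se <- sqrt(exact * (1 - exact) / 2000)
        expect_lt(abs(got$p_nominal - exact), 4 * se + 2 / 2001)
    }
})

test_that("two-sample z follows the formula and its invariances", {
    x <- rep(1, 5); y <- rep(1, 9)
    res <- twoSampleZ(x, y)
    expect_equal(res$z, 0)
    expect_equal(res$pvalue, 1)

    set.seed(35)
    x <- rnorm(500, 10, 1)
    y <- rnorm(500, 0, 1)
    expect_gt(abs(twoSampleZ(x, y)$z), 50)
    expect_lt(twoSampleZ(x, y)$pvalue, 1e-100)

    for (rep in 1:20) {
        x <- rnorm(30); y <- rnorm(30, 0.5)
        got <- twoSampleZ(x, y)
        expect_equal(got$z, oracleTwoSampleZ(x, y), tolerance = 1e-12)
        expect_equal(got$pvalue, 2 * pnorm(-abs(got$z)), tolerance = 1e-12)
        # common location/scale shift leaves z unchanged
        shifted <- twoSampleZ(3 * x + 7, 3 * y + 7)
        expect_equal(shifted$z, got$z, tolerance = 1e-9)
    }
    expect_error(twoSampleZ(1, c(1, 2)), "at least 2")
})

test_that("size-matched references pool same-size draws", {
    vals <- setNames(rep(4, 20), paste0("g", 1:20))
    ref <- sizeMatchedReference(vals, paste0("g", 1:5), nDraws = 50,
        seed = 1)
    expect_true(all(ref$pooled == 4))
    expect_true(all(ref$draw_means == 4))

    set.seed(36)
    vals <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    ref <- sizeMatchedReference(vals, names(vals)[1:10], nDraws = 4000,
        seed = 2)
    expect_lt(abs(mean(ref$draw_means) - mean(vals)),
        4 * sd(vals) / sqrt(10) / sqrt(4000) * 10)
    expect_length(ref$pooled, 10 * 4000)

    # N = 8, G = 2: sampled moments match exhaustive enumeration
    vals <- setNames(c(1, 2, 3, 4, 10, 20, 30, 40), paste0("g", 1:8))
    ref <- sizeMatchedReference(vals, c("g1", "g5"), nDraws = 20000,
        seed = 3)
    pairs <- combn(unname(vals), 2)
    exact_mean <- mean(colMeans(pairs))
    exact_sd <- sd(colMeans(pairs))
    expect_lt(abs(mean(ref$draw_means) - exact_mean),
        4 * exact_sd / sqrt(20000))

    # stratified draws respect the set's per-stratum composition
    stratum <- rep(c("short", "long"), each = 4)
    ref <- sizeMatchedReference(vals, c("g1", "g2", "g5"), nDraws = 100,
        seed = 4, stratum = stratum)
    draws <- matrix(ref$pooled, nrow = 3)
    short_vals <- unname(vals[1:4])
    expect_true(all(colSums(matrix(draws %in% short_vals, nrow = 3)) == 2))
})

test_that("BH adjustment matches hand computation", {
    expect_equal(adjustFdr(0.2), 0.2)
    expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(adjustFdr(rep(1, 5)), rep(1, 5))
    expect_error(adjustFdr(c(0.5, 1.2)), "\\[0, 1\\]")
    p <- c(0.01, 0.4, 0.03, 0.005)
    adj <- adjustFdr(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("collection-level statistics filter, adjust and sort", {
    set.seed(37)
    metric <- setNames(rnorm(300), sprintf("g%03d", 1:300))
    sets <- GeneSetCollection(list(
        top = names(sort(metric, decreasing = TRUE))[1:20],
        random = sample(names(metric), 25),
        tiny = names(metric)[1:2],
        outside = paste0("zz", 1:30)
    ))
    res <- runSetStats(metric, sets, method = "mean_rank", minSize = 5,
        nPerm = 200, seed = 9)
    expect_setequal(res$set_name, c("top", "random"))
    expect_equal(res$set_name[1], "top")   # sorted by p
    expect_true(all(res$p_adjusted >= res$p_nominal))
    expect_equal(res$p_adjusted, adjustFdr(res$p_nominal),
        tolerance = 1e-12)
    expect_equal(res$direction[res$set_name == "top"], "up")

    res_gsea <- runSetStats(metric, sets, method = "gsea", minSize = 5,
        nPerm = 200, seed = 9)
    expect_true(res_gsea$observed[res_gsea$set_name == "top"] > 0)
    expect_warning(empty <- runSetStats(metric, sets, minSize = 500),
        "survive")
    expect_equal(nrow(empty), 0L)
})

test_that("GMT files round-trip through the reader and writer", {
    sets <- GeneSetCollection(list(
        ribosome = paste0("Rp", 1:10),
        synapse = c("Shank1", "Dlg4", "Nrxn1")))
    path <- tempfile(fileext = ".gmt")
    writeGmt(sets, path)
    back <- readGmt(path)
    expect_identical(as.list(back), as.list(sets))
    expect_error(readGmt({
        p <- tempfile(); writeLines("one\tfield", p); p
    }), "malformed")
})
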