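test_that("TSS is the maximal pileup in the upstream scan window", {
    gm <- makeModel("t1", "g1", "+", tx_start = 1000L, tx_end = 2000L,
        coding_start = 1060L)
    trk <- CageTrack(rep("chr1", 2), rep("+", 2),
        pos = c(980L, 1005L), count = c(7L, 3L))
    hit <- callTss(gm, trk)
    expect_equal(hit$position, 980L)
    expect_equal(hit$height, 7L)

    # exhaustive max over the window on random pileups
    set.seed(11)
    for (rep in 1:20) {
        pos <- sample(0:2100, 15)
        cnt <- sample(1:40, 15, replace = TRUE)
        trk <- CageTrack(rep("chr1", 15), rep("+", 15), pos, cnt)
        hit <- callTss(gm, trk)
        in_win <- pos >= 1000L - 1000L & pos < 1060L
        if (!any(in_win)) {
            expect_true(is.na(hit$position))
        } else {
            best <- max(cnt[in_win])
            expect_equal(hit$height, best)
            # tie-break: most downstream of the tied maxima
            expect_equal(hit$position, max(pos[in_win & cnt == best]))
        }
    }
})

test_that("a window with no reads yields no signal", {
    gm <- makeModel("t1", "g1", "+", 1000L, 2000L, 1060L)
    expect_true(is.na(callTss(gm, CageTrack())$position))
    # reads only outside the window
    trk <- CageTrack("chr1", "+", pos = 1500L, count = 9L)
    expect_true(is.na(callTss(gm, trk)$position))
    call <- assignUtr5(NA, gm)
    expect_equal(call$status, "no_signal")
})

test_that("minus-strand calls mirror plus-strand calls", {
    # mirror of the first example around coordinate 3000
    gm_plus <- makeModel("t1", "g1", "+", 1000L, 2000L, 1060L)
    trk_plus <- CageTrack(rep("chr1", 2), rep("+", 2),
        pos = c(980L, 1005L), count = c(7L, 3L))
    mirror <- function(p) 3000L - p
    gm_minus <- makeModel("t1", "g1", "-",
        tx_start = mirror(2000L), tx_end = mirror(1000L),
        coding_start = mirror(1060L))
    trk_minus <- CageTrack(rep("chr1", 2), rep("-", 2),
        pos = mirror(c(980L, 1005L)), count = c(7L, 3L))
    hp <- callTss(gm_plus, trk_plus)
    hm <- callTss(gm_minus, trk_minus)
    expect_equal(hm$position, mirror(hp$position))
    expect_equal(assignUtr5(hm$position, gm_minus)$utr5_length,
        assignUtr5(hp$position, gm_plus)$utr5_length)

    # property: random pileups stay invariant under strand mirroring
    set.seed(13)
    for (rep in 1:20) {
        pos <- sample(0:2100, 12)
        cnt <- sample(1:30, 12, replace = TRUE)
        tp <- CageTrack(rep("chr1", 12), rep("+", 12), pos, cnt)
        tm <- CageTrack(rep("chr1", 12), rep("-", 12), mirror(pos), cnt)
        cp <- assignUtr5(callTss(gm_plus, tp)$position, gm_plus)
        cm <- assignUtr5(callTss(gm_minus, tm)$position, gm_minus)
        expect_equal(cm$status, cp$status)
        expect_equal(cm$utr5_length, cp$utr5_length)
    }
})

test_that("5'UTR assignment picks the closest downstream coding start", {
    gm <- rbind(
        makeModel("tA", "g1", "+", 900L, 2000L, 1060L),
        makeModel("tB", "g1", "+", 900L, 2000L, 1010L))
    call <- assignUtr5(980L, gm)
    expect_equal(call$status, "called")
    expect_equal(call$chosen_transcript, "tB")
    expect_equal(call$utr5_length, 30L)
})

test_that("5'UTRs longer than 500 nt are excluded", {
    gm <- makeModel("tA", "g1", "+", 900L, 2500L, 1600L)
    call <- assignUtr5(980L, gm)
    expect_equal(call$status, "excluded_long_utr")
    expect_equal(call$utr5_length, 620L)
})

test_that("a TSS downstream of any coding start is excluded", {
    gm <- rbind(
        makeModel("tA", "g1", "+", 900L, 2000L, 950L),
        makeModel("tB", "g1", "+", 900L, 2000L, 1010L))
    expect_equal(assignUtr5(980L, gm)$status, "excluded_downstream")
    # 0-nt 5'UTR counts as downstream (strictly-upstream reading)
    gm1 <- makeModel("tA", "g1", "+", 900L, 2000L, 980L)
    expect_equal(assignUtr5(980L, gm1)$status, "excluded_downstream")
})

test_that("degenerate or empty inputs are handled", {
    expect_error(callTss(makeModel("t", "g", "+", 1L, 2L, 1L)[0, ],
        CageTrack()), "empty")
    mixed <- rbind(makeModel("tA", "g1", "+", 900L, 2000L, 1000L),
        makeModel("tB", "g1", "-", 900L, 2000L, 1000L))
    expect_error(callTss(mixed, CageTrack()), "strand")
})

test_that("noiseless synthetic pileups are recovered exactly per status", {
    cfg <- simulationConfig(n_genes = 300L, cage_background = 0,
        n_random_sets = 2L, seed = 91L)
    uni <- generateUniverse(cfg)
    cage <- generateCage(uni)
    res <- callAllTss(cage$models, cage$track)
    expect_equal(sum(res$summary), 300L)
    tab <- merge(res$calls, cage$truth, by = "gene_id")
    expect_identical(tab$status, tab$expected_status)
    called <- tab[tab$status == "called", ]
    expect_gt(nrow(called), 0L)
    expect_identical(called$tss_position, called$true_tss)
    expect_identical(called$utr5_length, called$true_utr5)
    # exclusion rules fire on every planted case
    expect_true(all(
        tab$status[tab$expected_status == "excluded_downstream"] ==
            "excluded_downstream"))
    expect_true(all(
        tab$status[tab$expected_status == "excluded_long_utr"] ==
            "excluded_long_utr"))
})

test_that("no called gene ever carries an illegal 5'UTR length", {
    cfg <- simulationConfig(n_genes = 300L, cage_background = 0.1,
        n_random_sets = 2L, seed = 92L)
    uni <- generateUniverse(cfg)
    cage <- generateCage(uni)
    res <- callAllTss(cage$models, cage$track)
    called <- res$calls[res$calls$status == "called", ]
    expect_true(all(called$utr5_length > 0L))
    expect_true(all(called$utr5_length <= 500L))
    expect_equal(sum(res$summary), 300L)
})

test_that("bedGraph round trip preserves pileups and TSV/BED are written", {
    cfg <- simulationConfig(n_genes = 300L, cage_background = 0,
        n_random_sets = 2L, seed = 93L)
    uni <- generateUniverse(cfg)
    dir <- tempfile()
    paths <- writeSimulatedData(uni, dir)
    trk <- readCageBedGraph(paths[["cage_plus"]], paths[["cage_minus"]])
    models <- readGtfModels(paths[["gtf"]])
    res <- callAllTss(models, trk)
    truth <- read.delim(paths[["truth"]])
    tab <- merge(res$calls, truth, by = "gene_id")
    expect_identical(tab$status, tab$expected_status)
    out_tsv <- tempfile(fileext = ".tsv")
    out_bed <- tempfile(fileext = ".bed")
    writeTssCalls(res$calls, models, bedPath = out_bed, tsvPath = out_tsv)
    bed <- read.delim(out_bed, header = FALSE)
    expect_equal(nrow(bed), sum(res$calls$status == "called"))
    expect_true(all(bed$V3 - bed$V2 == 1L))
})
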