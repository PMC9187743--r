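test_that("principal transcript selection is argmax with deterministic ties", {
    ab <- data.frame(
        transcript_id = c("t1", "t2"), gene_id = "G", tpm = c(5.0, 9.2))
    expect_identical(selectPrincipalTranscript(ab), c(G = "t2"))

    single <- data.frame(transcript_id = "t1", gene_id = "G", tpm = 0)
    expect_identical(selectPrincipalTranscript(single), c(G = "t1"))

    tie <- data.frame(transcript_id = c("tB", "tA"), gene_id = "G",
        tpm = c(3, 3))
    expect_identical(selectPrincipalTranscript(tie), c(G = "tA"))

    set.seed(41)
    for (rep in 1:25) {
        ab <- data.frame(
            transcript_id = paste0("t", 1:9),
            gene_id = rep(paste0("g", 1:3), each = 3),
            tpm = round(runif(9, 0, 10), 3))
        got <- selectPrincipalTranscript(ab)
        # exhaustive per-gene argmax
        for (g in unique(ab$gene_id)) {
            sub <- ab[ab$gene_id == g, ]
            best <- sub$transcript_id[sub$tpm == max(sub$tpm)]
            expect_identical(unname(got[g]), sort(best)[1])
        }
    }
})

test_that("principal transcript selection rejects broken gene mappings", {
    bad <- data.frame(transcript_id = c("t1", "t1"),
        gene_id = c("g1", "g2"), tpm = c(1, 2))
    expect_error(selectPrincipalTranscript(bad), "multiple genes")
    expect_error(selectPrincipalTranscript(
        data.frame(transcript_id = "t1", gene_id = "", tpm = 1)),
        "exactly one gene")
})

test_that("GC content counts G+C over ACGT, excluding N", {
    expect_equal(computeGC("ATGC"), 0.5)
    expect_equal(computeGC("GGGG"), 1.0)
    expect_true(is.na(computeGC("NNNN")))
    expect_equal(computeGC("ANGC"), 2 / 3)  # N out of both sides
    expect_error(computeGC(""), "non-empty")

    set.seed(42)
    revcomp <- function(s) {
        chartr("ACGT", "TGCA",
            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    }
    for (rep in 1:30) {
        s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE),
            collapse = "")
        chars <- strsplit(s, "")[[1]]
        expected <- sum(chars %in% c("G", "C")) / sum(chars != "N")
        got <- computeGC(s)
        if (is.nan(expected)) {
            expect_true(is.na(got))
        } else {
            expect_equal(got, expected)
            expect_equal(computeGC(tolower(s)), expected)
            expect_equal(computeGC(revcomp(s)), expected)
        }
        expect_true(is.na(got) || (got >= 0 && got <= 1))
    }
})

test_that("gene table matches hand computation on a toy GTF/FASTA", {
    models <- readGtfModels(writeToyGtf())
    expect_setequal(models$transcript_id, c("t1", "t2"))
    m1 <- models[models$transcript_id == "t1", ]
    expect_equal(m1$tx_start, 100L)
    expect_equal(m1$tx_end, 400L)
    expect_equal(m1$coding_start, 150L)
    expect_equal(m1$cds_length, 100L)
    expect_equal(m1$exonic_length, 200L)
    expect_equal(m1$utr5_annot, 50L)
    expect_equal(m1$utr3_length, 50L)
    m2 <- models[models$transcript_id == "t2", ]
    expect_equal(m2$coding_start, 1079L)
    expect_equal(m2$utr5_annot, 20L)
    expect_equal(m2$utr3_length, 20L)

    ab <- data.frame(transcript_id = c("t1", "t2"),
        gene_id = c("g1", "g2"), tpm = c(7, 3), fpkm = c(5, 1))
    cds <- Biostrings::DNAStringSet(c(
        t1 = paste(rep("ACGT", 25), collapse = ""),   # 100 nt, GC 0.5
        t2 = paste(rep("GGC", 20), collapse = "")))   # 60 nt, GC 1.0
    ann <- buildGeneTable(models, ab, cdsSeqs = cds,
        useAnnotatedUtr5 = TRUE)
    expect_s4_class(ann, "GeneAnnotation")
    df <- as.data.frame(ann)
    g1 <- df[df$gene_id == "g1", ]
    expect_equal(g1$transcript_length, 200L)
    expect_equal(g1$cds_length, 100L)
    expect_equal(g1$utr5_length, 50L)
    expect_equal(g1$gc_cds, 0.5)
    expect_equal(g1$tpm, 7)
    expect_equal(g1$fpkm, 5)
    expect_equal(g1$gene_length, 300L)
    g2 <- df[df$gene_id == "g2", ]
    expect_equal(g2$gc_cds, 1.0)
    expect_equal(g2$utr5_length, 20L)
    expect_false(any(df$flagged))
})

test_that("genes without a CDS sequence are flagged, not dropped", {
    models <- readGtfModels(writeToyGtf())
    ab <- data.frame(transcript_id = c("t1", "t2"),
        gene_id = c("g1", "g2"), tpm = c(7, 3))
    cds <- Biostrings::DNAStringSet(
        c(t1 = paste(rep("ACGT", 25), collapse = "")))
    expect_warning(ann <- buildGeneTable(models, ab, cdsSeqs = cds),
        "flagged")
    expect_equal(nrow(ann), 2L)
    expect_true(ann$flagged[ann$gene_id == "g2"])
    expect_true(is.na(ann$gc_cds[ann$gene_id == "g2"]))
})

test_that("mismatched CDS sequence length warns and flags", {
    models <- readGtfModels(writeToyGtf())
    ab <- data.frame(transcript_id = c("t1", "t2"),
        gene_id = c("g1", "g2"), tpm = c(7, 3))
    cds <- Biostrings::DNAStringSet(c(
        t1 = "ACGTACGT",                              # wrong length
        t2 = paste(rep("GGC", 20), collapse = "")))
    expect_warning(ann <- buildGeneTable(models, ab, cdsSeqs = cds),
        "inconsistent")
    expect_true(ann$flagged[ann$gene_id == "g1"])
    expect_false(ann$flagged[ann$gene_id == "g2"])
})

test_that("empty annotation gives an empty table without error", {
    empty <- readGtfModels(writeToyGtf())[0, ]
    ann <- buildGeneTable(empty,
        data.frame(transcript_id = character(), gene_id = character(),
            tpm = numeric()))
    expect_s4_class(ann, "GeneAnnotation")
    expect_equal(nrow(ann), 0L)
})

test_that("expression filter is strict and monotone in the threshold", {
    ann <- makeAnn(paste0("g", 1:3), cds_length = c(300L, 600L, 900L),
        fpkm = c(1.9, 2.0, 2.1))
    expect_equal(geneIds(filterExpressed(ann, 2)), "g3")
    pos <- makeAnn(paste0("g", 1:4), cds_length = rep(300L, 4),
        fpkm = c(0.5, 1, 2, 4))
    expect_equal(nrow(filterExpressed(pos, 0)), 4L)

    set.seed(7)
    for (rep in 1:20) {
        fp <- round(runif(30, 0, 5), 2)
        tab <- makeAnn(sprintf("g%02d", 1:30), cds_length = rep(300L, 30),
            fpkm = fp)
        th <- runif(2, 0, 5)
        lo <- min(th); hi <- max(th)
        kept_hi <- geneIds(filterExpressed(tab, hi))
        kept_lo <- geneIds(filterExpressed(tab, lo))
        expect_true(all(kept_hi %in% kept_lo))
        expect_setequal(kept_lo, tab$gene_id[fp > lo])
    }
})

test_that("gene table TSV writer keeps the documented column order", {
    ann <- makeAnn(c("g1", "g2"), cds_length = c(300L, 600L))
    path <- tempfile(fileext = ".tsv")
    writeGeneTable(ann, path)
    header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
    expect_identical(header[1:9], c("gene_id", "principal_transcript",
        "transcript_length", "cds_length", "utr5_length", "utr3_length",
        "gc_cds", "tpm", "fpkm"))
})
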