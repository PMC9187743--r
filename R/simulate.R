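# Synthetic-data generator: gene universes with skewed length distributions,
# differential tables with length-dependent and set-specific effects, paired
# TRAP/total count matrices, and CAGE pileups with known true TSS positions.

#' Simulation configuration
#'
#' Defaults describe a hippocampal-translatome-like universe: 12000 detected
#' genes, lognormal CDS lengths (median ~1.3 kb), an 80-gene ribosomal-
#' protein-like set drawn from the shortest CDS tercile, a mild negative
#' dependence of log2 fold change on centred log2 CDS length
#' (`beta_len = -0.05`), a `+0.3` log2 shift for the RP-like set, and
#' per-gene noise of scale 0.15 on the log2 scale.
#'
#' @param n_genes number of genes.
#' @param cds_meanlog,cds_sdlog lognormal parameters for CDS length (nt).
#' @param utr5_meanlog,utr5_sdlog lognormal parameters for 5'UTR length.
#' @param utr3_meanlog,utr3_sdlog lognormal parameters for 3'UTR length.
#' @param rp_set_size size of the RP-like short-gene set.
#' @param beta_len slope of true log2 fold change on centred log2 CDS
#'   length.
#' @param gamma_rp additive true log2 fold change for RP-like genes.
#' @param sigma_noise scale of the per-gene standard error of the observed
#'   log2 fold change.
#' @param n_replicates replicates per condition (degrees of freedom of the
#'   per-gene standard-error draw; also the number of count-matrix pairs).
#' @param nb_dispersion negative-binomial dispersion of simulated counts
#'   (0 gives Poisson).
#' @param expr_meanlog,expr_sdlog lognormal parameters for baseline
#'   expression (mean normalized counts).
#' @param cage_signal Poisson mean of CAGE reads at the true TSS.
#' @param cage_background Poisson mean of background CAGE reads per base.
#' @param decoy_fraction fraction of genes given a second transcript and a
#'   pileup downstream of its coding start (exercises the
#'   `excluded_downstream` rule).
#' @param long_utr_fraction fraction of genes given a true 5'UTR longer
#'   than 500 nt (exercises the `excluded_long_utr` rule).
#' @param n_random_sets number of random gene sets emitted alongside the
#'   RP-like set.
#' @param random_set_sizes inclusive size range of the random sets.
#' @param seed master seed; every generator derives independent child
#'   streams from it.
#' @return a list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(n_genes = 12000L,
                             cds_meanlog = 7.2, cds_sdlog = 0.6,
                             utr5_meanlog = 4.7, utr5_sdlog = 0.6,
                             utr3_meanlog = 6.5, utr3_sdlog = 0.8,
                             rp_set_size = 80L,
                             beta_len = -0.05, gamma_rp = 0.3,
                             sigma_noise = 0.15, n_replicates = 4L,
                             nb_dispersion = 0.05,
                             expr_meanlog = 4, expr_sdlog = 1.5,
                             cage_signal = 50, cage_background = 0.05,
                             decoy_fraction = 0.10,
                             long_utr_fraction = 0.05,
                             n_random_sets = 50L,
                             random_set_sizes = c(15L, 60L),
                             seed = 1L) {
    cfg <- as.list(environment())
    stopifnot(
        cfg$n_genes > 0, cfg$rp_set_size < cfg$n_genes,
        cfg$sigma_noise >= 0, cfg$nb_dispersion >= 0,
        cfg$cage_signal >= 0, cfg$cage_background >= 0,
        cfg$decoy_fraction >= 0, cfg$decoy_fraction < 1,
        cfg$long_utr_fraction >= 0, cfg$long_utr_fraction < 1,
        cfg$n_replicates >= 1
    )
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Generate a gene universe with ground truth
#'
#' Draws per-gene CDS/UTR lengths, GC content and expression; plants the
#' RP-like set in the shortest CDS tercile; and assigns each gene its true
#' log2 fold change `beta_len * centred log2(CDS) + gamma_rp * I(RP-like)`.
#' Reproducible: the same config (including seed) yields identical output.
#'
#' @param config a [simulationConfig()].
#' @return list with `annotation` ([GeneAnnotation-class] including
#'   `gene_length`), `sets` ([GeneSetCollection-class]: `rp_like` plus
#'   random sets), `truth` (`data.frame`: `gene_id`, `true_log2fc`,
#'   `is_rp`, `true_utr5`, `is_decoy`, `is_long_utr`, `base_mean`) and
#'   `config`.
#' @export
generateUniverse <- function(config = simulationConfig()) {
    set.seed(childSeed(config$seed, 1L))
    n <- config$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    cds <- pmax(90L, as.integer(round(stats::rlnorm(n, config$cds_meanlog,
        config$cds_sdlog))))
    cds <- cds - cds %% 3L   # keep whole codons
    utr5 <- pmax(1L, as.integer(round(stats::rlnorm(n, config$utr5_meanlog,
        config$utr5_sdlog))))
    utr5 <- pmin(utr5, 500L)  # long-UTR genes are planted explicitly below
    utr3 <- pmax(1L, as.integer(round(stats::rlnorm(n, config$utr3_meanlog,
        config$utr3_sdlog))))
    is_long_utr <- seq_len(n) %in%
        sample.int(n, round(config$long_utr_fraction * n))
    utr5[is_long_utr] <- as.integer(round(stats::runif(sum(is_long_utr),
        501, 1500)))
    is_decoy <- rep(FALSE, n)
    eligible <- which(!is_long_utr & cds >= 600L)
    n_decoy <- round(config$decoy_fraction * n)
    is_decoy[sample(eligible, min(n_decoy, length(eligible)))] <- TRUE
    transcript_length <- utr5 + cds + utr3
    intron_factor <- pmax(1, stats::rlnorm(n, log(6), 1))
    gene_length <- as.integer(round(transcript_length * intron_factor))
    gc <- pmin(0.8, pmax(0.25, stats::rnorm(n, 0.52, 0.05)))
    base_mean <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    tpm <- base_mean / sum(base_mean) * 1e6
    fpkm <- base_mean / 10

    log2cds <- log2(cds)
    tercile <- stats::quantile(cds, 1 / 3)
    short_pool <- which(cds <= tercile)
    if (length(short_pool) < config$rp_set_size)
        stop("rp_set_size (", config$rp_set_size, ") exceeds the shortest ",
            "CDS tercile (", length(short_pool), " genes); reduce the set ",
            "size or increase n_genes")
    rp <- sample(short_pool, config$rp_set_size)
    is_rp <- seq_len(n) %in% rp
    true_lfc <- config$beta_len * (log2cds - mean(log2cds)) +
        config$gamma_rp * is_rp

    random_sets <- lapply(seq_len(config$n_random_sets), function(i) {
        sz <- sample(seq(config$random_set_sizes[1],
            config$random_set_sizes[2]), 1L)
        gene_id[sample.int(n, sz)]
    })
    names(random_sets) <- sprintf("set_%03d", seq_along(random_sets))
    sets <- GeneSetCollection(c(list(rp_like = gene_id[is_rp]), random_sets))

    annotation <- GeneAnnotation(data.frame(
        gene_id = gene_id,
        principal_transcript = paste0(gene_id, ".t1"),
        transcript_length = transcript_length,
        cds_length = cds,
        utr5_length = utr5,
        utr3_length = utr3,
        gc_cds = gc,
        tpm = tpm,
        fpkm = fpkm,
        gene_length = gene_length,
        stringsAsFactors = FALSE
    ))
    truth <- data.frame(
        gene_id = gene_id, true_log2fc = true_lfc, is_rp = is_rp,
        true_utr5 = utr5, is_decoy = is_decoy, is_long_utr = is_long_utr,
        base_mean = base_mean, stringsAsFactors = FALSE
    )
    list(annotation = annotation, sets = sets, truth = truth,
        config = config)
}

#' Generate a differential-expression table from a universe
#'
#' Each gene receives a standard error drawn from a scaled inverse-chi
#' distribution with `n_replicates` degrees of freedom
#' (`se = sigma_noise / sqrt(chi2_df / df)`), an observed log2 fold change
#' `true + Normal(0, se)`, a Wald-style statistic `observed / se` with a
#' two-sided normal p-value, and a BH-adjusted p. Under a null config the
#' p-values are exactly uniform by construction; with `sigma_noise = 0` the
#' observed fold change equals the truth.
#'
#' @param universe output of [generateUniverse()].
#' @param config defaults to the universe's config.
#' @return a [DifferentialTable-class] (contrast `"simulated"`).
#' @export
generateDeTable <- function(universe, config = universe$config) {
    set.seed(childSeed(config$seed, 2L))
    truth <- universe$truth
    n <- nrow(truth)
    df <- config$n_replicates
    if (config$sigma_noise > 0) {
        se <- config$sigma_noise / sqrt(stats::rchisq(n, df) / df)
        obs <- truth$true_log2fc + stats::rnorm(n, 0, se)
        stat <- obs / se
    } else {
        se <- rep(0, n)
        obs <- truth$true_log2fc
        stat <- ifelse(obs == 0, 0, sign(obs) * Inf)
    }
    pvalue <- 2 * stats::pnorm(-abs(stat))
    DifferentialTable(data.frame(
        gene_id = truth$gene_id, log2fc = obs, stat = stat,
        pvalue = pvalue, padj = adjustFdr(pvalue),
        stringsAsFactors = FALSE
    ), contrast = "simulated")
}

#' Generate paired TRAP/total count matrices
#'
#' Total counts are negative binomial around each gene's baseline mean;
#' TRAP counts use mean `baseline * 2^true_log2fc`. With dispersion 0 the
#' draws are Poisson.
#'
#' @param universe output of [generateUniverse()].
#' @param config defaults to the universe's config.
#' @return list with matrices `trap` and `total` (genes x replicates) and
#'   `pairing` (`data.frame` with columns `trap`, `total`).
#' @export
generateCounts <- function(universe, config = universe$config) {
    set.seed(childSeed(config$seed, 3L))
    truth <- universe$truth
    n <- nrow(truth)
    reps <- config$n_replicates
    draw <- function(mu) {
        if (config$nb_dispersion > 0)
            stats::rnbinom(length(mu), mu = mu,
                size = 1 / config$nb_dispersion)
        else
            stats::rpois(length(mu), mu)
    }
    mu_total <- truth$base_mean
    mu_trap <- truth$base_mean * 2^truth$true_log2fc
    total <- vapply(seq_len(reps), function(i) draw(mu_total), numeric(n))
    trap <- vapply(seq_len(reps), function(i) draw(mu_trap), numeric(n))
    dimnames(total) <- list(truth$gene_id, sprintf("total_%d", seq_len(reps)))
    dimnames(trap) <- list(truth$gene_id, sprintf("trap_%d", seq_len(reps)))
    list(trap = trap, total = total,
        pairing = data.frame(trap = colnames(trap), total = colnames(total)))
}

#' Generate a CAGE pileup with known TSS positions
#'
#' Lays each gene out on a synthetic chromosome (random strand, genes
#' spaced apart), puts the true TSS `true_utr5` bases upstream of the
#' coding start, and draws Poisson signal reads at the TSS plus Poisson
#' background across the 1 kb scan window. Decoy genes get a second
#' transcript with a more downstream coding start and their strongest
#' pileup planted between the two coding starts, so the
#' `excluded_downstream` rule fires; long-UTR genes exercise
#' `excluded_long_utr`.
#'
#' @param universe output of [generateUniverse()].
#' @param config defaults to the universe's config.
#' @return list with `track` ([CageTrack-class]), `models` (transcript-model
#'   table as from [readGtfModels()]) and `truth` (`data.frame`: `gene_id`,
#'   `true_tss`, `true_utr5`, `expected_status` under a noiseless track).
#' @export
generateCage <- function(universe, config = universe$config) {
    set.seed(childSeed(config$seed, 4L))
    ann <- universe$annotation
    tru <- universe$truth
    n <- nrow(ann)
    chrom <- "chrS1"
    span <- ann$transcript_length
    gap <- 2500L
    offset <- cumsum(c(2000L, span[-n] + gap))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    utr5 <- tru$true_utr5
    cds <- ann$cds_length
    utr3 <- ann$utr3_length

    tx_start <- offset
    tx_end <- offset + span
    coding_start <- ifelse(strand == "+", tx_start + utr5,
        tx_end - 1L - utr5)
    true_tss <- ifelse(strand == "+", tx_start, tx_end - 1L)

    models <- data.frame(
        transcript_id = ann$principal_transcript, gene_id = ann$gene_id,
        chrom = chrom, strand = strand, tx_start = tx_start,
        tx_end = tx_end, coding_start = as.integer(coding_start),
        cds_length = cds, exonic_length = span,
        utr5_annot = utr5, utr3_length = utr3,
        stringsAsFactors = FALSE
    )

    # decoy genes: second transcript whose coding start sits 300 nt further
    # downstream; the planted pileup lands between the two coding starts
    decoy <- which(tru$is_decoy)
    shift <- 300L
    if (length(decoy) > 0L) {
        d <- models[decoy, , drop = FALSE]
        d$transcript_id <- sub("\\.t1$", ".t2", d$transcript_id)
        d$coding_start <- ifelse(d$strand == "+", d$coding_start + shift,
            d$coding_start - shift)
        d$cds_length <- d$cds_length - shift
        d$utr5_annot <- d$utr5_annot + shift
        models <- rbind(models, d)
    }
    signal_pos <- true_tss
    signal_pos[decoy] <- ifelse(strand[decoy] == "+",
        coding_start[decoy] + shift %/% 2L,
        coding_start[decoy] - shift %/% 2L)

    pos_list <- vector("list", n)
    cnt_list <- vector("list", n)
    for (i in seq_len(n)) {
        p <- signal_pos[i]
        cnt <- max(1L, stats::rpois(1L, config$cage_signal))
        if (config$cage_background > 0) {
            if (strand[i] == "+") {
                win_from <- tx_start[i] - 1000L
                win_len <- max(coding_start[i], signal_pos[i] + 1L) - win_from
                bg_n <- stats::rpois(1L, config$cage_background * win_len)
                bg_pos <- win_from + sample.int(win_len, bg_n,
                    replace = TRUE) - 1L
            } else {
                win_to <- tx_end[i] - 1L + 1000L
                win_len <- win_to - min(coding_start[i], signal_pos[i] - 1L)
                bg_n <- stats::rpois(1L, config$cage_background * win_len)
                bg_pos <- win_to - sample.int(win_len, bg_n,
                    replace = TRUE) + 1L
            }
            p <- c(p, bg_pos)
            cnt <- c(cnt, rep(1L, bg_n))
        }
        pos_list[[i]] <- p
        cnt_list[[i]] <- cnt
    }
    gene_of <- rep(seq_len(n), lengths(pos_list))
    all_pos <- unlist(pos_list)
    all_cnt <- unlist(cnt_list)
    all_strand <- strand[gene_of]
    # aggregate counts landing on the same position and strand
    key <- paste(all_strand, all_pos)
    agg <- rowsum(all_cnt, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    track <- CageTrack(
        chrom = chrom,
        strand = vapply(parts, `[`, character(1), 1L),
        pos = as.integer(vapply(parts, `[`, character(1), 2L)),
        count = as.integer(agg[, 1L])
    )
    expected_status <- ifelse(tru$is_decoy, "excluded_downstream",
        ifelse(tru$is_long_utr, "excluded_long_utr", "called"))
    truth <- data.frame(
        gene_id = ann$gene_id, true_tss = as.integer(true_tss),
        true_utr5 = utr5, expected_status = expected_status,
        stringsAsFactors = FALSE
    )
    list(track = track, models = models, truth = truth)
}

# Random coding sequence of a given length and GC fraction.
.randomCds <- function(length, gc) {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
        prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Write simulated inputs in the formats the pipeline reads
#'
#' Emits a GTF of the CAGE gene models, a CDS FASTA (random sequences
#' matching each gene's length and GC fraction in expectation), a transcript
#' abundance TSV, the differential table TSV, the gene-set GMT, per-strand
#' bedGraph pileups, and a ground-truth TSV (for tests only).
#'
#' @param universe output of [generateUniverse()].
#' @param dir output directory (created if needed).
#' @param de optional [DifferentialTable-class] from [generateDeTable()].
#' @param cage optional output of [generateCage()].
#' @return named character vector of the paths written.
#' @export
writeSimulatedData <- function(universe, dir, de = NULL, cage = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ann <- universe$annotation
    paths <- c()
    set.seed(childSeed(universe$config$seed, 5L))

    if (is.null(cage))
        cage <- generateCage(universe)
    m <- cage$models
    exon <- GenomicRanges::GRanges(m$chrom,
        IRanges::IRanges(m$tx_start + 1L, m$tx_end), strand = m$strand)
    exon$type <- "exon"
    cds_start1 <- ifelse(m$strand == "+", m$coding_start + 1L,
        m$coding_start - m$cds_length + 2L)
    cdsr <- GenomicRanges::GRanges(m$chrom,
        IRanges::IRanges(cds_start1, cds_start1 + m$cds_length - 1L),
        strand = m$strand)
    cdsr$type <- "CDS"
    cdsr$phase <- 0L
    gtf <- c(exon, cdsr)
    gtf$source <- "riboshift_sim"
    gtf$transcript_id <- c(m$transcript_id, m$transcript_id)
    gtf$gene_id <- c(m$gene_id, m$gene_id)
    paths["gtf"] <- file.path(dir, "models.gtf")
    rtracklayer::export(gtf, paths[["gtf"]], format = "gtf")

    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(ann)), function(i) {
        .randomCds(ann$cds_length[i], ann$gc_cds[i])
    }, character(1)))
    names(seqs) <- ann$principal_transcript
    paths["cds_fasta"] <- file.path(dir, "cds.fa")
    Biostrings::writeXStringSet(seqs, paths[["cds_fasta"]])

    paths["abundance"] <- file.path(dir, "abundance.tsv")
    .writeTsv(data.frame(
        transcript_id = ann$principal_transcript, gene_id = ann$gene_id,
        tpm = ann$tpm, fpkm = ann$fpkm
    ), paths[["abundance"]])

    if (is.null(de))
        de <- generateDeTable(universe)
    paths["de_table"] <- file.path(dir, "de_table.tsv")
    .writeTsv(as.data.frame(de), paths[["de_table"]])

    paths["gmt"] <- file.path(dir, "sets.gmt")
    writeGmt(universe$sets, paths[["gmt"]])

    gr <- pileupPositions(cage$track)
    for (s in c("+", "-")) {
        tag <- if (s == "+") "plus" else "minus"
        sel <- gr[as.character(GenomicRanges::strand(gr)) == s]
        bg <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(sel)),
            start = GenomicRanges::start(sel) - 1L,
            end = GenomicRanges::start(sel),
            score = sel$score
        )
        bg <- bg[order(bg$chrom, bg$start), , drop = FALSE]
        p <- file.path(dir, sprintf("cage_%s.bedGraph", tag))
        utils::write.table(bg, p, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
        paths[paste0("cage_", tag)] <- p
    }

    paths["truth"] <- file.path(dir, "ground_truth.tsv")
    .writeTsv(merge(universe$truth, cage$truth, by = "gene_id"),
        paths[["truth"]])
    paths
}
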