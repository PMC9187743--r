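# End-to-end orchestration: one declarative config, deterministic outputs,
# a manifest echoing every threshold used.

.defaultRunConfig <- function() {
    list(
        seed = 1L,
        output_dir = "riboshift_out",
        n_perm = 1000L,
        alpha_adj = 0.1,
        alpha_nominal = 0.05,
        expression_threshold = 2,
        expression_measure = "fpkm",
        top_n = 500L,
        min_set = 20L,
        max_set = 50L,
        overlap_fraction = 0.9,
        window_upstream = 1000L,
        max_utr5 = 500L
    )
}

#' Validate and normalize a pipeline run configuration
#'
#' @param config a named list or a path to a YAML/JSON file. Recognized
#'   fields: `seed`, `output_dir`, `n_perm`, `alpha_adj`, `alpha_nominal`,
#'   `expression_threshold`, `expression_measure`, `top_n`, `min_set`,
#'   `max_set`, `overlap_fraction`, `window_upstream`, `max_utr5`, and
#'   either `simulate` (a list of [simulationConfig()] arguments) or
#'   `inputs` (paths: `gtf`, `abundance`, `cds_fasta` (optional),
#'   `de_table`, `gmt`, `cage_plus`/`cage_minus` (optional)).
#' @return the completed config list.
#' @export
validateRunConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        config <- if (grepl("\\.json$", config))
            jsonlite::read_json(config, simplifyVector = TRUE)
        else yaml::read_yaml(config)
    }
    cfg <- utils::modifyList(.defaultRunConfig(), config)
    for (th in c("alpha_adj", "alpha_nominal"))
        .assertScalarNumber(cfg[[th]], th, lo = 0, hi = 1)
    if (is.null(cfg$simulate) && is.null(cfg$inputs))
        stop("config needs either 'simulate' parameters or 'inputs' paths")
    if (!is.null(cfg$inputs)) {
        required <- c("gtf", "abundance", "de_table", "gmt")
        missing_in <- setdiff(required, names(cfg$inputs))
        if (length(missing_in) > 0L)
            stop("inputs missing: ", paste(missing_in, collapse = ", "))
        for (nm in names(cfg$inputs)) {
            p <- cfg$inputs[[nm]]
            if (!file.exists(p))
                stop("input file for '", nm, "' does not exist: ", p)
        }
    }
    cfg
}

#' Run the full analysis pipeline
#'
#' Builds (or simulates) the gene annotation, optionally calls TSS/5'UTRs
#' from CAGE pileups, runs the mean-rank gene-set statistics on the
#' fold-change ranking, the CDS-length bias analyses, the length-ranked
#' gene-set analysis, and the term z-score network clustering, writing every
#' result table plus a run manifest to the output directory. Deterministic:
#' re-running the same config reproduces the outputs.
#'
#' @param config see [validateRunConfig()].
#' @return invisibly, a list with the in-memory results and the paths
#'   written.
#' @export
runPipeline <- function(config) {
    cfg <- validateRunConfig(config)
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$output_dir, f)
    paths <- character()
    results <- list()

    if (!is.null(cfg$simulate)) {
        sim_cfg <- do.call(simulationConfig,
            utils::modifyList(cfg$simulate, list(seed = cfg$seed)))
        universe <- generateUniverse(sim_cfg)
        ann <- universe$annotation
        de <- generateDeTable(universe)
        sets <- universe$sets
        cage <- generateCage(universe)
        models <- cage$models
        track <- cage$track
        results$universe <- universe
    } else {
        models <- readGtfModels(cfg$inputs$gtf)
        abundance <- readAbundance(cfg$inputs$abundance)
        cds <- if (!is.null(cfg$inputs$cds_fasta))
            readCdsFasta(cfg$inputs$cds_fasta) else NULL
        ann <- buildGeneTable(models, abundance, cdsSeqs = cds)
        de <- readDeTable(cfg$inputs$de_table)
        sets <- readGmt(cfg$inputs$gmt)
        track <- if (!is.null(cfg$inputs$cage_plus) ||
                !is.null(cfg$inputs$cage_minus))
            readCageBedGraph(cfg$inputs$cage_plus, cfg$inputs$cage_minus)
        else NULL
    }

    if (!all(is.na(ann[[cfg$expression_measure]])))
        ann <- filterExpressed(ann, cfg$expression_threshold,
            cfg$expression_measure)
    results$annotation <- ann

    if (!is.null(track)) {
        tss <- callAllTss(models, track,
            windowUpstream = cfg$window_upstream, maxUtr5 = cfg$max_utr5)
        ann <- applyTssCalls(ann, tss$calls)
        results$tss <- tss
        paths["tss_calls"] <- out("tss_calls.tsv")
        writeTssCalls(tss$calls, models, bedPath = out("tss_calls.bed"),
            tsvPath = paths[["tss_calls"]])
    }

    detected <- intersect(geneIds(de), geneIds(ann))
    metric <- de$log2fc[match(detected, de$gene_id)]
    names(metric) <- detected

    set_stats <- runSetStats(metric, sets, method = "mean_rank",
        nPerm = cfg$n_perm, seed = childSeed(cfg$seed, 101L))
    results$set_stats <- set_stats
    paths["set_stats"] <- out("set_stats.tsv")
    writeSetStats(set_stats, paths[["set_stats"]])

    bins <- lengthBinReport(de, ann)
    results$length_bins <- bins
    paths["length_bins"] <- out("length_bins.tsv")
    .writeTsv(bins$per_bin, paths[["length_bins"]])

    top_n <- min(cfg$top_n, floor(length(detected) / 2))
    topn <- topNLengthComparison(de, ann, n = top_n)
    results$top_n <- topn
    paths["top_n"] <- out("top_n_length_z.tsv")
    .writeTsv(topn, paths[["top_n"]])

    lgsa <- lengthRankedGsa(ann, sets, minSize = cfg$min_set,
        maxSize = cfg$max_set, nPerm = cfg$n_perm,
        seed = childSeed(cfg$seed, 102L))
    results$length_gsa <- lgsa
    paths["length_gsa_shortest"] <- out("length_gsa_shortest_first.tsv")
    .writeTsv(lgsa$full$shortest_first, paths[["length_gsa_shortest"]])
    paths["length_gsa_longest"] <- out("length_gsa_longest_first.tsv")
    .writeTsv(lgsa$full$longest_first, paths[["length_gsa_longest"]])

    tz <- termZScores(sets, de)
    results$term_z <- tz
    paths["term_zscores"] <- out("term_zscores.tsv")
    .writeTsv(tz, paths[["term_zscores"]])

    pruned <- pruneRedundantTerms(sets, cfg$overlap_fraction)
    network <- buildTermNetwork(pruned$sets, annotations = tz)
    clusters <- clusterTerms(network)
    results$network <- network
    results$clusters <- clusters
    paths["term_edges"] <- out("term_edges.tsv")
    paths["term_clusters"] <- out("term_clusters.tsv")
    writeTermNetwork(network, clusters, edgePath = paths[["term_edges"]],
        membershipPath = paths[["term_clusters"]])

    manifest <- list(
        package = "riboshift",
        version = as.character(utils::packageVersion("riboshift")),
        seed = cfg$seed,
        parameters = cfg[setdiff(names(cfg), c("inputs", "simulate"))],
        simulate = cfg$simulate,
        inputs = cfg$inputs,
        outputs = as.list(paths)
    )
    paths["manifest"] <- out("manifest.json")
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
        pretty = TRUE, digits = NA, null = "null")
    invisible(list(results = results, paths = paths, config = cfg))
}
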