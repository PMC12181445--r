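# End-to-end orchestration: simulate -> preprocess -> score -> contrast ->
# cluster -> GSEA -> DE (-> ORA), driven by a single flat YAML config. All
# randomness flows from one master seed expanded deterministically per
# stage, and the manifest records everything needed to reproduce a run.

pipelineDefaults <- function() {
    list(
        geneset = "builtin:senskin",
        seed = 1L,
        stages = c("simulate", "score", "contrast", "cluster", "gsea", "de"),
        simulate = list(sc = list(), bulk = list(n_samples_per_condition = 24L)),
        score = list(scale = 1e4),
        contrast = list(alpha = 0.05, adjust = "bonferroni"),
        cluster = list(k = 5L, skewness_threshold = 2, log_mode = "global",
                       groupby = "sample_id"),
        gsea = list(n_perm = 1000L),
        de = list(lnfc_cutoff = 0.25, alpha = 0.05),
        ora = list(pathways_gmt = NULL, fdr_alpha = 0.05))
}

mergeConfig <- function(defaults, user) {
    for (k in names(user)) {
        defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]]))
            mergeConfig(defaults[[k]], user[[k]]) else user[[k]]
    }
    defaults
}

# Map a flat snake_case YAML section onto simConfig() arguments.
simConfigFromList <- function(x, seed) {
    args <- list()
    map <- c(n_genes = "nGenes", conditions = "conditions",
             n_samples_per_condition = "nSamplesPerCondition",
             effect_delta = "effectDelta", down_delta = "downDelta",
             affected_fraction = "affectedFraction",
             nb_dispersion = "nbDispersion",
             libsize_lognormal = "libsizeLognormal")
    for (k in names(map)) if (!is.null(x[[k]])) args[[map[[k]]]] <- unlist(x[[k]])
    if (!is.null(x$cells_per_type))
        args$cellsPerType <- unlist(x$cells_per_type)
    args$seed <- seed
    do.call(simConfig, args)
}

# Deterministic per-stage seed expansion kept inside 32-bit integer range.
stageSeed <- function(master, index) {
    as.integer((as.numeric(master) + index * 1000003) %% 2147483647)
}

resolveGeneSet <- function(spec) {
    if (identical(spec, "builtin:senskin")) return(builtinSenSkin())
    if (!is.character(spec) || length(spec) != 1L)
        stop("config field 'geneset' must be a path or 'builtin:senskin'")
    if (!file.exists(spec))
        stop("gene-set file not found (config field 'geneset'): ", spec)
    sets <- readSignedGmt(spec)
    if (!length(sets)) stop("gene-set file is empty: ", spec)
    sets[[1L]]
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on simulated data:
#' single-cell and bulk simulation, log-normalization and z-scoring,
#' composite scoring, per-cell-type contrasts, pseudobulk correlation
#' clustering, phenotype-permutation GSEA, Wilcoxon differential expression,
#' and (when a pathway GMT is configured) over-representation analysis of
#' the DE genes. All tabular outputs are TSV; a \code{manifest.json} records
#' package version, parameters, per-stage seeds and output checksums.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config Path to a YAML config file, or an equivalent nested list.
#'   See the packaged \code{inst/extdata/demo_config.yaml} for the layout;
#'   omitted fields take documented defaults.
#' @param outdir Output directory (created if needed); overrides the config.
#' @param seed Master seed; overrides the config.
#' @param verbose Print stage progress.
#' @return Invisibly, the manifest list.
#' @examples
#' cfg <- system.file("extdata", "demo_config.yaml", package = "SenSkinTools")
#' \donttest{
#' manifest <- runPipeline(cfg, outdir = tempfile("run"), seed = 1)
#' }
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL, verbose = TRUE) {
    user <- if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        yaml::read_yaml(config)
    } else config
    cfg <- mergeConfig(pipelineDefaults(), user)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    if (is.null(outdir)) outdir <- cfg$outdir
    if (is.null(outdir)) stop("an output directory is required ('outdir')")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (verbose) message(sprintf(...))

    runStage <- function(stage, fn) {
        tryCatch(fn(), error = function(e)
            stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                 call. = FALSE))
    }
    outputs <- character(0)
    seeds <- list(sc = stageSeed(cfg$seed, 1L), bulk = stageSeed(cfg$seed, 2L),
                  gsea = stageSeed(cfg$seed, 3L))
    set <- runStage("geneset", function() resolveGeneSet(cfg$geneset))
    stages <- cfg$stages

    sce <- se <- scores <- NULL
    if ("simulate" %in% stages) {
        say("stage simulate: single-cell + bulk negative-binomial draws")
        runStage("simulate", function() {
            sce <<- simulateCells(simConfigFromList(cfg$simulate$sc, seeds$sc), set)
            se <<- simulateBulk(simConfigFromList(cfg$simulate$bulk, seeds$bulk), set)
            writeCellCounts(sce, file.path(outdir, "sc_counts"))
            outputs <<- c(outputs, writeBulkCounts(se, file.path(outdir, "bulk_counts.tsv")))
        })
    }
    if ("score" %in% stages) {
        say("stage score: log-normalize, z-score, composite score")
        runStage("score", function() {
            sce <<- zscoreGenes(logNormalize(sce, scale = cfg$score$scale))
            scores <<- compositeScore(sce, set)
            outputs <<- c(outputs, writeTsv(
                cbind(cell_id = rownames(scores), as.data.frame(scores)),
                file.path(outdir, "scores.tsv")))
        })
    }
    if ("contrast" %in% stages) {
        say("stage contrast: per-cell-type Wilcoxon rank-sum tests")
        runStage("contrast", function() {
            ct <- contrastByCellType(scores, alpha = cfg$contrast$alpha,
                                     adjust = cfg$contrast$adjust)
            outputs <<- c(outputs, writeTsv(ct, file.path(outdir, "contrasts.tsv")))
        })
    }
    if ("cluster" %in% stages) {
        say("stage cluster: pseudobulk correlation, complete linkage (k = %d)",
            cfg$cluster$k)
        runStage("cluster", function() {
            pb <- pseudobulk(sce, groupby = unlist(cfg$cluster$groupby))
            pb <- gatedLogTransform(pb, threshold = cfg$cluster$skewness_threshold,
                                    mode = cfg$cluster$log_mode)
            present <- unionGenes(set)[!is.na(matchGenes(unionGenes(set),
                                                         rownames(pb)))]
            corr <- geneCorrelation(pb, genes = present)
            cl <- completeLinkage(corr, k = cfg$cluster$k)
            outputs <<- c(outputs,
                writeTsv(data.frame(gene = rownames(corr),
                                    as.data.frame(geneCorrelations(cl)),
                                    check.names = FALSE),
                         file.path(outdir, "correlation.tsv")),
                writeTsv(data.frame(gene = names(clusterAssignments(cl)),
                                    cluster = unname(clusterAssignments(cl)),
                                    dendrogram_position =
                                        order(dendrogramOrder(cl))),
                         file.path(outdir, "clusters.tsv")))
        })
    }
    gseaRes <- NULL
    if ("gsea" %in% stages) {
        say("stage gsea: phenotype permutation, %d permutations", cfg$gsea$n_perm)
        runStage("gsea", function() {
            gseaRes <<- gseaPhenotype(
                SummarizedExperiment::assay(se, "counts"),
                # second condition (aged/UV-exposed) first so positive NES
                # means enrichment there
                factor(se$group, levels = rev(unique(se$group))),
                set, nPerm = cfg$gsea$n_perm, seed = seeds$gsea)
            flat <- as.data.frame(gseaRes[, setdiff(colnames(gseaRes),
                                                    "leading_edge")])
            flat$leading_edge_size <- lengths(gseaRes$leading_edge)
            outputs <<- c(outputs, writeTsv(flat, file.path(outdir, "gsea.tsv")))
        })
    }
    deRes <- NULL
    if ("de" %in% stages) {
        say("stage de: Wilcoxon rank-sum differential expression")
        runStage("de", function() {
            deRes <<- wilcoxonDE(sce,
                                 factor(sce$condition,
                                        levels = rev(unique(sce$condition))),
                                 lnfcCutoff = cfg$de$lnfc_cutoff,
                                 alpha = cfg$de$alpha)
            outputs <<- c(outputs, writeTsv(deRes, file.path(outdir, "de.tsv")))
        })
    }
    if ("ora" %in% stages) {
        say("stage ora: hypergeometric over-representation")
        runStage("ora", function() {
            if (is.null(cfg$ora$pathways_gmt))
                stop("config field 'ora: pathways_gmt' is required")
            pw <- readSignedGmt(cfg$ora$pathways_gmt)
            names(pw) <- vapply(pw, geneSetName, character(1))
            query <- deRes$gene[deRes$passes]
            res <- ora(query, pw, universe = rownames(sce),
                       fdrAlpha = cfg$ora$fdr_alpha)
            outputs <<- c(outputs, writeTsv(res, file.path(outdir, "ora.tsv")))
        })
    }

    manifest <- list(
        package = "SenSkinTools",
        version = as.character(utils::packageVersion("SenSkinTools")),
        master_seed = cfg$seed,
        stage_seeds = seeds,
        geneset = if (identical(cfg$geneset, "builtin:senskin"))
            "builtin:senskin" else normalizePath(cfg$geneset),
        parameters = cfg[setdiff(names(cfg), c("outdir"))],
        outputs = as.list(tools::md5sum(outputs)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
}
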