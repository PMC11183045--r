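#' Run the full synthetic-data pipeline
#'
#' Composes every stage on data generated from planted ground truth:
#' simulation, single-cell QC/normalization/clustering/annotation, metacell
#' aggregation, regulon inference and motif pruning, AUCell activity
#' scoring, CSI module detection, REML variance decomposition with
#' knee-rule selection, bulk validation (moderated-t DE + ssGSEA + group
#' comparison on two cohorts), and hub-target intersection with ROC
#' diagnostics. All randomness derives from `config$seed`.
#'
#' @param config Nested parameter list from [defaultPipelineConfig()] or
#'   [loadConfig()].
#' @param outdir Optional directory; when given, the main intermediates
#'   are written as TSV/MTX/GMT with a provenance sidecar.
#' @return List with the truth, the per-stage results, the hub report and
#'   a run manifest (parameter snapshot + seed registry + timings).
#' @export
runFullPipeline <- function(config = defaultPipelineConfig(), outdir = NULL) {
    t0 <- Sys.time()
    seed <- config$seed
    timing <- c()
    tick <- function(stage, t) {
        timing[[stage]] <<- round(as.numeric(Sys.time()) - as.numeric(t), 2)
        Sys.time()
    }

    ## --- simulate ---------------------------------------------------------
    sm <- config$sim
    truth <- simulateTruth(
        n_celltypes = sm$n_celltypes, n_genes = sm$n_genes,
        n_tfs = sm$n_tfs, targets_per_tf = sm$targets_per_tf,
        n_responsive = sm$n_responsive, group_effect = sm$group_effect,
        composition_normal = sm$composition_normal,
        composition_dcm = sm$composition_dcm,
        n_hubs = sm$n_hubs, hub_regulons = sm$hub_regulons,
        markers_per_type = sm$markers_per_type, marker_fold = sm$marker_fold,
        loading_range = sm$loading_range,
        celltype_sd_range = sm$celltype_sd_range,
        dispersion = sm$dispersion,
        libsize_meanlog = sm$libsize_meanlog,
        libsize_sdlog = sm$libsize_sdlog,
        batch_sd = sm$batch_sd, seed = seed)
    sce <- simulateSingleCell(truth, sm$n_cells_per_group,
                              sm$n_samples_per_group, seed = seed + 1L)
    bulk1 <- simulateBulk(truth, sm$bulk1_n, sm$bulk_noise_sd,
                          seed = seed + 2L)
    bulk2 <- simulateBulk(truth, sm$bulk2_n, sm$bulk_noise_sd,
                          seed = seed + 3L)
    motif <- simulateMotifTable(truth, sm$true_support_rate,
                                sm$false_support_rate, seed = seed + 4L)
    t1 <- tick("simulate", t0)

    ## --- single-cell QC / clustering / annotation -------------------------
    qc <- config$scqc
    sce <- qcFilter(sce, qc$min_genes, qc$max_genes)
    sce <- normalizeCells(sce, qc$scale)
    hvg <- selectHVG(sce, qc$n_hvg)
    pca <- scalePCA(sce, hvg, qc$n_pcs, qc$clip)
    scores <- batchCenter(pca$scores, sce$batch)
    clusters <- clusterCells(scores, qc$k_neighbors, qc$resolution,
                             seed = seed + 5L)
    cm <- clusterMeans(sce, clusters)
    ann <- annotateClusters(cm, truth$markers)
    celltype <- stats::setNames(ann$cell_type, ann$cluster)[as.character(clusters)]
    composition <- cellComposition(
        data.frame(group = sce$group, cell_type = celltype))
    t2 <- tick("scqc", t1)

    ## --- metacells --------------------------------------------------------
    mcfg <- config$metacell
    micro <- overclusterCells(scores, sce$group, mcfg$resolution,
                              mcfg$k_neighbors, seed = seed + 6L)
    sce$cell_type_called <- unname(celltype)
    mc <- aggregateMetacells(sce, micro, mcfg$min_cells, mcfg$strict,
                             qc$scale)
    t3 <- tick("metacell", t2)

    ## --- regulon assembly -------------------------------------------------
    g <- config$grn
    floor <- if (identical(g$floor, "auto")) NULL else g$floor
    edges <- inferImportance(mc, truth$tfs, g$lambda, floor)
    regulons <- assembleRegulons(edges, motif, g$top_n_per_tf,
                                 g$min_regulon_size)
    genesets <- regulonsToGeneSets(regulons)
    t4 <- tick("grn", t3)

    ## --- activity (per cell: preserves the residual heterogeneity the
    ## knee rule needs; see the methods vignette) --------------------------
    ras <- rasMatrix(sce, regulons, config$activity$top_fraction)
    rss <- regulonSpecificity(ras, celltype)
    t5 <- tick("activity", t4)

    ## --- CSI modules ------------------------------------------------------
    pcc <- pccMatrix(ras)
    csi <- csiMatrix(pcc, strict = config$csi$strict)
    k_mod <- if (identical(config$csi$k_modules, "auto"))
        max(1L, as.integer(round(ncol(csi) / 50))) else
        min(as.integer(config$csi$k_modules), ncol(csi))
    modules <- clusterModules(csi, k_mod, config$csi$linkage)
    t6 <- tick("csi", t5)

    ## --- variance decomposition ------------------------------------------
    vd <- decomposeAll(ras, modules, celltype, sce$group,
                       config$vardecomp$slope_threshold)
    responsive_called <- attr(vd, "selected")
    t7 <- tick("vardecomp", t6)

    ## --- bulk validation --------------------------------------------------
    bv <- config$bulkval
    sel_sets <- genesets[intersect(responsive_called, names(genesets))]
    bulk_results <- lapply(list(bulk1 = bulk1, bulk2 = bulk2), function(b) {
        de <- deModerated(b, lfc_threshold = bv$lfc_threshold,
                          fdr_threshold = bv$fdr_threshold)
        comp <- NULL
        if (length(sel_sets)) {
            sc <- ssgseaScore(b, sel_sets, bv$alpha, bv$normalize)
            comp <- compareScores(sc, SummarizedExperiment::colData(b)$group)
        }
        list(de = de, compare = comp)
    })
    t8 <- tick("bulkval", t7)

    ## --- hub targets ------------------------------------------------------
    hub_report <- list(hubs = character(0), shared = character(0),
                       consistent = character(0), multi_targets = character(0))
    roc <- NULL
    diff_sets <- lapply(bulk_results, function(r) {
        if (is.null(r$compare)) return(stats::setNames(numeric(0), character(0)))
        sig <- r$compare[r$compare$fdr < bv$fdr_threshold & r$compare$direction != 0, ]
        stats::setNames(sig$direction, sig$set)
    })
    inter <- intersectRegulons(diff_sets)
    use_reg <- if (config$hub$consistent_only) inter$consistent else inter$shared
    if (length(use_reg) >= 2) {
        cmt <- countMultiTargets(regulons[use_reg], config$hub$min_occurrence)
        ht <- hubTargets(cmt$multi_targets,
                         lapply(bulk_results, `[[`, "de"),
                         regulons[use_reg])
        hub_report <- list(hubs = ht$hubs, shared = inter$shared,
                           consistent = inter$consistent,
                           multi_targets = cmt$multi_targets,
                           provenance = ht$provenance,
                           differential_targets = ht$differential_targets)
        if (length(ht$hubs)) {
            m1 <- SummarizedExperiment::assay(bulk1, "exprs")
            de1 <- bulk_results$bulk1$de
            roc <- lapply(stats::setNames(ht$hubs, ht$hubs), function(h) {
                # orient by the observed fold-change direction of the hub
                dirn <- if (de1$log2FC[de1$gene == h] >= 0) "higher" else "lower"
                rocBootstrapCI(m1[h, ],
                               SummarizedExperiment::colData(bulk1)$group,
                               positive = "DCM", direction = dirn,
                               n_boot = config$hub$n_boot,
                               seed = seed + 7L)
            })
        }
    }
    t9 <- tick("hub", t8)

    manifest <- list(seed = seed, params = config, timing_sec = timing,
                     n_cells_postqc = ncol(sce), n_metacells = ncol(mc),
                     n_regulons = length(regulons),
                     n_selected = length(responsive_called))
    result <- list(truth = truth, sce = sce, clusters = clusters,
                   annotation = ann, composition = composition,
                   metacells = mc, edges = edges, regulons = regulons,
                   genesets = genesets, ras = ras, rss = rss,
                   pcc = pcc, csi = csi,
                   modules = modules, vardecomp = vd,
                   responsive_called = responsive_called,
                   bulk = list(bulk1 = bulk1, bulk2 = bulk2),
                   bulk_results = bulk_results, hub_report = hub_report,
                   roc = roc, manifest = manifest)
    if (!is.null(outdir)) .writePipelineOutputs(result, outdir)
    result
}

.writePipelineOutputs <- function(result, outdir) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    writeCellMatrixMTX(result$sce, file.path(outdir, "cells"),
                       provenance = list(seed = result$manifest$seed))
    writeGMT(result$genesets, file.path(outdir, "regulons.gmt"))
    utils::write.table(result$vardecomp, file.path(outdir, "vardecomp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        data.frame(unit = rownames(result$ras), result$ras,
                   check.names = FALSE),
        file.path(outdir, "ras.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    jsonlite::write_json(
        list(hubs = result$hub_report$hubs,
             consistent = result$hub_report$consistent,
             multi_targets = result$hub_report$multi_targets,
             manifest = result$manifest[c("seed", "n_cells_postqc",
                                          "n_metacells", "n_regulons",
                                          "n_selected")]),
        file.path(outdir, "hub_report.json"), auto_unbox = TRUE)
    invisible(outdir)
}
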