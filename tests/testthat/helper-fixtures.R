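# Shared small-scale fixtures, built once per test run. All sizes are kept
# small so the whole suite stays fast; every object is seed-deterministic.

.fix_env <- new.env()

smallTruth <- function() {
    if (is.null(.fix_env$truth))
        .fix_env$truth <- simulateTruth(
            n_celltypes = 4L, n_genes = 600L, n_tfs = 12L,
            targets_per_tf = 20L, n_responsive = 3L, group_effect = 2,
            composition_normal = c(A = 0.55, B = 0.25, C = 0.12, D = 0.08),
            composition_dcm = c(A = 0.35, B = 0.35, C = 0.18, D = 0.12),
            n_hubs = 3L, hub_regulons = 3L, markers_per_type = 8L,
            seed = 101L)
    .fix_env$truth
}

smallSCE <- function() {
    if (is.null(.fix_env$sce)) {
        sce <- simulateSingleCell(smallTruth(), n_cells_per_group = 400L,
                                  n_samples_per_group = 2L, seed = 102L)
        sce <- normalizeCells(qcFilter(sce, 50L, 5000L))
        .fix_env$sce <- sce
    }
    .fix_env$sce
}

smallScores <- function() {
    if (is.null(.fix_env$scores)) {
        sce <- smallSCE()
        pca <- scalePCA(sce, selectHVG(sce, 200L), n_pcs = 20L)
        .fix_env$scores <- batchCenter(pca$scores, sce$batch)
    }
    .fix_env$scores
}

smallMetacells <- function() {
    if (is.null(.fix_env$mc)) {
        sce <- smallSCE()
        micro <- overclusterCells(smallScores(), sce$group, resolution = 4,
                                  k_neighbors = 15L, seed = 103L)
        .fix_env$mc <- aggregateMetacells(sce, micro, min_cells = 5L)
    }
    .fix_env$mc
}

smallRegulons <- function() {
    if (is.null(.fix_env$regs)) {
        tr <- smallTruth()
        motif <- simulateMotifTable(tr, 1, 0.05, seed = 104L)
        edges <- inferImportance(smallMetacells(), tr$tfs)
        .fix_env$regs <- assembleRegulons(edges, motif, top_n_per_tf = 40L,
                                          min_regulon_size = 5L)
    }
    .fix_env$regs
}

# independent BH step-up oracle (O(m log m)), used against stats::p.adjust
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- rep(NA_real_, m)
    running <- Inf
    rank_desc <- m:1
    for (i in seq_len(m)) {
        cand <- p[o[i]] * m / rank_desc[i]
        running <- min(running, cand)
        adj[o[i]] <- min(running, 1)
    }
    adj
}

# O(N^3) brute-force CSI oracle, written directly from the definition
csiOracle <- function(pcc, strict = FALSE) {
    n <- nrow(pcc)
    out <- matrix(1, n, n, dimnames = dimnames(pcc))
    for (a in seq_len(n)) for (b in seq_len(n)) {
        if (a == b) next
        v <- pcc[a, b]
        cnt <- 0L
        for (cc in seq_len(n)) {
            if (cc == a || cc == b) next
            ok <- if (strict) pcc[a, cc] < v && pcc[b, cc] < v
                  else pcc[a, cc] <= v && pcc[b, cc] <= v
            if (ok) cnt <- cnt + 1L
        }
        out[a, b] <- cnt / (n - 2)
    }
    out
}

# brute-force recovery-curve oracle: step integral of #targets among the
# top-i ranked genes, i = 1..k, normalized by the best achievable area
aucellOracle <- function(x, ids, targets, top_fraction) {
    G <- length(x)
    ord <- order(-x, rank(ids, ties.method = "first"))
    ranked <- ids[ord]
    k <- ceiling(top_fraction * G)
    m <- length(intersect(targets, ids))
    curve <- cumsum(ranked %in% targets)[seq_len(k)]
    mm <- min(m, k)
    best <- sum(pmin(seq_len(k), mm))
    sum(curve) / best
}
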