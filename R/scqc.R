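#' Quality-filter cells by detected-gene count
#'
#' Removes cells expressing fewer than `min_genes` or more than `max_genes`
#' genes; the boundaries themselves are retained (a cell with exactly 200
#' or 5000 detected genes survives the default filter).
#'
#' @param sce [SingleCellExperiment] with a `counts` assay.
#' @param min_genes,max_genes Inclusive bounds on the number of genes with
#'   nonzero counts per cell.
#' @return The filtered [SingleCellExperiment]; genes are untouched.
#' @export
qcFilter <- function(sce, min_genes = 200L, max_genes = 5000L) {
    detected <- Matrix::colSums(SingleCellExperiment::counts(sce) > 0)
    keep <- detected >= min_genes & detected <= max_genes
    if (!any(keep))
        stop(sprintf("all %d cells removed by QC (%d below %d genes, %d above %d)",
                     length(keep), sum(detected < min_genes), min_genes,
                     sum(detected > max_genes), max_genes))
    sce[, keep]
}

#' Library-size log-normalization
#'
#' `x -> ln(1 + scale * x / total)` per cell, the standard log-normal
#' counts transform (natural log).
#'
#' @param sce [SingleCellExperiment] with `counts`.
#' @param scale Size-factor target (default 1e4).
#' @return The input with a `logcounts` assay added and
#'   `metadata()$layer_tag = "lognorm"`.
#' @export
normalizeCells <- function(sce, scale = 10000) {
    m <- SingleCellExperiment::counts(sce)
    totals <- Matrix::colSums(m)
    if (any(totals == 0))
        stop("cell with zero total counts; run qcFilter() first")
    ln <- m %*% Matrix::Diagonal(x = scale / totals)
    ln@x <- log1p(ln@x)
    dimnames(ln) <- dimnames(m)
    SingleCellExperiment::logcounts(sce) <- ln
    S4Vectors::metadata(sce)$layer_tag <- "lognorm"
    sce
}

#' Select highly variable genes by standardized variance
#'
#' Fits a degree-2 polynomial mean-variance trend (log10 variance on log10
#' mean of raw counts), standardizes each gene's counts by the trend's
#' predicted SD with clipping at `sqrt(n)`, and ranks genes by the variance
#' of the standardized values (the vst-style criterion). Ties break by gene
#' id so selection is deterministic.
#'
#' @param sce Normalized [SingleCellExperiment] (counts still present).
#' @param n Number of genes to return.
#' @return Character vector of the top `n` gene ids.
#' @export
selectHVG <- function(sce, n = 2000L) {
    m <- SingleCellExperiment::counts(sce)
    if (n > nrow(m)) stop(sprintf("n = %d exceeds the %d genes present", n, nrow(m)))
    mu <- Matrix::rowSums(m) / ncol(m)
    v <- Matrix::rowSums(m^2) / ncol(m) - mu^2
    v <- v * ncol(m) / (ncol(m) - 1)
    use <- mu > 0 & v > 0
    fit <- stats::lm(log10(v[use]) ~ stats::poly(log10(mu[use]), 2))
    sd_fit <- rep(0, nrow(m))
    sd_fit[use] <- sqrt(10^stats::fitted(fit))
    std_var <- rep(0, nrow(m))
    names(std_var) <- rownames(m)
    clip <- sqrt(ncol(m))
    dm <- as.matrix(m[use, , drop = FALSE])
    z <- (dm - mu[use]) / sd_fit[use]
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[use] <- apply(z, 1, stats::var)
    ord <- order(-std_var, names(std_var))
    rownames(m)[ord][seq_len(n)]
}

#' Scale, clip and run exact PCA on the HVG submatrix
#'
#' Genes are z-scored across cells, clipped to `[-clip, clip]`, and
#' decomposed by exact PCA. Component signs follow the convention that the
#' largest-magnitude gene loading of each PC is positive.
#'
#' @param sce Normalized [SingleCellExperiment].
#' @param hvg Character vector of genes to use.
#' @param n_pcs Number of components.
#' @param clip Z-score clipping bound.
#' @return List with `scores` (cells x PCs), `rotation`, `sdev`, and the
#'   scaled matrix dimensions; `scores` is also stored in the returned
#'   `$sce` under `reducedDim(, "PCA")`.
#' @export
scalePCA <- function(sce, hvg, n_pcs = 30L, clip = 10) {
    if (!length(hvg)) stop("hvg must be non-empty")
    x <- as.matrix(SingleCellExperiment::logcounts(sce)[hvg, , drop = FALSE])
    if (n_pcs > min(dim(x))) stop("n_pcs exceeds matrix rank bound")
    mu <- rowMeans(x)
    s <- apply(x, 1, stats::sd)
    s[s == 0] <- 1
    z <- (x - mu) / s
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    pc <- stats::prcomp(Matrix::t(z), center = FALSE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        if (rot[which.max(abs(rot[, j])), j] < 0) {
            rot[, j] <- -rot[, j]
            scores[, j] <- -scores[, j]
        }
    }
    SingleCellExperiment::reducedDim(sce, "PCA") <- scores
    list(sce = sce, scores = scores, rotation = rot,
         sdev = pc$sdev[seq_len(k)], scaled = z)
}

#' Center batches in PC space
#'
#' Subtracts each batch's centroid from its cells' PC scores and adds back
#' the global centroid — a linear stand-in for iterative batch integration
#' that removes constant PC-space offsets exactly.
#'
#' @param scores Cells x PCs matrix.
#' @param batch Batch label per cell.
#' @return Adjusted score matrix of the same shape.
#' @export
batchCenter <- function(scores, batch) {
    stopifnot(nrow(scores) == length(batch))
    singles <- names(which(table(batch) == 1))
    if (length(singles))
        warning(sprintf("batch(es) with a single cell centered on themselves: %s",
                        paste(singles, collapse = ", ")))
    global <- colMeans(scores)
    out <- scores
    for (b in unique(batch)) {
        idx <- which(batch == b)
        ctr <- colMeans(scores[idx, , drop = FALSE])
        out[idx, ] <- sweep(scores[idx, , drop = FALSE], 2, ctr - global)
    }
    out
}

#' Graph-based clustering of cells
#'
#' Builds a shared-nearest-neighbor graph (Euclidean kNN, Jaccard edge
#' weights) on the PC scores and maximizes modularity by iterative local
#' moving (Louvain) at the given resolution. Cluster labels are contiguous
#' integers from 0, ordered by decreasing cluster size.
#'
#' @param scores Cells x PCs matrix.
#' @param k_neighbors Neighbors for the SNN graph.
#' @param resolution Modularity resolution parameter.
#' @param seed Seed for the community-detection restarts.
#' @return Integer vector of labels (named by cell if `scores` has
#'   rownames).
#' @export
clusterCells <- function(scores, k_neighbors = 20L, resolution = 0.7,
                         seed = 1L) {
    if (nrow(scores) < k_neighbors + 1)
        stop("need at least k_neighbors + 1 cells")
    g <- scran::buildSNNGraph(scores, k = k_neighbors, transposed = TRUE,
                              type = "jaccard")
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    lab <- as.integer(igraph::membership(cl))
    sizes <- table(lab)
    relabel <- stats::setNames(seq_along(sizes) - 1L,
                               names(sort(sizes, decreasing = TRUE)))
    out <- relabel[as.character(lab)]
    names(out) <- rownames(scores)
    out
}

.log2fc <- function(mx, my) log2((mx + 1) / (my + 1))

.wilcoxMarkers <- function(x_in, x_out, genes) {
    vapply(genes, function(g) {
        stats::wilcox.test(x_in[g, ], x_out[g, ], exact = FALSE)$p.value
    }, numeric(1))
}

#' Wilcoxon rank-sum marker detection
#'
#' One-vs-rest per cluster (or a single two-group comparison). Genes are
#' pre-filtered to `|log2FC| >= logfc_threshold` (fold change of
#' `mean(expm1(x)) + 1` ratios) and detection fraction `>= min_pct` on at
#' least one side, then tested two-sided with BH correction across the
#' tested genes of each comparison.
#'
#' @param sce Normalized [SingleCellExperiment].
#' @param labels Cluster or group label per cell.
#' @param logfc_threshold,min_pct Pre-filters as above.
#' @param mode `"one-vs-rest"` (every label against the rest) or
#'   `"two-group"` (exactly two labels, first vs second alphabetically
#'   unless `labels` is a factor).
#' @return `data.frame` with columns cluster, gene, log2FC, pct_in,
#'   pct_out, p_value, fdr.
#' @export
findMarkers <- function(sce, labels, logfc_threshold = 0.25, min_pct = 0.1,
                        mode = c("one-vs-rest", "two-group")) {
    mode <- match.arg(mode)
    m <- as.matrix(SingleCellExperiment::logcounts(sce))
    labels <- as.character(labels)
    ulab <- if (mode == "two-group") {
        u <- unique(labels)
        if (length(u) != 2) stop("two-group mode needs exactly 2 labels")
        sort(u)[1]
    } else sort(unique(labels))
    if (length(unique(labels)) < 2) stop("need at least 2 labels")
    res <- list()
    for (cl in ulab) {
        in_idx <- labels == cl
        out_idx <- !in_idx
        if (!any(in_idx) || !any(out_idx)) stop("empty comparison side")
        x_in <- m[, in_idx, drop = FALSE]
        x_out <- m[, out_idx, drop = FALSE]
        mean_in <- rowMeans(expm1(x_in))
        mean_out <- rowMeans(expm1(x_out))
        lfc <- .log2fc(mean_in, mean_out)
        pct_in <- rowMeans(x_in > 0)
        pct_out <- rowMeans(x_out > 0)
        keep <- abs(lfc) >= logfc_threshold & pmax(pct_in, pct_out) >= min_pct
        genes <- rownames(m)[keep]
        if (!length(genes)) next
        p <- .wilcoxMarkers(x_in, x_out, genes)
        res[[cl]] <- data.frame(cluster = cl, gene = genes,
                                log2FC = lfc[keep], pct_in = pct_in[keep],
                                pct_out = pct_out[keep], p_value = p,
                                fdr = stats::p.adjust(p, "BH"),
                                row.names = NULL)
    }
    if (!length(res))
        return(data.frame(cluster = character(), gene = character(),
                          log2FC = numeric(), pct_in = numeric(),
                          pct_out = numeric(), p_value = numeric(),
                          fdr = numeric()))
    do.call(rbind, res)
}

#' Annotate clusters from reference marker sets
#'
#' Scores each (cluster, type) pair as the mean z-scored expression (across
#' clusters) of the type's marker genes and assigns the argmax type, with
#' ties broken by the declared order of the reference sets.
#'
#' @param cluster_means Clusters x genes matrix of mean normalized
#'   expression (see [clusterMeans()]).
#' @param reference_markers Named list of marker-gene vectors, one per cell
#'   type.
#' @return `data.frame` with cluster, cell_type, score and margin (gap to
#'   the runner-up type).
#' @export
annotateClusters <- function(cluster_means, reference_markers) {
    present <- colnames(cluster_means)
    ref <- lapply(reference_markers, function(g) {
        missing <- setdiff(g, present)
        if (length(missing))
            warning(sprintf("dropping %d absent marker(s): %s",
                            length(missing), paste(missing, collapse = ", ")))
        intersect(g, present)
    })
    empty <- names(ref)[lengths(ref) == 0]
    if (length(empty))
        stop(sprintf("all markers absent for type(s): %s",
                     paste(empty, collapse = ", ")))
    z <- scale(cluster_means)
    z[is.nan(z)] <- 0
    scores <- vapply(ref, function(g)
        rowMeans(z[, g, drop = FALSE]), numeric(nrow(cluster_means)))
    if (is.null(dim(scores)))
        scores <- matrix(scores, nrow = 1, dimnames = list(rownames(cluster_means), names(ref)))
    best <- apply(scores, 1, function(s) {
        top <- which(s == max(s))
        if (length(top) > 1)
            warning("tied annotation scores; using declared type order")
        top[1]
    })
    margin <- apply(scores, 1, function(s) {
        st <- sort(s, decreasing = TRUE)
        if (length(st) > 1) st[1] - st[2] else Inf
    })
    data.frame(cluster = rownames(cluster_means),
               cell_type = colnames(scores)[best],
               score = scores[cbind(seq_along(best), best)],
               margin = margin, row.names = NULL)
}

#' Per-cluster mean expression matrix
#'
#' @param sce Normalized [SingleCellExperiment].
#' @param labels Cluster label per cell.
#' @return Clusters x genes matrix of mean `logcounts`.
#' @export
clusterMeans <- function(sce, labels) {
    m <- SingleCellExperiment::logcounts(sce)
    ulab <- sort(unique(as.character(labels)))
    out <- vapply(ulab, function(cl)
        Matrix::rowSums(m[, labels == cl, drop = FALSE]) / sum(labels == cl),
        numeric(nrow(m)))
    Matrix::t(out)
}

#' Cell-type composition by group
#'
#' @param cell_meta `data.frame`/`DataFrame` with `group` and `cell_type`.
#' @return `data.frame` with group, cell_type, n and proportion (within
#'   group; proportions sum to 1 per group).
#' @export
cellComposition <- function(cell_meta) {
    cell_meta <- as.data.frame(cell_meta)
    if (anyNA(cell_meta$cell_type) || anyNA(cell_meta$group))
        stop("every cell must carry a group and a cell type")
    tab <- as.data.frame(table(group = cell_meta$group,
                               cell_type = cell_meta$cell_type),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    tab$proportion <- stats::ave(tab$n, tab$group,
                                 FUN = function(x) x / sum(x))
    tab
}
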