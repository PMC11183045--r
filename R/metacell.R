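#' Over-cluster cells into group-pure micro-clusters
#'
#' Runs graph clustering separately within each group at a high resolution
#' (default 50) so that no micro-cluster spans groups; labels are
#' namespaced by group (`"Normal_3"`).
#'
#' @param scores Cells x PCs matrix.
#' @param group Group label per cell.
#' @param resolution Modularity resolution (high values give many small
#'   clusters).
#' @param k_neighbors Neighbors for the SNN graph.
#' @param seed Seed for community detection.
#' @return Character vector of micro-cluster labels, named by cell.
#' @export
overclusterCells <- function(scores, group, resolution = 50,
                             k_neighbors = 10L, seed = 1L) {
    stopifnot(nrow(scores) == length(group))
    out <- character(nrow(scores))
    names(out) <- rownames(scores)
    for (g in unique(group)) {
        idx <- which(group == g)
        if (length(idx) < k_neighbors + 1)
            stop(sprintf("group '%s' has %d cells, fewer than k_neighbors + 1",
                         g, length(idx)))
        lab <- clusterCells(scores[idx, , drop = FALSE],
                            k_neighbors = k_neighbors,
                            resolution = resolution, seed = seed)
        out[idx] <- sprintf("%s_%d", g, lab)
    }
    out
}

#' Aggregate micro-clusters into metacells
#'
#' Each metacell's profile is the sum of its member cells' raw counts,
#' subsequently library-size log-normalized. Metacells at or below
#' `min_cells` members are discarded (strictly more than `min_cells` cells
#' are required, matching the >10-cell retention rule; set
#' `strict = FALSE` for `>=`). The dominant cell type is the modal member
#' type.
#'
#' @param sce [SingleCellExperiment] with `counts` and `colData` columns
#'   `group` (required) and `cell_type` (optional).
#' @param labels Micro-cluster label per cell (see [overclusterCells()]).
#' @param min_cells Membership threshold.
#' @param strict If `TRUE` (default) keep metacells with `n > min_cells`,
#'   else `n >= min_cells`.
#' @param scale Normalization size factor.
#' @return A [SingleCellExperiment] of metacells with assays `counts`
#'   (summed) and `logcounts`, `colData` columns `group`, `cell_type`,
#'   `n_cells`, and member cell ids in `metadata()$members`.
#' @export
aggregateMetacells <- function(sce, labels, min_cells = 10L, strict = TRUE,
                               scale = 10000) {
    stopifnot(ncol(sce) == length(labels))
    labels <- as.character(labels)
    ulab <- sort(unique(labels))
    m <- SingleCellExperiment::counts(sce)
    cd <- SummarizedExperiment::colData(sce)
    sizes <- table(labels)[ulab]
    keep <- if (strict) sizes > min_cells else sizes >= min_cells
    if (!any(keep))
        stop(sprintf("all %d metacells discarded at min_cells = %d",
                     length(ulab), min_cells))
    kept <- ulab[keep]
    prof <- vapply(kept, function(l)
        Matrix::rowSums(m[, labels == l, drop = FALSE]), numeric(nrow(m)))
    groups <- vapply(kept, function(l) {
        g <- unique(as.character(cd$group[labels == l]))
        if (length(g) != 1) stop("metacell spans groups; overcluster within groups")
        g
    }, character(1))
    types <- if ("cell_type" %in% colnames(cd)) {
        vapply(kept, function(l) {
            tt <- table(as.character(cd$cell_type[labels == l]))
            names(tt)[which.max(tt)]
        }, character(1))
    } else rep(NA_character_, length(kept))
    members <- lapply(kept, function(l) colnames(sce)[labels == l])
    names(members) <- kept
    out <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(prof, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(group = unname(groups),
                                       cell_type = unname(types),
                                       n_cells = as.integer(unname(sizes[kept])),
                                       row.names = kept))
    out <- normalizeCells(out, scale = scale)
    S4Vectors::metadata(out)$members <- members
    S4Vectors::metadata(out)$discarded <- ulab[!keep]
    out
}
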