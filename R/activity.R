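# positions of genes when ranked by decreasing expression, ties broken by
# ascending gene id; returns genes x units integer matrix
.rankPositions <- function(expr) {
    id_idx <- rank(rownames(expr), ties.method = "first")
    pos <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
    for (j in seq_len(ncol(expr))) {
        ord <- order(-expr[, j], id_idx)
        pos[ord, j] <- seq_len(nrow(expr))
    }
    pos
}

.aucellFromPositions <- function(pos, targets, k) {
    G <- nrow(pos)
    tg <- intersect(targets, rownames(pos))
    m_eff <- length(tg)
    if (!m_eff) stop("empty effective target set")
    mm <- min(m_eff, k)
    max_area <- mm * k - mm * (mm - 1) / 2
    sub <- pos[tg, , drop = FALSE]
    credit <- (k - sub + 1) * (sub <= k)
    Matrix::colSums(credit) / max_area
}

#' AUCell-style activity score of one gene set
#'
#' Per unit (cell or metacell), genes are ranked by decreasing expression
#' with a deterministic tie-break (ascending gene id among ties). With
#' threshold `k = ceiling(top_fraction * G)`, the score is the area under
#' the target-recovery step curve over ranks `1..k`, normalized by the
#' maximum area achievable by the effective target set, so it lies in
#' `[0, 1]`.
#'
#' @param expr Genes x units expression matrix (any monotone scale; the
#'   score is rank-based).
#' @param targets Character vector of target gene ids.
#' @param top_fraction Fraction of top-ranked genes scored.
#' @return Numeric vector of per-unit scores in `[0, 1]`.
#' @export
aucellScore <- function(expr, targets, top_fraction = 0.05) {
    expr <- as.matrix(expr)
    cov <- mean(targets %in% rownames(expr))
    if (is.nan(cov) || cov == 0) stop("empty effective target set")
    if (cov < 0.8)
        warning(sprintf("only %.0f%% of targets are present in the matrix",
                        100 * cov))
    k <- as.integer(ceiling(top_fraction * nrow(expr)))
    .aucellFromPositions(.rankPositions(expr), targets, k)
}

#' Regulon activity score (RAS) matrix
#'
#' Scores every regulon with [aucellScore()] on a shared ranking of each
#' unit's expression. Because the score depends on within-unit ranks only,
#' it is invariant to any strictly increasing transform of a unit's
#' expression vector.
#'
#' @param x Normalized [SingleCellExperiment] (uses `logcounts`) or a plain
#'   genes x units matrix.
#' @param regulons A [RegulonSet-class].
#' @param top_fraction Fraction of top-ranked genes scored.
#' @return Units x regulons matrix with `attr(, "top_fraction")`.
#' @export
rasMatrix <- function(x, regulons, top_fraction = 0.05) {
    expr <- if (methods::is(x, "SummarizedExperiment"))
        as.matrix(SingleCellExperiment::logcounts(x)) else as.matrix(x)
    if (!length(regulons)) stop("need at least one regulon")
    pos <- .rankPositions(expr)
    k <- as.integer(ceiling(top_fraction * nrow(expr)))
    tg <- regulonTargets(regulons)
    ras <- vapply(tg, function(t) .aucellFromPositions(pos, t, k),
                  numeric(ncol(expr)))
    if (is.null(dim(ras)))
        ras <- matrix(ras, nrow = ncol(expr),
                      dimnames = list(colnames(expr), names(tg)))
    rownames(ras) <- colnames(expr)
    attr(ras, "top_fraction") <- top_fraction
    ras
}

.jsd2 <- function(p, q) {
    m <- (p + q) / 2
    term <- function(a) {
        idx <- a > 0
        sum(a[idx] * log2(a[idx] / m[idx]))
    }
    (term(p) + term(q)) / 2
}

#' Regulon specificity scores (RSS) per cell type
#'
#' For regulon `r` and cell type `t`, `RSS = 1 - sqrt(JSD(p, q))` with
#' base-2 Jensen-Shannon divergence between `p`, the regulon's activity
#' normalized to a distribution over units, and `q`, the normalized
#' indicator of membership in `t`. RSS is 1 when activity is uniform over
#' exactly the type's units and bounded in `[0, 1]`.
#'
#' @param ras Units x regulons activity matrix.
#' @param cell_type Cell-type label per unit.
#' @return Regulons x cell-types matrix of RSS values (NA for all-zero
#'   activity columns, with a warning).
#' @export
regulonSpecificity <- function(ras, cell_type) {
    stopifnot(nrow(ras) == length(cell_type))
    types <- sort(unique(as.character(cell_type)))
    out <- matrix(NA_real_, ncol(ras), length(types),
                  dimnames = list(colnames(ras), types))
    qs <- lapply(types, function(t) {
        q <- as.numeric(cell_type == t)
        q / sum(q)
    })
    for (r in seq_len(ncol(ras))) {
        tot <- sum(ras[, r])
        if (tot == 0) {
            warning(sprintf("all-zero activity for regulon '%s'; RSS undefined",
                            colnames(ras)[r]))
            next
        }
        p <- ras[, r] / tot
        out[r, ] <- vapply(qs, function(q) 1 - sqrt(.jsd2(p, q)), numeric(1))
    }
    out
}
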