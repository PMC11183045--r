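#' Pearson correlation between regulon activity profiles
#'
#' @param ras Units x regulons activity matrix (at least 3 units).
#' @return Symmetric regulons x regulons correlation matrix with unit
#'   diagonal; correlations involving constant columns are stored as 0 with
#'   a warning.
#' @export
pccMatrix <- function(ras) {
    if (nrow(ras) < 3) stop("need at least 3 units")
    const <- apply(ras, 2, stats::sd) == 0
    if (any(const))
        warning(sprintf("constant activity column(s) stored as PCC 0: %s",
                        paste(colnames(ras)[const], collapse = ", ")))
    pcc <- suppressWarnings(stats::cor(ras))
    pcc[is.na(pcc)] <- 0
    diag(pcc) <- 1
    pcc
}

#' Connection specificity index (CSI)
#'
#' `CSI(A, B)` is the fraction of the other `N - 2` regulons `C` whose
#' correlation with `A` and with `B` both do not exceed `PCC(A, B)`:
#' `|{C : PCC(A,C) <= PCC(A,B) and PCC(B,C) <= PCC(A,B)}| / (N - 2)`. A
#' high CSI means the A-B association is specific rather than shared
#' network-wide. The comparison is non-strict by default (`strict = TRUE`
#' uses `<`); the diagonal is 1.
#'
#' @param pcc Square symmetric correlation matrix (`N >= 3`).
#' @param strict Use strict inequality in the comparison.
#' @return Symmetric CSI matrix with values on the grid
#'   `{0, 1/(N-2), ..., 1}`.
#' @export
csiMatrix <- function(pcc, strict = FALSE) {
    n <- nrow(pcc)
    if (n < 3) stop("CSI needs at least 3 regulons")
    stopifnot(ncol(pcc) == n)
    csi <- matrix(1, n, n, dimnames = dimnames(pcc))
    cmp <- if (strict) `<` else `<=`
    for (a in seq_len(n - 1)) {
        for (b in (a + 1):n) {
            v <- pcc[a, b]
            ok <- cmp(pcc[a, ], v) & cmp(pcc[b, ], v)
            ok[c(a, b)] <- FALSE
            csi[a, b] <- csi[b, a] <- sum(ok) / (n - 2)
        }
    }
    csi
}

#' Cluster regulons into CSI modules
#'
#' Agglomerative clustering (average linkage by default) on Euclidean
#' distances between CSI rows, cut at `k` modules; modules are renamed
#' `M1..Mk` in decreasing size order (ties by first member index).
#'
#' @param csi CSI matrix from [csiMatrix()].
#' @param k Number of modules.
#' @param linkage `hclust` agglomeration method.
#' @return Named character vector regulon -> module, with the `hclust` tree
#'   in `attr(, "tree")`.
#' @export
clusterModules <- function(csi, k = 8L, linkage = "average") {
    n <- nrow(csi)
    if (k > n) stop(sprintf("k = %d exceeds the %d regulons", k, n))
    tree <- stats::hclust(stats::dist(csi), method = linkage)
    cut <- stats::cutree(tree, k = k)
    sizes <- table(cut)
    first <- vapply(names(sizes), function(cl) min(which(cut == as.integer(cl))),
                    integer(1))
    ord <- order(-as.integer(sizes), first)
    relabel <- stats::setNames(sprintf("M%d", seq_along(ord)),
                               names(sizes)[ord])
    out <- relabel[as.character(cut)]
    names(out) <- rownames(csi)
    attr(out, "tree") <- tree
    out
}

#' Mean regulon activity per module
#'
#' @param ras Units x regulons activity matrix.
#' @param modules Named module assignment from [clusterModules()]; must
#'   cover every RAS column.
#' @return Units x modules matrix of row-wise means over member regulons.
#' @export
moduleActivity <- function(ras, modules) {
    if (!all(colnames(ras) %in% names(modules)))
        stop("modules must cover all regulons")
    mods <- sort(unique(unname(modules[colnames(ras)])))
    out <- vapply(mods, function(m) {
        cols <- colnames(ras)[modules[colnames(ras)] == m]
        rowMeans(ras[, cols, drop = FALSE])
    }, numeric(nrow(ras)))
    if (is.null(dim(out)))
        out <- matrix(out, nrow = nrow(ras), dimnames = list(rownames(ras), mods))
    out
}
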