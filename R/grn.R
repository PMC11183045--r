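#' Estimate TF-to-target importances by standardized ridge regression
#'
#' For every target gene, each TF's importance is the magnitude of its
#' coefficient in a ridge regression of the (standardized) target on all
#' (standardized) TF profiles across metacells. On the correlation scale
#' the coefficient vector is `(C_TT + lambda I)^-1 c_Ty`. Importances below
#' `floor` are zeroed; the estimator is deterministic.
#'
#' @param mc Metacell [SingleCellExperiment] with `logcounts` (or a plain
#'   genes x units matrix of normalized expression).
#' @param tf_list Character vector of TF gene ids (must be present).
#' @param lambda Ridge penalty on the correlation scale.
#' @param floor Importances at or below this value are dropped; the default
#'   (`NULL`) uses `2 / ((1 + lambda) * sqrt(n_units))`, the two-sigma
#'   magnitude of a standardized ridge coefficient for an independent
#'   target, so that null edges are rejected with high probability.
#' @return Edge `data.frame` (`tf`, `target`, `importance`) sorted by TF
#'   then decreasing importance; self-edges excluded.
#' @export
inferImportance <- function(mc, tf_list, lambda = 1, floor = NULL) {
    expr <- if (methods::is(mc, "SummarizedExperiment"))
        as.matrix(SingleCellExperiment::logcounts(mc)) else as.matrix(mc)
    missing <- setdiff(tf_list, rownames(expr))
    if (length(missing))
        stop(sprintf("TFs absent from the matrix: %s",
                     paste(missing, collapse = ", ")))
    n <- ncol(expr)
    if (n < 30) warning("fewer than 30 metacells; importances will be noisy")
    if (is.null(floor)) floor <- 2 / ((1 + lambda) * sqrt(n))
    X <- Matrix::t(expr[tf_list, , drop = FALSE])
    sx <- apply(X, 2, stats::sd)
    if (any(sx == 0)) warning("constant TF profile(s); their importances are 0")
    Xs <- scale(X)
    Xs[, sx == 0] <- 0
    targets <- rownames(expr)
    Y <- Matrix::t(expr[targets, , drop = FALSE])
    sy <- apply(Y, 2, stats::sd)
    if (any(sy == 0))
        warning(sprintf("%d constant target gene(s); their importances are 0",
                        sum(sy == 0)))
    Ys <- scale(Y)
    Ys[, sy == 0] <- 0
    Cxx <- crossprod(Xs) / (n - 1)
    Cxy <- crossprod(Xs, Ys) / (n - 1)
    B <- solve(Cxx + diag(lambda, ncol(Cxx)), Cxy)  # TFs x targets
    imp <- abs(B)
    idx <- which(imp > floor, arr.ind = TRUE)
    out <- data.frame(tf = tf_list[idx[, 1]], target = targets[idx[, 2]],
                      importance = imp[idx], stringsAsFactors = FALSE)
    out <- out[out$tf != out$target, ]
    out <- out[order(out$tf, -out$importance, out$target), ]
    rownames(out) <- NULL
    out
}

#' Assemble motif-supported regulons from an edge table
#'
#' Per TF, edges are ranked by decreasing importance (ties by target id),
#' truncated at `top_n_per_tf`, and pruned to motif-supported edges; TFs
#' with fewer than `min_regulon_size` surviving targets are dropped.
#'
#' @param edges Edge `data.frame` from [inferImportance()] (columns `tf`,
#'   `target`, `importance`).
#' @param motif_table Motif-support `data.frame` (`tf`, `target`,
#'   `motif_supported`); must cover every edge.
#' @param top_n_per_tf Importance-rank truncation per TF.
#' @param min_regulon_size Minimum surviving target count.
#' @return A [RegulonSet-class]; regulons named `"TF(+)"`.
#' @export
assembleRegulons <- function(edges, motif_table, top_n_per_tf = 50L,
                             min_regulon_size = 10L) {
    key <- paste(motif_table$tf, motif_table$target)
    supp <- stats::setNames(motif_table$motif_supported, key)
    ekey <- paste(edges$tf, edges$target)
    if (anyNA(supp[ekey]))
        stop("motif_table does not cover the edge vocabulary")
    tfs <- character(); targets <- list(); importance <- list()
    attrition <- character()
    for (tf in unique(edges$tf)) {
        e <- edges[edges$tf == tf, ]
        e <- e[order(-e$importance, e$target), ]
        e <- utils::head(e, top_n_per_tf)
        e <- e[supp[paste(e$tf, e$target)], ]
        if (nrow(e) >= min_regulon_size) {
            tfs <- c(tfs, tf)
            targets <- c(targets, list(e$target))
            importance <- c(importance, list(e$importance))
        } else {
            attrition <- c(attrition, sprintf("%s: %d supported targets", tf,
                                              nrow(e)))
        }
    }
    if (!length(tfs))
        stop(paste0("no regulon survived motif pruning; per-TF attrition:\n  ",
                    paste(attrition, collapse = "\n  ")))
    RegulonSet(tfs, targets, importance)
}

#' Convert regulons to a gene-set collection
#'
#' One set per regulon containing its targets; the TF itself is excluded by
#' default so that downstream set scoring is not self-enriched.
#'
#' @param regulons A [RegulonSet-class].
#' @param include_tf Add the TF gene to its own set.
#' @return Named list of gene-id vectors (GMT-compatible, see
#'   [writeGMT()]).
#' @export
regulonsToGeneSets <- function(regulons, include_tf = FALSE) {
    sets <- lapply(regulons@elements, function(r)
        if (include_tf) c(r$tf, r$targets) else r$targets)
    attr(sets, "description") <- stats::setNames(
        vapply(regulons@elements, `[[`, character(1), "tf"), names(sets))
    sets
}
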