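# Newton inversion of the trigamma function (for the moderated-t prior df)
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:60) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (abs(dif / y) < 1e-10) break
    }
    y
}

#' Moderated-t differential expression (DCM vs Normal)
#'
#' Two-sample comparison on log2-scale bulk expression with empirical-Bayes
#' variance moderation: per-gene pooled variances `s_g^2` (d = n - 2 df)
#' are shrunk toward a prior `s0^2` with `d0` df estimated by the method of
#' moments on `log s_g^2` (the scaled-F model), giving posterior variances
#' `(d0 s0^2 + d s_g^2) / (d0 + d)` and a t-statistic on `d0 + d` df.
#' Positive log2FC means higher in DCM.
#'
#' @param bulk [SummarizedExperiment] with log2-scale assay `exprs` and
#'   `colData$group`, or a plain matrix (then supply `groups`).
#' @param groups Group label per sample (`"Normal"`/`"DCM"`); taken from
#'   `colData` when `bulk` is a SummarizedExperiment.
#' @param lfc_threshold,fdr_threshold Filters stored in `passes_filter`
#'   (`|log2FC| > lfc_threshold` and `fdr < fdr_threshold`).
#' @param d0,s0 Optional prior overrides (mainly for limit checks).
#' @return `data.frame` per gene: log2FC, mean_expr, t_ordinary,
#'   t_moderated, p, fdr, passes_filter; prior estimates in
#'   `attr(, "prior")`.
#' @export
deModerated <- function(bulk, groups = NULL, lfc_threshold = 0.5,
                        fdr_threshold = 0.05, d0 = NULL, s0 = NULL) {
    if (methods::is(bulk, "SummarizedExperiment")) {
        if (is.null(groups))
            groups <- SummarizedExperiment::colData(bulk)$group
        sc <- S4Vectors::metadata(bulk)$scale
        if (!is.null(sc) && sc != "log")
            stop("bulk matrix must be declared log-scale for fold-change arithmetic")
        m <- SummarizedExperiment::assay(bulk, "exprs")
    } else m <- as.matrix(bulk)
    stopifnot(!is.null(groups), length(groups) == ncol(m))
    i1 <- groups == "DCM"; i0 <- groups == "Normal"
    n1 <- sum(i1); n0 <- sum(i0)
    if (n1 < 2 || n0 < 2) stop("need at least 2 samples per group")
    m1 <- rowMeans(m[, i1, drop = FALSE]); m0 <- rowMeans(m[, i0, drop = FALSE])
    v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
    v0 <- apply(m[, i0, drop = FALSE], 1, stats::var)
    d <- n1 + n0 - 2
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / d
    lfc <- m1 - m0
    se_factor <- sqrt(1 / n1 + 1 / n0)
    zerovar <- s2 == 0
    if (any(zerovar))
        warning(sprintf("%d gene(s) with zero variance in both groups; p set to NA",
                        sum(zerovar)))
    t_ord <- ifelse(zerovar, NA_real_, lfc / (sqrt(s2) * se_factor))
    if (is.null(d0) || is.null(s0)) {
        z <- log(s2[!zerovar])
        e <- z - digamma(d / 2) + log(d / 2)
        ve <- stats::var(e)
        excess <- ve - trigamma(d / 2)
        if (is.na(excess) || excess <= 0) {
            d0 <- Inf
            s02 <- exp(mean(e))
        } else {
            d0 <- 2 * .trigammaInverse(excess)
            s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
        }
    } else s02 <- s0^2
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
        (d0 * s02 + d * s2) / (d0 + d)
    df_total <- min(d0 + d, 1e6)
    t_mod <- ifelse(zerovar, NA_real_, lfc / (sqrt(s2_post) * se_factor))
    p <- 2 * stats::pt(-abs(t_mod), df = df_total)
    fdr <- rep(NA_real_, length(p))
    fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], "BH")
    out <- data.frame(gene = rownames(m), log2FC = lfc,
                      mean_expr = (m1 * n1 + m0 * n0) / (n1 + n0),
                      t_ordinary = t_ord, t_moderated = t_mod, p = p,
                      fdr = fdr,
                      passes_filter = !is.na(fdr) & abs(lfc) > lfc_threshold &
                          fdr < fdr_threshold,
                      row.names = NULL)
    attr(out, "prior") <- c(d0 = d0, s0 = sqrt(s02))
    out
}

.ssgseaSample <- function(x, gene_ids, sets, alpha) {
    G <- length(x)
    r <- rank(x, ties.method = "average")  # high expression -> high rank
    ord <- order(-x, gene_ids)
    w <- r[ord]^alpha
    in_set_scores <- vapply(sets, function(s) {
        member <- gene_ids[ord] %in% s
        n_in <- sum(member)
        if (n_in == G) stop("gene set covers every gene; out-set is empty")
        inc <- ifelse(member, w / sum(w[member]), -1 / (G - n_in))
        sum(cumsum(inc))
    }, numeric(1))
    in_set_scores
}

#' Single-sample GSEA (ssGSEA) scores
#'
#' Per sample, genes are ranked by decreasing expression (average ranks for
#' ties); walking down the list, members of a set add their rank weight
#' raised to `alpha` (normalized by the in-set weight total) while
#' non-members subtract `1/(G - |S|)`; the enrichment score is the sum of
#' the running difference over all positions (the integral form). With
#' `normalize = TRUE` all scores are divided by the range (max - min) of
#' the whole score matrix.
#'
#' @param bulk [SummarizedExperiment] (assay `exprs`) or genes x samples
#'   matrix.
#' @param gene_sets Named list of gene-id vectors.
#' @param alpha Rank-weight exponent.
#' @param normalize Divide by the overall score range.
#' @return Sets x samples score matrix.
#' @export
ssgseaScore <- function(bulk, gene_sets, alpha = 0.25, normalize = TRUE) {
    m <- if (methods::is(bulk, "SummarizedExperiment"))
        SummarizedExperiment::assay(bulk, "exprs") else as.matrix(bulk)
    cov <- vapply(gene_sets, function(s) mean(s %in% rownames(m)), numeric(1))
    if (any(cov == 0)) stop("gene set(s) with no overlap with the matrix")
    if (any(cov < 0.5))
        warning(sprintf("low gene coverage (< 50%%) for set(s): %s",
                        paste(names(gene_sets)[cov < 0.5], collapse = ", ")))
    scores <- vapply(seq_len(ncol(m)), function(j)
        .ssgseaSample(m[, j], rownames(m), gene_sets, alpha),
        numeric(length(gene_sets)))
    if (is.null(dim(scores)))
        scores <- matrix(scores, nrow = length(gene_sets))
    dimnames(scores) <- list(names(gene_sets), colnames(m))
    if (normalize) {
        rng <- max(scores) - min(scores)
        if (rng > 0) scores <- scores / rng
    }
    scores
}

#' Two-group comparison of per-sample set scores
#'
#' Two-sided Wilcoxon rank-sum test per gene set with BH correction across
#' sets; the direction is the sign of the median difference (DCM -
#' Normal) and significance stars follow the usual 0.05/0.01/0.001 map.
#'
#' @param scores Sets x samples matrix (e.g. from [ssgseaScore()]).
#' @param groups Group label per sample.
#' @return `data.frame` with set, p, fdr, direction (+1/-1/0), stars.
#' @export
compareScores <- function(scores, groups) {
    stopifnot(ncol(scores) == length(groups))
    i1 <- groups == "DCM"; i0 <- groups == "Normal"
    if (!any(i1) || !any(i0)) stop("need both groups")
    p <- apply(scores, 1, function(x) {
        if (stats::sd(x) == 0) return(1)
        stats::wilcox.test(x[i1], x[i0], exact = FALSE)$p.value
    })
    dirn <- apply(scores, 1, function(x)
        sign(stats::median(x[i1]) - stats::median(x[i0])))
    fdr <- stats::p.adjust(p, "BH")
    stars <- cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf), right = FALSE,
                 labels = c("***", "**", "*", "ns"))
    data.frame(set = rownames(scores), p = p, fdr = fdr, direction = dirn,
               stars = as.character(stars), row.names = NULL)
}
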