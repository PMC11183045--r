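#' Intersect differential regulons across bulk datasets
#'
#' @param diff_sets List (one per dataset, at least 2) of named numeric
#'   vectors `regulon -> direction` (+1 up in DCM, -1 down).
#' @return List with `shared` (regulon names present in every dataset),
#'   `consistent` (shared with identical direction everywhere) and a
#'   per-regulon direction table.
#' @export
intersectRegulons <- function(diff_sets) {
    if (length(diff_sets) < 2) stop("need at least 2 datasets")
    shared <- Reduce(intersect, lapply(diff_sets, names))
    dirs <- vapply(diff_sets, function(d) d[shared], numeric(length(shared)))
    if (length(shared) == 1) dirs <- matrix(dirs, nrow = 1,
                                            dimnames = list(shared, NULL))
    consistent <- shared[apply(dirs, 1, function(x) length(unique(x)) == 1)]
    list(shared = shared, consistent = consistent,
         directions = if (length(shared))
             data.frame(regulon = shared, dirs, row.names = NULL)
         else data.frame(regulon = character()))
}

#' Count target occurrences across shared regulons
#'
#' @param regulons A [RegulonSet-class] (or named list of target vectors)
#'   restricted to the shared regulons; at least 2.
#' @param min_occurrence Multi-target threshold (default 2).
#' @return List with `counts` (target -> number of regulons containing
#'   it), `multi_targets` (count >= `min_occurrence`) and the binary
#'   co-membership matrix (targets x regulons).
#' @export
countMultiTargets <- function(regulons, min_occurrence = 2L) {
    sets <- if (methods::is(regulons, "RegulonSet"))
        regulonTargets(regulons) else regulons
    if (length(sets) < 2) stop("need at least 2 regulons")
    all_t <- sort(unique(unlist(sets)))
    member <- vapply(sets, function(s) all_t %in% s, logical(length(all_t)))
    if (is.null(dim(member)))
        member <- matrix(member, nrow = length(all_t))
    dimnames(member) <- list(all_t, names(sets))
    counts <- rowSums(member)
    list(counts = counts,
         multi_targets = names(counts)[counts >= min_occurrence],
         comembership = member)
}

#' Final hub targets: multi-targets that are DE in every bulk dataset
#'
#' @param multi_targets Character vector from [countMultiTargets()].
#' @param deg_tables List of [deModerated()] tables (with `passes_filter`).
#' @param regulons Optional [RegulonSet-class] used to report which
#'   regulons contain each hub.
#' @return List with `hubs`, per-dataset `differential_targets`, and a
#'   `provenance` list (hub -> containing regulon names).
#' @export
hubTargets <- function(multi_targets, deg_tables, regulons = NULL) {
    diff_targets <- lapply(deg_tables, function(tab)
        intersect(multi_targets, tab$gene[tab$passes_filter]))
    hubs <- sort(Reduce(intersect, diff_targets))
    provenance <- NULL
    if (!is.null(regulons)) {
        tg <- regulonTargets(regulons)
        provenance <- lapply(stats::setNames(hubs, hubs), function(h)
            names(tg)[vapply(tg, function(s) h %in% s, logical(1))])
    }
    list(hubs = hubs, differential_targets = diff_targets,
         provenance = provenance)
}

#' ROC AUC by the rank (Mann-Whitney) identity
#'
#' `AUC = (sum of positive-class ranks - n1(n1+1)/2) / (n1 n0)` with
#' average ranks, giving half credit to ties. By default higher values
#' predict the positive class; `direction = "lower"` flips the
#' orientation (as for markers that are lower in disease).
#'
#' @param values Numeric scores.
#' @param labels Binary labels (logical, 0/1, or factor with the positive
#'   class given by `positive`).
#' @param positive Positive-class label (default `"DCM"` for character
#'   labels, `1`/`TRUE` otherwise).
#' @param direction `"higher"` or `"lower"`: which end of `values`
#'   predicts the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(values, labels, positive = NULL,
                   direction = c("higher", "lower")) {
    direction <- match.arg(direction)
    if (is.null(positive))
        positive <- if (is.character(labels) || is.factor(labels)) "DCM" else 1
    pos <- labels == positive
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    if (direction == "lower") values <- -values
    r <- rank(values, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for the ROC AUC
#'
#' Stratified resampling within each class, percentile 95% interval,
#' seed-deterministic.
#'
#' @inheritParams rocAuc
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `auc`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
rocBootstrapCI <- function(values, labels, positive = NULL,
                           direction = c("higher", "lower"),
                           n_boot = 2000L, seed = 1L) {
    direction <- match.arg(direction)
    if (is.null(positive))
        positive <- if (is.character(labels) || is.factor(labels)) "DCM" else 1
    pos_idx <- which(labels == positive)
    neg_idx <- which(labels != positive)
    auc <- rocAuc(values, labels, positive, direction)
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
        i <- c(sample(pos_idx, length(pos_idx), replace = TRUE),
               sample(neg_idx, length(neg_idx), replace = TRUE))
        rocAuc(values[i], labels[i], positive, direction)
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
    list(auc = auc, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         seed = seed)
}

#' Over-representation analysis (one-sided hypergeometric)
#'
#' @param hits Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Background gene vector.
#' @param gene_sets Named list of gene sets (intersected with the
#'   universe).
#' @return `data.frame` with set, overlap, set_size, p (hypergeometric
#'   upper tail), fdr (BH across sets), fold_enrichment.
#' @export
oraTest <- function(hits, universe, gene_sets) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    hits <- unique(intersect(hits, universe))
    if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
    N <- length(universe); n <- length(hits)
    res <- lapply(names(gene_sets), function(nm) {
        s <- intersect(gene_sets[[nm]], universe)
        k <- length(intersect(hits, s))
        m <- length(s)
        p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
        fe <- if (m > 0 && n > 0) (k / n) / (m / N) else NA_real_
        data.frame(set = nm, overlap = k, set_size = m, p = p,
                   fold_enrichment = fe)
    })
    out <- do.call(rbind, res)
    out$fdr <- stats::p.adjust(out$p, "BH")
    out[order(out$p), c("set", "overlap", "set_size", "p", "fdr",
                        "fold_enrichment")]
}
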