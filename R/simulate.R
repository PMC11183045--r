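#' Simulate regulatory ground truth
#'
#' Draws the latent structure every other generator consumes: cell-type
#' baseline expression profiles with exclusive marker genes, planted
#' TF->target regulons with positive loadings (activating arcs only), a
#' responsive subset whose activity shifts in the DCM group, per-regulon
#' cell-type activity offsets, group-dependent cell-type compositions, and
#' a Gamma-Poisson noise model. A small number of hub genes is planted into
#' several responsive regulons so that hub-target recovery has a known
#' answer; `hub_targets` records every gene belonging to at least two
#' responsive regulons (planted or by chance overlap).
#'
#' @param n_celltypes,n_genes,n_tfs,targets_per_tf Dimensions of the truth;
#'   TFs are genes named `TF01..`, other genes `G0001..`.
#' @param n_responsive Number of regulons whose activity shifts with
#'   disease (`n_responsive <= n_tfs`).
#' @param group_effect Mean activity shift, in activity-SD units, applied
#'   to responsive regulons in DCM cells.
#' @param composition_normal,composition_dcm Named cell-type proportion
#'   vectors (each summing to 1); defaults follow the myocardial
#'   composition used throughout the package (cardiomyocytes 59.2% in
#'   Normal vs 36.3% in DCM).
#' @param n_hubs,hub_regulons Hub genes planted into `hub_regulons`
#'   distinct responsive regulons each.
#' @param markers_per_type,marker_fold Exclusive marker genes per cell type
#'   and their fold-elevation in that type.
#' @param loading_range Uniform range for per-target loadings (log-scale
#'   effect of one activity SD on target expression).
#' @param tf_loading Loading coupling a TF's own transcript to its regulon
#'   activity (makes TF expression an observable proxy of activity).
#' @param celltype_sd_range Uniform range for the per-regulon SD of
#'   cell-type activity offsets.
#' @param dispersion Gamma-Poisson dispersion (scalar or per-gene vector).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size model.
#' @param batch_sd SD of per-sample gene-wise log-mean offsets.
#' @param seed Integer seed; the truth is fully reproducible from it.
#' @return An object of class `SyntheticTruth` (a list).
#' @examples
#' tr <- simulateTruth(n_genes = 300, n_tfs = 10, targets_per_tf = 15,
#'                     seed = 1)
#' tr$responsive
#' @export
simulateTruth <- function(n_celltypes = 8L, n_genes = 2000L, n_tfs = 50L,
                          targets_per_tf = 30L, n_responsive = 5L,
                          group_effect = 2,
                          composition_normal = NULL, composition_dcm = NULL,
                          n_hubs = 5L, hub_regulons = 3L,
                          markers_per_type = 15L, marker_fold = 8,
                          loading_range = c(0.25, 0.45), tf_loading = 0.5,
                          celltype_sd_range = c(0.5, 1.5),
                          dispersion = 0.4,
                          libsize_meanlog = log(5000), libsize_sdlog = 0.3,
                          batch_sd = 0.1, seed = 1L) {
    if (n_responsive > n_tfs) stop("n_responsive must not exceed n_tfs")
    defaults <- defaultPipelineConfig()$sim
    if (is.null(composition_normal)) composition_normal <- defaults$composition_normal
    if (is.null(composition_dcm)) composition_dcm <- defaults$composition_dcm
    for (comp in list(composition_normal, composition_dcm)) {
        if (length(comp) != n_celltypes || any(comp < 0) ||
            abs(sum(comp) - 1) > 1e-8)
            stop("composition vectors must be length-n_celltypes simplices")
    }
    types <- names(composition_normal)
    if (is.null(types)) types <- sprintf("type%02d", seq_len(n_celltypes))
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    others <- sprintf("G%04d", seq_len(n_genes - n_tfs))
    genes <- c(tfs, others)
    n_marker_total <- markers_per_type * n_celltypes
    pool_size <- length(others) - n_marker_total
    if (targets_per_tf > pool_size)
        stop("infeasible target draw: targets_per_tf exceeds the non-TF, non-marker gene pool")

    set.seed(seed)
    baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    names(baseline) <- genes
    marker_pool <- sample(others, n_marker_total)
    markers <- split(marker_pool, rep(types, each = markers_per_type))[types]
    profiles <- matrix(baseline, nrow = n_genes, ncol = n_celltypes,
                       dimnames = list(genes, types))
    for (t in types) profiles[markers[[t]], t] <-
        profiles[markers[[t]], t] * marker_fold

    target_pool <- setdiff(others, marker_pool)
    regulons <- vector("list", n_tfs)
    names(regulons) <- tfs
    for (i in seq_len(n_tfs)) {
        tg <- sample(target_pool, targets_per_tf)
        loading <- stats::runif(targets_per_tf, loading_range[1], loading_range[2])
        names(loading) <- tg
        regulons[[i]] <- list(tf = tfs[i], targets = tg, loading = loading)
    }
    responsive <- if (n_responsive > 0) sort(sample(tfs, n_responsive)) else character()

    # plant hub genes into several responsive regulons each
    planted_hubs <- character()
    if (n_hubs > 0 && length(responsive) >= max(2L, hub_regulons)) {
        in_use <- unique(unlist(lapply(regulons, `[[`, "targets")))
        planted_hubs <- sample(setdiff(target_pool, in_use), n_hubs)
        for (h in planted_hubs) {
            homes <- sample(responsive, hub_regulons)
            for (r in homes) {
                reg <- regulons[[r]]
                drop <- sample(setdiff(reg$targets, planted_hubs), 1)
                reg$targets[reg$targets == drop] <- h
                names(reg$loading)[names(reg$loading) == drop] <- h
                reg$loading[h] <- stats::runif(1, loading_range[1], loading_range[2])
                regulons[[r]] <- reg
            }
        }
    }
    resp_targets <- unlist(lapply(regulons[responsive], `[[`, "targets"))
    hub_targets <- sort(unique(resp_targets[duplicated(resp_targets)]))

    ct_sd <- stats::runif(n_tfs, celltype_sd_range[1], celltype_sd_range[2])
    celltype_effect <- matrix(stats::rnorm(n_tfs * n_celltypes, 0, ct_sd),
                              nrow = n_tfs, ncol = n_celltypes,
                              dimnames = list(tfs, types))
    disp <- rep_len(dispersion, n_genes)
    names(disp) <- genes
    if (any(disp <= 0)) stop("dispersions must be positive")

    structure(list(
        genes = genes, tfs = tfs, types = types,
        profiles = profiles, markers = markers,
        regulons = regulons, responsive = responsive,
        group_effect = group_effect,
        celltype_effect = celltype_effect,
        composition = list(Normal = composition_normal, DCM = composition_dcm),
        tf_loading = tf_loading,
        hub_targets = hub_targets, planted_hubs = planted_hubs,
        noise = list(dispersion = disp, libsize_meanlog = libsize_meanlog,
                     libsize_sdlog = libsize_sdlog, batch_sd = batch_sd),
        seed = seed), class = "SyntheticTruth")
}

#' @exportS3Method base::print
print.SyntheticTruth <- function(x, ...) {
    cat(sprintf("SyntheticTruth: %d genes, %d TFs (%d responsive), %d cell types\n",
                length(x$genes), length(x$tfs), length(x$responsive),
                length(x$types)))
    cat(sprintf("  group effect %.2f SD; %d hub targets\n",
                x$group_effect, length(x$hub_targets)))
    invisible(x)
}

# loading matrix genes x TFs (targets plus the TF's own transcript)
.loadingMatrix <- function(truth) {
    gi <- seq_along(truth$genes)
    names(gi) <- truth$genes
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (j in seq_along(truth$tfs)) {
        reg <- truth$regulons[[j]]
        ii <- c(ii, gi[reg$targets], gi[reg$tf])
        jj <- c(jj, rep(j, length(reg$targets) + 1L))
        xx <- c(xx, unname(reg$loading), truth$tf_loading)
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                         dims = c(length(truth$genes), length(truth$tfs)),
                         dimnames = list(truth$genes, truth$tfs))
}

#' Simulate a single-cell UMI count matrix from planted truth
#'
#' For each cell: the cell type is drawn from its group's composition; each
#' regulon's latent activity is `celltype offset + group shift (responsive
#' regulons, DCM cells) + N(0,1)`; gene log-means are the cell type's
#' baseline profile plus `loading x activity` on regulon targets (and the
#' TF's own transcript) plus a small per-sample batch offset; counts are
#' Gamma-Poisson with log-normal library sizes.
#'
#' @param truth A [simulateTruth()] object.
#' @param n_cells_per_group Cells per group (scalar or `c(Normal, DCM)`).
#' @param n_samples_per_group Samples (= batches) per group.
#' @param seed Integer seed.
#' @return A [SingleCellExperiment] with integer `counts`, `colData`
#'   columns `sample_id`, `group`, `batch`, `cell_type`, and the latent
#'   activity matrix in `metadata()$activity` (regulons x cells).
#' @export
simulateSingleCell <- function(truth, n_cells_per_group = 1000L,
                               n_samples_per_group = 4L, seed = 1L) {
    stopifnot(inherits(truth, "SyntheticTruth"))
    set.seed(seed)
    ncg <- rep_len(as.integer(n_cells_per_group), 2L)
    groups <- c("Normal", "DCM")
    n_genes <- length(truth$genes)
    n_tfs <- length(truth$tfs)

    all_counts <- vector("list", 2L)
    meta <- vector("list", 2L)
    acts <- vector("list", 2L)
    for (g in 1:2) {
        grp <- groups[g]
        n <- ncg[g]
        samples <- sprintf("%s_S%d", grp, seq_len(n_samples_per_group))
        batch_off <- matrix(stats::rnorm(n_genes * n_samples_per_group, 0,
                                         truth$noise$batch_sd),
                            nrow = n_genes)
        type_idx <- sample(seq_along(truth$types), n, replace = TRUE,
                           prob = truth$composition[[grp]])
        sample_idx <- rep_len(seq_len(n_samples_per_group), n)
        A <- truth$celltype_effect[, type_idx, drop = FALSE] +
            matrix(stats::rnorm(n_tfs * n), nrow = n_tfs)
        if (grp == "DCM" && length(truth$responsive))
            A[truth$responsive, ] <- A[truth$responsive, ] + truth$group_effect
        L <- .loadingMatrix(truth)
        logmu <- log(truth$profiles)[, type_idx, drop = FALSE] +
            as.matrix(L %*% A) + batch_off[, sample_idx, drop = FALSE]
        p <- exp(logmu)
        p <- sweep(p, 2, colSums(p), "/")
        lib <- stats::rlnorm(n, truth$noise$libsize_meanlog,
                             truth$noise$libsize_sdlog)
        mu <- sweep(p, 2, lib, "*")
        cnt <- matrix(stats::rnbinom(n_genes * n,
                                     size = 1 / truth$noise$dispersion,
                                     mu = as.vector(mu)),
                      nrow = n_genes)
        all_counts[[g]] <- cnt
        meta[[g]] <- data.frame(sample_id = samples[sample_idx], group = grp,
                                batch = samples[sample_idx],
                                cell_type = truth$types[type_idx],
                                stringsAsFactors = FALSE)
        acts[[g]] <- A
    }
    counts <- cbind(all_counts[[1]], all_counts[[2]])
    cd <- rbind(meta[[1]], meta[[2]])
    cells <- sprintf("cell%05d", seq_len(nrow(cd)))
    dimnames(counts) <- list(truth$genes, cells)
    rownames(cd) <- cells
    A <- cbind(acts[[1]], acts[[2]])
    colnames(A) <- cells
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(counts, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(cd))
    S4Vectors::metadata(sce)$activity <- A
    S4Vectors::metadata(sce)$layer_tag <- "counts"
    sce
}

#' Simulate a bulk expression matrix as a noisy pseudobulk mixture
#'
#' Each sample is the log2 of a composition-weighted mixture of the truth's
#' cell-type mean profiles, with the responsive regulons' expression effect
#' applied in the DCM group, plus i.i.d. Gaussian noise per gene.
#'
#' @param truth A [simulateTruth()] object.
#' @param n_per_group Named vector `c(Normal = ..., DCM = ...)`.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param seed Integer seed.
#' @return A [SummarizedExperiment] with assay `exprs` (log2 scale) and
#'   `colData$group`.
#' @export
simulateBulk <- function(truth, n_per_group = c(Normal = 16L, DCM = 86L),
                         noise_sd = 0.3, seed = 1L) {
    stopifnot(inherits(truth, "SyntheticTruth"))
    set.seed(seed)
    groups <- c("Normal", "DCM")
    n_genes <- length(truth$genes)
    L <- .loadingMatrix(truth)
    mats <- lapply(groups, function(grp) {
        n <- as.integer(n_per_group[[grp]])
        # expected activity per type: celltype offset (+ shift in DCM)
        A_mean <- truth$celltype_effect
        if (grp == "DCM" && length(truth$responsive))
            A_mean[truth$responsive, ] <- A_mean[truth$responsive, ] +
                truth$group_effect
        prof <- truth$profiles * exp(as.matrix(L %*% A_mean))
        mix <- as.vector(prof %*% truth$composition[[grp]])
        mix <- mix / sum(mix) * 1e6
        base <- log2(mix + 1)
        base + matrix(stats::rnorm(n_genes * n, 0, noise_sd), nrow = n_genes)
    })
    m <- do.call(cbind, mats)
    samples <- sprintf("%s_B%03d", rep(groups, times = n_per_group[groups]),
                       seq_len(ncol(m)))
    dimnames(m) <- list(truth$genes, samples)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = m),
        colData = S4Vectors::DataFrame(
            group = rep(groups, times = n_per_group[groups]),
            row.names = samples))
    S4Vectors::metadata(se)$scale <- "log"
    se
}

#' Simulate a motif-support table
#'
#' Emulates motif-based regulon pruning input: planted TF->target edges are
#' flagged as motif-supported with probability `true_support_rate`, every
#' other (TF, gene) pair with probability `false_support_rate`.
#'
#' @param truth A [simulateTruth()] object.
#' @param true_support_rate,false_support_rate Support probabilities in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A regulon-edge `data.frame` (`tf`, `target`, `importance` = 1
#'   for planted edges else 0, `motif_supported`).
#' @export
simulateMotifTable <- function(truth, true_support_rate = 1,
                               false_support_rate = 0.05, seed = 1L) {
    stopifnot(inherits(truth, "SyntheticTruth"),
              true_support_rate >= 0, true_support_rate <= 1,
              false_support_rate >= 0, false_support_rate <= 1)
    set.seed(seed)
    tab <- expand.grid(target = truth$genes, tf = truth$tfs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- tab[tab$target != tab$tf, c("tf", "target")]
    planted <- unlist(lapply(truth$regulons, function(r)
        paste(r$tf, r$targets)), use.names = FALSE)
    is_planted <- paste(tab$tf, tab$target) %in% planted
    prob <- ifelse(is_planted, true_support_rate, false_support_rate)
    tab$importance <- as.numeric(is_planted)
    tab$motif_supported <- stats::rbinom(nrow(tab), 1, prob) == 1
    rownames(tab) <- NULL
    tab
}
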