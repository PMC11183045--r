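.toy_sce <- function(m) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(m, "CsparseMatrix")))
}

test_that("QC keeps boundary cells and matches a brute-force scan", {
    m <- matrix(0, 300, 4)
    m[1:199, 1] <- 1   # 199 detected -> removed
    m[1:200, 2] <- 1   # exactly min  -> retained
    m[1:250, 3] <- 1   # retained
    m[1:260, 4] <- 5   # retained
    sce <- .toy_sce(m)
    kept <- qcFilter(sce, min_genes = 200L, max_genes = 250L)
    expect_identical(colnames(kept), c("c002", "c003"))

    set.seed(5)
    r <- matrix(rpois(200 * 50, 0.8), 200, 50)
    rs <- .toy_sce(r)
    kept <- qcFilter(rs, 100L, 160L)
    oracle <- colnames(rs)[vapply(seq_len(50), function(j) {
        g <- sum(r[, j] > 0); g >= 100 && g <= 160
    }, logical(1))]
    expect_identical(colnames(kept), oracle)
    # idempotence
    expect_identical(colnames(qcFilter(kept, 100L, 160L)), colnames(kept))

    expect_error(qcFilter(rs, 5000L, 6000L), "all 50 cells removed")
})

test_that("log-normalization matches the closed form and is scale invariant", {
    m <- matrix(0, 5, 2)
    m[1, 1] <- 10; m[2, 1] <- 9990      # total 10000, gene count 10 -> ln(11)
    m[, 2] <- c(2, 4, 8, 16, 2)
    sce <- normalizeCells(.toy_sce(m), scale = 10000)
    ln <- as.matrix(SingleCellExperiment::logcounts(sce))
    expect_equal(ln[1, 1], log(11), tolerance = 1e-12)

    m2 <- m; m2[, 2] <- m[, 2] * 2      # doubling a cell's counts
    ln2 <- as.matrix(SingleCellExperiment::logcounts(
        normalizeCells(.toy_sce(m2), scale = 10000)))
    expect_equal(ln2[, 2], ln[, 2], tolerance = 1e-12)

    set.seed(6)
    r <- matrix(rpois(100 * 20, 2), 100, 20)
    r[1, ] <- r[1, ] + 1  # avoid zero-total cells
    lnr <- as.matrix(SingleCellExperiment::logcounts(
        normalizeCells(.toy_sce(r), scale = 1e4)))
    direct <- log1p(sweep(r, 2, colSums(r), "/") * 1e4)
    dimnames(direct) <- dimnames(lnr)
    expect_equal(lnr, direct, tolerance = 1e-12)

    zc <- .toy_sce(matrix(c(1, 0), 1, 2))
    expect_error(normalizeCells(zc), "zero total")
})

test_that("HVG selection ranks dispersed genes above flat ones", {
    tr <- smallTruth()
    sce <- smallSCE()
    expect_error(selectHVG(sce, nrow(sce) + 1L), "exceeds")
    expect_setequal(selectHVG(sce, nrow(sce)), rownames(sce))

    # planted high-dispersion genes outrank baseline genes
    disp <- rep(0.3, 400)
    hi <- sample(400, 40)
    disp[hi] <- 3
    tr2 <- simulateTruth(n_celltypes = 2, n_genes = 400, n_tfs = 5,
                         targets_per_tf = 10, n_responsive = 0, n_hubs = 0,
                         composition_normal = c(0.5, 0.5),
                         composition_dcm = c(0.5, 0.5),
                         markers_per_type = 5L, marker_fold = 1,
                         dispersion = disp, seed = 61)
    sce2 <- simulateSingleCell(tr2, 400, 1, seed = 62)
    sce2 <- normalizeCells(sce2)
    sel <- selectHVG(sce2, 40L)
    recall <- mean(tr2$genes[hi] %in% sel)
    expect_gt(recall, 0.9)

    # constant genes are never preferred over varying ones
    m <- rbind(matrix(3, 5, 30), matrix(rpois(20 * 30, 3), 20, 30))
    sce3 <- normalizeCells(.toy_sce(m))
    sel3 <- selectHVG(sce3, 20L)
    expect_false(any(sprintf("g%03d", 1:5) %in% sel3))
})

test_that("scaled PCA is exact, ordered, sign-fixed and reconstructs", {
    sce <- smallSCE()
    hvg <- selectHVG(sce, 100L)
    pca <- scalePCA(sce, hvg, n_pcs = 20L)
    expect_true(all(diff(pca$sdev) <= 1e-12))
    # sign convention: largest-magnitude loading positive
    for (j in seq_len(ncol(pca$rotation)))
        expect_gte(pca$rotation[which.max(abs(pca$rotation[, j])), j], 0)
    # full-rank reconstruction of the scaled matrix
    pall <- scalePCA(sce, hvg, n_pcs = min(100L, ncol(sce)))
    full <- stats::prcomp(t(pall$scaled), center = FALSE)
    rec <- full$x %*% t(full$rotation)
    expect_equal(rec, t(pall$scaled), tolerance = 1e-8,
                 ignore_attr = TRUE)

    # rank-2 matrix: no variance beyond PC2
    u <- outer(rnorm(30), rnorm(12)) + outer(rnorm(30), rnorm(12))
    rownames(u) <- sprintf("g%03d", 1:30); colnames(u) <- sprintf("c%03d", 1:12)
    sceu <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(matrix(1, 30, 12,
            dimnames = dimnames(u)), "CsparseMatrix"),
            logcounts = u))
    p2 <- scalePCA(sceu, rownames(u), n_pcs = 5L, clip = 1e9)
    expect_lt(sum(p2$sdev[3:5]^2) / sum(p2$sdev^2), 1e-12)

    expect_error(scalePCA(sce, hvg, n_pcs = 1e4L), "n_pcs")
    expect_error(scalePCA(sce, character(0)), "non-empty")
})

test_that("batch centering removes constant offsets and fixes planted batches", {
    s <- matrix(rnorm(100 * 5), 100, 5)
    expect_equal(batchCenter(s, rep("b1", 100)), s, tolerance = 1e-12)

    # two batches that are the same cloud up to a constant PC-space offset:
    # centering removes the offset exactly, superimposing the clouds
    off <- c(3, -1, 2, 0.5, -2)
    base <- s[1:50, ]
    s2 <- rbind(base, sweep(base, 2, off, "+"))
    cen <- batchCenter(s2, rep(c("b1", "b2"), each = 50))
    expect_equal(cen[1:50, ], cen[51:100, ], tolerance = 1e-12)
    expect_equal(colMeans(cen[1:50, ]), colMeans(cen[51:100, ]),
                 tolerance = 1e-12)

    expect_warning(batchCenter(s, c("solo", rep("b", 99))), "single cell")
})

test_that("graph clustering separates blobs, collapses at low resolution, and is order invariant", {
    set.seed(71)
    blob <- rbind(matrix(rnorm(150 * 5), 150, 5),
                  matrix(rnorm(150 * 5, mean = 10), 150, 5))
    rownames(blob) <- sprintf("c%03d", 1:300)
    cl <- clusterCells(blob, k_neighbors = 15L, resolution = 0.7, seed = 1L)
    expect_equal(length(unique(cl)), 2L)
    expect_equal(length(unique(cl[1:150])), 1L)
    expect_equal(length(unique(cl[151:300])), 1L)

    # a connected graph collapses to one community at vanishing resolution
    one_blob <- matrix(rnorm(200 * 5), 200, 5,
                       dimnames = list(sprintf("b%03d", 1:200), NULL))
    cl_low <- clusterCells(one_blob, 15L, resolution = 1e-4, seed = 1L)
    expect_equal(length(unique(cl_low)), 1L)

    perm <- sample(300)
    cl_p <- clusterCells(blob[perm, ], 15L, 0.7, seed = 1L)
    # identical partition up to label renaming
    expect_equal(length(unique(paste(cl[perm], cl_p))),
                 length(unique(cl)))

    expect_error(clusterCells(blob[1:10, ], 15L, 0.7), "k_neighbors")
})

test_that("marker detection matches a hand-built Wilcoxon oracle and behaves at nulls", {
    # oracle: normal-approximation rank-sum with tie correction + continuity
    wilcox_oracle <- function(x, y) {
        n1 <- length(x); n2 <- length(y); N <- n1 + n2
        r <- rank(c(x, y))
        U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
        ties <- table(r)
        s2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        z <- U - n1 * n2 / 2
        z <- (z - sign(z) * 0.5) / sqrt(s2)
        2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5)
    }
    set.seed(81)
    for (i in 1:100) {
        x <- sample(0:5, 25, TRUE) + rnorm(25, sd = 0.01 * (i %% 2))
        y <- sample(0:5, 30, TRUE) + rnorm(30, sd = 0.01 * (i %% 2))
        expect_equal(stats::wilcox.test(x, y, exact = FALSE)$p.value,
                     wilcox_oracle(x, y), tolerance = 1e-8)
    }

    # a gene exclusive to one cluster gets that cluster's smallest p
    set.seed(82)
    m <- matrix(rpois(60 * 80, 2), 60, 80)
    m[1, 1:40] <- 50; m[1, 41:80] <- 0
    sce <- normalizeCells(.toy_sce(m))
    lab <- rep(c("A", "B"), each = 40)
    mk <- findMarkers(sce, lab, mode = "one-vs-rest")
    a <- mk[mk$cluster == "A", ]
    expect_equal(a$gene[which.min(a$p_value)], "g001")
    expect_equal(a$pct_out[a$gene == "g001"], 0)

    # identical groups: unadjusted p roughly uniform
    set.seed(83)
    null_m <- matrix(rpois(1000 * 60, 3), 1000, 60)
    null_sce <- normalizeCells(.toy_sce(null_m))
    lab <- rep(c("A", "B"), 30)
    mk0 <- findMarkers(null_sce, lab, logfc_threshold = 0, min_pct = 0,
                       mode = "two-group")
    frac <- mean(mk0$p_value < 0.05)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(mk0)) + 0.01)

    expect_error(findMarkers(sce, rep("A", 80)), "2 labels")
})

test_that("annotation assigns marker-driven types with deterministic ties", {
    cm <- rbind(cl0 = c(TTN = 5, MYH6 = 4, VWF = 0.1, DCN = 0.2),
                cl1 = c(TTN = 0.1, MYH6 = 0.2, VWF = 6, DCN = 0.1),
                cl2 = c(TTN = 0.2, MYH6 = 0.1, VWF = 0.1, DCN = 7))
    ref <- list(cardiomyocyte = c("TTN", "MYH6"), endothelial = "VWF",
                fibroblast = "DCN")
    ann <- annotateClusters(cm, ref)
    expect_identical(ann$cell_type[ann$cluster == "cl0"], "cardiomyocyte")
    expect_identical(ann$cell_type[ann$cluster == "cl1"], "endothelial")
    expect_true(all(ann$margin > 0))

    # identical marker sets: deterministic tie-break with a warning
    ref2 <- list(typeA = c("TTN", "MYH6"), typeB = c("TTN", "MYH6"))
    expect_warning(ann2 <- annotateClusters(cm, ref2), "tie")
    expect_identical(ann2$cell_type[ann2$cluster == "cl0"], "typeA")

    expect_warning(annotateClusters(cm, list(cardiomyocyte = c("TTN", "NOPE"),
                                             endothelial = "VWF")),
                   "absent")
    expect_error(annotateClusters(cm, list(ghost = "NOPE",
                                           endothelial = "VWF")),
                 "all markers absent")

    # simulated clusters with planted profiles annotate perfectly
    sce <- smallSCE()
    cm2 <- clusterMeans(sce, sce$cell_type)
    ann3 <- annotateClusters(cm2, smallTruth()$markers)
    expect_identical(ann3$cell_type, ann3$cluster)
})

test_that("composition tables count and normalize within groups", {
    meta <- data.frame(group = c("Normal", "Normal", "DCM"),
                       cell_type = c("cm", "cm", "cm"))
    tab <- cellComposition(meta)
    expect_equal(tab$proportion, c(1, 1))

    sce <- smallSCE()
    tab2 <- cellComposition(data.frame(group = sce$group,
                                       cell_type = sce$cell_type))
    sums <- tapply(tab2$proportion, tab2$group, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)))
    expect_error(cellComposition(data.frame(group = "a",
                                            cell_type = NA_character_)),
                 "every cell")
})
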