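test_that("regulon intersection tracks shared names and direction consistency", {
    r <- intersectRegulons(list(d1 = c(A = -1, B = 1),
                                d2 = c(A = -1, C = 1)))
    expect_identical(r$shared, "A")
    expect_identical(r$consistent, "A")

    r2 <- intersectRegulons(list(d1 = c(A = -1), d2 = c(A = 1)))
    expect_identical(r2$shared, "A")
    expect_length(r2$consistent, 0)

    r3 <- intersectRegulons(list(d1 = c(A = -1, B = 1, C = -1),
                                 d2 = c(B = 1, C = 1, D = 1),
                                 d3 = c(B = 1, C = -1)))
    expect_setequal(r3$shared, c("B", "C"))
    expect_identical(r3$consistent, "B")
    expect_error(intersectRegulons(list(c(A = 1))), "at least 2")
})

test_that("multi-target counting matches brute force and ignores regulon order", {
    r <- countMultiTargets(list(r1 = c("a", "b"), r2 = c("b", "c")))
    expect_equal(r$counts[["b"]], 2)
    expect_identical(r$multi_targets, "b")
    expect_identical(countMultiTargets(list(r1 = c("a"), r2 = "b"))$multi_targets,
                     character(0))

    set.seed(601)
    for (i in 1:20) {
        sets <- lapply(1:6, function(j) sample(letters, sample(3:15, 1)))
        names(sets) <- sprintf("r%d", 1:6)
        got <- countMultiTargets(sets)
        brute <- table(unlist(lapply(sets, unique)))
        expect_equal(as.numeric(got$counts[names(brute)]),
                     as.numeric(brute))
        perm <- sample(6)
        expect_identical(countMultiTargets(sets[perm])$multi_targets,
                         got$multi_targets)
    }
})

test_that("hub targets are the DE multi-targets in every dataset, monotonically", {
    deg <- function(genes, pass) data.frame(gene = genes,
                                            passes_filter = pass)
    ht <- hubTargets(c("x", "y"),
                     list(deg(c("x", "y"), c(TRUE, FALSE)),
                          deg(c("x", "y"), c(TRUE, TRUE))))
    expect_identical(ht$hubs, "x")
    ht0 <- hubTargets(c("x", "y"),
                      list(deg(c("x", "y"), c(FALSE, FALSE)),
                           deg(c("x", "y"), c(TRUE, TRUE))))
    expect_length(ht0$hubs, 0)

    # relaxing thresholds (more passes) never removes a hub
    set.seed(602)
    for (i in 1:10) {
        genes <- sprintf("g%02d", 1:30)
        multi <- sample(genes, 10)
        p1 <- runif(30) < 0.4; p2 <- runif(30) < 0.4
        h_strict <- hubTargets(multi, list(deg(genes, p1), deg(genes, p2)))
        h_relax <- hubTargets(multi, list(deg(genes, p1 | runif(30) < 0.3),
                                          deg(genes, p2 | runif(30) < 0.3)))
        expect_true(all(h_strict$hubs %in% h_relax$hubs))
    }

    rs <- RegulonSet(c("TF1", "TF2"), list(c("x", "q"), c("x", "y")),
                     list(c(1, 1), c(1, 1)))
    ht2 <- hubTargets("x", list(deg("x", TRUE), deg("x", TRUE)), rs)
    expect_setequal(ht2$provenance$x, c("TF1(+)", "TF2(+)"))
})

test_that("ROC AUC follows the rank identity, handles ties, and matches oracles", {
    expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                        c(1, 1, 1, 0, 0, 0), positive = 1), 1.0)
    expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 1, 0, 1), positive = 1), 0.75)
    expect_equal(rocAuc(rep(5, 10), rep(c(0, 1), 5), positive = 1), 0.5)
    expect_error(rocAuc(1:4, rep(1, 4), positive = 1), "both classes")

    # Mann-Whitney U identity against wilcox.test's statistic
    set.seed(603)
    for (i in 1:50) {
        n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
        v <- c(rnorm(n1, 0.5), rnorm(n0))
        if (i %% 2 == 0) v <- round(v)  # force ties
        lab <- rep(c(1, 0), c(n1, n0))
        U <- stats::wilcox.test(v[lab == 1], v[lab == 0],
                                exact = FALSE)$statistic
        expect_equal(rocAuc(v, lab, positive = 1), unname(U) / (n1 * n0),
                     tolerance = 1e-12)
    }

    # direction flip mirrors the score
    v <- c(1, 2, 3, 4); lab <- c(1, 1, 0, 0)
    expect_equal(rocAuc(v, lab, positive = 1, direction = "lower"),
                 1 - rocAuc(v, lab, positive = 1, direction = "higher"))
})

test_that("ROC AUC agrees with an established implementation", {
    skip_if_not_installed("pROC")
    set.seed(604)
    for (i in 1:10) {
        v <- rnorm(60); lab <- rep(c(1, 0), each = 30)
        v[lab == 1] <- v[lab == 1] + runif(1, 0, 2)
        ref <- suppressMessages(pROC::auc(pROC::roc(lab, v,
                                                    direction = "<",
                                                    quiet = TRUE)))
        expect_equal(rocAuc(v, lab, positive = 1), as.numeric(ref),
                     tolerance = 1e-12)
    }
})

test_that("bootstrap CI is stratified, deterministic, and covers the point estimate", {
    set.seed(605)
    v <- c(rnorm(40, 2), rnorm(40))
    lab <- rep(c("DCM", "Normal"), each = 40)
    r1 <- rocBootstrapCI(v, lab, n_boot = 500, seed = 7)
    r2 <- rocBootstrapCI(v, lab, n_boot = 500, seed = 7)
    expect_identical(r1, r2)
    expect_lte(r1$ci_low, r1$auc)
    expect_gte(r1$ci_high, r1$auc)

    sep <- c(rep(1, 30), rep(0, 30)) + 0
    lab2 <- rep(c("DCM", "Normal"), each = 30)
    rp <- rocBootstrapCI(sep, lab2, n_boot = 200, seed = 1)
    expect_equal(rp$ci_high, 1.0)
    expect_equal(rp$auc, 1.0)
})

test_that("over-representation p-values equal hypergeometric tail sums", {
    universe <- sprintf("g%03d", 1:100)
    sets <- list(hit_set = universe[1:10], other = universe[51:70])
    res <- oraTest(universe[1:10], universe, sets)
    expect_identical(res$set[which.min(res$p)], "hit_set")

    # 2x2 example: 10 hits, 5 in a 20-gene set, universe 100
    res2 <- oraTest(universe[c(1:5, 96:100)], universe,
                    list(S = universe[1:20]))
    manual <- sum(dhyper(5:10, 20, 80, 10))
    expect_equal(res2$p[1], manual, tolerance = 1e-12)
    expect_equal(res2$fold_enrichment[1], (5 / 10) / (20 / 100))

    # null hits: super-uniform p (the hypergeometric p is discrete, so
    # uniformity is checked as P(p <= a) <= a plus binomial slack)
    set.seed(606)
    ps <- replicate(200, {
        oraTest(sample(universe, 10), universe,
                list(S = universe[1:20]))$p[1]
    })
    for (a in c(0.05, 0.1, 0.25, 0.5))
        expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 200))
    expect_error(oraTest("g001", character(0), sets), "empty universe")
})
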