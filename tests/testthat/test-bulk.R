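test_that("moderated t collapses to the ordinary t in the weak-prior limit", {
    set.seed(501)
    m <- matrix(rnorm(100 * 10), 100, 10,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:10)))
    gr <- rep(c("Normal", "DCM"), each = 5)
    de <- deModerated(m, gr, d0 = 1e-8, s0 = 1)
    expect_equal(de$t_moderated, de$t_ordinary, tolerance = 1e-5)
})

test_that("moderated t agrees with an independent empirical-Bayes implementation", {
    skip_if_not_installed("limma")
    set.seed(502)
    m <- matrix(rnorm(400 * 12, sd = rep(exp(rnorm(400, 0, 0.5)), 12)),
                400, 12,
                dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:12)))
    gr <- rep(c("Normal", "DCM"), each = 6)
    m[1:30, gr == "DCM"] <- m[1:30, gr == "DCM"] + 1.5
    de <- deModerated(m, gr)

    design <- cbind(1, gr == "DCM")
    fit <- limma::eBayes(limma::lmFit(m, design))
    expect_equal(de$t_moderated, fit$t[, 2], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(de$p, fit$p.value[, 2], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(unname(attr(de, "prior")["d0"]), fit$df.prior,
                 tolerance = 1e-6)
})

test_that("null genes keep FDR control and planted genes give power", {
    set.seed(503)
    m <- matrix(rnorm(2000 * 20, sd = 0.7), 2000, 20,
                dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:20)))
    gr <- rep(c("Normal", "DCM"), each = 10)
    de <- deModerated(m, gr)
    frac <- mean(de$fdr < 0.05, na.rm = TRUE)
    expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))

    # cohort-shaped power run: log2FC = 1, sd = 0.5, 16 vs 86
    set.seed(504)
    n1 <- 16; n2 <- 86
    m2 <- matrix(rnorm(500 * (n1 + n2), sd = 0.5), 500, n1 + n2,
                 dimnames = list(sprintf("g%03d", 1:500), NULL))
    colnames(m2) <- sprintf("s%03d", seq_len(n1 + n2))
    gr2 <- rep(c("Normal", "DCM"), c(n1, n2))
    m2[1:100, gr2 == "DCM"] <- m2[1:100, gr2 == "DCM"] + 1
    de2 <- deModerated(m2, gr2)
    power <- mean(de2$passes_filter[1:100])
    expect_gt(power, 0.9)

    m2[5, ] <- 3
    expect_warning(de3 <- deModerated(m2, gr2), "zero variance")
    expect_true(is.na(de3$p[5]))
    expect_error(deModerated(m2[, 1:3], gr2[1:3]), "at least 2")
})

test_that("ssGSEA reproduces the 5-gene hand computation and is rank based", {
    # genes ranked g1 > g2 > ... > g5; set {g1}, alpha = 0.25:
    # increments: +1 at position 1, then -1/4 at each non-member;
    # running sums 1, .75, .5, .25, 0 -> ES = 2.5
    x <- matrix(c(10, 8, 6, 4, 2), ncol = 1,
                dimnames = list(paste0("g", 1:5), "s1"))
    es <- ssgseaScore(x, list(S = "g1"), alpha = 0.25, normalize = FALSE)
    expect_equal(unname(es["S", "s1"]), 2.5, tolerance = 1e-10)

    # a two-member set with unequal weights: hand-computed running sum
    # ranks (desc) g1..g5 get weights 5,4,3,2,1; set {g2, g4}:
    # wsum = 4^.25 + 2^.25; inc2 = 4^.25/wsum at pos2, inc4 = 2^.25/wsum
    # at pos4, dec = 1/3 at pos 1,3,5
    w2 <- 4^0.25; w4 <- 2^0.25; ws <- w2 + w4
    run <- cumsum(c(-1/3, w2/ws, -1/3, w4/ws, -1/3))
    es2 <- ssgseaScore(x, list(S = c("g2", "g4")), alpha = 0.25,
                       normalize = FALSE)
    expect_equal(unname(es2["S", "s1"]), sum(run), tolerance = 1e-10)

    # identical rankings give identical scores; monotone transforms too
    set.seed(505)
    m <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:4)))
    m[, 2] <- m[, 1] * 3 + 7          # same ranking as sample 1
    sets <- list(A = sprintf("g%03d", 1:20), B = sprintf("g%03d", 50:70))
    sc <- ssgseaScore(m, sets, normalize = FALSE)
    expect_equal(sc[, 1], sc[, 2], tolerance = 1e-12)
    sc_t <- ssgseaScore(exp(m / 2), sets, normalize = FALSE)
    expect_equal(sc, sc_t, tolerance = 1e-10)

    # normalization divides by the overall range
    scn <- ssgseaScore(m, sets, normalize = TRUE)
    expect_equal(scn, sc / (max(sc) - min(sc)), tolerance = 1e-12)

    expect_error(ssgseaScore(x, list(S = paste0("g", 1:5))), "every gene")
    expect_warning(ssgseaScore(m, list(thin = c("g001", "zzz", "yyy"))),
                   "coverage")
})

test_that("score comparison tests, orients, and stars set-level differences", {
    set.seed(506)
    sc <- matrix(rnorm(6 * 60), 6, 60,
                 dimnames = list(sprintf("set%d", 1:6), sprintf("s%02d", 1:60)))
    gr <- rep(c("Normal", "DCM"), each = 30)
    sc[1, gr == "DCM"] <- sc[1, gr == "DCM"] + 2  # 2 SD shift
    cmp <- compareScores(sc, gr)
    expect_lt(cmp$p[cmp$set == "set1"], 0.001)
    expect_equal(cmp$direction[cmp$set == "set1"], 1)
    expect_identical(cmp$stars[cmp$set == "set1"], "***")
    expect_gt(min(cmp$p[-1]), 0.05)

    const <- rbind(flat = rep(1, 60))
    expect_equal(compareScores(const, gr)$p, 1)

    # star boundaries
    expect_identical(
        as.character(cut(c(0.049, 0.05, 0.009, 0.0009),
                         c(-Inf, 0.001, 0.01, 0.05, Inf), right = FALSE,
                         labels = c("***", "**", "*", "ns"))),
        c("*", "ns", "**", "***"))
    # identical groups: no significance
    cmp0 <- compareScores(sc[2:6, , drop = FALSE], gr)
    expect_gt(min(cmp0$p), 0.05)
})

test_that("BH adjustment agrees with an independent step-up oracle", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    set.seed(507)
    for (i in 1:25) {
        p <- runif(sample(5:200, 1))^sample(1:3, 1)
        expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
    }
})
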