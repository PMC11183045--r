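# REML machinery for y = mu + sum_j Z_j u_j + e with independent random
# intercepts per factor. Works on the profiled scale: V = sigma_e^2 * W(gamma),
# W = I + sum_j gamma_j Z_j Z_j', gamma_j = sigma_j^2 / sigma_e^2. All matrix
# work happens on q x q blocks (q = total factor levels) via Woodbury.

.remlPrep <- function(y, factors) {
    n <- length(y)
    Zs <- lapply(factors, function(f) {
        f <- factor(f)
        stats::model.matrix(~ f - 1)
    })
    Z <- do.call(cbind, Zs)
    list(n = n, q_each = vapply(Zs, ncol, integer(1)),
         ZtZ = crossprod(Z), Zty = drop(crossprod(Z, y)),
         Zt1 = drop(crossprod(Z, rep(1, n))),
         yty = sum(y^2), sy = sum(y))
}

# profiled -2*REML criterion (up to an additive constant) for active gamma;
# active is a logical over factors, gam the gamma values of active factors
.remlCriterion <- function(gam, active, prep) {
    n <- prep$n
    blocks <- rep(active, prep$q_each)
    if (!any(blocks)) {
        yPy <- prep$yty - prep$sy^2 / n
        return(list(f = (n - 1) * log(yPy) + log(n), yPy = yPy))
    }
    gfull <- rep(gam, prep$q_each[active])
    M <- prep$ZtZ[blocks, blocks, drop = FALSE]
    diag(M) <- diag(M) + 1 / gfull
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(list(f = Inf, yPy = NA_real_))
    logdetW <- 2 * sum(log(diag(R))) + sum(log(gfull))
    solveM <- function(v) backsolve(R, backsolve(R, v, transpose = TRUE))
    zy <- prep$Zty[blocks]; z1 <- prep$Zt1[blocks]
    My <- solveM(zy); M1 <- solveM(z1)
    w_yy <- prep$yty - sum(zy * My)
    w_xy <- prep$sy - sum(z1 * My)
    w_xx <- n - sum(z1 * M1)
    yPy <- w_yy - w_xy^2 / w_xx
    if (!is.finite(yPy) || yPy <= 0) return(list(f = Inf, yPy = NA_real_))
    list(f = (n - 1) * log(yPy) + logdetW + log(w_xx), yPy = yPy)
}

#' REML variance components for crossed random intercepts
#'
#' Fits `y = mu + sum_j u_j(f_j) + e` with each factor's random intercepts
#' i.i.d. `N(0, sigma_j^2)` by restricted maximum likelihood. The residual
#' variance is profiled out and the criterion is optimized over
#' variance-ratio space with multi-starts from the grid `{0.01, 0.1, 1}`
#' per component; every subset of components is also compared at the
#' `sigma_j^2 = 0` boundary, so boundary solutions are exact.
#'
#' @param y Numeric response.
#' @param factors Named list of grouping factors (each of length
#'   `length(y)`).
#' @return List with `sigma2` (named: one entry per factor plus
#'   `resid`), `proportions`, `criterion` (profiled -2 REML, up to a
#'   constant) and `converged`.
#' @examples
#' y <- rnorm(60) + rep(rnorm(3, sd = 2), each = 20)
#' remlVarComp(y, list(block = rep(1:3, each = 20)))
#' @export
remlVarComp <- function(y, factors) {
    stopifnot(length(factors) >= 1, all(lengths(factors) == length(y)))
    if (stats::var(y) == 0)
        stop("response is constant; variance components are undefined")
    prep <- .remlPrep(y, factors)
    J <- length(factors)
    best <- NULL
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), J))
    for (s in seq_len(nrow(subsets))) {
        active <- as.logical(subsets[s, ])
        if (!any(active)) {
            cr <- .remlCriterion(numeric(0), active, prep)
            cand <- list(f = cr$f, gamma = rep(0, J), yPy = cr$yPy,
                         converged = TRUE)
            if (is.null(best) || cand$f < best$f) best <- cand
            next
        }
        na <- sum(active)
        starts <- expand.grid(rep(list(log(c(0.01, 0.1, 1))), na))
        for (st in seq_len(nrow(starts))) {
            par0 <- as.numeric(starts[st, ])
            fn <- function(p) {
                f <- .remlCriterion(exp(p), active, prep)$f
                if (!is.finite(f)) 1e10 else f
            }
            res <- if (na == 1) {
                stats::optim(par0, fn, method = "Brent",
                             lower = log(1e-9), upper = log(1e9))
            } else {
                stats::optim(par0, fn, method = "Nelder-Mead",
                             control = list(reltol = 1e-12, maxit = 2000))
            }
            gam <- rep(0, J)
            gam[active] <- exp(res$par)
            cr <- .remlCriterion(exp(res$par), active, prep)
            cand <- list(f = res$value, gamma = gam, yPy = cr$yPy,
                         converged = res$convergence == 0)
            if (is.null(best) || cand$f < best$f - 1e-10) best <- cand
        }
    }
    sigma_e2 <- best$yPy / (prep$n - 1)
    sigma2 <- c(best$gamma * sigma_e2, sigma_e2)
    names(sigma2) <- c(names(factors), "resid")
    list(sigma2 = sigma2, proportions = varianceProportions(sigma2),
         criterion = best$f, converged = best$converged)
}

#' Variance decomposition of one regulon's activity
#'
#' Decomposes per-unit activity into cell-type, group and residual
#' variance by [remlVarComp()] with cell type and group as crossed random
#' factors. Estimating a variance from only two group levels is
#' statistically fragile; it is retained deliberately because the disease
#' contrast has exactly two arms, and the recovery benchmarks quantify the
#' resulting bias.
#'
#' @param y Activity per unit.
#' @param celltype Cell-type label per unit (at least 2 levels).
#' @param group Group label per unit (exactly 2 levels, Normal/DCM).
#' @return List as [remlVarComp()] with components named `celltype`,
#'   `group`, `resid`.
#' @export
fitLmmReml <- function(y, celltype, group) {
    if (length(unique(celltype)) < 2) stop("need at least 2 cell types")
    if (length(unique(group)) != 2) stop("need exactly 2 groups")
    if (length(y) < 20) stop("need at least 20 units")
    remlVarComp(y, list(celltype = celltype, group = group))
}

#' Normalize variance components to proportions
#'
#' @param components Non-negative variance components with positive sum.
#' @return Components divided by their sum (summing to 1).
#' @export
varianceProportions <- function(components) {
    if (any(components < 0)) stop("components must be non-negative")
    s <- sum(components)
    if (s <= 0) stop("components sum to zero")
    components / s
}

#' Knee-rule selection on a sorted group-variance curve
#'
#' Values are sorted decreasingly (ties by name), the x-axis is the rank
#' fraction `(i - 1) / (n - 1)` and the y-axis is min-max normalized;
#' consecutive segment slopes are computed on these normalized axes, and
#' the leading run of segments steeper than `slope_threshold` (default -1)
#' determines the selection: with `L >= 1` such segments the first `L + 1`
#' points are selected, otherwise the selection is empty. A flat curve
#' (all values equal) selects nothing.
#'
#' @param values Named numeric vector (e.g. per-regulon group-variance
#'   proportions within one module).
#' @param slope_threshold Slope cut on the normalized axes.
#' @return Character vector of selected names (possibly empty).
#' @export
kneeSelect <- function(values, slope_threshold = -1) {
    if (length(values) < 2) stop("need at least 2 values")
    ord <- order(-values, names(values))
    v <- values[ord]
    if (max(v) == min(v)) {
        warning("flat curve; empty selection")
        return(character(0))
    }
    n <- length(v)
    xh <- (seq_len(n) - 1) / (n - 1)
    yh <- (v - min(v)) / (max(v) - min(v))
    slopes <- diff(yh) / diff(xh)
    steep <- slopes < slope_threshold
    L <- if (!steep[1]) 0L else which.min(c(steep, FALSE)) - 1L
    if (L == 0L) character(0) else names(v)[seq_len(L + 1L)]
}

#' Variance decomposition and knee selection across all regulons
#'
#' Fits [fitLmmReml()] per RAS column, then applies [kneeSelect()] to the
#' group-variance proportions within each CSI module; the union of the
#' per-module selections is the disease-responsive regulon set.
#' Non-converged fits are excluded from selection with a warning.
#'
#' @param ras Units x regulons activity matrix.
#' @param modules Named module assignment covering all regulons.
#' @param celltype,group Labels per unit.
#' @param slope_threshold Knee slope cut.
#' @return `data.frame` (one row per regulon: variance components,
#'   proportions, module, converged, selected) with the selected set in
#'   `attr(, "selected")`.
#' @export
decomposeAll <- function(ras, modules, celltype, group,
                         slope_threshold = -1) {
    if (!all(colnames(ras) %in% names(modules)))
        stop("modules must cover all regulons")
    failed <- list(sigma2 = c(celltype = NA_real_, group = NA_real_,
                              resid = NA_real_),
                   proportions = c(celltype = NA_real_, group = NA_real_,
                                   resid = NA_real_),
                   criterion = NA_real_, converged = FALSE)
    fits <- lapply(seq_len(ncol(ras)), function(j)
        tryCatch(fitLmmReml(ras[, j], celltype, group),
                 error = function(e) failed))
    tab <- data.frame(
        regulon = colnames(ras),
        sigma2_celltype = vapply(fits, function(f) f$sigma2[["celltype"]], 1),
        sigma2_group = vapply(fits, function(f) f$sigma2[["group"]], 1),
        sigma2_resid = vapply(fits, function(f) f$sigma2[["resid"]], 1),
        p_celltype = vapply(fits, function(f) f$proportions[["celltype"]], 1),
        p_group = vapply(fits, function(f) f$proportions[["group"]], 1),
        p_resid = vapply(fits, function(f) f$proportions[["resid"]], 1),
        module = unname(modules[colnames(ras)]),
        converged = vapply(fits, `[[`, logical(1), "converged"),
        row.names = NULL)
    if (any(!tab$converged))
        warning(sprintf("%d regulon fit(s) did not converge; excluded from selection",
                        sum(!tab$converged)))
    selected <- character(0)
    for (m in unique(tab$module)) {
        sub <- tab[tab$module == m & tab$converged, ]
        if (nrow(sub) < 2) next
        vals <- stats::setNames(sub$p_group, sub$regulon)
        selected <- c(selected, suppressWarnings(
            kneeSelect(vals, slope_threshold)))
    }
    tab$selected <- tab$regulon %in% selected
    attr(tab, "selected") <- sort(selected)
    tab
}
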