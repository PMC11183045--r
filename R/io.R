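#' Read a MatrixMarket single-cell count matrix
#'
#' Reads the standard MTX triplet layout (sparse genes x cells counts plus
#' one-column gene and barcode files) into a [SingleCellExperiment] with a
#' `counts` assay. Optional per-cell metadata (tab-separated with a header
#' containing at least `cell_id`, `sample_id`, `group`) is attached as
#' `colData`.
#'
#' @param matrix_path Path to the MatrixMarket coordinate file.
#' @param genes_path Path to the gene-id file (one id per line).
#' @param barcodes_path Path to the cell-barcode file (one id per line).
#' @param meta_path Optional path to a per-cell metadata TSV; rows are
#'   matched to barcodes by the `cell_id` column and must cover every cell.
#' @return A [SingleCellExperiment] with integer `counts`.
#' @examples
#' d <- tempfile(); dir.create(d)
#' sce <- simulateSingleCell(simulateTruth(seed = 1), 50, 2, seed = 1)
#' writeCellMatrixMTX(sce, d)
#' sce2 <- readCellMatrixMTX(file.path(d, "matrix.mtx"),
#'                           file.path(d, "genes.tsv"),
#'                           file.path(d, "barcodes.tsv"),
#'                           file.path(d, "cell_meta.tsv"))
#' @export
readCellMatrixMTX <- function(matrix_path, genes_path, barcodes_path,
                              meta_path = NULL) {
    m <- Matrix::readMM(matrix_path)
    genes <- readLines(genes_path)
    genes <- genes[nzchar(genes)]
    barcodes <- readLines(barcodes_path)
    barcodes <- barcodes[nzchar(barcodes)]
    if (nrow(m) != length(genes))
        stop(sprintf("format error: %s has %d rows but %s lists %d genes",
                     matrix_path, nrow(m), genes_path, length(genes)))
    if (ncol(m) != length(barcodes))
        stop(sprintf("format error: %s has %d columns but %s lists %d barcodes",
                     matrix_path, ncol(m), barcodes_path, length(barcodes)))
    if (anyDuplicated(genes))
        stop(sprintf("format error: duplicated gene ids in %s", genes_path))
    if (anyDuplicated(barcodes))
        stop(sprintf("format error: duplicated barcodes in %s", barcodes_path))
    v <- m@x
    if (length(v) && (any(v < 0) || any(v != round(v))))
        stop(sprintf("format error: non-integer or negative entries in %s",
                     matrix_path))
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, barcodes)
    cd <- S4Vectors::DataFrame(row.names = barcodes)
    if (!is.null(meta_path)) {
        meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
        if (!"cell_id" %in% colnames(meta))
            stop("format error: cell metadata lacks a 'cell_id' column")
        idx <- match(barcodes, meta$cell_id)
        if (anyNA(idx))
            stop("format error: cell metadata does not cover every barcode")
        cd <- S4Vectors::DataFrame(meta[idx, setdiff(colnames(meta), "cell_id"),
                                        drop = FALSE],
                                   row.names = barcodes)
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m), colData = cd)
}

#' Write a single-cell count matrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cell_meta.tsv`
#' into `dir`, together with a JSON provenance sidecar.
#'
#' @param sce A [SingleCellExperiment] with a `counts` assay.
#' @param dir Output directory (created if missing).
#' @param provenance Optional named list recorded in the sidecar.
#' @return Invisibly, the directory path.
#' @export
writeCellMatrixMTX <- function(sce, dir, provenance = list()) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- methods::as(SingleCellExperiment::counts(sce), "CsparseMatrix")
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    writeLines(rownames(sce), file.path(dir, "genes.tsv"))
    writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
    meta <- as.data.frame(SummarizedExperiment::colData(sce))
    meta <- cbind(cell_id = colnames(sce), meta)
    utils::write.table(meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeProvenance(file.path(dir, "provenance.json"), provenance)
    invisible(dir)
}

#' Read / write a dense bulk expression matrix
#'
#' The on-disk format is a TSV of genes x samples with a header row of
#' sample ids and gene ids in the first column. Group labels come either
#' from a two-column metadata TSV (`sample_id`, `group`) or a character
#' vector parallel to the columns.
#'
#' @param path Expression TSV.
#' @param groups Character vector of group labels (`"Normal"`/`"DCM"`), or
#'   `NULL` if `meta_path` is given.
#' @param meta_path Optional sample-metadata TSV.
#' @param scale Declared scale of the values, `"log"` or `"linear"`; the
#'   caller must state it because downstream fold-change arithmetic assumes
#'   log2 values.
#' @return A [SummarizedExperiment] with assay `exprs` and `colData$group`;
#'   `metadata(x)$scale` records the declared scale.
#' @export
readBulkMatrix <- function(path, groups = NULL, meta_path = NULL,
                           scale = c("log", "linear")) {
    scale <- match.arg(scale)
    tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    m <- as.matrix(tab)
    if (anyDuplicated(rownames(m)))
        stop(sprintf("format error: duplicated gene ids in %s", path))
    if (anyDuplicated(colnames(m)))
        stop(sprintf("format error: duplicated sample ids in %s", path))
    if (!is.null(meta_path)) {
        meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
        idx <- match(colnames(m), meta$sample_id)
        if (anyNA(idx))
            stop("format error: sample metadata does not cover every sample")
        groups <- meta$group[idx]
    }
    if (is.null(groups) || anyNA(groups) || length(groups) != ncol(m))
        stop("every sample needs a group label")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = m),
        colData = S4Vectors::DataFrame(group = groups, row.names = colnames(m)))
    S4Vectors::metadata(se)$scale <- scale
    se
}

#' @rdname readBulkMatrix
#' @param se A [SummarizedExperiment] as returned by [readBulkMatrix()].
#' @export
writeBulkMatrix <- function(se, path, meta_path = NULL) {
    m <- SummarizedExperiment::assay(se, "exprs")
    tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(meta_path)) {
        meta <- data.frame(sample_id = colnames(m),
                           group = SummarizedExperiment::colData(se)$group)
        utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' A GMT line is `name<TAB>description<TAB>member1<TAB>member2...`. The
#' in-memory representation is a named list of character vectors with the
#' descriptions kept in `attr(x, "description")`.
#'
#' @param path File path.
#' @return `readGMT()`: a named list of gene-id vectors.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeGMT(list(S1 = c("g1", "g2")), f)
#' readGMT(f)
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nms <- vapply(parts, `[[`, character(1), 1)
    if (anyDuplicated(nms))
        stop(sprintf("format error: duplicated set name in %s: %s", path,
                     nms[duplicated(nms)][1]))
    bad <- lengths(parts) < 3
    if (any(bad))
        stop(sprintf("format error: set '%s' in %s has zero members",
                     nms[bad][1], path))
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- nms
    attr(sets, "description") <- stats::setNames(
        vapply(parts, `[[`, character(1), 2), nms)
    sets
}

#' @rdname readGMT
#' @param sets Named list of non-empty character vectors; an optional
#'   `description` attribute (named character) supplies the second column.
#' @export
writeGMT <- function(sets, path) {
    if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("sets must be a non-empty uniquely named list")
    if (any(lengths(sets) == 0)) stop("sets must be non-empty")
    desc <- attr(sets, "description")
    if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a regulon edge table
#'
#' Tab-separated with header columns `tf`, `target`, `importance`,
#' `motif_supported` (the last parsed from `0/1/true/false`).
#'
#' @param path File path.
#' @return A `data.frame` with typed columns; `(tf, target)` pairs unique.
#' @export
readRegulonTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(tf = "character",
                                            target = "character"))
    need <- c("tf", "target", "importance", "motif_supported")
    if (!all(need %in% colnames(tab)))
        stop(sprintf("format error: %s must have columns %s", path,
                     paste(need, collapse = ", ")))
    if (anyDuplicated(tab[c("tf", "target")]))
        stop(sprintf("format error: repeated (tf, target) pair in %s", path))
    imp <- suppressWarnings(as.numeric(tab$importance))
    if (anyNA(imp) || any(!is.finite(imp)))
        stop(sprintf("format error: unparseable importance in %s", path))
    ms <- tolower(as.character(tab$motif_supported))
    if (!all(ms %in% c("0", "1", "true", "false")))
        stop(sprintf("format error: motif_supported must be 0/1/true/false in %s",
                     path))
    data.frame(tf = tab$tf, target = tab$target, importance = imp,
               motif_supported = ms %in% c("1", "true"),
               stringsAsFactors = FALSE)
}

#' @rdname readRegulonTable
#' @param table A regulon edge `data.frame` (columns as above).
#' @export
writeRegulonTable <- function(table, path) {
    stopifnot(all(c("tf", "target", "importance", "motif_supported")
                  %in% colnames(table)))
    if (anyDuplicated(table[c("tf", "target")]))
        stop("repeated (tf, target) pair")
    out <- table
    out$motif_supported <- as.integer(table$motif_supported)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a JSON provenance sidecar (parameters, seeds, package version)
#'
#' @param path Output path.
#' @param params Named list of stage parameters.
#' @return Invisibly, the path.
#' @export
writeProvenance <- function(path, params = list()) {
    rec <- list(package = "regulonDCM",
                version = as.character(utils::packageVersion("regulonDCM")),
                written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                params = params)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, null = "null")
    invisible(path)
}
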