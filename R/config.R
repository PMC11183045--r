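#' Default pipeline configuration
#'
#' Returns the full nested parameter record for [runFullPipeline()]. The
#' thresholds mirror the study's stated settings (QC bounds 200/5000
#' detected genes, clustering resolution 0.7, over-clustering resolution 50
#' with the >10-cell metacell filter, marker filters logFC 0.25 / min.pct
#' 0.1, DEG filters |log2FC| > 0.5 and FDR < 0.05, eight CSI modules);
#' synthetic-data parameters define the reference simulation described in
#' the methods vignette. Every stochastic stage has an explicit seed derived
#' from `seed`.
#'
#' @param seed Master seed; per-stage seeds are `seed + stage offset`.
#' @return A nested named list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
    seed <- as.integer(seed)
    list(
        seed = seed,
        sim = list(
            n_celltypes = 8L,
            n_genes = 2000L,
            n_tfs = 50L,
            targets_per_tf = 30L,
            n_responsive = 5L,
            group_effect = 2,
            n_hubs = 5L,
            hub_regulons = 3L,
            composition_normal = c(cardiomyocyte = 0.592, endothelial = 0.207,
                                   fibroblast = 0.073, pericyte = 0.047,
                                   smooth_muscle = 0.030, macrophage = 0.022,
                                   T_cell = 0.018, epithelial = 0.011),
            composition_dcm = c(cardiomyocyte = 0.363, endothelial = 0.301,
                                fibroblast = 0.109, pericyte = 0.060,
                                smooth_muscle = 0.055, macrophage = 0.050,
                                T_cell = 0.040, epithelial = 0.022),
            markers_per_type = 15L,
            marker_fold = 8,
            loading_range = c(0.25, 0.45),
            celltype_sd_range = c(0.5, 1.5),
            dispersion = 0.4,
            libsize_meanlog = log(5000),
            libsize_sdlog = 0.3,
            batch_sd = 0.1,
            n_cells_per_group = 1500L,
            n_samples_per_group = 4L,
            bulk1_n = c(Normal = 16L, DCM = 86L),
            bulk2_n = c(Normal = 136L, DCM = 82L),
            bulk_noise_sd = 0.3,
            true_support_rate = 1.0,
            false_support_rate = 0.05
        ),
        scqc = list(
            min_genes = 200L,
            max_genes = 5000L,
            scale = 10000,
            n_hvg = 500L,
            n_pcs = 30L,
            clip = 10,
            k_neighbors = 20L,
            resolution = 0.7,
            logfc_threshold = 0.25,
            min_pct = 0.1
        ),
        metacell = list(
            resolution = 4,
            k_neighbors = 20L,
            min_cells = 10L,
            strict = TRUE
        ),
        grn = list(
            lambda = 1,
            floor = "auto",
            top_n_per_tf = 50L,
            min_regulon_size = 10L
        ),
        activity = list(top_fraction = 0.05),
        csi = list(k_modules = "auto", linkage = "average", strict = FALSE),
        vardecomp = list(slope_threshold = -1),
        bulkval = list(lfc_threshold = 0.5, fdr_threshold = 0.05,
                       alpha = 0.25, normalize = TRUE),
        hub = list(min_occurrence = 2L, consistent_only = TRUE,
                   n_boot = 2000L)
    )
}

.checkConfigKeys <- function(user, ref, path = "") {
    for (key in names(user)) {
        if (!key %in% names(ref))
            stop(sprintf("unknown config key '%s%s'; valid keys here: %s",
                         path, key, paste(names(ref), collapse = ", ")))
        if (is.list(user[[key]]) && is.list(ref[[key]]))
            .checkConfigKeys(user[[key]], ref[[key]], paste0(path, key, "."))
    }
    invisible(TRUE)
}

#' Load and validate a pipeline configuration file
#'
#' The config dialect is YAML mirroring the nesting of
#' [defaultPipelineConfig()]. Missing keys take their defaults; unknown keys
#' are rejected with the list of valid keys at that nesting level.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @param seed Master seed used for defaults not overridden by the file.
#' @return The fully materialized nested parameter list.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("scqc:\n  resolution: 0.9", f)
#' cfg <- loadConfig(f)
#' cfg$scqc$resolution
#' @export
loadConfig <- function(path, seed = 1L) {
    defaults <- defaultPipelineConfig(seed)
    user <- yaml::read_yaml(path)
    if (is.null(user)) return(defaults)
    if (!is.list(user)) stop("config must be a YAML mapping")
    .checkConfigKeys(user, defaults)
    utils::modifyList(defaults, user)
}
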