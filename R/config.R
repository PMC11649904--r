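#' Default run configuration
#'
#' Returns the full configuration list driving the pipeline, with documented
#' defaults. Any subset of fields may be overridden via `...` or by
#' [loadConfig()]; values are range-checked.
#'
#' Key fields: `n_resamples` (100 stratified splits), `train_fraction` (0.8),
#' `n_folds` (5 inner folds), `gsea_fdr` (0.20, lenient per-resample
#' enrichment cutoff), `rra_fdr` (0.05, consensus cutoff), `auroc_screen`
#' (0.5, minimum test AUROC for a resample to contribute ranks), `grid_size`
#' (20 alphas x 20 lambdas = 400 hyperparameter pairs), `n_permutations`
#' (10000 gene-label permutations for GSEA p-values), `master_seed`, and the
#' modality-specific QC thresholds (`snp_missing_max` 0.01, `maf_min` 0.01,
#' `hwe_p_min` 1e-10, `het_sd` 3, `metab_missing_max` 0.70,
#' `clinical_missing_max` 0.10, `mahalanobis_cutoff` 4, `knn_k` 10,
#' `window_upstream` 2000 bp, `window_downstream` 500 bp).
#'
#' @param ... named overrides of default fields.
#' @return A named list of class `mmConfig`.
#' @examples
#' cfg <- mmConfig(n_resamples = 25)
#' cfg$grid_size^2  # 400 tuning combinations by default
#' @seealso [loadConfig()]
#' @export
mmConfig <- function(...) {
    cfg <- list(
        n_resamples = 100L,
        train_fraction = 0.8,
        n_folds = 5L,
        gsea_fdr = 0.20,
        rra_fdr = 0.05,
        auroc_screen = 0.5,
        grid_size = 20L,
        n_permutations = 10000L,
        master_seed = 1L,
        baseline_modality = "clinical",
        mnsi_threshold = 3,
        # gene set enrichment
        gsea_min_size = 5L,
        gsea_max_size = 500L,
        weight_exponent = 1,
        # QC thresholds
        snp_missing_max = 0.01,
        maf_min = 0.01,
        hwe_p_min = 1e-10,
        het_sd = 3,
        metab_missing_max = 0.70,
        clinical_missing_max = 0.10,
        mahalanobis_cutoff = 4,
        knn_k = 10L,
        window_upstream = 2000L,
        window_downstream = 500L,
        pc_var_fraction = 0.999,
        # elastic net
        lambda_grid = "linear",     # literal [0,1] grid; "log" enables a log path
        importance_mode = "wald",   # or "coef"
        single_pass = FALSE,        # proteomics-style one-shot selection
        modality_files = list()
    )
    override <- list(...)
    if (length(override)) {
        bad <- setdiff(names(override), names(cfg))
        if (length(bad))
            stop("unknown config field(s): ", paste(bad, collapse = ", "))
        cfg[names(override)] <- override
    }
    validateConfig(cfg)
}

validateConfig <- function(cfg) {
    chkFrac <- function(key) {
        v <- cfg[[key]]
        if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
            stop(sprintf("%s must be in (0,1)", key), call. = FALSE)
    }
    chkCount <- function(key) {
        v <- cfg[[key]]
        if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v))
            stop(sprintf("%s must be a positive integer", key), call. = FALSE)
        cfg[[key]] <<- as.integer(v)
    }
    chkProb <- function(key) {
        v <- cfg[[key]]
        if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
            stop(sprintf("%s must be in [0,1]", key), call. = FALSE)
    }
    chkFrac("train_fraction")
    for (k in c("n_resamples", "n_folds", "grid_size", "n_permutations",
                "knn_k", "gsea_min_size", "gsea_max_size"))
        chkCount(k)
    for (k in c("gsea_fdr", "rra_fdr", "auroc_screen", "snp_missing_max",
                "maf_min", "hwe_p_min", "metab_missing_max",
                "clinical_missing_max", "pc_var_fraction"))
        chkProb(k)
    if (cfg$mahalanobis_cutoff <= 0) stop("mahalanobis_cutoff must be > 0")
    if (cfg$window_upstream < 0 || cfg$window_downstream < 0)
        stop("annotation windows must be non-negative")
    class(cfg) <- "mmConfig"
    cfg
}

#' Load a configuration file
#'
#' Reads a YAML key/value file (nested sections allowed and flattened one
#' level), fills in defaults from [mmConfig()] for absent keys, and
#' range-checks every field. An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `mmConfig` list.
#' @export
loadConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    # flatten single-level sections: section: {key: val} -> key: val
    flat <- list()
    for (nm in names(raw)) {
        v <- raw[[nm]]
        if (is.list(v) && !is.null(names(v)) && nm != "modality_files")
            flat[names(v)] <- v
        else flat[[nm]] <- v
    }
    do.call(mmConfig, flat)
}

#' @method print mmConfig
#' @export
print.mmConfig <- function(x, ...) {
    cat("mmselect configuration\n")
    for (nm in names(x)) {
        v <- x[[nm]]
        if (is.list(v)) next
        cat(sprintf("  %-22s %s\n", nm, paste(v, collapse = ", ")))
    }
    invisible(x)
}
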