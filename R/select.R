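# Cohort partitioning, stratified resampling, and the per-modality feature
# selection loop: resampled enrichment -> leading-edge elastic-net screen ->
# rank aggregation -> consensus enrichment.

#' Split a sparse cohort into selection pools and the training pool
#'
#' Samples measured in every modality form the final-training pool; each
#' modality's selection pool holds the samples measured in that modality but
#' missing at least one other. The pools are disjoint by construction, so
#' feature selection never sees a training-pool sample.
#'
#' @param matrices named list of [FeatureMatrix-class].
#' @param labels phenotype data.frame or named 0/1 vector (used only to
#'   validate coverage).
#' @return list with `training` (character ids) and `selection` (named list
#'   of character ids per modality).
#' @export
partitionCohort <- function(matrices, labels = NULL) {
    ids <- lapply(matrices, sampleIDs)
    training <- Reduce(intersect, ids)
    if (!length(training)) stop("no fully characterised samples")
    selection <- lapply(ids, function(x) setdiff(x, training))
    list(training = training, selection = selection)
}

#' Build a stratified resampling plan
#'
#' Creates `n` stratified train/test splits (per-class rounding keeps class
#' proportions within one sample of the cohort ratio) and a stratified
#' `n_folds` fold assignment within each train set. Deterministic under
#' `seed`.
#'
#' @param labels phenotype data.frame (`sample_id`, `label`) or named 0/1
#'   vector.
#' @param n number of resamples.
#' @param train_fraction fraction of samples in each train set (default 0.8).
#' @param n_folds inner folds (default 5).
#' @param seed integer seed.
#' @return A [ResamplePlan-class].
#' @export
makeResamplePlan <- function(labels, n, train_fraction = 0.8, n_folds = 5L,
                             seed = 1L) {
    if (is.data.frame(labels)) {
        y <- stats::setNames(labels$label, labels$sample_id)
    } else y <- labels
    if (is.null(names(y))) stop("labels must be named by sample id")
    cases <- names(y)[y == 1]; controls <- names(y)[y == 0]
    n_tr_case <- round(train_fraction * length(cases))
    n_tr_ctrl <- round(train_fraction * length(controls))
    if (min(n_tr_case, n_tr_ctrl) < n_folds)
        stop(sprintf(
            "too few minority-class samples: need at least %d per class in training (have %d cases, %d controls)",
            n_folds, length(cases), length(controls)))
    train <- test <- folds <- vector("list", n)
    withSeed(seed, {
        for (i in seq_len(n)) {
            ca <- sample(cases); co <- sample(controls)
            tr <- c(ca[seq_len(n_tr_case)], co[seq_len(n_tr_ctrl)])
            te <- setdiff(c(cases, controls), tr)
            # stratified folds: deal each class round-robin after shuffling
            f <- integer(length(tr)); names(f) <- tr
            trc <- sample(intersect(tr, cases))
            trn <- sample(intersect(tr, controls))
            f[trc] <- rep_len(seq_len(n_folds), length(trc))
            f[trn] <- rep_len(seq_len(n_folds), length(trn))
            train[[i]] <- tr; test[[i]] <- te; folds[[i]] <- f
        }
    })
    new("ResamplePlan", train = train, test = test, folds = folds,
        n_folds = as.integer(n_folds), seed = as.integer(seed))
}

# Rank features/genes on the training samples of one resample. Returns a
# rankedList plus the feature-level ids backing each set-level id.
rankForEnrichment <- function(fm, y, ranker, annotation) {
    if (ranker == "t") {
        assoc <- moderatedTAssociation(fm, y)
        list(ranked = rankedList(stats::setNames(assoc$t_statistic,
                                                 assoc$feature_id)),
             unit_map = NULL)
    } else if (ranker == "snp") {
        gs <- snpGeneZscores(fm, annotation, y)
        list(ranked = rankedList(stats::setNames(gs$z_value, gs$gene_id)),
             unit_map = annotation)
    } else if (ranker == "cpg") {
        assoc <- suppressWarnings(moderatedTAssociation(fm, y))
        gs <- cpgGeneScores(assoc, annotation)
        list(ranked = rankedList(stats::setNames(gs$z_value, gs$gene_id)),
             unit_map = annotation)
    } else stop("unknown ranker: ", ranker)
}

# Map set-level leading-edge ids (genes) back to matrix features.
unitsForIds <- function(ids, unit_map, features) {
    if (is.null(unit_map)) return(intersect(ids, features))
    intersect(unit_map$feature_id[unit_map$gene_id %in% ids], features)
}

#' Per-modality molecular feature selection
#'
#' The resampled selection loop for one molecular modality: on each
#' resample's training samples, rank features (moderated t, or gene-level
#' SNP/CpG scores), run preranked enrichment and keep sets at
#' `gsea_fdr`, pool their leading-edge members and fit a class-weighted,
#' tuned elastic net on them, then score the held-out test samples. Resamples
#' whose screen AUROC exceeds `auroc_screen` contribute their full set
#' ranking (by enrichment adjusted p) to robust rank aggregation; sets at
#' `bh_adjusted_p < rra_fdr` form the consensus, and a final enrichment on
#' the whole selection pool restricted to those sets yields the selected
#' leading-edge features. With `config$single_pass` (small cohorts), a single
#' enrichment on all selection samples replaces the resampling loop.
#'
#' @param matrix [FeatureMatrix-class] restricted to the modality's selection
#'   pool, standardised.
#' @param labels phenotype data.frame or named 0/1 vector.
#' @param sets [GeneSetList-class] over features (or genes for `snp`/`cpg`
#'   rankers).
#' @param plan [ResamplePlan-class] over the selection pool.
#' @param config an [mmConfig()] list.
#' @param ranker `"t"` (default), `"snp"` or `"cpg"`.
#' @param annotation unit-to-gene map for `snp`/`cpg` rankers.
#' @return A `ConsensusSelection` list: `modality`, `consensus_sets`
#'   (data.frame set_id, bh_adjusted_p), `features` (character),
#'   `audit` (per-resample data.frame), `kept` (resample indices).
#' @export
selectMolecularFeatures <- function(matrix, labels, sets, plan,
                                    config = mmConfig(), ranker = "t",
                                    annotation = NULL) {
    v <- featureValues(matrix)
    y_all <- normaliseLabels(labels, rownames(v))
    names(y_all) <- rownames(v)
    mod <- modality(matrix)

    if (isTRUE(config$single_pass)) {
        rk <- rankForEnrichment(matrix, y_all, ranker, annotation)
        enr <- gseaPreranked(rk$ranked, sets, config$n_permutations,
                             config$gsea_min_size, config$gsea_max_size,
                             config$weight_exponent,
                             seed = deriveSeed(config$master_seed,
                                               paste0("gsea_", mod)))
        sig <- enr[enr$adjusted_p < config$gsea_fdr, , drop = FALSE]
        feats <- unitsForIds(
            unique(unlist(strsplit(sig$leading_edge, ","))),
            rk$unit_map, colnames(v))
        out <- list(modality = mod,
                    consensus_sets = data.frame(
                        set_id = sig$set_id, bh_adjusted_p = sig$adjusted_p,
                        stringsAsFactors = FALSE),
                    features = feats, audit = NULL, kept = integer())
        class(out) <- "ConsensusSelection"
        return(out)
    }

    n_res <- length(plan@train)
    rankings <- list()
    audit <- data.frame(resample = seq_len(n_res), n_sig_sets = 0L,
                        n_leading_edge = 0L, screen_auroc = NA_real_,
                        kept = FALSE)
    for (i in seq_len(n_res)) {
        tr <- intersect(plan@train[[i]], rownames(v))
        te <- intersect(plan@test[[i]], rownames(v))
        logSampleUse(paste0("select_", mod), i, "rank", tr)
        rk <- tryCatch(
            rankForEnrichment(matrix[tr, ], y_all[tr], ranker, annotation),
            error = function(e) NULL)
        if (is.null(rk)) next
        enr <- gseaPreranked(rk$ranked, sets, config$n_permutations,
                             config$gsea_min_size, config$gsea_max_size,
                             config$weight_exponent,
                             seed = deriveSeed(config$master_seed,
                                               paste0("gsea_", mod), i))
        if (!nrow(enr)) next
        sig <- enr[enr$adjusted_p < config$gsea_fdr, , drop = FALSE]
        audit$n_sig_sets[i] <- nrow(sig)
        if (!nrow(sig)) next  # no enriched sets: contributes no ranks
        le_ids <- unique(unlist(strsplit(sig$leading_edge, ",")))
        feats <- unitsForIds(le_ids, rk$unit_map, colnames(v))
        audit$n_leading_edge[i] <- length(feats)
        if (!length(feats)) next
        Xtr <- v[tr, feats, drop = FALSE]
        Xtr[is.na(Xtr)] <- 0  # standardised scale: mean-impute residual NAs
        logSampleUse(paste0("select_", mod), i, "tune_fit", tr)
        tuned <- tuneElasticNet(Xtr, y_all[tr], plan@folds[[i]][tr],
                                grid_size = config$grid_size,
                                lambda_grid = config$lambda_grid)
        fit <- fitWeightedElasticNet(Xtr, y_all[tr], tuned$alpha,
                                     tuned$lambda)
        Xte <- v[te, feats, drop = FALSE]
        Xte[is.na(Xte)] <- 0
        logSampleUse(paste0("select_", mod), i, "predict", te)
        p <- predictRisk(fit, Xte)
        logSampleUse(paste0("select_", mod), i, "auroc", te)
        a <- if (length(unique(y_all[te])) == 2) auroc(y_all[te], p)
             else NA_real_
        audit$screen_auroc[i] <- a
        if (!is.na(a) && a > config$auroc_screen) {
            audit$kept[i] <- TRUE
            # ties in the discrete permutation p broken by enrichment
            # strength (continuous), then id, so no set is favoured
            # systematically across lists
            ord <- order(enr$adjusted_p, enr$p_value, -abs(enr$es),
                         enr$set_id)
            rankings[[length(rankings) + 1L]] <- enr$set_id[ord]
        }
    }

    consensus <- data.frame(set_id = character(),
                            bh_adjusted_p = numeric(),
                            stringsAsFactors = FALSE)
    feats <- character()
    if (length(rankings)) {
        rra <- aggregateRanks(rankings)
        hit <- rra[rra$bh_adjusted_p < config$rra_fdr, , drop = FALSE]
        if (nrow(hit)) {
            consensus <- data.frame(set_id = hit$item_id,
                                    bh_adjusted_p = hit$bh_adjusted_p,
                                    stringsAsFactors = FALSE)
            # final consensus enrichment on the full selection pool
            keep_sets <- GeneSetList(geneSets(sets)[hit$item_id],
                                     rep("", nrow(hit)))
            rk <- rankForEnrichment(matrix, y_all, ranker, annotation)
            fin <- gseaPreranked(rk$ranked, keep_sets, config$n_permutations,
                                 min(config$gsea_min_size,
                                     min(lengths(geneSets(keep_sets)))),
                                 config$gsea_max_size,
                                 config$weight_exponent,
                                 seed = deriveSeed(config$master_seed,
                                                   paste0("gsea_final_", mod)))
            # only sets confirmed significant on the full pool contribute
            # leading-edge features to the final panel
            fin <- fin[fin$adjusted_p < config$gsea_fdr, , drop = FALSE]
            consensus <- consensus[consensus$set_id %in% fin$set_id, ,
                                   drop = FALSE]
            feats <- unitsForIds(
                unique(unlist(strsplit(fin$leading_edge, ","))),
                rk$unit_map, colnames(v))
        }
    } else {
        warning("modality ", mod, ": no resample passed the AUROC screen; ",
                "empty selection")
    }
    out <- list(modality = mod, consensus_sets = consensus,
                features = feats, audit = audit,
                kept = which(audit$kept))
    class(out) <- "ConsensusSelection"
    out
}

#' @method print ConsensusSelection
#' @export
print.ConsensusSelection <- function(x, ...) {
    cat(sprintf(
        "ConsensusSelection [%s]: %d consensus set(s), %d feature(s), %d resample(s) kept\n",
        x$modality, nrow(x$consensus_sets), length(x$features),
        length(x$kept)))
    invisible(x)
}

#' Clinical feature selection by resampled elastic-net importance
#'
#' On each resample, tunes and fits a class-weighted elastic net on the
#' (one-hot encoded, standardised) clinical training samples, computes
#' feature importance -- Wald statistics of an unpenalised logistic refit on
#' the features with non-zero coefficients (`config$importance_mode = "wald"`,
#' default) or |coefficient| (`"coef"`) -- and ranks features by importance
#' magnitude. Zero-importance features receive no rank from that resample.
#' Rankings are aggregated by robust rank aggregation; features at
#' `bh_adjusted_p < rra_fdr` are selected.
#'
#' @param clinical standardised clinical [FeatureMatrix-class].
#' @param labels phenotype data.frame or named 0/1 vector.
#' @param plan [ResamplePlan-class].
#' @param config an [mmConfig()] list.
#' @return list: `features` (selected ids), `rra` (aggregation table),
#'   `audit` (per-resample data.frame).
#' @export
selectClinicalFeatures <- function(clinical, labels, plan,
                                   config = mmConfig()) {
    v <- featureValues(clinical)
    if (anyNA(v)) stop("clinical matrix must be complete")
    y_all <- normaliseLabels(labels, rownames(v))
    names(y_all) <- rownames(v)
    n_res <- length(plan@train)
    rankings <- list()
    audit <- data.frame(resample = seq_len(n_res), n_nonzero = 0L)
    for (i in seq_len(n_res)) {
        tr <- intersect(plan@train[[i]], rownames(v))
        logSampleUse("select_clinical", i, "tune_fit", tr)
        tuned <- tuneElasticNet(v[tr, , drop = FALSE], y_all[tr],
                                plan@folds[[i]][tr],
                                grid_size = config$grid_size,
                                lambda_grid = config$lambda_grid)
        fit <- fitWeightedElasticNet(v[tr, , drop = FALSE], y_all[tr],
                                     tuned$alpha, tuned$lambda)
        imp <- featureImportance(fit, v[tr, , drop = FALSE], y_all[tr],
                                 mode = config$importance_mode)
        imp <- imp[imp != 0]
        audit$n_nonzero[i] <- length(imp)
        if (length(imp))
            rankings[[length(rankings) + 1L]] <-
                names(sort(-abs(imp)))
    }
    if (!length(rankings)) {
        warning("all resamples produced empty models; empty clinical selection")
        return(list(features = character(), rra = NULL, audit = audit))
    }
    # rankings list only non-zero-importance features; normalise by the full
    # clinical feature count so short lists stay informative
    rra <- aggregateRanks(rankings, universe_size = ncol(v))
    feats <- rra$item_id[rra$bh_adjusted_p < config$rra_fdr]
    list(features = feats, rra = rra, audit = audit)
}

# Importance of a fitted elastic net: Wald z-statistics of an unpenalised
# weighted logistic refit on the non-zero-coefficient features (default), or
# the penalised coefficients themselves. Zero-coefficient features get 0.
featureImportance <- function(fit, X, y, mode = "wald") {
    nz <- names(fit$beta)[fit$beta != 0]
    imp <- stats::setNames(rep(0, length(fit$beta)), names(fit$beta))
    if (!length(nz)) return(imp)
    if (mode == "coef") {
        imp[nz] <- fit$beta[nz]
        return(imp)
    }
    df <- data.frame(y = y, X[, nz, drop = FALSE], check.names = FALSE)
    refit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial(),
                   weights = classWeights(y)))
    co <- summary(refit)$coefficients
    # a separating refit has unbounded coefficients and inflated standard
    # errors, making Wald z uninformative; fall back to the penalised
    # coefficients, which are finite and carry the signs
    sep <- !refit$converged ||
        any(!is.finite(co[, "Std. Error"])) ||
        any(co[-1, "Std. Error"] > 100)
    if (sep) {
        message("featureImportance: unpenalised refit separates; ",
                "using penalised coefficients")
        imp[nz] <- fit$beta[nz]
        return(imp)
    }
    rn <- rownames(co)
    for (f in nz) {
        hit <- match(paste0("`", f, "`"), rn)
        if (is.na(hit)) hit <- match(f, rn)
        if (!is.na(hit)) imp[f] <- co[hit, "z value"]
    }
    imp[!is.finite(imp)] <- 0
    imp
}
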