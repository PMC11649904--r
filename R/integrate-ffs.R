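# Iterative forward selection over data modalities, comparator integrators
# (concatenation, ensemble stacking, univariate thresholding), complexity
# choice and the final consensus model.

# Column-bind the selected panels for given samples; duplicate feature ids
# across panels are suffixed by modality.
bindPanels <- function(panels, mods, ids) {
    blocks <- lapply(mods, function(m) {
        x <- featureValues(panels[[m]])[ids, , drop = FALSE]
        colnames(x) <- paste0(colnames(x), "\r", m)  # tag, stripped below
        x
    })
    X <- do.call(cbind, blocks)
    nm <- sub("\r.*$", "", colnames(X))
    if (!anyDuplicated(nm)) colnames(X) <- nm
    else colnames(X) <- sub("\r", ".", colnames(X), fixed = TRUE)
    X[is.na(X)] <- 0
    X
}

stratifiedFolds <- function(y, n_folds, seed) {
    f <- integer(length(y)); names(f) <- names(y)
    withSeed(seed, {
        for (cl in c(0, 1)) {
            ids <- sample(names(y)[y == cl])
            f[ids] <- rep_len(seq_len(n_folds), length(ids))
        }
    })
    f
}

#' Iterative forward selection over data modalities
#'
#' For each stratified resample, greedily builds a model one modality at a
#' time: at every step each remaining modality is evaluated by tuning a
#' class-weighted elastic net (20 x 20 grid, weighted log-loss) on the
#' current-plus-candidate feature set via inner stratified cross-validation,
#' and the candidate with the best mean inner-CV AUROC is added (ties break
#' alphabetically). The step's model is refit on the full training split,
#' Platt-calibrated on the inner out-of-fold predictions, and scored on the
#' held-out test split, yielding one test AUROC per (resample, complexity).
#' A `baseline` modality, when given, is forced in first regardless of
#' performance.
#'
#' @param panels named list of [FeatureMatrix-class] (selected features per
#'   modality), all covering the training pool.
#' @param labels phenotype data.frame or named 0/1 vector.
#' @param plan [ResamplePlan-class] over the training pool.
#' @param baseline modality forced at complexity 1, or `NULL` for a free
#'   first pick.
#' @param config an [mmConfig()] list.
#' @return An `FFSTrace` list: `trace` (data.frame: resample, step,
#'   modality_added, cv_auroc, cv_logloss, alpha, lambda, test_auroc),
#'   `models` (per resample, per step coefficient vectors and modality sets),
#'   `modalities`.
#' @seealso [chooseComplexity()], [buildFinalModel()], [summarizeTrace()]
#' @export
ffsIntegrate <- function(panels, labels, plan, baseline = NULL,
                         config = mmConfig()) {
    empty <- vapply(panels, function(p) ncol(featureValues(p)) == 0,
                    logical(1))
    if (any(empty)) {
        warning("skipping zero-feature panel(s): ",
                paste(names(panels)[empty], collapse = ", "))
        panels <- panels[!empty]
    }
    mods <- sort(names(panels))
    pool <- Reduce(intersect, lapply(panels, sampleIDs))
    y_all <- normaliseLabels(labels, pool)
    names(y_all) <- pool
    if (!is.null(baseline) && !baseline %in% mods)
        stop("baseline modality not among panels: ", baseline)
    n_res <- length(plan@train)
    rows <- list()
    models <- vector("list", n_res)
    for (i in seq_len(n_res)) {
        tr <- intersect(plan@train[[i]], pool)
        te <- intersect(plan@test[[i]], pool)
        folds <- plan@folds[[i]][tr]
        current <- character()
        remaining <- mods
        models[[i]] <- list()
        for (k in seq_along(mods)) {
            cands <- if (k == 1L && !is.null(baseline)) baseline
                     else remaining
            logSampleUse("ffs", i, "tune_fit", tr)
            evals <- lapply(cands, function(m) {
                X <- bindPanels(panels, c(current, m), tr)
                tuneElasticNet(X, y_all[tr], folds,
                               grid_size = config$grid_size,
                               lambda_grid = config$lambda_grid)
            })
            cv_auc <- vapply(evals, `[[`, numeric(1), "cv_auroc")
            best <- which(cv_auc == max(cv_auc))[1]  # cands sorted: ties alphabetical
            m_add <- cands[best]
            tuned <- evals[[best]]
            current <- c(current, m_add)
            remaining <- setdiff(remaining, m_add)
            Xtr <- bindPanels(panels, current, tr)
            fit <- fitWeightedElasticNet(Xtr, y_all[tr], tuned$alpha,
                                         tuned$lambda)
            cal <- tryCatch(plattFit(tuned$oof, y_all[tr]),
                            error = function(e) NULL)
            Xte <- bindPanels(panels, current, te)
            logSampleUse("ffs", i, "predict", te)
            p_raw <- predictRisk(fit, Xte)
            p <- if (!is.null(cal)) plattApply(cal, p_raw) else p_raw
            logSampleUse("ffs", i, "auroc", te)
            a <- auroc(y_all[te], p)
            rows[[length(rows) + 1L]] <- data.frame(
                resample = i, step = k, modality_added = m_add,
                cv_auroc = tuned$cv_auroc, cv_logloss = tuned$cv_logloss,
                alpha = tuned$alpha, lambda = tuned$lambda, test_auroc = a,
                stringsAsFactors = FALSE)
            models[[i]][[k]] <- list(beta = fit$beta, a0 = fit$a0,
                                     modalities = current)
        }
    }
    out <- list(trace = do.call(rbind, rows), models = models,
                modalities = mods)
    class(out) <- "FFSTrace"
    out
}

#' @method print FFSTrace
#' @export
print.FFSTrace <- function(x, ...) {
    cat(sprintf("FFSTrace: %d resamples x %d complexities\n",
                max(x$trace$resample), max(x$trace$step)))
    print(summarizeTrace(x))
    invisible(x)
}

#' Summarise test AUROC per model complexity
#'
#' Median, interquartile range, and bootstrap 95% confidence interval of the
#' median test AUROC at each complexity of an FFS trace.
#'
#' @param trace an `FFSTrace` from [ffsIntegrate()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap.
#' @return data.frame (step, median_auroc, iqr_lo, iqr_hi, ci_lo, ci_hi).
#' @export
summarizeTrace <- function(trace, n_boot = 1000L, seed = 1L) {
    tr <- trace$trace
    withSeed(seed, {
        do.call(rbind, lapply(sort(unique(tr$step)), function(k) {
            a <- tr$test_auroc[tr$step == k]
            boot <- replicate(n_boot, stats::median(sample(a, replace = TRUE)))
            data.frame(step = k, median_auroc = stats::median(a),
                       iqr_lo = unname(stats::quantile(a, 0.25)),
                       iqr_hi = unname(stats::quantile(a, 0.75)),
                       ci_lo = unname(stats::quantile(boot, 0.025)),
                       ci_hi = unname(stats::quantile(boot, 0.975)))
        }))
    })
}

#' Concatenation integrator (comparator)
#'
#' Per resample, a single tuned class-weighted elastic net on the
#' column-concatenation of all panels; the test AUROC is recorded.
#'
#' @inheritParams ffsIntegrate
#' @return data.frame (resample, test_auroc, alpha, lambda).
#' @export
concatIntegrate <- function(panels, labels, plan, config = mmConfig()) {
    mods <- sort(names(panels))
    pool <- Reduce(intersect, lapply(panels, sampleIDs))
    y_all <- normaliseLabels(labels, pool)
    names(y_all) <- pool
    rows <- lapply(seq_along(plan@train), function(i) {
        tr <- intersect(plan@train[[i]], pool)
        te <- intersect(plan@test[[i]], pool)
        X <- bindPanels(panels, mods, tr)
        logSampleUse("concat", i, "tune_fit", tr)
        tuned <- tuneElasticNet(X, y_all[tr], plan@folds[[i]][tr],
                                grid_size = config$grid_size,
                                lambda_grid = config$lambda_grid)
        fit <- fitWeightedElasticNet(X, y_all[tr], tuned$alpha, tuned$lambda)
        cal <- tryCatch(plattFit(tuned$oof, y_all[tr]),
                        error = function(e) NULL)
        p <- predictRisk(fit, bindPanels(panels, mods, te))
        if (!is.null(cal)) p <- plattApply(cal, p)
        logSampleUse("concat", i, "auroc", te)
        data.frame(resample = i, test_auroc = auroc(y_all[te], p),
                   alpha = tuned$alpha, lambda = tuned$lambda)
    })
    do.call(rbind, rows)
}

#' Ensemble stacking integrator (comparator)
#'
#' Per resample: each modality's elastic net produces out-of-fold predictions
#' on the training split (no sample is predicted by a model trained on its
#' own fold); a meta elastic net is trained on the prediction matrix; base
#' models refit on the full training split feed the meta model at test time.
#' Modalities with constant out-of-fold predictions are excluded from the
#' meta design.
#'
#' @inheritParams ffsIntegrate
#' @return data.frame (resample, test_auroc, n_modalities_used) with the
#'   per-resample meta-model coefficient vectors in attribute `meta_beta`.
#' @export
stackingIntegrate <- function(panels, labels, plan, config = mmConfig()) {
    mods <- sort(names(panels))
    pool <- Reduce(intersect, lapply(panels, sampleIDs))
    y_all <- normaliseLabels(labels, pool)
    names(y_all) <- pool
    rows <- lapply(seq_along(plan@train), function(i) {
        tr <- intersect(plan@train[[i]], pool)
        te <- intersect(plan@test[[i]], pool)
        folds <- plan@folds[[i]][tr]
        oof <- list(); test_pred <- list()
        for (m in mods) {
            X <- bindPanels(panels, m, tr)
            logSampleUse("stacking", i, "tune_fit", tr)
            tuned <- tuneElasticNet(X, y_all[tr], folds,
                                    grid_size = config$grid_size,
                                    lambda_grid = config$lambda_grid)
            if (stats::sd(tuned$oof) == 0) {
                message("stacking: modality ", m,
                        " has constant predictions; excluded from meta design")
                next
            }
            oof[[m]] <- tuned$oof
            base <- fitWeightedElasticNet(X, y_all[tr], tuned$alpha,
                                          tuned$lambda)
            test_pred[[m]] <- predictRisk(base, bindPanels(panels, m, te))
        }
        if (!length(oof))
            return(data.frame(resample = i, test_auroc = NA_real_,
                              n_modalities_used = 0L))
        # standardise the prediction matrix so meta coefficients are
        # comparable across modalities with different probability spreads
        Z <- do.call(cbind, oof); rownames(Z) <- tr
        mu <- colMeans(Z); sd_ <- apply(Z, 2, stats::sd)
        Z <- sweep(sweep(Z, 2, mu, "-"), 2, sd_, "/")
        meta_tuned <- tuneElasticNet(Z, y_all[tr], folds,
                                     grid_size = config$grid_size,
                                     lambda_grid = config$lambda_grid)
        meta <- fitWeightedElasticNet(Z, y_all[tr], meta_tuned$alpha,
                                      meta_tuned$lambda)
        Zte <- do.call(cbind, test_pred); rownames(Zte) <- te
        Zte <- sweep(sweep(Zte, 2, mu, "-"), 2, sd_, "/")
        logSampleUse("stacking", i, "auroc", te)
        list(row = data.frame(
                 resample = i,
                 test_auroc = auroc(y_all[te], predictRisk(meta, Zte)),
                 n_modalities_used = length(oof)),
             meta_beta = meta$beta)
    })
    out <- do.call(rbind, lapply(rows, `[[`, "row"))
    attr(out, "meta_beta") <- lapply(rows, `[[`, "meta_beta")
    out
}

#' Univariate thresholding selector (comparator)
#'
#' Selects features with unadjusted moderated-t p-values below `p_cut`
#' (default 0.05), the conventional fixed-threshold alternative to
#' enrichment-based selection.
#'
#' @param matrix a [FeatureMatrix-class].
#' @param labels phenotype data.frame or named 0/1 vector.
#' @param p_cut significance cutoff (default 0.05).
#' @return Character vector of selected feature ids.
#' @export
thresholdSelect <- function(matrix, labels, p_cut = 0.05) {
    assoc <- moderatedTAssociation(matrix, labels)
    assoc$feature_id[assoc$p_value < p_cut]
}

#' Choose the model complexity from a test-AUROC trace
#'
#' Returns the largest complexity k whose test-AUROC distribution improves
#' significantly on complexity k-1 (one-sided Wilcoxon rank-sum, p < alpha)
#' with no significant improvement at any later step; 1 if no step improves.
#'
#' @param trace an `FFSTrace` or its `trace` data.frame (columns `step`,
#'   `test_auroc`).
#' @param alpha significance level (default 0.05).
#' @return Integer complexity `k*`.
#' @export
chooseComplexity <- function(trace, alpha = 0.05) {
    tr <- if (inherits(trace, "FFSTrace")) trace$trace else trace
    ks <- sort(unique(tr$step))
    if (length(ks) < 2L) {
        warning("fewer than 2 complexities; returning 1")
        return(1L)
    }
    if (sum(tr$step == ks[1]) < 10L)
        warning("fewer than 10 resamples; complexity choice is unstable")
    sig <- vapply(ks[-1], function(k) {
        a1 <- tr$test_auroc[tr$step == k]
        a0 <- tr$test_auroc[tr$step == k - 1L]
        suppressWarnings(
            stats::wilcox.test(a1, a0, alternative = "greater")$p.value) < alpha
    }, logical(1))
    if (!any(sig)) return(1L)
    as.integer(ks[-1][max(which(sig))])
}

#' Final consensus model at the chosen complexity
#'
#' Aggregates per-resample feature importances (|coefficient|;
#' zero-coefficient features contribute no rank) of the models at complexity
#' `k_star` by robust rank aggregation at `rra_fdr`, then trains a final
#' tuned class-weighted elastic net on all training samples restricted to the
#' consensus features. Reported importance is the Wald t/z statistic of an
#' unpenalised weighted logistic refit (or the coefficient, per
#' `config$importance_mode`).
#'
#' @param trace an `FFSTrace` from [ffsIntegrate()].
#' @param panels the panels the trace was built from.
#' @param labels phenotype data.frame or named 0/1 vector.
#' @param k_star chosen complexity (see [chooseComplexity()]).
#' @param config an [mmConfig()] list.
#' @return A `FinalModelReport` list: `k_star`, `combinations` (frequency
#'   table of modality sets at `k_star`), `consensus` (data.frame:
#'   feature_id, modality, importance), `model` (`ElasticNetModel`),
#'   `alpha`, `lambda`.
#' @export
buildFinalModel <- function(trace, panels, labels, k_star,
                            config = mmConfig()) {
    stopifnot(inherits(trace, "FFSTrace"))
    pool <- Reduce(intersect, lapply(panels, sampleIDs))
    y_all <- normaliseLabels(labels, pool)
    names(y_all) <- pool
    rankings <- list()
    combos <- character()
    for (i in seq_along(trace$models)) {
        mk <- trace$models[[i]][[k_star]]
        if (is.null(mk)) next
        combos <- c(combos, paste(sort(mk$modalities), collapse = "+"))
        b <- mk$beta[mk$beta != 0]
        if (length(b))
            rankings[[length(rankings) + 1L]] <- names(sort(-abs(b)))
    }
    if (!length(rankings))
        stop("no non-empty models at complexity ", k_star)
    n_feat_total <- sum(vapply(panels, function(p)
        length(featureIDs(p)), integer(1)))
    rra <- aggregateRanks(rankings, universe_size = n_feat_total)
    cons <- rra$item_id[rra$bh_adjusted_p < config$rra_fdr]
    if (!length(cons))
        stop("empty consensus at FDR ", config$rra_fdr,
             "; consider a higher rra_fdr or more resamples")
    # map consensus features to modalities and assemble the design
    feat_mod <- unlist(lapply(names(panels), function(m)
        stats::setNames(rep(m, length(featureIDs(panels[[m]]))),
                        featureIDs(panels[[m]]))))
    X <- bindPanels(panels, sort(names(panels)), pool)
    cons <- intersect(cons, colnames(X))
    X <- X[, cons, drop = FALSE]
    folds <- stratifiedFolds(y_all, config$n_folds,
                             deriveSeed(config$master_seed, "final_folds"))
    tuned <- tuneElasticNet(X, y_all, folds, grid_size = config$grid_size,
                            lambda_grid = config$lambda_grid)
    fit <- fitWeightedElasticNet(X, y_all, tuned$alpha, tuned$lambda)
    imp <- featureImportance(fit, X, y_all, mode = config$importance_mode)
    report <- list(
        k_star = k_star,
        combinations = sort(table(combos), decreasing = TRUE),
        consensus = data.frame(feature_id = cons,
                               modality = unname(feat_mod[cons]),
                               importance = unname(imp[cons]),
                               stringsAsFactors = FALSE),
        model = fit, alpha = tuned$alpha, lambda = tuned$lambda)
    class(report) <- "FinalModelReport"
    report
}

#' @method print FinalModelReport
#' @export
print.FinalModelReport <- function(x, ...) {
    cat(sprintf("FinalModelReport: k* = %d, %d consensus feature(s)\n",
                x$k_star, nrow(x$consensus)))
    top <- x$consensus[order(-abs(x$consensus$importance)), ]
    print(utils::head(top, 10), row.names = FALSE)
    invisible(x)
}
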