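# Univariate association and gene-level aggregation producing ranked lists
# for enrichment.

# Newton inversion of the trigamma function (for the moment estimator of the
# prior degrees of freedom).
trigammaInv <- function(y) {
    if (y > 1e7) return(1 / sqrt(y))
    if (y < 1e-6) return(1 / y)
    x <- 0.5 + 1 / y
    for (i in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
        x <- x + dif
        if (abs(dif) / x < 1e-8) break
    }
    x
}

#' Empirical-Bayes moderated two-group association
#'
#' For every feature, fits the two-group linear model `value ~ label` and
#' computes a moderated t-statistic: per-feature residual variances are
#' shrunk toward a pooled prior variance whose scale and degrees of freedom
#' are estimated from all features by the method of moments (matching the
#' log-variance mean and spread against their theoretical scaled-chi-square
#' moments). P-values use the augmented degrees of freedom. With
#' `prior_df = 0` the statistic reduces exactly to the ordinary pooled-variance
#' two-sample t.
#'
#' Features observed in fewer than two samples of either class are dropped
#' with a warning. Perfectly separating features (zero residual variance after
#' moderation) are capped at the largest representable statistic.
#'
#' @param matrix a [FeatureMatrix-class] (missing values allowed per feature).
#' @param labels binary 0/1 vector named by sample id, or a phenotype
#'   data.frame with columns `sample_id` and `label`.
#' @param prior_df optional fixed prior degrees of freedom; `NULL` (default)
#'   estimates it from the data, `0` yields the unmoderated t.
#' @return data.frame (`feature_id`, `t_statistic`, `p_value`, `direction`)
#'   with one row per tested feature.
#' @export
moderatedTAssociation <- function(matrix, labels, prior_df = NULL) {
    v <- featureValues(matrix)
    y <- normaliseLabels(labels, rownames(v))
    if (sum(y == 1) < 2 || sum(y == 0) < 2)
        stop("each class needs at least 2 samples")
    obs <- !is.na(v)
    case <- y == 1
    n1 <- colSums(obs & case); n0 <- colSums(obs & !case)
    keep <- n1 >= 2 & n0 >= 2
    if (!all(keep)) {
        warning("dropping ", sum(!keep),
                " feature(s) with fewer than 2 observations in a class")
        v <- v[, keep, drop = FALSE]; obs <- obs[, keep, drop = FALSE]
        n1 <- n1[keep]; n0 <- n0[keep]
    }
    v0 <- v; v0[!obs] <- 0
    s1 <- colSums(v0[case, , drop = FALSE]); s0c <- colSums(v0[!case, , drop = FALSE])
    m1 <- s1 / n1; m0 <- s0c / n0
    ss1 <- colSums(v0[case, , drop = FALSE]^2) - n1 * m1^2
    ss0 <- colSums(v0[!case, , drop = FALSE]^2) - n0 * m0^2
    df <- n1 + n0 - 2
    s2 <- pmax((ss1 + ss0) / df, 0)

    if (is.null(prior_df)) {
        pos <- s2 > 0
        if (sum(pos) >= 2) {
            z <- log(s2[pos])
            e <- z - digamma(df[pos] / 2) + log(df[pos] / 2)
            evar <- stats::var(e) - mean(trigamma(df[pos] / 2))
            if (is.finite(evar) && evar > 0) {
                d0 <- 2 * trigammaInv(evar)
                s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
            } else {
                d0 <- Inf
                s02 <- exp(mean(e))
            }
        } else { d0 <- 0; s02 <- 0 }
    } else {
        d0 <- prior_df
        s02 <- if (d0 > 0) mean(s2[s2 > 0]) else 0
    }
    stilde2 <- if (is.infinite(d0)) rep(s02, length(s2))
               else if (d0 > 0) (d0 * s02 + df * s2) / (d0 + df)
               else s2
    se <- sqrt(stilde2 * (1 / n1 + 1 / n0))
    diff <- m1 - m0
    t <- diff / se
    df_tot <- if (is.infinite(d0)) rep(Inf, length(df)) else df + d0
    p <- 2 * stats::pt(-abs(t), df = df_tot)
    # perfect separation: capped statistic, minimum representable p
    inf <- !is.finite(t)
    if (any(inf)) {
        t[inf] <- sign(diff[inf]) * sqrt(.Machine$double.xmax)
        p[inf] <- .Machine$double.xmin
    }
    p <- pmax(p, .Machine$double.xmin)
    data.frame(feature_id = colnames(v), t_statistic = t, p_value = p,
               direction = sign(t), row.names = NULL,
               stringsAsFactors = FALSE)
}

normaliseLabels <- function(labels, sample_ids) {
    if (is.data.frame(labels)) {
        y <- labels$label
        names(y) <- labels$sample_id
    } else y <- labels
    if (!is.null(names(y))) {
        missing <- setdiff(sample_ids, names(y))
        if (length(missing))
            stop("no label for sample(s): ",
                 paste(utils::head(missing, 5), collapse = ", "))
        y <- y[sample_ids]
    } else if (length(y) != length(sample_ids))
        stop("labels must be named or match the number of samples")
    if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
    as.integer(y)
}

#' Gene-level association scores from SNP dosages
#'
#' For each gene, runs a principal component analysis of its annotated SNP
#' dosages, retains components explaining at least `pc_var_fraction`
#' cumulative variance (capped at `min(n_snps, n_samples / 10)`), regresses
#' the binary label on the retained components by least squares and converts
#' the overall F-test p-value to a one-sided z-score, `z = qnorm(1 - p)`
#' (large z = stronger association). Genes whose SNPs are all constant are
#' omitted with a warning. Missing dosages are mean-imputed within SNP for
#' the decomposition.
#'
#' @param genotypes QC'd dosage [FeatureMatrix-class].
#' @param annotation data.frame map (`feature_id`, `gene_id`).
#' @param labels binary labels (see [moderatedTAssociation()]).
#' @param pc_var_fraction cumulative variance to retain (default 0.999).
#' @return data.frame (`gene_id`, `z_value`, `p_value`, `n_units`).
#' @export
snpGeneZscores <- function(genotypes, annotation, labels,
                           pc_var_fraction = 0.999) {
    v <- featureValues(genotypes)
    y <- normaliseLabels(labels, rownames(v))
    ann <- annotation[annotation$feature_id %in% colnames(v), , drop = FALSE]
    genes <- split(ann$feature_id, ann$gene_id)
    out <- vector("list", length(genes))
    skipped <- character()
    for (i in seq_along(genes)) {
        snps <- genes[[i]]
        x <- v[, snps, drop = FALSE]
        for (j in seq_len(ncol(x))) {     # mean-impute within SNP
            m <- is.na(x[, j])
            if (any(m)) x[m, j] <- mean(x[, j], na.rm = TRUE)
        }
        sds <- apply(x, 2, stats::sd)
        x <- x[, sds > 0, drop = FALSE]
        if (!ncol(x)) { skipped <- c(skipped, names(genes)[i]); next }
        pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
        cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
        npc <- min(which(cum >= pc_var_fraction))
        npc <- max(1L, min(npc, ncol(x), floor(nrow(x) / 10)))
        fit <- stats::lm(y ~ pc$x[, seq_len(npc), drop = FALSE])
        fs <- summary(fit)$fstatistic
        p <- if (is.null(fs)) 1
             else stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
        z <- stats::qnorm(min(max(p, 1e-300), 1 - 1e-16), lower.tail = FALSE)
        out[[i]] <- data.frame(gene_id = names(genes)[i], z_value = z,
                               p_value = p, n_units = length(snps),
                               stringsAsFactors = FALSE)
    }
    if (length(skipped))
        warning("omitting gene(s) with all-constant SNPs: ",
                paste(skipped, collapse = ", "))
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(res) <- NULL
    res
}

#' Competitive gene-set test on gene z-scores
#'
#' Regresses gene z-scores on a set-membership indicator plus covariates
#' (default: log of the number of aggregated units per gene) and reports the
#' one-sided p-value for a positive membership coefficient, BH-adjusted
#' across sets. Sets with fewer than two members present are skipped with a
#' warning; absent members are ignored.
#'
#' @param genes data.frame from [snpGeneZscores()] or [cpgGeneScores()].
#' @param sets a [GeneSetList-class].
#' @param covariates optional data.frame of per-gene covariates (rows matched
#'   by `gene_id`); default uses `log(n_units)`.
#' @return data.frame (`set_id`, `beta`, `p_value`, `adjusted_p`, `size`).
#' @export
magmaGeneSetTest <- function(genes, sets, covariates = NULL) {
    z <- genes$z_value
    if (is.null(covariates))
        covariates <- data.frame(log_units = log(genes$n_units))
    rows <- list()
    for (sid in setIDs(sets)) {
        member <- genes$gene_id %in% sets[[sid]]
        if (sum(member) < 2L) {
            warning("skipping set ", sid, ": fewer than 2 members present")
            next
        }
        df <- data.frame(z = z, member = as.numeric(member), covariates)
        fit <- stats::lm(z ~ ., data = df)
        co <- summary(fit)$coefficients
        if (!"member" %in% rownames(co)) next
        tstat <- co["member", "t value"]
        p <- stats::pt(tstat, df = fit$df.residual, lower.tail = FALSE)
        rows[[sid]] <- data.frame(set_id = sid, beta = co["member", "Estimate"],
                                  p_value = p, size = sum(member),
                                  stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(set_id = character(), beta = numeric(),
                          p_value = numeric(), adjusted_p = numeric(),
                          size = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, rows)
    res$adjusted_p <- adjustBH(res$p_value)
    rownames(res) <- NULL
    res[c("set_id", "beta", "p_value", "adjusted_p", "size")]
}

#' Gene scores from CpG associations via rank aggregation
#'
#' Ranks all CpGs by association p-value (ties by |t| descending then id),
#' normalises ranks to (0, 1], and scores each gene by the beta order-statistic
#' bound of its CpGs' ranks ([betaScore()]), corrected by the number of CpGs.
#' The gene p-value is converted to a z-score, `qnorm(1 - p/2)`, signed by the
#' mean t-statistic of the gene's CpGs so that enrichment sees direction.
#'
#' @param cpg_assoc data.frame from [moderatedTAssociation()] on CpG probes.
#' @param annotation data.frame map (`feature_id`, `gene_id`).
#' @return data.frame (`gene_id`, `z_value`, `p_value`, `n_units`).
#' @export
cpgGeneScores <- function(cpg_assoc, annotation) {
    ord <- order(cpg_assoc$p_value, -abs(cpg_assoc$t_statistic),
                 cpg_assoc$feature_id)
    ranked <- cpg_assoc$feature_id[ord]
    nr <- stats::setNames(seq_along(ranked) / length(ranked), ranked)
    tstat <- stats::setNames(cpg_assoc$t_statistic, cpg_assoc$feature_id)
    ann <- annotation[annotation$feature_id %in% ranked, , drop = FALSE]
    genes <- split(ann$feature_id, ann$gene_id)
    rows <- lapply(names(genes), function(g) {
        cpgs <- genes[[g]]
        r <- sort(nr[cpgs])
        rho <- betaScore(r)
        p <- min(1, rho * length(r))
        z <- stats::qnorm(min(max(p, 1e-300), 1) / 2, lower.tail = FALSE)
        data.frame(gene_id = g, z_value = sign(mean(tstat[cpgs])) * z,
                   p_value = p, n_units = length(cpgs),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}
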