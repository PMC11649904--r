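#' Derive prevalent and incident case labels from MNSI-style scores
#'
#' A sample is a prevalent case when its baseline score reaches the threshold
#' (default 3). Incidence is defined only for baseline controls: incident case
#' when the follow-up score reaches the threshold, control when it does not,
#' and excluded (`NA`) when the follow-up score is missing. Samples with a
#' missing baseline score are excluded from both tasks.
#'
#' @param mnsi_baseline,mnsi_followup numeric scores in `[0, 10]` (NA allowed).
#' @param threshold case-defining score (default 3).
#' @return data.frame with columns `prevalent` and `incident` (0/1/NA).
#' @examples
#' assignLabels(c(3, 2, 2), c(NA, 3, NA))
#' @export
assignLabels <- function(mnsi_baseline, mnsi_followup = NULL, threshold = 3) {
    if (is.null(mnsi_followup))
        mnsi_followup <- rep(NA_real_, length(mnsi_baseline))
    if (length(mnsi_followup) != length(mnsi_baseline))
        stop("baseline and follow-up scores must have equal length")
    ok <- !is.na(mnsi_baseline)
    if (any(mnsi_baseline[ok] < 0 | mnsi_baseline[ok] > 10) ||
        any(mnsi_followup[!is.na(mnsi_followup)] < 0 |
            mnsi_followup[!is.na(mnsi_followup)] > 10))
        stop("MNSI scores must lie in [0, 10]")
    prevalent <- ifelse(is.na(mnsi_baseline), NA_integer_,
                        as.integer(mnsi_baseline >= threshold))
    incident <- ifelse(is.na(mnsi_baseline) | mnsi_baseline >= threshold,
                       NA_integer_,
                       ifelse(is.na(mnsi_followup), NA_integer_,
                              as.integer(mnsi_followup >= threshold)))
    data.frame(prevalent = prevalent, incident = incident)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg proportions at the observed allele frequency.
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference hom, het, alternate hom).
#' @return p-value.
#' @examples
#' hweTest(25, 50, 25)   # exact HWE: p = 1
#' hweTest(50, 0, 50)    # extreme heterozygote deficit
#' @export
hweTest <- function(n_AA, n_Aa, n_aa) {
    if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative")
    n <- n_AA + n_Aa + n_aa
    if (n == 0) stop("no observations")
    p <- (2 * n_aa + n_Aa) / (2 * n)   # alternate allele frequency
    if (p == 0 || p == 1) return(1)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Applies the SNP-level filters in a fixed, audited order -- missing rate
#' `>= snp_missing_max`, minor allele frequency `< maf_min`, Hardy-Weinberg
#' p `< hwe_p_min` -- then removes samples whose heterozygosity rate (fraction
#' of dosage-1 calls among non-missing calls) deviates more than `het_sd`
#' standard deviations from the cohort mean. Every removal appears exactly
#' once in the report with one primary reason.
#'
#' @param genotypes [FeatureMatrix-class] of allele dosages in {0, 1, 2},
#'   missing allowed.
#' @param config an [mmConfig()] list supplying the thresholds.
#' @return list with `matrix` (filtered FeatureMatrix), `report` (data.frame:
#'   item, type, reason, value) and `stats` (per-SNP missing rate, MAF, HWE p).
#' @export
snpQC <- function(genotypes, config = mmConfig()) {
    v <- featureValues(genotypes)
    bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
    if (length(bad)) {
        i <- ((bad[1] - 1L) %% nrow(v)) + 1L
        j <- ((bad[1] - 1L) %/% nrow(v)) + 1L
        stop(sprintf("non-dosage value %g for SNP %s in sample %s",
                     v[bad[1]], colnames(v)[j], rownames(v)[i]))
    }
    nobs <- colSums(!is.na(v))
    miss_rate <- 1 - nobs / nrow(v)
    alt_freq <- colSums(v, na.rm = TRUE) / (2 * nobs)
    maf <- pmin(alt_freq, 1 - alt_freq)
    hwe_p <- vapply(seq_len(ncol(v)), function(j) {
        g <- v[, j]
        hweTest(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
    }, numeric(1))
    stats_df <- data.frame(feature_id = colnames(v), missing_rate = miss_rate,
                           maf = maf, hwe_p = hwe_p, row.names = NULL,
                           stringsAsFactors = FALSE)

    report <- list()
    drop <- rep(FALSE, ncol(v))
    note <- function(items, type, reason, values) {
        if (!length(items)) return()
        report[[length(report) + 1L]] <<-
            data.frame(item = items, type = type, reason = reason,
                       value = values, stringsAsFactors = FALSE)
    }
    sel <- !drop & miss_rate >= config$snp_missing_max
    note(colnames(v)[sel], "snp", "missing_rate", miss_rate[sel]); drop <- drop | sel
    sel <- !drop & maf < config$maf_min
    note(colnames(v)[sel], "snp", "maf", maf[sel]); drop <- drop | sel
    sel <- !drop & hwe_p < config$hwe_p_min
    note(colnames(v)[sel], "snp", "hwe", hwe_p[sel]); drop <- drop | sel

    v2 <- v[, !drop, drop = FALSE]
    het <- rowSums(v2 == 1, na.rm = TRUE) / rowSums(!is.na(v2))
    z <- if (stats::sd(het) > 0) (het - mean(het)) / stats::sd(het) else het * 0
    bad_s <- abs(z) > config$het_sd
    note(rownames(v2)[bad_s], "sample", "heterozygosity", z[bad_s])
    v2 <- v2[!bad_s, , drop = FALSE]

    rep_df <- if (length(report)) do.call(rbind, report)
              else data.frame(item = character(), type = character(),
                              reason = character(), value = numeric(),
                              stringsAsFactors = FALSE)
    list(matrix = FeatureMatrix(v2, modality(genotypes)),
         report = rep_df, stats = stats_df)
}

#' Annotate SNPs (or CpGs) to genes by strand-aware windows
#'
#' A SNP maps to every gene whose extended window contains it: for `+` strand
#' genes the window is `[start - upstream, end + downstream]`, mirrored for
#' `-` strand. Coordinates are 1-based inclusive. SNPs on chromosomes absent
#' from the gene table are left unmapped with a warning.
#'
#' @param snp_positions data.frame with columns `feature_id`, `chrom`, `pos`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param window_upstream,window_downstream window sizes in bp (defaults
#'   2000 and 500).
#' @return data.frame map with columns `feature_id`, `gene_id`; unmapped
#'   features are absent.
#' @export
annotateSnpsToGenes <- function(snp_positions, genes,
                                window_upstream = 2000,
                                window_downstream = 500) {
    if (window_upstream < 0 || window_downstream < 0)
        stop("windows must be non-negative")
    if (any(genes$start > genes$end)) stop("gene start must be <= end")
    unknown <- setdiff(unique(snp_positions$chrom), unique(genes$chrom))
    if (length(unknown))
        warning("SNPs on chromosome(s) ", paste(unknown, collapse = ", "),
                " have no annotated genes and remain unmapped")
    plus <- genes$strand == "+"
    ws <- ifelse(plus, genes$start - window_upstream,
                 genes$start - window_downstream)
    we <- ifelse(plus, genes$end + window_downstream,
                 genes$end + window_upstream)
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(1, ws), we))
    sr <- GenomicRanges::GRanges(snp_positions$chrom,
                                 IRanges::IRanges(snp_positions$pos,
                                                  snp_positions$pos))
    hits <- GenomicRanges::findOverlaps(sr, gr)
    data.frame(
        feature_id = snp_positions$feature_id[S4Vectors::queryHits(hits)],
        gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE)
}

#' k-nearest-neighbour imputation
#'
#' Replaces each missing cell by the mean of that feature over the `k`
#' nearest samples, with Euclidean distance computed on features observed in
#' both samples and scaled by the number of shared features. Observed cells
#' are never altered.
#'
#' @param matrix a [FeatureMatrix-class] (or plain matrix).
#' @param k number of neighbours (default 10).
#' @return Imputed [FeatureMatrix-class] with no missing cells.
#' @export
knnImpute <- function(matrix, k = 10L) {
    fm <- if (is(matrix, "FeatureMatrix")) matrix
          else FeatureMatrix(matrix, "unknown")
    v <- featureValues(fm)
    if (!anyNA(v)) return(fm)
    if (k < 1) stop("k must be >= 1")
    all_missing <- colSums(!is.na(v)) == 0L
    if (any(all_missing))
        stop("feature(s) missing in all samples: ",
             paste(colnames(v)[all_missing], collapse = ", "))
    if (any(rowSums(!is.na(v)) == 0L))
        stop("sample(s) with no observed values cannot be imputed")
    obs <- !is.na(v)
    v0 <- v; v0[!obs] <- 0
    # pairwise mean squared difference over shared observed features
    shared <- obs %*% t(obs)
    cross <- v0 %*% t(v0)
    sq <- (v0^2 %*% t(obs)) + (obs %*% t(v0^2)) - 2 * cross
    d2 <- sq / pmax(shared, 1)
    d2[shared == 0] <- Inf
    diag(d2) <- Inf
    out <- v
    for (i in seq_len(nrow(v))) {
        mis <- which(!obs[i, ])
        if (!length(mis)) next
        ord <- order(d2[i, ])
        for (j in mis) {
            donors <- ord[obs[ord, j]]
            donors <- donors[is.finite(d2[i, donors])]
            if (!length(donors))
                stop("no donor samples available for feature ",
                     colnames(v)[j])
            use <- donors[seq_len(min(k, length(donors)))]
            out[i, j] <- mean(v[use, j])
        }
    }
    FeatureMatrix(out, modality(fm))
}

#' Drop features exceeding a missingness bound
#'
#' Removes features whose fraction of missing values strictly exceeds
#' `max_fraction` (e.g. 0.70 for metabolites, 0.10 for clinical variables).
#'
#' @param matrix a [FeatureMatrix-class].
#' @param max_fraction missingness bound in `[0, 1]`.
#' @return Filtered [FeatureMatrix-class].
#' @export
dropHighMissingness <- function(matrix, max_fraction) {
    if (max_fraction < 0 || max_fraction > 1)
        stop("max_fraction must be in [0,1]")
    v <- featureValues(matrix)
    frac <- colMeans(is.na(v))
    keep <- frac <= max_fraction
    if (!any(keep))
        message("dropHighMissingness: no features retained")
    FeatureMatrix(v[, keep, drop = FALSE], modality(matrix))
}

#' Multivariate outlier removal by standardised Mahalanobis distance
#'
#' Removes samples whose Mahalanobis distance, divided by the square root of
#' the dimension used, exceeds `cutoff` (default 4). When the feature count
#' reaches half the sample count the distance is computed on the leading
#' principal components capturing 95% of variance; a singular covariance is
#' ridge-regularised with a message.
#'
#' @param matrix complete (imputed) [FeatureMatrix-class].
#' @param cutoff standardised distance cutoff (default 4).
#' @return list with `matrix` (filtered) and `removed` (sample ids).
#' @export
mahalanobisFilter <- function(matrix, cutoff = 4) {
    v <- featureValues(matrix)
    if (anyNA(v)) stop("matrix must be complete (impute first)")
    x <- v
    if (ncol(x) >= nrow(x) / 2) {
        pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
        cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
        keep <- max(1L, min(which(cum >= 0.95)))
        keep <- min(keep, nrow(x) - 2L)
        x <- pc$x[, seq_len(keep), drop = FALSE]
    }
    S <- stats::cov(x)
    d2 <- tryCatch(stats::mahalanobis(x, colMeans(x), S),
                   error = function(e) {
                       message("mahalanobisFilter: singular covariance, ",
                               "applying ridge regularisation")
                       S <- S + diag(1e-6 * mean(diag(S)), ncol(S))
                       stats::mahalanobis(x, colMeans(x), S)
                   })
    std <- sqrt(d2) / sqrt(ncol(x))
    removed <- rownames(v)[std > cutoff]
    list(matrix = matrix[setdiff(rownames(v), removed), ], removed = removed)
}

#' Z-score standardisation per feature
#'
#' Centres and scales every feature to mean 0 and sample SD 1 over its
#' observed entries; missing values are preserved. Constant features are
#' dropped with a warning (their SD is undefined).
#'
#' @param matrix a [FeatureMatrix-class].
#' @return Standardised [FeatureMatrix-class].
#' @export
zscoreStandardize <- function(matrix) {
    v <- featureValues(matrix)
    mu <- colMeans(v, na.rm = TRUE)
    sd_ <- apply(v, 2, stats::sd, na.rm = TRUE)
    const <- is.na(sd_) | sd_ == 0
    if (any(const)) {
        warning("dropping constant feature(s): ",
                paste(colnames(v)[const], collapse = ", "))
        v <- v[, !const, drop = FALSE]
        mu <- mu[!const]; sd_ <- sd_[!const]
    }
    FeatureMatrix(sweep(sweep(v, 2, mu, "-"), 2, sd_, "/"), modality(matrix))
}

#' One-hot encode a mixed clinical table
#'
#' Categorical (factor/character) columns with L levels become L binary
#' indicator columns named `variable.level`; numeric columns pass through
#' unchanged. Single-level categoricals are dropped with a warning.
#'
#' @param clinical data.frame with sample ids as row names.
#' @return A [FeatureMatrix-class] tagged `clinical`.
#' @export
oneHotEncode <- function(clinical) {
    stopifnot(is.data.frame(clinical))
    cols <- list()
    for (nm in names(clinical)) {
        x <- clinical[[nm]]
        if (is.numeric(x)) {
            cols[[nm]] <- x
        } else {
            f <- factor(x)
            if (nlevels(f) < 2L) {
                warning("dropping single-level categorical: ", nm)
                next
            }
            for (lv in levels(f))
                cols[[paste0(nm, ".", lv)]] <- as.numeric(f == lv)
        }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- rownames(clinical)
    FeatureMatrix(m, "clinical")
}

#' Residualise features on technical covariates
#'
#' Replaces every feature by the residuals of an ordinary least-squares fit
#' on the covariates (intercept included), removing e.g. plate, RNA-quality
#' or storage-time effects before association testing.
#'
#' @param matrix a [FeatureMatrix-class] (complete for the fitted samples).
#' @param covariates data.frame or matrix of covariates, rows matching the
#'   matrix samples.
#' @return Residualised [FeatureMatrix-class].
#' @export
regressOutCovariates <- function(matrix, covariates) {
    v <- featureValues(matrix)
    cv <- as.data.frame(covariates)
    if (nrow(cv) != nrow(v)) {
        if (!is.null(rownames(cv)) && all(rownames(v) %in% rownames(cv)))
            cv <- cv[rownames(v), , drop = FALSE]
        else stop("covariates must cover all samples in the matrix")
    }
    if (anyNA(cv)) stop("covariates must be complete for all samples")
    X <- stats::model.matrix(~ ., data = cv)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("rank-deficient covariate design; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    res <- qr.resid(qrX, v)
    dimnames(res) <- dimnames(v)
    FeatureMatrix(res, modality(matrix))
}
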