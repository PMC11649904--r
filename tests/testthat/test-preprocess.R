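test_that("MNSI labelling follows the threshold-and-followup rules", {
    lab <- assignLabels(c(3, 2, 2, NA, 5), c(NA, 3, NA, 4, 1), threshold = 3)
    expect_equal(lab$prevalent, c(1L, 0L, 0L, NA, 1L))
    # incident defined only for baseline controls; missing follow-up excluded
    expect_equal(lab$incident, c(NA, 1L, NA, NA, NA))
    expect_error(assignLabels(11, 2), "\\[0, 10\\]")
    # boundary: exactly at threshold is a case
    expect_equal(assignLabels(3)$prevalent, 1L)
    expect_equal(assignLabels(2, 3)$incident, 1L)
})

test_that("HWE chi-square matches hand-computed and convention cases", {
    expect_equal(hweTest(25, 50, 25), 1)          # exact HWE proportions
    expect_lt(hweTest(50, 0, 50), 1e-10)          # chi2 = 100 at expected 25/50/25
    expect_equal(hweTest(10, 0, 0), 1)            # monomorphic convention
    expect_error(hweTest(-1, 0, 1), "non-negative")
    expect_error(hweTest(0, 0, 0), "no observations")
})

test_that("HWE chi-square agrees with an exact multinomial enumeration", {
    # oracle: exact P(chi2 >= observed) enumerating all genotype splits of n
    # under multinomial HWE at the observed allele frequency; each enumerated
    # triple re-estimates its own frequency, as the test statistic does
    exactHwe <- function(nAA, nAa, naa) {
        n <- nAA + nAa + naa
        p <- (2 * naa + nAa) / (2 * n)
        probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
        chi2 <- function(a, h, b) {
            pt <- (2 * b + h) / (2 * n)
            if (pt == 0 || pt == 1) return(0)
            e <- n * c((1 - pt)^2, 2 * pt * (1 - pt), pt^2)
            sum((c(a, h, b) - e)^2 / e)
        }
        obs <- chi2(nAA, nAa, naa)
        tot <- 0
        for (a in 0:n) for (h in 0:(n - a)) {
            b <- n - a - h
            if (chi2(a, h, b) >= obs - 1e-12)
                tot <- tot + stats::dmultinom(c(a, h, b), prob = probs)
        }
        tot
    }
    set.seed(42)
    for (rep in 1:12) {
        n <- 100
        p <- runif(1, 0.15, 0.5)
        g <- table(factor(rbinom(n, 2, p), levels = 0:2))
        approx <- hweTest(g[1], g[2], g[3])
        exact <- exactHwe(g[1], g[2], g[3])
        expect_lt(abs(approx - exact), 0.06)  # chi-square approximation error
    }
})

test_that("genotype QC applies the documented filters in order", {
    set.seed(7)
    n <- 100
    g <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
                dimnames = list(sprintf("S%03d", 1:n), paste0("snp", 1:5)))
    g[1:2, 1] <- NA                         # 2% missing -> removed
    g[, 2] <- 0; g[1, 2] <- 1               # MAF 0.005 -> removed
    g[, 3] <- rep(c(0, 2), each = n / 2)    # het deficit -> HWE removed
    qc <- snpQC(FeatureMatrix(g, "genomic"), mmConfig())
    expect_false("snp1" %in% featureIDs(qc$matrix))
    expect_false("snp2" %in% featureIDs(qc$matrix))
    expect_false("snp3" %in% featureIDs(qc$matrix))
    expect_setequal(qc$report$reason[qc$report$item == "snp1"], "missing_rate")
    expect_setequal(qc$report$reason[qc$report$item == "snp2"], "maf")
    expect_setequal(qc$report$reason[qc$report$item == "snp3"], "hwe")
    # each removal appears exactly once
    expect_equal(anyDuplicated(qc$report$item), 0L)

    clean <- matrix(rbinom(n * 4, 2, 0.4), n, 4,
                    dimnames = list(rownames(g), paste0("c", 1:4)))
    qc2 <- snpQC(FeatureMatrix(clean, "genomic"), mmConfig())
    expect_equal(featureValues(qc2$matrix), clean + 0)

    bad <- clean; bad[3, 2] <- 3
    expect_error(snpQC(FeatureMatrix(bad, "genomic")), "c2.*S003")
})

test_that("SNP-to-gene windows are strand-aware and boundary-exact", {
    genes <- data.frame(gene_id = c("g+", "g-"), chrom = "chr1",
                        start = c(10000, 50000), end = c(12000, 52000),
                        strand = c("+", "-"), stringsAsFactors = FALSE)
    snps <- data.frame(
        feature_id = c("in_body", "up_ok", "down_edge", "down_out",
                       "minus_up_ok", "far", "nochrom"),
        chrom = c(rep("chr1", 6), "chr9"),
        pos = c(11000,            # inside body
                10000 - 1000,     # within 2 kb upstream
                12000 + 500,      # exactly at downstream edge (inclusive)
                12000 + 501,      # one past the window
                52000 + 1000,     # - strand: upstream is to the right
                30000, 100),
        stringsAsFactors = FALSE)
    expect_warning(
        map <- annotateSnpsToGenes(snps, genes, 2000, 500),
        "chr9")
    hits <- split(map$gene_id, map$feature_id)
    expect_equal(hits$in_body, "g+")
    expect_equal(hits$up_ok, "g+")
    expect_equal(hits$down_edge, "g+")
    expect_false("down_out" %in% names(hits))
    expect_equal(hits$minus_up_ok, "g-")
    expect_false("far" %in% names(hits))
})

test_that("kNN imputation matches a brute-force neighbour oracle", {
    # duplicate rows: k = 1 copies the duplicate's value
    m <- matrix(c(1, 2, 3,
                  1, 2, 3,
                  9, 9, 9), 3, 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
    m[1, 3] <- NA
    out <- featureValues(knnImpute(FeatureMatrix(m, "metabolomic"), k = 1))
    expect_equal(out["a", "z"], 3)
    # observed cells never altered; complete input unchanged
    expect_equal(out[-1, ], m[-1, ])
    full <- tinyMatrix(5, 4)
    expect_equal(featureValues(knnImpute(full, 2)), featureValues(full))

    # random instances vs exhaustive-distance oracle
    set.seed(11)
    for (rep in 1:10) {
        mm <- matrix(rnorm(8 * 5), 8, 5,
                     dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
        mm[2, 4] <- NA
        got <- featureValues(knnImpute(FeatureMatrix(mm, "metabolomic"),
                                       k = 2))[2, 4]
        obsf <- setdiff(1:5, 4)
        d <- apply(mm[-2, obsf], 1, function(r)
            mean((r - mm[2, obsf])^2))
        want <- mean(mm[-2, 4][order(d)][1:2])
        expect_equal(got, want)
    }
    allmiss <- matrix(c(1, 2, NA, NA), 2, 2,
                      dimnames = list(c("a", "b"), c("x", "y")))
    expect_error(knnImpute(FeatureMatrix(allmiss, "m"), 1),
                 "missing in all samples")
})

test_that("missingness filter uses a strict bound", {
    set.seed(3)
    m <- matrix(rnorm(100 * 3), 100, 3,
                dimnames = list(sprintf("s%03d", 1:100), c("a", "b", "c")))
    m[1:71, 1] <- NA  # 71% missing -> dropped at 0.70
    m[1:70, 2] <- NA  # exactly 70% -> kept (not strictly greater)
    out <- dropHighMissingness(FeatureMatrix(m, "metabolomic"), 0.70)
    expect_setequal(featureIDs(out), c("b", "c"))
    full <- tinyMatrix(4, 3)
    expect_equal(featureValues(dropHighMissingness(full, 0.1)),
                 featureValues(full))
})

test_that("Mahalanobis filter removes gross outliers, keeps typical points", {
    set.seed(5)
    m <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(sprintf("s%03d", 1:200), paste0("f", 1:5)))
    m[1, ] <- 10  # displaced ~10 SD
    res <- mahalanobisFilter(FeatureMatrix(m, "metabolomic"), cutoff = 4)
    expect_true("s001" %in% res$removed)
    # homogeneous Gaussian data: standardised distances concentrate below 4
    expect_lte(length(res$removed) / 200, 0.05)
    # duplicating a central sample removes neither copy
    m2 <- rbind(m[-1, ], central = colMeans(m[-1, ]),
                central2 = colMeans(m[-1, ]))
    rownames(m2) <- c(rownames(m)[-1], "c1", "c2")
    res2 <- mahalanobisFilter(FeatureMatrix(m2, "metabolomic"), 4)
    expect_true(all(c("c1", "c2") %in% sampleIDs(res2$matrix)))
})

test_that("z-scoring is exact, idempotent, and preserves missingness", {
    m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "f"))
    z <- featureValues(zscoreStandardize(FeatureMatrix(m, "clinical")))
    expect_equal(unname(z[, 1]), c(-1, 0, 1))
    z2 <- featureValues(zscoreStandardize(FeatureMatrix(z, "clinical")))
    expect_equal(z, z2, tolerance = 1e-12)
    mna <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
                  dimnames = list(c("a", "b", "c"), c("f", "g")))
    zna <- featureValues(zscoreStandardize(FeatureMatrix(mna, "clinical")))
    expect_true(is.na(zna["b", "f"]))
    expect_equal(unname(zna[c("a", "c"), "f"]),
                 c(-1, 1) / sqrt(2), tolerance = 1e-12)
    const <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2,
                    dimnames = list(c("a", "b", "c"), c("k", "g")))
    expect_warning(out <- zscoreStandardize(FeatureMatrix(const, "clinical")),
                   "constant")
    expect_equal(featureIDs(out), "g")
})

test_that("one-hot encoding expands categoricals and passes numerics through", {
    df <- data.frame(cat3 = factor(c("a", "b", "c", "a")),
                     cat2 = factor(c("x", "y", "x", "y")),
                     num = c(1, 0, 1, 0),
                     row.names = sprintf("s%d", 1:4))
    fm <- oneHotEncode(df)
    expect_equal(ncol(featureValues(fm)), 3 + 2 + 1)
    ind <- featureValues(fm)[, paste0("cat3.", c("a", "b", "c"))]
    expect_equal(unname(rowSums(ind)), rep(1, 4))
    expect_equal(featureValues(fm)[, "num"],
                 stats::setNames(df$num, rownames(df)))
    df$solo <- factor("only")
    expect_warning(fm2 <- oneHotEncode(df), "single-level")
    expect_false(any(grepl("solo", featureIDs(fm2))))
})

test_that("covariate residualisation removes exactly the fitted span", {
    set.seed(6)
    n <- 500
    cov <- data.frame(c1 = rnorm(n))
    f <- 2 * cov$c1 + rnorm(n, sd = 0.5)
    m <- matrix(f, n, 1, dimnames = list(sprintf("s%03d", 1:n), "feat"))
    out <- featureValues(regressOutCovariates(FeatureMatrix(m, "transcriptomic"),
                                              cov))
    expect_lt(abs(stats::var(out[, 1]) - 0.25), 0.025)  # within 10%
    # covariate identical to the feature: residuals vanish
    outz <- regressOutCovariates(FeatureMatrix(m, "transcriptomic"),
                                 data.frame(c1 = f))
    expect_lt(max(abs(featureValues(outz))), 1e-10)
    # orthogonal covariate: feature unchanged up to centering
    orth <- rnorm(n)
    orth <- orth - sum(orth * f) / sum(f^2) * f
    outo <- featureValues(regressOutCovariates(
        FeatureMatrix(m, "transcriptomic"), data.frame(c1 = orth)))
    expect_equal(stats::cor(outo[, 1], f), 1, tolerance = 1e-6)
    expect_error(regressOutCovariates(FeatureMatrix(m, "transcriptomic"),
                                      data.frame(a = cov$c1, b = cov$c1)),
                 "collinear")
})
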