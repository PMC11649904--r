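test_that("with zero prior df the moderated t reduces to the pooled t", {
    set.seed(2)
    lm_ <- labelledMatrix(40, 20, seed = 2)
    got <- moderatedTAssociation(lm_$fm, lm_$y, prior_df = 0)
    v <- featureValues(lm_$fm)
    for (j in sample(20, 20)) {
        x1 <- v[lm_$y == 1, j]; x0 <- v[lm_$y == 0, j]
        sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
                   (length(x1) + length(x0) - 2))
        tt <- (mean(x1) - mean(x0)) / (sp * sqrt(1 / length(x1) + 1 / length(x0)))
        expect_equal(got$t_statistic[j], tt, tolerance = 1e-10)
    }
})

test_that("moderated t tracks the reference empirical-Bayes implementation", {
    skip_if_not_installed("limma")
    set.seed(3)
    lm_ <- labelledMatrix(50, 200, d = 0.8, n_signal = 20, seed = 3)
    got <- moderatedTAssociation(lm_$fm, lm_$y)
    design <- cbind(1, lm_$y)
    fit <- limma::eBayes(limma::lmFit(t(featureValues(lm_$fm)), design))
    ref_t <- fit$t[, 2]
    expect_gt(stats::cor(got$t_statistic, ref_t[got$feature_id]), 0.999)
    # shrunk variances should make |t_mod| <= |t_raw| for high-variance genes
    raw <- moderatedTAssociation(lm_$fm, lm_$y, prior_df = 0)
    expect_gt(stats::cor(got$t_statistic, raw$t_statistic), 0.98)
})

test_that("perfect class separation yields capped statistics", {
    lm_ <- labelledMatrix(20, 3, seed = 4)
    v <- featureValues(lm_$fm)
    v[, 1] <- lm_$y  # feature equals the label
    got <- moderatedTAssociation(FeatureMatrix(v, "x"), lm_$y, prior_df = 0)
    expect_true(is.finite(got$t_statistic[1]))
    expect_gt(abs(got$t_statistic[1]), 1e100)
    expect_lte(got$p_value[1], .Machine$double.xmin)
})

test_that("null association p-values are uniform", {
    set.seed(5)
    lm_ <- labelledMatrix(200, 1000, seed = 5)
    got <- moderatedTAssociation(lm_$fm, lm_$y)
    ks <- suppressWarnings(stats::ks.test(got$p_value, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("the unmoderated t is invariant to affine feature rescaling", {
    # per-feature affine invariance is exact for the pooled t; the moderated
    # statistic shares variance information across features, so it is only
    # equivariant under a common rescaling (as for limma)
    lm_ <- labelledMatrix(30, 5, d = 1, n_signal = 2, seed = 6)
    a <- moderatedTAssociation(lm_$fm, lm_$y, prior_df = 0)
    v <- featureValues(lm_$fm)
    v2 <- sweep(sweep(v, 2, c(2, 5, 0.1, 3, 7), "*"),
                2, c(-1, 4, 0, 2, 9), "+")
    b <- moderatedTAssociation(FeatureMatrix(v2, "x"), lm_$y, prior_df = 0)
    expect_equal(a$t_statistic, b$t_statistic, tolerance = 1e-10)

    am <- moderatedTAssociation(lm_$fm, lm_$y)
    bm <- moderatedTAssociation(FeatureMatrix(3 * v + 1, "x"), lm_$y)
    expect_equal(am$t_statistic, bm$t_statistic, tolerance = 1e-8)
})

test_that("single-SNP genes reduce to the probit of the F-test p", {
    set.seed(7)
    n <- 120
    g <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
                dimnames = list(sprintf("s%03d", 1:n), paste0("snp", 1:3)))
    y <- stats::setNames(rbinom(n, 1, 0.4), rownames(g))
    ann <- data.frame(feature_id = "snp1", gene_id = "G1")
    got <- snpGeneZscores(FeatureMatrix(g, "genomic"), ann, y)
    x <- g[, 1] - mean(g[, 1])
    fit <- stats::lm(y ~ x)
    fs <- summary(fit)$fstatistic
    p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    expect_equal(got$p_value, unname(p), tolerance = 1e-8)
    expect_equal(got$z_value, stats::qnorm(1 - got$p_value), tolerance = 1e-8)

    # identical-copy SNPs collapse to one component, same z as single SNP
    g2 <- cbind(snpA = g[, 1], snpB = g[, 1])
    rownames(g2) <- rownames(g)
    ann2 <- data.frame(feature_id = c("snpA", "snpB"), gene_id = "G1")
    got2 <- snpGeneZscores(FeatureMatrix(g2, "genomic"), ann2, y)
    expect_equal(got2$z_value, got$z_value, tolerance = 1e-6)

    # all-constant gene omitted with a warning
    g3 <- cbind(g, mono = 0); rownames(g3) <- rownames(g)
    ann3 <- rbind(ann, data.frame(feature_id = "mono", gene_id = "G2"))
    expect_warning(got3 <- snpGeneZscores(FeatureMatrix(g3, "genomic"),
                                          ann3, y), "constant")
    expect_false("G2" %in% got3$gene_id)
})

test_that("gene z-scores are calibrated under permuted labels", {
    set.seed(8)
    n <- 150; n_genes <- 200
    g <- matrix(rbinom(n * n_genes * 2, 2, 0.3), n, n_genes * 2,
                dimnames = list(sprintf("s%03d", 1:n),
                                paste0("snp", seq_len(n_genes * 2))))
    ann <- data.frame(feature_id = colnames(g),
                      gene_id = rep(paste0("G", seq_len(n_genes)), each = 2))
    y <- stats::setNames(sample(rep(c(0, 1), c(100, 50))), rownames(g))
    got <- snpGeneZscores(FeatureMatrix(g, "genomic"), ann, y)
    se <- 1 / sqrt(nrow(got))
    expect_lt(abs(mean(got$z_value)), 3 * se)
    expect_gt(stats::var(got$z_value), 0.8)
    expect_lt(stats::var(got$z_value), 1.2)
})

test_that("competitive gene-set regression controls type I error and has power", {
    set.seed(9)
    n_genes <- 500
    reps <- 200
    hits <- vapply(seq_len(reps), function(r) {
        z <- rnorm(n_genes)
        genes <- data.frame(gene_id = paste0("G", seq_len(n_genes)),
                            z_value = z, p_value = pnorm(-z),
                            n_units = sample(1:10, n_genes, TRUE))
        sets <- GeneSetList(list(s1 = paste0("G", sample(n_genes, 30))))
        magmaGeneSetTest(genes, sets)$p_value < 0.05
    }, logical(1))
    se <- sqrt(0.05 * 0.95 / reps)
    expect_lt(abs(mean(hits) - 0.05), 3 * se)

    # power: member z shifted by +1
    z <- rnorm(n_genes); mem <- sample(n_genes, 30)
    z[mem] <- z[mem] + 1
    genes <- data.frame(gene_id = paste0("G", seq_len(n_genes)), z_value = z,
                        p_value = pnorm(-z), n_units = 1L)
    sets <- GeneSetList(list(s1 = paste0("G", mem)))
    res <- magmaGeneSetTest(genes, sets)
    expect_gt(res$beta, 0)
    expect_lt(res$p_value, 0.05)

    # sets with <2 present members are skipped
    sets2 <- GeneSetList(list(tiny = "G1", ok = paste0("G", 1:20)))
    expect_warning(res2 <- magmaGeneSetTest(genes, sets2), "tiny")
    expect_equal(res2$set_id, "ok")
})

test_that("CpG-to-gene aggregation follows the beta order-statistic bound", {
    # a single-CpG gene at normalised rank r has p = r (Beta(1,1) CDF)
    n <- 100
    assoc <- data.frame(feature_id = paste0("cg", 1:n),
                        t_statistic = seq(5, -5, length.out = n),
                        p_value = seq(0.001, 1, length.out = n),
                        direction = 1)
    ann <- data.frame(feature_id = "cg25", gene_id = "G1")
    got <- cpgGeneScores(assoc, ann)
    expect_equal(got$p_value, 25 / 100)
    expect_gt(got$z_value, 0)  # positive mean t preserved as sign

    # all CpGs in the global top 1% force a small gene p
    ann2 <- data.frame(feature_id = c("cg1", "cg1000"),
                       gene_id = c("T", "T"))
    assoc2 <- data.frame(feature_id = paste0("cg", 1:1000),
                         t_statistic = seq(8, -8, length.out = 1000),
                         p_value = seq(1e-6, 1, length.out = 1000),
                         direction = 1)
    ann2 <- data.frame(feature_id = c("cg1", "cg5"), gene_id = "T")
    got2 <- cpgGeneScores(assoc2, ann2)
    expect_lt(got2$p_value, 0.01)

    # null: with the CpG-count correction the gene p is valid (conservative,
    # never anti-conservative) at the relevant thresholds
    set.seed(10)
    ps <- replicate(400, {
        pv <- runif(300)
        assoc3 <- data.frame(feature_id = paste0("cg", 1:300),
                             t_statistic = rnorm(300), p_value = pv,
                             direction = 1)
        ann3 <- data.frame(feature_id = paste0("cg", sample(300, 4)),
                           gene_id = "G")
        cpgGeneScores(assoc3, ann3)$p_value
    })
    for (a in c(0.05, 0.1, 0.2))
        expect_lte(mean(ps < a), a + 3 * sqrt(a * (1 - a) / 400))
    # single-CpG genes are exactly uniform (identity Beta(1,1))
    ps1 <- replicate(300, {
        pv <- runif(200)
        assoc4 <- data.frame(feature_id = paste0("cg", 1:200),
                             t_statistic = rnorm(200), p_value = pv,
                             direction = 1)
        ann4 <- data.frame(feature_id = "cg7", gene_id = "G")
        cpgGeneScores(assoc4, ann4)$p_value
    })
    ks <- suppressWarnings(stats::ks.test(ps1, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
})
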