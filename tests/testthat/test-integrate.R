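test_that("weighted log loss matches closed forms and balance invariance", {
    expect_equal(weightedLogLoss(c(1, 0), c(0.5, 0.5)), log(2))
    expect_lt(weightedLogLoss(c(1, 0), c(1 - 1e-12, 1e-12)), 1e-10)
    expect_warning(weightedLogLoss(c(1, 0), c(1, 0)), "clipped")
    # balanced weights make the loss invariant to duplicating all controls
    set.seed(30)
    y <- c(rep(1, 5), rep(0, 10)); p <- runif(15, 0.1, 0.9)
    y2 <- c(y, rep(0, 10)); p2 <- c(p, p[6:15])
    expect_equal(weightedLogLoss(y, p), weightedLogLoss(y2, p2),
                 tolerance = 1e-12)
})

test_that("AUROC equals its pair-counting value and the trapezoidal ROC area", {
    expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1)), 0.75)
    expect_equal(auroc(c(0, 1), c(0, 1)), 1)
    expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")

    trapezoid <- function(y, s) {  # explicit ROC integration oracle
        th <- sort(unique(s), decreasing = TRUE)
        tpr <- c(0, vapply(th, function(t) mean(s[y == 1] >= t), 1), 1)
        fpr <- c(0, vapply(th, function(t) mean(s[y == 0] >= t), 1), 1)
        sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    }
    set.seed(31)
    for (rep in 1:100) {
        n <- sample(10:60, 1)
        y <- rbinom(n, 1, 0.4)
        if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
        s <- rnorm(n) + y * runif(1, 0, 2)
        if (runif(1) < 0.3) s <- round(s, 1)  # force ties
        expect_equal(auroc(y, s), trapezoid(y, s), tolerance = 1e-12)
    }
})

test_that("the penalised fit collapses to weighted logistic regression at lambda 0", {
    set.seed(32)
    n <- 200
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0)))
    fit <- fitWeightedElasticNet(X, y, alpha = 0.5, lambda = 0)
    w <- classWeights(y)
    ref <- suppressWarnings(  # weighted binomial glm warns about weights
        stats::glm(y ~ X, family = stats::binomial(), weights = w))
    expect_equal(unname(fit$beta), unname(stats::coef(ref)[-1]),
                 tolerance = 1e-4)
    expect_equal(fit$a0, unname(stats::coef(ref)[1]), tolerance = 1e-4)
})

test_that("full shrinkage zeroes coefficients; the intercept is the weighted log-odds", {
    set.seed(33)
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rbinom(n, 1, 0.25)
    fit <- fitWeightedElasticNet(X, y, alpha = 0.5, lambda = 50)
    expect_true(all(fit$beta == 0))
    # with balanced weights, the weighted prevalence is 1/2: log-odds 0
    expect_equal(fit$a0, 0, tolerance = 1e-6)

    # lasso sparsity: one strong feature among noise
    y2 <- rbinom(n, 1, plogis(3 * X[, 1]))
    fit2 <- fitWeightedElasticNet(X, y2, alpha = 1, lambda = 0.1)
    expect_true(abs(fit2$beta["f1"]) > 0)
    expect_true(all(fit2$beta[c("f3", "f4")] == 0))
})

test_that("the tuning grid has the documented cardinality and tie policy", {
    set.seed(34)
    n <- 100
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c(0, 1), 50)
    folds <- rep_len(1:5, n)
    tuned <- tuneElasticNet(X, y, folds, grid_size = 20)
    expect_equal(tuned$n_evaluated, 400L)
    expect_true(tuned$alpha %in% seq(0, 1, length.out = 20))
    expect_true(tuned$lambda %in% seq(0, 1, length.out = 20))
    # degenerate grid
    t1 <- tuneElasticNet(X, y, folds, grid_size = 1)
    expect_equal(c(t1$alpha, t1$lambda), c(0, 0))
    # strong signal: the chosen lambda is not the grid maximum
    y2 <- rbinom(n, 1, plogis(2 * X[, 1] - X[, 2]))
    if (length(unique(y2)) == 2) {
        t2 <- tuneElasticNet(X, y2, folds, grid_size = 10)
        expect_lt(t2$lambda, 1)
    }
    expect_error(tuneElasticNet(X, rep(0:1, c(98, 2)), folds), "lacks a class")
})

test_that("Platt scaling preserves ranking exactly and improves calibration", {
    set.seed(35)
    n <- 2000
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(s))
    cal <- plattFit(s, y)
    expect_equal(cal$slope, 1, tolerance = 0.1)
    expect_equal(cal$intercept, 0, tolerance = 0.1)
    p <- plattApply(cal, s)
    expect_equal(auroc(y, p), auroc(y, s))  # monotone: AUROC unchanged

    # shifted-logit miscalibration: Brier never worse after scaling
    brier <- function(y, p) mean((y - p)^2)
    worse <- vapply(1:25, function(r) {
        set.seed(100 + r)
        s <- rnorm(400)
        y <- rbinom(400, 1, plogis(2 * s + 1))
        raw <- plogis(s)           # too flat and uncentred
        m <- plattFit(s, y)
        brier(y, plattApply(m, s)) > brier(y, raw) + 1e-10
    }, logical(1))
    expect_false(any(worse))
    expect_error(plattFit(rep(1, 10), rep(c(0, 1), 5)), "constant")
})

test_that("complexity choice finds the last significant improvement", {
    set.seed(36)
    mk <- function(...) {
        vals <- list(...)
        do.call(rbind, lapply(seq_along(vals), function(k)
            data.frame(step = k, test_auroc = vals[[k]])))
    }
    base <- rnorm(40, 0.6, 0.02)
    tr <- mk(base, base + 0.1, base + 0.1 + rnorm(40, 0, 0.001))
    expect_equal(chooseComplexity(tr), 2L)
    flat <- mk(base, base + rnorm(40, 0, 0.001), base + rnorm(40, 0, 0.001))
    expect_equal(chooseComplexity(flat), 1L)
    mono <- mk(base, base + 0.05, base + 0.10, base + 0.15)
    expect_equal(chooseComplexity(mono), 4L)
    expect_warning(k1 <- chooseComplexity(mk(base)), "fewer than 2")
    expect_equal(k1, 1L)
})

test_that("thresholding selector has the expected power and type-I count", {
    set.seed(37)
    lm_ <- labelledMatrix(300, 60, d = 1, n_signal = 20, seed = 37)
    sel <- thresholdSelect(lm_$fm, lm_$y, 0.05)
    expect_gte(mean(paste0("f", sprintf("%03d", 1:20)) %in% sel), 0.8)
    null <- labelledMatrix(200, 1000, seed = 38)
    sel0 <- thresholdSelect(null$fm, null$y, 0.05)
    se <- sqrt(1000 * 0.05 * 0.95)
    expect_lt(abs(length(sel0) - 50), 3 * se)
})

test_that("forward selection prefers the informative modality and matches concat at one panel", {
    set.seed(39)
    n <- 120
    y <- stats::setNames(rep(c(0, 1), n / 2), sprintf("s%03d", 1:n))
    sig <- matrix(rnorm(n * 8), n, 8,
                  dimnames = list(names(y), paste0("a", 1:8)))
    sig[, 1:4] <- sig[, 1:4] + y
    noise <- matrix(rnorm(n * 8), n, 8,
                    dimnames = list(names(y), paste0("b", 1:8)))
    panels <- list(alpha = FeatureMatrix(sig, "alpha"),
                   beta = FeatureMatrix(noise, "beta"))
    plan <- makeResamplePlan(y, 8, seed = 11)
    cfg <- mmConfig(grid_size = 8)
    tr <- ffsIntegrate(panels, y, plan, baseline = NULL, config = cfg)
    first <- tr$trace$modality_added[tr$trace$step == 1]
    expect_gte(mean(first == "alpha"), 0.9)

    # forcing a baseline overrides performance at step 1
    trb <- ffsIntegrate(panels, y, plan, baseline = "beta", config = cfg)
    expect_true(all(trb$trace$modality_added[trb$trace$step == 1] == "beta"))

    # single panel: FFS at k = 1 equals the concatenation integrator
    single <- panels["alpha"]
    tr1 <- ffsIntegrate(single, y, plan, config = cfg)
    cc <- concatIntegrate(single, y, plan, config = cfg)
    expect_equal(tr1$trace$test_auroc, cc$test_auroc, tolerance = 1e-12)

    # zero-feature panels are skipped with a warning
    panels$empty <- FeatureMatrix(
        matrix(numeric(0), n, 0,
               dimnames = list(names(y), character(0))), "empty")
    expect_warning(ffsIntegrate(panels, y,
                                makeResamplePlan(y, 2, seed = 1),
                                config = cfg), "zero-feature")
})

test_that("stacking weights the informative modality and never leaks folds", {
    set.seed(40)
    n <- 120
    y <- stats::setNames(rep(c(0, 1), n / 2), sprintf("s%03d", 1:n))
    sig <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(names(y), paste0("a", 1:6)))
    sig[, 1:3] <- sig[, 1:3] + 1.2 * y
    noise <- matrix(rnorm(n * 6), n, 6,
                    dimnames = list(names(y), paste0("b", 1:6)))
    panels <- list(alpha = FeatureMatrix(sig, "alpha"),
                   beta = FeatureMatrix(noise, "beta"))
    plan <- makeResamplePlan(y, 10, seed = 12)
    res <- stackingIntegrate(panels, y, plan, config = mmConfig(grid_size = 8))
    betas <- attr(res, "meta_beta")
    wins <- vapply(betas, function(b) {
        length(b) > 0 && names(which.max(abs(b))) == "alpha"
    }, logical(1))
    expect_gte(mean(wins), 0.9)
    expect_gt(stats::median(res$test_auroc), 0.7)
})

test_that("the final model recovers the informative feature with the right sign", {
    set.seed(41)
    n <- 150
    y <- stats::setNames(rep(c(0, 1), c(100, 50)), sprintf("s%03d", 1:n))
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(names(y), paste0("f", 1:10)))
    X[, 1] <- X[, 1] + 1.5 * y
    panels <- list(mono = FeatureMatrix(X, "mono"))
    plan <- makeResamplePlan(y, 12, seed = 13)
    cfg <- mmConfig(grid_size = 8)
    tr <- ffsIntegrate(panels, y, plan, config = cfg)
    rep_ <- buildFinalModel(tr, panels, y, k_star = 1L, config = cfg)
    expect_true("f1" %in% rep_$consensus$feature_id)
    top <- rep_$consensus$feature_id[which.max(abs(rep_$consensus$importance))]
    expect_identical(top, "f1")
    expect_gt(rep_$consensus$importance[rep_$consensus$feature_id == "f1"], 0)
    # consensus features arise from non-zero coefficients of trace models
    nz <- unique(unlist(lapply(tr$models, function(mm)
        names(mm[[1]]$beta)[mm[[1]]$beta != 0])))
    expect_true(all(rep_$consensus$feature_id %in% nz))
})
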