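# Shared fixture builders: everything generated in code, nothing on disk.

tinyMatrix <- function(n = 6, p = 4, modality = "transcriptomic", seed = 1) {
    set.seed(seed)
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%02d", seq_len(n)),
                                sprintf("f%02d", seq_len(p))))
    FeatureMatrix(m, modality)
}

# two-group cohort with optional informative features (mean shift d)
labelledMatrix <- function(n = 60, p = 20, d = 0, n_signal = 0,
                           modality = "transcriptomic", seed = 1) {
    set.seed(seed)
    y <- rep(c(0, 1), length.out = n)
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", seq_len(n)),
                                sprintf("f%03d", seq_len(p))))
    if (n_signal > 0) m[, seq_len(n_signal)] <- m[, seq_len(n_signal)] + d * y
    names(y) <- rownames(m)
    list(fm = FeatureMatrix(m, modality), y = y)
}

# independent brute-force enrichment-score oracle: literal running sum
bruteES <- function(stats, members, exponent = 1) {
    N <- length(stats)
    hit <- names(stats) %in% members
    k <- sum(hit)
    w <- abs(stats)^exponent
    wr <- sum(w[hit])
    run <- numeric(N)
    cur <- 0
    for (i in seq_len(N)) {
        cur <- cur + if (hit[i]) {
            if (wr > 0) w[i] / wr else 1 / k
        } else -1 / (N - k)
        run[i] <- cur
    }
    peak <- which.max(abs(run))
    list(es = run[peak], peak_index = peak, run = run)
}

# tie-aware comparison of an enrichment score against the brute-force running
# sum: when two positions tie in |running sum| (to rounding), either is a
# valid peak, and summation order decides which one each implementation picks
expectEsMatchesRun <- function(got, run, tol = 1e-9) {
    mx <- max(abs(run))
    near <- which(abs(abs(run) - mx) < tol)
    testthat::expect_true(got$peak_index %in% near)
    testthat::expect_equal(abs(got$es), mx, tolerance = tol)
    testthat::expect_equal(got$es, run[got$peak_index], tolerance = tol)
}
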