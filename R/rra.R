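# Robust rank aggregation across resampled rankings: beta order-statistic
# scores, list-count correction, shared BH utility.

#' Beta order-statistic score of a sorted rank vector
#'
#' For normalised ranks `r_1 <= ... <= r_n`, the score is
#' `rho = min_k P(Beta(k, n - k + 1) <= r_k)` -- the smallest probability,
#' under uniform random ranking, that the k-th best rank is as good as the
#' one observed. Small rho means the item ranks consistently high across
#' lists.
#'
#' @param sorted_normalised_ranks numeric vector in (0, 1], sorted ascending.
#' @return The rho score.
#' @examples
#' betaScore(0.2)            # single list: identity
#' betaScore(c(0.1, 0.9))    # min(1 - 0.9^2, 0.9^2) = 0.19
#' @export
betaScore <- function(sorted_normalised_ranks) {
    r <- sorted_normalised_ranks
    if (!length(r)) stop("empty rank vector")
    if (any(r <= 0 | r > 1)) stop("normalised ranks must lie in (0, 1]")
    if (is.unsorted(r)) stop("ranks must be sorted ascending")
    n <- length(r)
    k <- seq_len(n)
    min(stats::pbeta(r, k, n - k + 1))
}

# Monte-Carlo estimate of the same score: the k-th order statistic CDF is
# estimated from random uniform rank vectors. Used as the permutation mode
# and as an independent oracle.
betaScoreMC <- function(sorted_normalised_ranks, n_draws = 1e5L, seed = 1L) {
    r <- sorted_normalised_ranks
    n <- length(r)
    withSeed(seed, {
        u <- matrix(stats::runif(n_draws * n), ncol = n)
        u <- matrix(u[order(row(u), u)], ncol = n, byrow = TRUE)  # row-sort
        pk <- colMeans(sweep(u, 2, r, "<="))
        min(pk)
    })
}

#' Aggregate ranked lists into consensus scores
#'
#' Items are scored by [betaScore()] over their normalised ranks across the
#' lists that contain them, corrected for multiplicity by the number of
#' contributing lists (`corrected_p = min(1, rho * n_lists)`), and
#' BH-adjusted across items. Items absent from a list receive no rank from
#' it. Ranks are normalised by `universe_size` when given (so partial lists
#' -- e.g. only the non-zero-importance features of a model -- remain
#' informative), otherwise by the list length (appropriate when every list
#' ranks the full item set).
#'
#' @param lists list of character vectors, each an ordered ranking (best
#'   first).
#' @param universe_size optional total number of rankable items; must be at
#'   least the longest list. When given, normalised rank = position /
#'   universe_size.
#' @param mode `"analytic"` (default, beta bound) or `"permutation"`
#'   (Monte-Carlo order-statistic estimate; slower).
#' @param n_draws Monte-Carlo draws for permutation mode.
#' @param seed seed for permutation mode.
#' @return data.frame (`item_id`, `rho`, `n_lists`, `corrected_p`,
#'   `bh_adjusted_p`) sorted by corrected p.
#' @export
aggregateRanks <- function(lists, universe_size = NULL,
                           mode = c("analytic", "permutation"),
                           n_draws = 1e5L, seed = 1L) {
    mode <- match.arg(mode)
    if (!length(lists)) stop("at least one list required")
    if (!is.null(universe_size) && universe_size < max(lengths(lists)))
        stop("universe_size smaller than a list length")
    ranks <- list()
    for (l in lists) {
        if (anyDuplicated(l)) stop("duplicate items within a list")
        denom <- if (is.null(universe_size)) length(l) else universe_size
        nr <- seq_along(l) / denom
        for (i in seq_along(l))
            ranks[[l[i]]] <- c(ranks[[l[i]]], nr[i])
    }
    items <- names(ranks)
    rho <- vapply(seq_along(items), function(i) {
        r <- sort(ranks[[i]])
        if (mode == "analytic") betaScore(r)
        else betaScoreMC(r, n_draws, deriveSeed(seed, items[i]))
    }, numeric(1))
    n_lists <- lengths(ranks)
    corrected <- pmin(1, rho * n_lists)
    res <- data.frame(item_id = items, rho = rho,
                      n_lists = as.integer(n_lists),
                      corrected_p = corrected,
                      bh_adjusted_p = adjustBH(corrected),
                      stringsAsFactors = FALSE)
    res <- res[order(res$corrected_p, res$rho, res$item_id), ]
    rownames(res) <- NULL
    res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1).
#' Input p-values outside `[0, 1]` are rejected.
#'
#' @param p_values numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
adjustBH <- function(p_values) {
    if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p_values, method = "BH")
}
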