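# Preranked gene-set enrichment: weighted running-sum enrichment scores,
# gene-label permutation p-values, BH adjustment, leading-edge extraction.

#' Build a ranked list from named statistics
#'
#' Sorts features by statistic, descending, breaking ties by feature id
#' (lexicographic) so that enrichment is deterministic.
#'
#' @param stats named numeric vector (signed t or z statistics).
#' @return Named numeric vector sorted for enrichment.
#' @export
rankedList <- function(stats) {
    if (is.null(names(stats)) || anyDuplicated(names(stats)))
        stop("stats must be uniquely named")
    if (length(stats) < 2L) stop("ranked list needs at least 2 items")
    stats[order(-stats, names(stats))]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating `|stat|^weight_exponent /
#' sum(member |stat|^weight_exponent)` at member positions and
#' `-1 / (N - N_members)` elsewhere. The enrichment score is the signed
#' maximum deviation of this running sum, and `peak_index` its position.
#'
#' @param ranked a [rankedList()] (named, descending).
#' @param members character vector of member ids; at least one must be
#'   present and they must not cover the whole list.
#' @param weight_exponent weighting of statistics (default 1, classic
#'   weighted enrichment).
#' @return list with `es` (in `[-1, 1]`) and `peak_index`.
#' @examples
#' r <- rankedList(c(a = 2, b = 1, c = -1, d = -2))
#' enrichmentScore(r, "a")  # es = 1 at the top of the list
#' @export
enrichmentScore <- function(ranked, members, weight_exponent = 1) {
    N <- length(ranked)
    hit <- names(ranked) %in% members
    k <- sum(hit)
    if (k == 0L) stop("no set members present in the ranked list")
    if (k == N) stop("set covers the entire ranked list")
    w <- abs(ranked)^weight_exponent
    wr <- sum(w[hit])
    inc <- if (wr > 0) w * hit / wr else hit / k  # all-zero stats: flat weights
    run <- cumsum(inc - (!hit) / (N - k))
    peak <- which.max(abs(run))
    list(es = run[[peak]], peak_index = as.integer(peak))
}

# Enrichment scores of many random member-position draws of size k, used for
# the permutation null. positions: k x nperm matrix of sorted positions.
esFromPositions <- function(pos_sorted, w, N, k) {
    # running sum evaluated just after and just before each member position
    wm <- matrix(w[pos_sorted], nrow = k)
    cw <- matrix(apply(wm, 2, cumsum), nrow = k)
    tot <- cw[k, ]
    zero <- tot == 0
    if (any(zero)) {            # all-zero member stats: flat unit weights
        wm[, zero] <- 1 / k
        cw[, zero] <- seq_len(k) / k
        tot[zero] <- 1
    }
    j <- seq_len(k)
    after <- sweep(cw, 2, tot, "/") - (pos_sorted - j) / (N - k)
    before <- after - wm / rep(tot, each = k)
    hi <- pmax(apply(after, 2, max), 0)
    lo <- pmin(apply(before, 2, min), 0)
    ifelse(hi >= -lo, hi, lo)
}

#' Preranked gene-set enrichment with permutation p-values
#'
#' For each set (filtered to members present, size within
#' `[min_size, max_size]`), computes the enrichment score and a permutation
#' p-value from `n_permutations` random member-label draws of equal size:
#' `p = (1 + #(same sign & |ES_perm| >= |ES|)) / (1 + n_permutations)`.
#' P-values are BH-adjusted across tested sets and results carry leading-edge
#' members ([extractLeadingEdge()]).
#'
#' @param ranked a [rankedList()].
#' @param sets a [GeneSetList-class].
#' @param n_permutations number of permutations (>= 100; default 10000).
#' @param min_size,max_size set-size bounds after filtering (defaults 5, 500).
#' @param weight_exponent see [enrichmentScore()].
#' @param seed integer seed for the permutation draws.
#' @return data.frame (`set_id`, `es`, `peak_index`, `size`, `p_value`,
#'   `adjusted_p`, `direction`, `leading_edge` comma-joined), one row per
#'   tested set.
#' @export
gseaPreranked <- function(ranked, sets, n_permutations = 10000L,
                          min_size = 5L, max_size = 500L,
                          weight_exponent = 1, seed = 1L) {
    if (n_permutations < 100L)
        stop("n_permutations must be at least 100 for stable p-values")
    N <- length(ranked)
    present <- lapply(geneSets(sets), intersect, x = names(ranked))
    sizes <- lengths(present)
    keep <- sizes >= min_size & sizes <= max_size & sizes < N
    present <- present[keep]
    if (!length(present))
        return(data.frame(set_id = character(), es = numeric(),
                          peak_index = integer(), size = integer(),
                          p_value = numeric(), adjusted_p = numeric(),
                          direction = character(), leading_edge = character(),
                          stringsAsFactors = FALSE))
    w <- abs(ranked)^weight_exponent
    rows <- withSeed(seed, {
        # share permutation draws across sets of equal size
        null_by_k <- list()
        lapply(names(present), function(sid) {
            mem <- present[[sid]]
            k <- length(mem)
            obs <- enrichmentScore(ranked, mem, weight_exponent)
            kk <- as.character(k)
            if (is.null(null_by_k[[kk]])) {
                pos <- replicate(n_permutations, sort.int(sample.int(N, k)))
                pos <- matrix(pos, nrow = k)
                null_by_k[[kk]] <<- esFromPositions(pos, w, N, k)
            }
            perm <- null_by_k[[kk]]
            # p is computed within the same-sign half of the permutation
            # null, so it is uniform under random member draws
            if (obs$es >= 0) {
                extreme <- sum(perm >= obs$es); denom <- sum(perm >= 0)
            } else {
                extreme <- sum(perm <= obs$es); denom <- sum(perm < 0)
            }
            p <- (1 + extreme) / (1 + denom)
            le <- extractLeadingEdge(ranked, list(
                es = obs$es, peak_index = obs$peak_index, members = mem))
            data.frame(set_id = sid, es = obs$es,
                       peak_index = obs$peak_index, size = k, p_value = p,
                       direction = if (obs$es >= 0) "up" else "down",
                       leading_edge = paste(le, collapse = ","),
                       stringsAsFactors = FALSE)
        })
    })
    res <- do.call(rbind, rows)
    res$adjusted_p <- adjustBH(res$p_value)
    rownames(res) <- NULL
    res[c("set_id", "es", "peak_index", "size", "p_value", "adjusted_p",
          "direction", "leading_edge")]
}

#' Leading-edge members of an enrichment result
#'
#' For up-regulated sets (positive enrichment score) the leading edge is the
#' members at list positions 1..peak; for down-regulated sets, the members at
#' positions peak..N.
#'
#' @param ranked the [rankedList()] the result was computed from.
#' @param result a list or one-row data.frame with `es`, `peak_index` and
#'   `members` (or a `leading_edge`-free row from [gseaPreranked()] plus a
#'   `members` element).
#' @return Character vector of leading-edge member ids.
#' @export
extractLeadingEdge <- function(ranked, result) {
    peak <- result$peak_index
    if (is.null(peak) || peak < 1 || peak > length(ranked))
        stop("peak_index out of range")
    members <- result$members
    ids <- names(ranked)
    if (result$es >= 0)
        intersect(ids[seq_len(peak)], members)
    else
        intersect(ids[peak:length(ids)], members)
}
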