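#' Derive a stage seed from the master seed
#'
#' All randomised stages draw their RNG seed deterministically from the master
#' seed, a stage label and an index, so that a whole pipeline run is
#' reproducible from one integer and individual stages can be re-run in
#' isolation.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. "gsea", "resample").
#' @param index integer index (resample number, set index, ...), default 0.
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, "gsea", 3)
#' @export
deriveSeed <- function(master, stage, index = 0L) {
    M <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
    h <- 17
    for (v in c(as.numeric(master), as.numeric(utf8ToInt(stage)),
                as.numeric(index)))
        h <- (h * 31 + (v %% M)) %% M
    as.integer(h)
}

# Evaluate expr with a local, restored RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
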