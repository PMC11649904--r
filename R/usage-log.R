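# Instrumented sample-usage log.
#
# Every pipeline routine that consumes sample-level data funnels the ids it
# touches through logSampleUse(), tagged with a stage and purpose. With
# logging enabled this yields an audit trail from which tests verify the
# leakage contract: held-out test samples are touched only to score
# predictions (purposes "predict"/"auroc"), never for ranking, enrichment,
# tuning or fitting.

.usageEnv <- new.env(parent = emptyenv())
.usageEnv$active <- FALSE
.usageEnv$records <- list()

#' Sample-usage audit log
#'
#' `enableUsageLog()` starts recording which sample ids each pipeline stage
#' consumes and for what purpose; `disableUsageLog()` stops recording;
#' `usageLog()` returns the records as a data.frame (stage, resample, purpose,
#' sample_id); `clearUsageLog()` empties it. Used to audit that test samples
#' of a resample are only ever touched when scoring predictions.
#'
#' @return `usageLog()` returns a data.frame; the others are called for their
#'   side effect.
#' @name usageLog
#' @export
enableUsageLog <- function() {
    .usageEnv$active <- TRUE
    invisible(TRUE)
}

#' @rdname usageLog
#' @export
disableUsageLog <- function() {
    .usageEnv$active <- FALSE
    invisible(TRUE)
}

#' @rdname usageLog
#' @export
clearUsageLog <- function() {
    .usageEnv$records <- list()
    invisible(TRUE)
}

#' @rdname usageLog
#' @export
usageLog <- function() {
    if (!length(.usageEnv$records))
        return(data.frame(stage = character(), resample = integer(),
                          purpose = character(), sample_id = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, .usageEnv$records)
}

logSampleUse <- function(stage, resample, purpose, sample_ids) {
    if (!.usageEnv$active || !length(sample_ids)) return(invisible(NULL))
    .usageEnv$records[[length(.usageEnv$records) + 1L]] <-
        data.frame(stage = stage, resample = as.integer(resample),
                   purpose = purpose, sample_id = as.character(sample_ids),
                   stringsAsFactors = FALSE)
    invisible(NULL)
}
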