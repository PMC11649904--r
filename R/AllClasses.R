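#' @import methods
NULL

#' Canonical modality names
#'
#' The seven data layers the framework was designed around. `FeatureMatrix`
#' objects may carry any modality label; this constant is used by the
#' synthetic cohort generator and the CLI for their defaults.
#'
#' @export
kModalities <- c("genomic", "transcriptomic", "proteomic", "metabolomic",
                 "methylomic", "inflammatory", "clinical")

#' FeatureMatrix: a samples-by-features data layer
#'
#' Container for one data modality: a numeric matrix with samples in rows and
#' features in columns, tagged with a modality name. Missing values are
#' represented as `NA`; all non-missing values must be finite. Row and column
#' names must be unique and non-empty.
#'
#' @slot values numeric matrix, samples in rows, features in columns.
#' @slot modality single character string naming the data layer.
#'
#' @seealso [FeatureMatrix()] for construction, [readFeatureMatrix()] to read
#'   one from disk.
#' @export
setClass("FeatureMatrix",
         representation(values = "matrix", modality = "character"))

setValidity("FeatureMatrix", function(object) {
    v <- object@values
    msgs <- character()
    if (length(object@modality) != 1L || is.na(object@modality) ||
        !nzchar(object@modality))
        msgs <- c(msgs, "'modality' must be a single non-empty string")
    if (!is.numeric(v))
        msgs <- c(msgs, "'values' must be a numeric matrix")
    if ((nrow(v) > 0 && is.null(rownames(v))) ||
        (ncol(v) > 0 && is.null(colnames(v))))
        msgs <- c(msgs, "'values' must have sample (row) and feature (column) names")
    else {
        dup <- unique(rownames(v)[duplicated(rownames(v))])
        if (length(dup))
            msgs <- c(msgs, paste0("duplicate sample ids: ",
                                   paste(dup, collapse = ", ")))
        dup <- unique(colnames(v)[duplicated(colnames(v))])
        if (length(dup))
            msgs <- c(msgs, paste0("duplicate feature ids: ",
                                   paste(dup, collapse = ", ")))
    }
    if (is.numeric(v) && any(is.infinite(v)))
        msgs <- c(msgs, "non-missing values must be finite")
    if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (samples x features) with unique dimnames.
#' @param modality modality name (any non-empty string; see [kModalities]).
#' @return A validated [FeatureMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' fm <- FeatureMatrix(m, "transcriptomic")
#' @export
FeatureMatrix <- function(values, modality) {
    if (is.data.frame(values)) values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("FeatureMatrix", values = values, modality = modality)
}

#' GeneSetList: named collections of feature identifiers
#'
#' Gene (or metabolite) sets used for enrichment: each set has a unique id, a
#' free-text description and a non-empty character vector of member
#' identifiers.
#'
#' @slot sets named list of character vectors (members).
#' @slot descriptions character vector parallel to `sets`.
#' @seealso [GeneSetList()], [readGmt()]
#' @export
setClass("GeneSetList",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetList", function(object) {
    msgs <- character()
    nm <- names(object@sets)
    if (length(object@sets)) {
        if (is.null(nm) || any(!nzchar(nm)))
            msgs <- c(msgs, "all sets must be named")
        else if (anyDuplicated(nm))
            msgs <- c(msgs, paste0("duplicate set ids: ",
                                   paste(unique(nm[duplicated(nm)]), collapse = ", ")))
        if (!all(vapply(object@sets, is.character, logical(1))))
            msgs <- c(msgs, "set members must be character identifiers")
        if (any(lengths(object@sets) == 0L))
            msgs <- c(msgs, "sets must be non-empty")
    }
    if (length(object@descriptions) != length(object@sets))
        msgs <- c(msgs, "one description per set required")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors of member identifiers;
#'   duplicate members within a set are dropped.
#' @param descriptions optional character vector of descriptions (recycled
#'   to "" when absent).
#' @return A validated [GeneSetList-class].
#' @export
GeneSetList <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(x) unique(as.character(x)))
    if (is.null(descriptions)) descriptions <- rep("", length(sets))
    new("GeneSetList", sets = sets, descriptions = descriptions)
}

#' ResamplePlan: stratified train/test splits with inner folds
#'
#' A reproducible plan of stratified resamples: for each resample a train set
#' (default 80%) and disjoint test set, plus a stratified fold assignment of
#' the train set for inner cross-validation. Class proportions in every train,
#' test and fold are within one sample of the cohort ratio.
#'
#' @slot train list of character vectors of train sample ids, one per resample.
#' @slot test list of character vectors of test sample ids.
#' @slot folds list of named integer vectors (fold index per train sample).
#' @slot n_folds number of inner folds.
#' @slot seed integer seed the plan was derived from.
#' @seealso [makeResamplePlan()]
#' @export
setClass("ResamplePlan",
         representation(train = "list", test = "list", folds = "list",
                        n_folds = "integer", seed = "integer"))

setValidity("ResamplePlan", function(object) {
    msgs <- character()
    if (length(object@train) != length(object@test) ||
        length(object@train) != length(object@folds))
        msgs <- c(msgs, "train/test/folds must have one entry per resample")
    for (i in seq_along(object@train)) {
        if (length(intersect(object@train[[i]], object@test[[i]])))
            msgs <- c(msgs, sprintf("resample %d: train and test overlap", i))
        f <- object@folds[[i]]
        if (!setequal(names(f), object@train[[i]]))
            msgs <- c(msgs, sprintf("resample %d: folds must partition the train set", i))
    }
    if (length(msgs)) msgs else TRUE
})
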