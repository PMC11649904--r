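#' @include AllClasses.R
NULL

#' Accessors for FeatureMatrix and GeneSetList
#'
#' `featureValues` returns the numeric samples-by-features matrix,
#' `sampleIDs`/`featureIDs` its dimnames, and `modality` the layer tag.
#' `geneSets` returns the named list of member vectors of a [GeneSetList-class]
#' and `setIDs` its names.
#'
#' @param x a [FeatureMatrix-class] or [GeneSetList-class] object.
#' @name accessors
#' @aliases featureValues sampleIDs featureIDs modality geneSets setIDs
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setIDs", function(x) standardGeneric("setIDs"))

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("sampleIDs", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("featureIDs", "FeatureMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("modality", "FeatureMatrix", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("setIDs", "GeneSetList", function(x) names(x@sets))

#' @describeIn accessors number of samples / sets
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' Subset a FeatureMatrix by sample and feature ids (or indices)
#'
#' @param x a FeatureMatrix
#' @param i sample selector
#' @param j feature selector
#' @param ... unused
#' @param drop ignored; dimensions are always kept
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
    v <- x@values
    if (!missing(i)) v <- v[i, , drop = FALSE]
    if (!missing(j)) v <- v[, j, drop = FALSE]
    new("FeatureMatrix", values = v, modality = x@modality)
})

#' Extract one gene set
#' @param x a GeneSetList
#' @param i set selector (id or index)
#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

setMethod("show", "FeatureMatrix", function(object) {
    v <- object@values
    cat(sprintf("FeatureMatrix [%s]: %d samples x %d features, %.1f%% missing\n",
                object@modality, nrow(v), ncol(v), 100 * mean(is.na(v))))
})

setMethod("show", "GeneSetList", function(object) {
    n <- length(object@sets)
    cat(sprintf("GeneSetList: %d sets, member counts %s\n", n,
                if (n) paste0(min(lengths(object@sets)), "-",
                              max(lengths(object@sets))) else "-"))
})

setMethod("show", "ResamplePlan", function(object) {
    cat(sprintf("ResamplePlan: %d resamples, %d inner folds, seed %d\n",
                length(object@train), object@n_folds, object@seed))
})
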