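#' Read a feature matrix from TSV/CSV
#'
#' The first row holds feature ids, the first column sample ids; the delimiter
#' is chosen by file extension (`.csv` comma, otherwise tab). `NA` or empty
#' cells are missing. Duplicate sample or feature ids, ragged rows and
#' non-numeric cells are rejected with informative errors.
#'
#' @param path file path.
#' @param modality modality name to tag the matrix with.
#' @return A [FeatureMatrix-class].
#' @seealso [writeResultTable()] for the inverse of the on-disk convention.
#' @export
readFeatureMatrix <- function(path, modality) {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    lines <- readLines(path)
    if (!length(lines)) stop("empty file: ", path)
    # strsplit drops a trailing empty field; preserve it (empty = missing)
    parts <- strsplit(lines, sep, fixed = TRUE)
    ends <- endsWith(lines, sep)
    parts[ends] <- lapply(parts[ends], c, "")
    nfield <- lengths(parts)
    # header may or may not carry a leading cell for the id column
    body_n <- nfield[-1]
    if (length(unique(body_n)) > 1L)
        stop("ragged rows: line ", which(body_n != body_n[1])[1] + 1L,
             " has ", body_n[which(body_n != body_n[1])[1]],
             " fields, expected ", body_n[1])
    header <- parts[[1]]
    if (length(header) == body_n[1]) header <- header[-1]
    if (length(header) != body_n[1] - 1L)
        stop("header has ", length(header) + 1L,
             " fields but data rows have ", body_n[1])
    feat <- header
    samp <- vapply(parts[-1], `[[`, character(1), 1L)
    dup <- unique(samp[duplicated(samp)])
    if (length(dup))
        stop("duplicate sample ids: ", paste(dup, collapse = ", "))
    dup <- unique(feat[duplicated(feat)])
    if (length(dup))
        stop("duplicate feature ids: ", paste(dup, collapse = ", "))
    cells <- unlist(lapply(parts[-1], `[`, -1L), use.names = FALSE)
    miss <- cells %in% c("NA", "")
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & is.na(num))
    if (length(bad))
        stop("non-numeric cell \"", cells[bad[1]], "\" at row ",
             (bad[1] - 1L) %/% length(feat) + 1L, ", column ",
             (bad[1] - 1L) %% length(feat) + 1L)
    num[miss] <- NA_real_
    m <- matrix(num, nrow = length(samp), ncol = length(feat),
                byrow = TRUE, dimnames = list(samp, feat))
    FeatureMatrix(m, modality)
}

#' Write a FeatureMatrix or result table as TSV
#'
#' Tables are written tab-separated with a header row; missing values are
#' rendered as `NA`. A written [FeatureMatrix-class] round-trips exactly
#' through [readFeatureMatrix()].
#'
#' @param x a FeatureMatrix or data.frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeResultTable <- function(x, path) {
    if (is(x, "FeatureMatrix")) {
        v <- featureValues(x)
        df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                         stringsAsFactors = FALSE)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
    } else {
        if (!is.data.frame(x)) stop("x must be a FeatureMatrix or data.frame")
        if (anyDuplicated(names(x)))
            stop("duplicate column names: ",
                 paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
        utils::write.table(x, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "NA")
    }
    invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path TSV file path.
#' @return A data.frame.
#' @export
readResultTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                      check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' Each line is `set_id TAB description TAB member TAB member ...`; duplicate
#' members within a line are dropped. Lines with fewer than three fields are
#' rejected with their line number.
#'
#' @param path GMT file path.
#' @return A [GeneSetList-class].
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
        stop("line ", short[1], ": fewer than 3 fields")
    ids <- vapply(parts, `[[`, character(1), 1L)
    desc <- vapply(parts, `[[`, character(1), 2L)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- ids
    GeneSetList(sets, desc)
}

#' Write gene sets in GMT format
#'
#' @param gsl a [GeneSetList-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(gsl, path) {
    lines <- vapply(seq_along(gsl@sets), function(i) {
        paste(c(names(gsl@sets)[i], gsl@descriptions[i], gsl@sets[[i]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
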