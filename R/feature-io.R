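## Plain-text I/O: TSV feature tables (QIIME-style "#OTU ID" headers
## tolerated), newick trees via ape, TSV metadata and metric outputs.
## Orientation is always explicit -- no sniffing.

#' Read a TSV feature table
#'
#' Reads a tab-separated count table whose first column holds row
#' identifiers. \code{orientation} states what the rows are; the result is
#' always normalised to the internal features-by-samples layout. A leading
#' \code{#} on the header id cell (QIIME's \code{#OTU ID}) is tolerated.
#'
#' @param path TSV file path
#' @param orientation \code{"samples_as_rows"} (simulator output default) or
#'   \code{"features_as_rows"} (QIIME exports)
#' @param metadata optional path to a TSV of per-sample metadata whose first
#'   column holds sample identifiers
#' @return a [FeatureTable-class]
#' @export
readFeatureTable <- function(path,
                             orientation = c("samples_as_rows",
                                             "features_as_rows"),
                             metadata = NULL) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE, comment.char = "",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate row identifier: ", ids[duplicated(ids)][1L])
    colIds <- colnames(df)[-1L]
    if (anyDuplicated(colIds))
        stop("duplicate column identifier: ", colIds[duplicated(colIds)][1L])
    m <- matrix(0, nrow(df), length(colIds), dimnames = list(ids, colIds))
    for (j in seq_along(colIds)) {
        v <- suppressWarnings(as.numeric(df[[j + 1L]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop("cell (", ids[bad[1L]], ", ", colIds[j],
                 ") does not parse as a number: '", df[[j + 1L]][bad[1L]], "'")
        bad <- which(v < 0)
        if (length(bad))
            stop("negative count at (", ids[bad[1L]], ", ", colIds[j], "): ",
                 v[bad[1L]])
        bad <- which(abs(v - round(v)) > 1e-9)
        if (length(bad))
            stop("non-integer count at (", ids[bad[1L]], ", ", colIds[j],
                 "): ", v[bad[1L]])
        m[, j] <- v
    }
    md <- if (is.null(metadata)) NULL else readSampleMetadata(metadata)
    FeatureTable(m, orientation = orientation, metadata = md)
}

#' Write a FeatureTable to TSV
#'
#' Counts only; sample metadata, if any, is written to a separate file
#' keyed by sample identifier. Lossless round trip with
#' [readFeatureTable()] under the same orientation.
#'
#' @param table a [FeatureTable-class]
#' @param path output TSV path
#' @param orientation which dimension to write as rows
#' @param metadataPath optional path for the per-sample metadata TSV
#' @export
writeFeatureTable <- function(table, path,
                              orientation = c("samples_as_rows",
                                              "features_as_rows"),
                              metadataPath = NULL) {
    orientation <- match.arg(orientation)
    stopifnot(methods::is(table, "FeatureTable"))
    m <- as.matrix(counts(table))            # features x samples
    storage.mode(m) <- "integer"
    if (orientation == "samples_as_rows") {
        m <- t(m)
        idHeader <- "sample_id"
    } else idHeader <- "#OTU ID"
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idHeader
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    cd <- SummarizedExperiment::colData(table)
    if (!is.null(metadataPath) && ncol(cd)) {
        md <- data.frame(sample_id = rownames(cd), as.data.frame(cd),
                         check.names = FALSE)
        utils::write.table(md, metadataPath, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
    }
    invisible(NULL)
}

#' Read per-sample metadata
#'
#' TSV whose first column is the sample identifier; all remaining columns
#' are read as character.
#'
#' @param path TSV path
#' @return data.frame with sample ids as rownames
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE, comment.char = "",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (anyDuplicated(df[[1L]]))
        stop("duplicate sample identifier in metadata")
    rownames(df) <- df[[1L]]
    df[-1L]
}

#' Read a rooted newick tree
#'
#' Wraps \code{ape::read.tree} with the checks the diversity metrics need:
#' labelled, unique tips; branch lengths (absent or NA lengths are set to 0
#' with a warning); rootedness (an unrooted basal multifurcation is kept,
#' with its basal node treated as the root, and a warning).
#'
#' @param path newick file path
#' @return an \code{ape::phylo}
#' @export
readTree <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    # ape warns and returns NULL on malformed input; fold both into one error
    tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                     error = function(e) stop("newick parse error in '",
                                              path, "': ", conditionMessage(e)))
    if (is.null(tree)) stop("newick parse error in '", path, "'")
    if (any(is.na(tree$tip.label)) || any(tree$tip.label == ""))
        stop("tree contains unlabeled tips")
    if (anyDuplicated(tree$tip.label))
        stop("duplicate tip labels: ",
             tree$tip.label[duplicated(tree$tip.label)][1L])
    if (is.null(tree$edge.length)) {
        warning("tree has no branch lengths; all set to 0")
        tree$edge.length <- rep(0, nrow(tree$edge))
    } else if (anyNA(tree$edge.length)) {
        warning("missing branch lengths set to 0")
        tree$edge.length[is.na(tree$edge.length)] <- 0
    }
    if (any(tree$edge.length < 0))
        stop("tree contains negative branch lengths")
    if (!ape::is.rooted(tree))
        warning("tree is unrooted; its basal node is treated as the root")
    tree
}

#' Write a tree to newick
#'
#' @param tree an \code{ape::phylo}
#' @param path output path
#' @export
writeTree <- function(tree, path) {
    ape::write.tree(tree, file = path, digits = 15)
    invisible(NULL)
}

#' Write an AlphaMatrix to TSV
#'
#' \code{"wide"}: one row per sample, one column per metric. \code{"long"}:
#' one row per (sample, metric) pair with the metric's category. Missing
#' values are serialised as empty fields, never as \code{"NA"} text.
#'
#' @param matrix an [AlphaMatrix-class]
#' @param path output TSV path
#' @param layout \code{"wide"} or \code{"long"}
#' @export
writeAlphaMatrix <- function(matrix, path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    stopifnot(methods::is(matrix, "AlphaMatrix"))
    v <- alphaValues(matrix)                       # samples x metrics
    if (layout == "wide") {
        df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
    } else {
        cats <- metricCategories(matrix)
        df <- data.frame(
            sample_id = rep(rownames(v), times = ncol(v)),
            metric = rep(colnames(v), each = nrow(v)),
            category = rep(unname(cats[colnames(v)]), each = nrow(v)),
            value = as.vector(v))
        df <- df[order(match(df$sample_id, rownames(v))), ]
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    invisible(NULL)
}

#' Read a wide-layout AlphaMatrix TSV
#'
#' Inverse of [writeAlphaMatrix()] for the wide layout. Categories are
#' looked up in the default metric registry; unknown metric columns are
#' rejected unless \code{categories} supplies them.
#'
#' @param path TSV path
#' @param categories optional named character vector of category labels
#' @return an [AlphaMatrix-class]
#' @export
readAlphaMatrix <- function(path, categories = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = "")
    v <- as.matrix(df[-1L])
    rownames(v) <- df[[1L]]
    if (is.null(categories)) {
        reg <- metricRegistry()
        categories <- stats::setNames(reg$category, reg$name)
    }
    unknown <- setdiff(colnames(v), names(categories))
    if (length(unknown))
        stop("no category known for metric column(s): ",
             paste(unknown, collapse = ", "))
    AlphaMatrix(v, categories)
}
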