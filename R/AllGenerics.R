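#' @importFrom BiocGenerics counts
NULL

#' Accessors for alphadiv containers
#'
#' \code{sampleIDs} and \code{featureIDs} return the sample / feature
#' identifiers of a [FeatureTable-class] (or the sample / metric identifiers
#' of an [AlphaMatrix-class]); \code{counts} returns the features-by-samples
#' count matrix; \code{alphaValues} returns the samples-by-metrics value
#' matrix; \code{metricCategories} the named category vector;
#' \code{designTable} and \code{communityTree} the design and tree of a
#' [SyntheticDataset-class].
#'
#' @param object an alphadiv container
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))

#' @rdname accessors
#' @export
setGeneric("alphaValues", function(object) standardGeneric("alphaValues"))

#' @rdname accessors
#' @export
setGeneric("metricCategories", function(object) standardGeneric("metricCategories"))

#' @rdname accessors
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @rdname accessors
#' @export
setGeneric("communityTree", function(object) standardGeneric("communityTree"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "FeatureTable", function(object) colnames(object))

#' @rdname accessors
#' @export
setMethod("featureIDs", "FeatureTable", function(object) rownames(object))

#' @rdname accessors
#' @export
setMethod("counts", "FeatureTable",
    function(object) SummarizedExperiment::assay(object, "counts"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "AlphaMatrix", function(object) colnames(object))

#' @rdname accessors
#' @export
setMethod("alphaValues", "AlphaMatrix",
    function(object) t(SummarizedExperiment::assay(object, "alpha")))

#' @rdname accessors
#' @export
setMethod("metricCategories", "AlphaMatrix", function(object) {
    stats::setNames(SummarizedExperiment::rowData(object)$category,
                    rownames(object))
})

#' @rdname accessors
#' @export
setMethod("designTable", "SyntheticDataset", function(object) object@design)

#' @rdname accessors
#' @export
setMethod("communityTree", "SyntheticDataset", function(object) object@tree)

#' @rdname accessors
#' @export
setMethod("counts", "SyntheticDataset", function(object) counts(object@table))

#' @rdname accessors
#' @param object a SyntheticDataset
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))

#' @rdname accessors
#' @export
setMethod("featureTable", "SyntheticDataset", function(object) object@table)

setMethod("show", "FeatureTable", function(object) {
    cat("FeatureTable with", nrow(object), "features and",
        ncol(object), "samples\n")
    m <- counts(object)
    tot <- if (methods::is(m, "sparseMatrix")) sum(m@x) else sum(m)
    cat("  total reads:", format(tot, big.mark = ","),
        "| sparse:", methods::is(m, "sparseMatrix"), "\n")
    if (ncol(SummarizedExperiment::colData(object)))
        cat("  sample metadata:",
            paste(colnames(SummarizedExperiment::colData(object)),
                  collapse = ", "), "\n")
})

setMethod("show", "AlphaMatrix", function(object) {
    cats <- table(SummarizedExperiment::rowData(object)$category)
    cat("AlphaMatrix:", ncol(object), "samples x", nrow(object), "metrics\n")
    cat("  categories:",
        paste(names(cats), cats, sep = "=", collapse = ", "), "\n")
    nmiss <- sum(is.na(SummarizedExperiment::assay(object, "alpha")))
    if (nmiss) cat("  missing values:", nmiss, "\n")
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig\n")
    cat("  richness:", min(object@richnessLevels), "-",
        max(object@richnessLevels),
        sprintf("(%d levels)", length(object@richnessLevels)), "\n")
    cat("  singletons: step", object@singletonStep, ", cap min(",
        object@singletonCapAbsolute, ",",
        object@singletonCapFraction, "* S )\n")
    cat("  doubletons:", object@doubletonFraction, "x singletons\n")
    cat("  distribution:", object@distribution, "\n")
    cat("  unevenness ratio:",
        if (is.na(object@unevennessRatio)) "none" else object@unevennessRatio,
        "| seed:", object@seed, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
    cat("SyntheticDataset:", length(sampleIDs(object@table)), "samples,",
        length(featureIDs(object@table)), "features,",
        "tree:", !is.null(object@tree), "\n")
    methods::show(object@config)
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat("CorrelationMatrix over", length(object@metricNames), "metrics:",
        paste(object@metricNames, collapse = ", "), "\n")
    cat("Spearman:\n")
    print(round(object@spearman, 3))
})
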