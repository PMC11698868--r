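#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' FeatureTable: a samples-by-features count container
#'
#' An S4 container for ASV/OTU count data, extending
#' \linkS4class{SummarizedExperiment}. Following Bioconductor convention,
#' features (ASVs/OTUs) are rows and samples are columns; the user-facing
#' accessors speak the amplicon idiom (\code{featureIDs}, \code{sampleIDs},
#' \code{counts}). Per-sample metadata lives in \code{colData}.
#'
#' Counts must be non-negative integers: unseen-species corrections
#' (Chao1, ACE), Brillouin and the singleton-based Robbins estimator are
#' undefined on fractional (e.g. rarefied-and-averaged) abundances, so
#' fractional tables are rejected at construction.
#'
#' @slot .. inherits all slots from SummarizedExperiment; the single assay
#'   is named \code{"counts"} and may be a base matrix or a sparse
#'   \code{dgCMatrix}.
#' @seealso [FeatureTable()], [readFeatureTable()], [computeAlphaDiversity()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

.validFeatureTable <- function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'counts' is missing")
    m <- SummarizedExperiment::assay(object, "counts")
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
    if (anyNA(v))
        msg <- c(msg, "counts contain NA")
    else {
        if (any(v < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(abs(v - round(v)) > 1e-8))
            msg <- c(msg, "counts must be integral (rarefied/fractional tables are not supported)")
    }
    if (nrow(object) > 0 &&
        (is.null(rownames(object)) || anyDuplicated(rownames(object))))
        msg <- c(msg, "feature identifiers must be present and unique")
    if (ncol(object) > 0 &&
        (is.null(colnames(object)) || anyDuplicated(colnames(object))))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (length(msg)) msg else TRUE
}
setValidity("FeatureTable", .validFeatureTable)

#' Construct a FeatureTable
#'
#' @param counts matrix (or sparse \code{dgCMatrix}) of non-negative integer
#'   counts. Orientation is given by \code{orientation}; internally features
#'   are stored as rows.
#' @param orientation \code{"samples_as_rows"} (default for simulator output)
#'   or \code{"features_as_rows"} (QIIME-style).
#' @param metadata optional data.frame of per-sample metadata; its rownames
#'   must be a subset of the sample identifiers.
#' @return a validated [FeatureTable-class] object
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 2L, 0L, 3L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("ASV1", "ASV2", "ASV3")))
#' ft <- FeatureTable(m)
#' sampleIDs(ft)
#' @export
FeatureTable <- function(counts, orientation = c("samples_as_rows", "features_as_rows"),
                         metadata = NULL) {
    orientation <- match.arg(orientation)
    if (orientation == "samples_as_rows")
        counts <- t(counts)
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
    if (!is.null(metadata)) {
        extra <- setdiff(rownames(metadata), colnames(counts))
        if (length(extra))
            stop("metadata rows not among sample identifiers: ",
                 paste(utils::head(extra, 5), collapse = ", "))
        for (cn in colnames(metadata))
            cd[[cn]] <- as.character(metadata[colnames(counts), cn])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    methods::new("FeatureTable", se)
}

#' AlphaMatrix: computed metric values per sample
#'
#' Holds the samples-by-metrics result of [computeAlphaDiversity()] as a
#' \linkS4class{SummarizedExperiment} with metrics as rows and samples as
#' columns. Each metric carries its category label
#' (richness, dominance, information or phylogenetic) in \code{rowData}.
#' Values a metric cannot produce for a sample (e.g. Pielou on a
#' single-taxon sample) are \code{NA}.
#'
#' @seealso [AlphaMatrix()], [alphaValues()], [minmaxNormalize()]
#' @export
setClass("AlphaMatrix", contains = "SummarizedExperiment")

.alphaCategories <- c("richness", "dominance", "information", "phylogenetic")

.validAlphaMatrix <- function(object) {
    msg <- character()
    if (!("alpha" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'alpha' is missing")
    rd <- SummarizedExperiment::rowData(object)
    if (!("category" %in% colnames(rd)))
        return("rowData must carry a 'category' column")
    bad <- setdiff(unique(rd$category), .alphaCategories)
    if (length(bad))
        msg <- c(msg, paste0("unknown categories: ", paste(bad, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "metric names must be present and unique")
    if (length(msg)) msg else TRUE
}
setValidity("AlphaMatrix", .validAlphaMatrix)

#' Construct an AlphaMatrix from a samples-by-metrics value matrix
#'
#' @param values numeric matrix, samples as rows, metrics as columns,
#'   \code{NA} marking undefined values
#' @param categories named character vector mapping every metric name to one
#'   of \code{"richness"}, \code{"dominance"}, \code{"information"},
#'   \code{"phylogenetic"}
#' @return an [AlphaMatrix-class]
#' @export
AlphaMatrix <- function(values, categories) {
    if (is.null(colnames(values)))
        stop("'values' must have metric names as column names")
    missing <- setdiff(colnames(values), names(categories))
    if (length(missing))
        stop("no category for metric(s): ", paste(missing, collapse = ", "))
    rd <- S4Vectors::DataFrame(category = unname(categories[colnames(values)]),
                               row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(alpha = t(values)), rowData = rd)
    methods::new("AlphaMatrix", se)
}

#' Synthetic community generator configuration
#'
#' Parameterises the synthetic ASV-table grid: per-sample richness levels,
#' the singleton schedule (arithmetic, capped both absolutely and as a
#' fraction of richness), the doubleton fraction, the abundance distribution
#' for the non-rare portion, an optional top-two dominance (unevenness)
#' ratio, a replicate multiplier and the random seed.
#'
#' @slot richnessLevels integer vector of per-sample target richness values
#' @slot singletonStep integer step of the singleton schedule
#' @slot singletonCapAbsolute absolute cap on singletons per sample
#' @slot singletonCapFraction cap on singletons as a fraction of richness
#' @slot doubletonFraction doubletons as a fraction of singletons
#' @slot distribution one of \code{"normal"}, \code{"negative_binomial"},
#'   \code{"uniform"}, \code{"exponential"}, \code{"poisson"}
#' @slot distributionParams named list of distribution parameters
#' @slot unevennessRatio top-two dominance ratio (\code{NA} = none)
#' @slot replicates grid replicate multiplier
#' @slot seed integer random seed
#' @seealso [generatorConfig()], [generateDataset()]
#' @export
setClass("GeneratorConfig",
    representation(richnessLevels = "integer",
                   singletonStep = "integer",
                   singletonCapAbsolute = "integer",
                   singletonCapFraction = "numeric",
                   doubletonFraction = "numeric",
                   distribution = "character",
                   distributionParams = "list",
                   unevennessRatio = "numeric",
                   replicates = "integer",
                   seed = "integer"))

.distributions <- c("normal", "negative_binomial", "uniform", "exponential",
                    "poisson")

.validGeneratorConfig <- function(object) {
    msg <- character()
    if (any(object@richnessLevels < 3L))
        msg <- c(msg, "all richness levels must be >= 3")
    if (object@singletonStep < 1L)
        msg <- c(msg, "singletonStep must be >= 1")
    if (object@singletonCapFraction <= 0 || object@singletonCapFraction >= 1)
        msg <- c(msg, "singletonCapFraction must lie in (0, 1)")
    if (object@doubletonFraction < 0)
        msg <- c(msg, "doubletonFraction must be >= 0")
    if (!(object@distribution %in% .distributions))
        msg <- c(msg, paste0("unknown distribution '", object@distribution,
                             "'; choose one of ",
                             paste(.distributions, collapse = ", ")))
    if (!is.na(object@unevennessRatio) && object@unevennessRatio <= 1)
        msg <- c(msg, "unevennessRatio, when set, must exceed 1")
    if (object@replicates < 1L)
        msg <- c(msg, "replicates must be >= 1")
    if (length(msg)) msg else TRUE
}
setValidity("GeneratorConfig", .validGeneratorConfig)

#' A generated synthetic dataset
#'
#' Bundles the generated [FeatureTable-class], the per-sample design table
#' (targets and realized values for richness, singletons, doubletons, the
#' distribution and the unevenness ratio), the configuration that produced
#' it, and an optional random phylogeny over the features.
#'
#' @slot table the generated FeatureTable (features are sample-private)
#' @slot design per-sample design \code{DataFrame}
#' @slot tree an \code{ape::phylo} over all feature identifiers, or NULL
#' @slot config the [GeneratorConfig-class] used
#' @export
setClass("SyntheticDataset",
    representation(table = "FeatureTable",
                   design = "DataFrame",
                   tree = "ANY",
                   config = "GeneratorConfig"))

setValidity("SyntheticDataset", function(object) {
    if (!is.null(object@tree) && !inherits(object@tree, "phylo"))
        return("tree must be NULL or an ape 'phylo' object")
    if (nrow(object@design) != length(sampleIDs(object@table)))
        return("design rows must match the number of samples")
    TRUE
})

#' Within-category correlation structure
#'
#' Pairwise Pearson and Spearman correlation matrices over the samples
#' complete for each metric pair, with the per-pair sample count.
#'
#' @slot metricNames character vector of metric names
#' @slot pearson,spearman symmetric correlation matrices (NA where undefined)
#' @slot n integer matrix of pairwise-complete sample counts
#' @export
setClass("CorrelationMatrix",
    representation(metricNames = "character",
                   pearson = "matrix",
                   spearman = "matrix",
                   n = "matrix"))

setValidity("CorrelationMatrix", function(object) {
    k <- length(object@metricNames)
    for (nm in c("pearson", "spearman", "n")) {
        m <- methods::slot(object, nm)
        if (!all(dim(m) == c(k, k)))
            return(paste0("'", nm, "' must be ", k, "x", k))
    }
    for (nm in c("pearson", "spearman")) {
        m <- methods::slot(object, nm)
        if (any(abs(m) > 1 + 1e-8, na.rm = TRUE))
            return(paste0("'", nm, "' entries must lie in [-1, 1]"))
        if (any(abs(m - t(m)) > 1e-12, na.rm = TRUE))
            return(paste0("'", nm, "' must be symmetric"))
    }
    TRUE
})
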