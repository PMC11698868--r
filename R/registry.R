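#' The metric registry
#'
#' The full suite is 19 metrics in four complementary categories:
#' 7 richness (observed_features, chao1, ace, fisher_alpha, margalef,
#' menhinick, robbins), 7 dominance (berger_parker, simpson, dominance,
#' enspie, gini, mcintosh, strong), 4 information (shannon, brillouin,
#' heip, pielou) and 1 phylogenetic (faith_pd). The registry drives
#' [computeAlphaDiversity()]: each entry carries the metric's category,
#' its callable, and whether it needs integer counts or a tree.
#'
#' @param includeTree include faith_pd (set \code{FALSE} when no phylogeny
#'   is available; the abundance-based 18 remain)
#' @param shannonBase logarithm base for shannon (heip and pielou are
#'   unaffected: heip is defined on natural-log entropy and pielou is
#'   base-invariant)
#' @param robbinsDenominator \code{"reads"} or \code{"features"}, see
#'   [robbins()]
#' @param aceRareThreshold rare/abundant cutoff for [ace()]
#' @return data.frame with columns \code{name}, \code{category},
#'   \code{requiresInteger}, \code{requiresTree} and list-column \code{fun}
#' @examples
#' table(metricRegistry()$category)
#' @export
metricRegistry <- function(includeTree = TRUE, shannonBase = 2,
                           robbinsDenominator = c("reads", "features"),
                           aceRareThreshold = 10) {
    robbinsDenominator <- match.arg(robbinsDenominator)
    force(shannonBase); force(aceRareThreshold)
    entry <- function(name, category, fun, int = FALSE, tree = FALSE)
        list(name = name, category = category, fun = fun,
             requiresInteger = int, requiresTree = tree)
    entries <- list(
        entry("observed_features", "richness", observedFeatures, int = TRUE),
        entry("chao1", "richness", chao1, int = TRUE),
        entry("ace", "richness",
              function(x) ace(x, rareThreshold = aceRareThreshold),
              int = TRUE),
        entry("fisher_alpha", "richness", fisherAlpha),
        entry("margalef", "richness", margalef),
        entry("menhinick", "richness", menhinick),
        entry("robbins", "richness",
              function(x) robbins(x, denominator = robbinsDenominator),
              int = TRUE),
        entry("berger_parker", "dominance", bergerParker),
        entry("simpson", "dominance", simpson),
        entry("dominance", "dominance", dominanceIndex),
        entry("enspie", "dominance", enspie),
        entry("gini", "dominance", gini),
        entry("mcintosh", "dominance", mcintosh),
        entry("strong", "dominance", strongDominance),
        entry("shannon", "information",
              function(x) shannon(x, base = shannonBase)),
        entry("brillouin", "information", brillouin, int = TRUE),
        entry("heip", "information", heip),
        entry("pielou", "information", pielou),
        entry("faith_pd", "phylogenetic", NULL, tree = TRUE))
    if (!includeTree)
        entries <- Filter(function(e) !e$requiresTree, entries)
    data.frame(
        name = vapply(entries, `[[`, "", "name"),
        category = vapply(entries, `[[`, "", "category"),
        requiresInteger = vapply(entries, `[[`, NA, "requiresInteger"),
        requiresTree = vapply(entries, `[[`, NA, "requiresTree"),
        fun = I(lapply(entries, `[[`, "fun")),
        stringsAsFactors = FALSE)
}

#' Compute the alpha-diversity matrix for a feature table
#'
#' Evaluates every registered metric on every sample. A metric failing on
#' one sample (all-zero sample, ACE with zero rare-group coverage, Fisher
#' on an all-singleton sample, S = 1 evenness) records a missing value for
#' that cell -- with the reason collected into a single summarising warning
#' -- rather than aborting the run.
#'
#' @param table a [FeatureTable-class]
#' @param tree rooted \code{ape::phylo} covering all observed features;
#'   required if the registry contains a tree-based metric
#' @param registry a [metricRegistry()] data.frame
#' @param includeRoot passed to [faithPD()]
#' @return an [AlphaMatrix-class] (samples x metrics, \code{NA} marking
#'   undefined cells)
#' @examples
#' m <- matrix(c(5L, 1L, 1L, 0L, 2L, 7L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' am <- computeAlphaDiversity(FeatureTable(m),
#'                             registry = metricRegistry(includeTree = FALSE))
#' alphaValues(am)[, "shannon"]
#' @export
computeAlphaDiversity <- function(table, tree = NULL,
                                  registry = metricRegistry(
                                      includeTree = !is.null(tree)),
                                  includeRoot = TRUE) {
    stopifnot(methods::is(table, "FeatureTable"))
    needTree <- any(registry$requiresTree)
    if (needTree && is.null(tree))
        stop("registry contains tree-based metrics (",
             paste(registry$name[registry$requiresTree], collapse = ", "),
             ") but no tree was given")
    m <- counts(table)
    sids <- colnames(m); fids <- rownames(m)
    if (needTree) {
        present <- fids[Matrix::rowSums(m) > 0]
        missing <- setdiff(present, tree$tip.label)
        if (length(missing))
            stop("features absent from the tree: ",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (and %d more)",
                                                  length(missing) - 5))
    }
    sparse <- methods::is(m, "sparseMatrix")
    if (sparse) m <- methods::as(m, "CsparseMatrix")
    vals <- matrix(NA_real_, length(sids), nrow(registry),
                   dimnames = list(sids, registry$name))
    failures <- character()
    for (j in seq_along(sids)) {
        if (sparse) {
            idx <- (m@p[j] + 1L):m@p[j + 1L]
            if (m@p[j] == m@p[j + 1L]) idx <- integer()
            cx <- m@x[idx]
            names(cx) <- fids[m@i[idx] + 1L]
        } else {
            cx <- m[, j]
            names(cx) <- fids
            cx <- cx[cx > 0]
        }
        if (length(cx) == 0L) {
            failures <- c(failures,
                          paste0(sids[j], ": all-zero sample, all metrics missing"))
            next
        }
        for (k in seq_len(nrow(registry))) {
            f <- registry$fun[[k]]
            res <- tryCatch({
                if (registry$requiresTree[k])
                    faithPD(cx, tree, includeRoot = includeRoot)
                else f(cx)
            }, error = function(e) {
                failures <<- c(failures, paste0(sids[j], "/",
                                                registry$name[k], ": ",
                                                conditionMessage(e)))
                NA_real_
            })
            vals[j, k] <- res
        }
    }
    if (length(failures))
        warning(length(failures), " metric value(s) recorded as missing:\n  ",
                paste(utils::head(failures, 10), collapse = "\n  "),
                if (length(failures) > 10) "\n  ...")
    AlphaMatrix(vals, stats::setNames(registry$category, registry$name))
}
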