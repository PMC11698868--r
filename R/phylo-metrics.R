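#' Faith's phylogenetic diversity
#'
#' The sum of branch lengths of the phylogenetic subtree spanning the taxa
#' observed in a sample. Abundance plays no role beyond presence/absence.
#' By default paths run all the way to the root (the convention of the
#' common amplicon toolchains), so even a single observed tip has positive
#' PD; with \code{includeRoot = FALSE} the edges above the most recent
#' common ancestor of the observed set are excluded.
#'
#' Implemented by a single postorder sweep that counts, for every edge, the
#' observed tips below it; an edge contributes its length when its subtree
#' holds at least one observed tip (and, for \code{includeRoot = FALSE},
#' not all of them).
#'
#' @param x named non-negative count vector; names are tip labels, zeros
#'   are absences
#' @param tree a rooted \code{ape::phylo} with branch lengths whose tips
#'   cover every positively observed feature
#' @param includeRoot logical; include the root-to-MRCA edges (default)
#' @return total branch length of the spanning subtree
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' faithPD(c(A = 3), tr)           # 2: tip edge plus its stem
#' faithPD(c(A = 1, B = 1, C = 1, D = 1), tr)  # 6: whole tree
#' @export
faithPD <- function(x, tree, includeRoot = TRUE) {
    if (!inherits(tree, "phylo"))
        stop("'tree' must be an ape 'phylo' object")
    if (is.null(tree$edge.length))
        stop("'tree' has no branch lengths")
    n <- .checkCounts(x, what = "abundances")
    if (is.null(names(x)))
        stop("'x' must be a named vector (names are tree tip labels)")
    obs <- unique(names(x)[x > 0])
    missing <- setdiff(obs, tree$tip.label)
    if (length(missing))
        stop("observed features absent from the tree: ",
             paste(missing, collapse = ", "))
    nt <- length(tree$tip.label)
    tr <- ape::reorder.phylo(tree, "postorder")
    nObs <- integer(nt + tree$Nnode)
    nObs[match(obs, tree$tip.label)] <- 1L
    parent <- tr$edge[, 1L]; child <- tr$edge[, 2L]
    for (e in seq_along(parent))                # postorder: children first
        nObs[parent[e]] <- nObs[parent[e]] + nObs[child[e]]
    below <- nObs[child]
    keep <- if (includeRoot) below > 0L
            else below > 0L & below < length(obs)
    sum(tr$edge.length[keep])
}

#' Total branch length of a tree
#'
#' The sum of all branch lengths; the upper bound of [faithPD()] for any
#' subset of tips.
#'
#' @param tree an \code{ape::phylo} with branch lengths
#' @export
totalBranchLength <- function(tree) {
    if (!inherits(tree, "phylo"))
        stop("'tree' must be an ape 'phylo' object")
    if (is.null(tree$edge.length))
        stop("'tree' has no branch lengths")
    sum(tree$edge.length)
}
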