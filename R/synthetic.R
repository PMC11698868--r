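## Synthetic ASV communities with exact control of the two key drivers of
## alpha-diversity metrics -- richness (S) and singletons (F1) -- plus
## doubletons, the abundance distribution of the non-rare portion, and the
## top-two dominance ratio. Non-rare counts are drawn as 3 + round(draw),
## an offset that guarantees a generated count never collides with the
## rare classes, so realized F1/F2 always equal their targets exactly.

.defaultDistributionParams <- list(
    normal = list(mean = 50, sd = 15),
    negative_binomial = list(mean = 50, dispersion = 0.5),
    uniform = list(min = 0, max = 100),
    exponential = list(mean = 50),
    poisson = list(lambda = 50))

#' Build a generator configuration
#'
#' Defaults encode the reference study grid: per-sample richness 50 to 500
#' in steps of 10; singletons 0 upward in steps of 3, capped at
#' min(100, 40\% of richness); doubletons at 40\% of the singletons; the
#' non-rare remainder drawn from one of five abundance distributions.
#' An optional unevenness ratio r > 1 rescales the most abundant taxon to
#' r times the second most abundant.
#'
#' @param richnessLevels integer vector of target richness values
#' @param singletonStep step of the singleton schedule
#' @param singletonCapAbsolute absolute singleton cap
#' @param singletonCapFraction fractional singleton cap (share of richness)
#' @param doubletonFraction doubletons as a fraction of singletons
#' @param distribution abundance distribution of the non-rare taxa
#' @param distributionParams named list overriding the distribution's
#'   default parameters (\code{normal}: mean 50, sd 15, truncated at 0;
#'   \code{negative_binomial}: mean 50, dispersion 0.5; \code{uniform}:
#'   0--100; \code{exponential}: mean 50; \code{poisson}: lambda 50)
#' @param unevennessRatio top-two dominance ratio (NA = leave as drawn)
#' @param replicates how many copies of the design grid to generate
#' @param seed integer random seed
#' @return a validated [GeneratorConfig-class]
#' @examples
#' generatorConfig(distribution = "poisson", seed = 1)
#' @export
generatorConfig <- function(richnessLevels = seq(50L, 500L, by = 10L),
                            singletonStep = 3L,
                            singletonCapAbsolute = 100L,
                            singletonCapFraction = 0.40,
                            doubletonFraction = 0.40,
                            distribution = c("poisson", "normal",
                                             "negative_binomial", "uniform",
                                             "exponential"),
                            distributionParams = list(),
                            unevennessRatio = NA_real_,
                            replicates = 1L,
                            seed = 1L) {
    distribution <- match.arg(distribution)
    params <- .defaultDistributionParams[[distribution]]
    unknown <- setdiff(names(distributionParams), names(params))
    if (length(unknown))
        stop("unknown parameter(s) for ", distribution, ": ",
             paste(unknown, collapse = ", "))
    params[names(distributionParams)] <- distributionParams
    methods::new("GeneratorConfig",
        richnessLevels = as.integer(richnessLevels),
        singletonStep = as.integer(singletonStep),
        singletonCapAbsolute = as.integer(singletonCapAbsolute),
        singletonCapFraction = singletonCapFraction,
        doubletonFraction = doubletonFraction,
        distribution = distribution,
        distributionParams = params,
        unevennessRatio = as.numeric(unevennessRatio),
        replicates = as.integer(replicates),
        seed = as.integer(seed))
}

#' Enumerate the per-sample design grid
#'
#' The Cartesian grid of richness levels and singleton targets
#' \{0, step, 2 step, ...\} up to min(absolute cap, floor(fraction * S)),
#' with doubleton targets rounded from the doubleton fraction. Designs
#' whose non-rare remainder S - F1 - F2 would vanish are removed.
#'
#' @param config a [GeneratorConfig-class]
#' @return data.frame with one row per sample: \code{sample_id}, targets
#'   \code{S}, \code{F1}, \code{F2}, \code{distribution},
#'   \code{unevenness_ratio}, \code{replicate}
#' @examples
#' nrow(subset(buildDesignGrid(generatorConfig()), S == 50))  # 7 designs
#' @export
buildDesignGrid <- function(config) {
    stopifnot(methods::is(config, "GeneratorConfig"))
    rows <- list()
    for (rep in seq_len(config@replicates)) {
        for (S in config@richnessLevels) {
            cap <- min(config@singletonCapAbsolute,
                       floor(config@singletonCapFraction * S))
            f1s <- seq(0L, cap, by = config@singletonStep)
            for (F1 in f1s) {
                F2 <- as.integer(round(config@doubletonFraction * F1))
                if (S - F1 - F2 < 1L) next
                rows[[length(rows) + 1L]] <- data.frame(
                    S = as.integer(S), F1 = F1, F2 = F2,
                    replicate = rep, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows)) stop("design grid is empty")
    grid <- do.call(rbind, rows)
    grid$sample_id <- sprintf("S%03d_a%03d_r%02d", grid$S, grid$F1,
                              grid$replicate)
    grid$distribution <- config@distribution
    grid$unevenness_ratio <- config@unevennessRatio
    grid[c("sample_id", "S", "F1", "F2", "distribution",
           "unevenness_ratio", "replicate")]
}

.drawNonRare <- function(n, distribution, p) {
    draw <- switch(distribution,
        normal = pmax(stats::rnorm(n, p$mean, p$sd), 0),
        negative_binomial = stats::rnbinom(n, size = p$dispersion,
                                           mu = p$mean),
        uniform = stats::runif(n, p$min, p$max),
        exponential = stats::rexp(n, rate = 1 / p$mean),
        poisson = stats::rpois(n, p$lambda),
        stop("unknown distribution '", distribution, "'"))
    3L + as.integer(round(draw))
}

#' Generate one sample from a design row
#'
#' Exactly \code{F1} features receive count 1 and \code{F2} count 2; the
#' remaining S - F1 - F2 receive 3 + round(draw) from the configured
#' distribution (draws truncated at zero), so the rare-class targets are
#' realized exactly.
#'
#' @param design one row of [buildDesignGrid()] output (or any list with
#'   \code{sample_id}, \code{S}, \code{F1}, \code{F2})
#' @param config a [GeneratorConfig-class]
#' @param seed optional seed; \code{NULL} uses the current RNG stream
#' @return named integer count vector (labels
#'   \code{ASV_<sample_id>_<k>})
#' @export
generateSample <- function(design, config, seed = NULL) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    S <- as.integer(design$S); F1 <- as.integer(design$F1)
    F2 <- as.integer(design$F2)
    nNon <- S - F1 - F2
    if (nNon < 1L)
        stop("design leaves no non-rare taxa (S - F1 - F2 < 1)")
    x <- c(rep(1L, F1), rep(2L, F2),
           .drawNonRare(nNon, config@distribution,
                        config@distributionParams))
    names(x) <- paste0("ASV_", design$sample_id, "_", seq_len(S))
    x
}

#' Impose a top-two dominance ratio
#'
#' Rescales the most abundant feature to \code{round(ratio * second)} reads,
#' leaving every other count -- in particular the singleton and doubleton
#' tallies -- untouched. For integer ratios the realized max/second ratio
#' is exact. Idempotent: reapplying the same ratio changes nothing.
#'
#' @param x named count vector with at least two observed taxa
#' @param ratio dominance ratio > 1
#' @return modified count vector
#' @export
applyUnevenness <- function(x, ratio) {
    n <- .checkCounts(x, integer = TRUE)
    if (length(n) < 2L)
        stop("unevenness needs at least two observed taxa")
    if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 1)
        stop("'ratio' must be a single value > 1")
    pos <- which(x > 0)
    imax <- pos[which.max(x[pos])]
    second <- max(x[pos[pos != imax]])
    if (second < 3)
        stop("second most abundant count is below 3; rescaling the top ",
             "feature would collide with singleton/doubleton bookkeeping")
    x[imax] <- as.integer(round(ratio * second))
    x
}

#' Generate a full synthetic dataset
#'
#' Runs the whole design grid, applies the configured unevenness ratio,
#' and assembles one sparse [FeatureTable-class] over the union of the
#' per-sample feature sets (features are sample-private: each sample has
#' its own ASV identifiers, since alpha diversity is a within-sample
#' quantity). The attached design table records targets and realized
#' values. Fully reproducible from \code{config@seed}.
#'
#' @param config a [GeneratorConfig-class]
#' @param tree logical; also build a random phylogeny over all features
#'   via [generateRandomTree()] (intended for modest grids)
#' @return a [SyntheticDataset-class]
#' @examples
#' cfg <- generatorConfig(richnessLevels = c(50L, 60L), seed = 7)
#' sds <- generateDataset(cfg)
#' designTable(sds)[1:3, ]
#' @export
generateDataset <- function(config, tree = FALSE) {
    stopifnot(methods::is(config, "GeneratorConfig"))
    grid <- buildDesignGrid(config)
    set.seed(config@seed)
    samples <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        x <- generateSample(grid[i, ], config)
        if (!is.na(config@unevennessRatio))
            x <- applyUnevenness(x, config@unevennessRatio)
        samples[[i]] <- x
    }
    featIds <- unlist(lapply(samples, names), use.names = FALSE)
    lens <- lengths(samples)
    mat <- Matrix::sparseMatrix(
        i = seq_along(featIds),
        j = rep(seq_len(nrow(grid)), times = lens),
        x = as.numeric(unlist(samples, use.names = FALSE)),
        dims = c(length(featIds), nrow(grid)),
        dimnames = list(featIds, grid$sample_id))
    ft <- FeatureTable(mat, orientation = "features_as_rows")
    grid$realized_S <- vapply(samples, function(s) sum(s > 0), 0L)
    grid$realized_F1 <- vapply(samples, function(s) sum(s == 1L), 0L)
    grid$realized_F2 <- vapply(samples, function(s) sum(s == 2L), 0L)
    grid$top_two_ratio <- vapply(samples, function(s) {
        srt <- sort(s, decreasing = TRUE)
        if (length(srt) < 2L) NA_real_ else srt[1L] / srt[2L]
    }, 0)
    phylo <- NULL
    if (isTRUE(tree))
        phylo <- generateRandomTree(featIds, seed = config@seed + 1L)
    methods::new("SyntheticDataset", table = ft,
                 design = S4Vectors::DataFrame(grid, row.names = grid$sample_id),
                 tree = phylo, config = config)
}

#' Generate a random phylogeny over feature identifiers
#'
#' A random rooted binary topology (recursive random splits) with
#' independent exponential(1) branch lengths, so every abundance-based
#' test fixture can also exercise phylogenetic diversity. Reproducible
#' from the seed.
#'
#' @param featureIds at least two tip labels
#' @param seed integer seed
#' @return an \code{ape::phylo}
#' @export
generateRandomTree <- function(featureIds, seed = 1L) {
    n <- length(featureIds)
    if (n < 2L) stop("need at least two features to build a tree")
    set.seed(as.integer(seed))
    tr <- ape::rtree(n, rooted = TRUE, tip.label = featureIds,
                     br = stats::rexp)
    tr
}
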