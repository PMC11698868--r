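## Analysis layer: normalisation, within-category correlation structure,
## dominance-vs-Berger-Parker regressions, LOESS fits, group testing, and
## the key-factor (richness/singleton) behaviour summary.

#' Min-max normalise an AlphaMatrix
#'
#' Rescales every metric column linearly to [0, 1] across samples so
#' metrics with different natural ranges become comparable. Constant
#' columns map to all zeros with a warning; missing values propagate.
#'
#' @param matrix an [AlphaMatrix-class] with at least two samples
#' @return an [AlphaMatrix-class] of normalised values
#' @export
minmaxNormalize <- function(matrix) {
    stopifnot(methods::is(matrix, "AlphaMatrix"))
    v <- alphaValues(matrix)
    if (nrow(v) < 2L)
        stop("min-max normalisation needs at least two samples")
    constant <- character()
    for (j in seq_len(ncol(v))) {
        rng <- range(v[, j], na.rm = TRUE)
        if (!all(is.finite(rng))) next               # all-missing column
        if (rng[1] == rng[2]) {
            v[!is.na(v[, j]), j] <- 0
            constant <- c(constant, colnames(v)[j])
        } else {
            v[, j] <- (v[, j] - rng[1]) / (rng[2] - rng[1])
        }
    }
    if (length(constant))
        warning("constant metric column(s) mapped to 0: ",
                paste(constant, collapse = ", "))
    AlphaMatrix(v, metricCategories(matrix))
}

#' Within-category correlation structure
#'
#' Pairwise Pearson and Spearman coefficients among the metrics of one
#' category, over the samples complete for each pair (pairwise deletion:
#' evenness metrics are missing for single-taxon samples, and dropping
#' whole samples would bias the remaining pairs). Pairs involving a
#' constant metric are marked missing.
#'
#' @param matrix an [AlphaMatrix-class]
#' @param category one of \code{"richness"}, \code{"dominance"},
#'   \code{"information"}, \code{"phylogenetic"}; or \code{"all"}
#' @param metrics optional explicit metric subset (overrides category)
#' @return a [CorrelationMatrix-class]
#' @export
correlateCategory <- function(matrix, category = c("richness", "dominance",
                                                   "information",
                                                   "phylogenetic", "all"),
                              metrics = NULL) {
    stopifnot(methods::is(matrix, "AlphaMatrix"))
    v <- alphaValues(matrix)
    if (is.null(metrics)) {
        category <- match.arg(category)
        cats <- metricCategories(matrix)
        metrics <- if (category == "all") names(cats)
                   else names(cats)[cats == category]
    }
    absent <- setdiff(metrics, colnames(v))
    if (length(absent))
        stop("metric(s) not in the matrix: ", paste(absent, collapse = ", "))
    v <- v[, metrics, drop = FALSE]
    if (sum(stats::complete.cases(v)) < 3L && nrow(v) < 3L)
        stop("need at least 3 samples")
    pe <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                      method = "pearson"))
    sp <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                      method = "spearman"))
    ok <- !is.na(v)
    n <- crossprod(ok)
    storage.mode(n) <- "integer"
    methods::new("CorrelationMatrix", metricNames = metrics,
                 pearson = pe, spearman = sp, n = n)
}

#' Regress a metric on Berger-Parker dominance
#'
#' Ordinary least squares of a response metric on the berger_parker column.
#' With \code{transform = "exponential"} the model is fitted on
#' log(response) -- appropriate for ENSPIE, whose dependence on dominance
#' is exponential rather than linear -- and slope, intercept and R-squared
#' are reported on that log scale.
#'
#' @param matrix an [AlphaMatrix-class] containing \code{berger_parker}
#' @param response name of the response metric column
#' @param transform \code{"identity"} or \code{"exponential"}
#' @return a \code{RegressionFit} list: predictor, response, transform,
#'   slope, intercept, r_squared, n
#' @export
regressOnBergerParker <- function(matrix, response,
                                  transform = c("identity", "exponential")) {
    transform <- match.arg(transform)
    stopifnot(methods::is(matrix, "AlphaMatrix"))
    v <- alphaValues(matrix)
    for (nm in c("berger_parker", response))
        if (!(nm %in% colnames(v)))
            stop("metric '", nm, "' not in the matrix")
    x <- v[, "berger_parker"]; y <- v[, response]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L)
        stop("need at least 3 paired complete observations")
    if (transform == "exponential") {
        bad <- which(y <= 0)
        if (length(bad))
            stop("non-positive response under exponential transform for ",
                 "sample(s): ",
                 paste(utils::head(names(bad), 5), collapse = ", "))
        y <- log(y)
    }
    fit <- stats::lm(y ~ x)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((y - mean(y))^2)
    structure(list(predictor = "berger_parker", response = response,
                   transform = transform,
                   slope = unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]),
                   r_squared = 1 - ss_res / ss_tot,
                   n = length(x)),
              class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
    cat(sprintf("RegressionFit: %s%s ~ %s  (n = %d)\n",
                if (x$transform == "exponential") "log " else "",
                x$response, x$predictor, x$n))
    cat(sprintf("  slope %.6g, intercept %.6g, R^2 %.4f\n",
                x$slope, x$intercept, x$r_squared))
    invisible(x)
}

#' LOESS fit with coefficient of determination
#'
#' Tricube-weighted local polynomial regression (\code{stats::loess}) of y
#' on x, returning the fitted values aligned to the inputs and an
#' R-squared defined as 1 - SS_res/SS_tot on those fitted values (LOESS
#' has no canonical R-squared; this residual definition mirrors its use
#' for linear fits).
#'
#' @param x,y numeric vectors of equal length, n >= 10, x not all equal
#' @param span LOESS span
#' @param degree local polynomial degree (1 or 2)
#' @return a \code{LoessFit} list: span, degree, fitted, r_squared, n
#' @export
loessFit <- function(x, y, span = 0.75, degree = 2) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 10L) stop("need at least 10 complete observations")
    if (diff(range(x)) == 0) stop("x values are all equal")
    fit <- stats::loess(y ~ x, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    fitted <- stats::fitted(fit)
    ss_res <- sum((y - fitted)^2)
    ss_tot <- sum((y - mean(y))^2)
    structure(list(span = span, degree = degree, x = x, y = y,
                   fitted = fitted, r_squared = 1 - ss_res / ss_tot,
                   n = length(x)),
              class = "LoessFit")
}

#' @export
print.LoessFit <- function(x, ...) {
    cat(sprintf("LoessFit: span %.2f, degree %d, n = %d, R^2 %.4f\n",
                x$span, x$degree, x$n, x$r_squared))
    invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on (groups - 1)
#' degrees of freedom. Degenerate all-equal inputs (for which the tie
#' correction annihilates H) are rejected explicitly.
#'
#' @param values numeric observations
#' @param groups group labels, same length as \code{values}
#' @return list with \code{H}, \code{p}, \code{df}
#' @examples
#' kruskalWallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))$H  # 2.4
#' @export
kruskalWallis <- function(values, groups) {
    if (length(values) != length(groups))
        stop("values and groups must have equal length")
    keep <- !is.na(values) & !is.na(groups)
    values <- values[keep]; groups <- factor(groups[keep])
    if (nlevels(groups) < 2L)
        stop("need at least two groups")
    if (length(values) < 3L)
        stop("need at least 3 observations in total")
    if (diff(range(values)) == 0)
        stop("all observations are identical: H is undefined under the ",
             "tie correction")
    kt <- stats::kruskal.test(values, groups)
    list(H = unname(kt$statistic), p = kt$p.value,
         df = unname(kt$parameter))
}

#' Top-two abundance ratio
#'
#' The second most abundant count over the most abundant, in (0, 1]; the
#' quantity the dominance category tracks most directly.
#'
#' @param x count vector with at least two observed taxa
#' @export
topTwoRatio <- function(x) {
    n <- .checkCounts(x)
    if (length(n) < 2L) stop("need at least two observed taxa")
    srt <- sort(n, decreasing = TRUE)
    srt[2L] / srt[1L]
}

#' Key-factor behaviour summary
#'
#' How each metric tracks the two key drivers of alpha diversity in
#' amplicon data: total richness S and the singleton count F1. Reports
#' Spearman rank correlations of every metric against both, with a
#' monotonicity direction label.
#'
#' @param matrix an [AlphaMatrix-class]
#' @param design data.frame (or DataFrame) with columns \code{sample_id},
#'   \code{S}, \code{F1} covering every sample of the matrix
#' @param flatThreshold |rho| at or below which a trend is labelled flat
#' @return data.frame: metric, category, spearman_S, spearman_F1,
#'   trend_S, trend_F1
#' @export
keyFactorSummary <- function(matrix, design, flatThreshold = 0.1) {
    stopifnot(methods::is(matrix, "AlphaMatrix"))
    design <- as.data.frame(design)
    v <- alphaValues(matrix)
    missing <- setdiff(rownames(v), design$sample_id)
    if (length(missing))
        stop("design does not cover sample(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
    idx <- match(rownames(v), design$sample_id)
    S <- design$S[idx]; F1 <- design$F1[idx]
    lab <- function(r) {
        if (is.na(r)) "undefined"
        else if (r > flatThreshold) "increasing"
        else if (r < -flatThreshold) "decreasing"
        else "flat"
    }
    cats <- metricCategories(matrix)
    out <- data.frame(metric = colnames(v),
                      category = unname(cats[colnames(v)]),
                      spearman_S = NA_real_, spearman_F1 = NA_real_,
                      trend_S = "", trend_F1 = "",
                      stringsAsFactors = FALSE)
    for (j in seq_len(ncol(v))) {
        out$spearman_S[j] <- suppressWarnings(
            stats::cor(v[, j], S, method = "spearman",
                       use = "pairwise.complete.obs"))
        out$spearman_F1[j] <- suppressWarnings(
            stats::cor(v[, j], F1, method = "spearman",
                       use = "pairwise.complete.obs"))
        out$trend_S[j] <- lab(out$spearman_S[j])
        out$trend_F1[j] <- lab(out$spearman_F1[j])
    }
    out
}

#' The recommended reporting panel
#'
#' One metric from each complementary category: observed_features
#' (richness), robbins (unseen-taxon likelihood), berger_parker
#' (dominance), shannon (information) and, when available, faith_pd
#' (phylogenetics). Returns the per-sample panel and, if a grouping is
#' supplied, per-group median and quartiles of every panel metric.
#'
#' @param matrix an [AlphaMatrix-class] containing at least
#'   observed_features, robbins, berger_parker and shannon
#' @param metadata optional data.frame of per-sample metadata (rownames =
#'   sample ids)
#' @param group optional metadata column name to summarise by
#' @return list of class \code{RecommendedPanel}: \code{panel} data.frame,
#'   \code{summary} (NULL without grouping), \code{note}
#' @export
recommendedPanel <- function(matrix, metadata = NULL, group = NULL) {
    stopifnot(methods::is(matrix, "AlphaMatrix"))
    v <- alphaValues(matrix)
    need <- c("observed_features", "robbins", "berger_parker", "shannon")
    absent <- setdiff(need, colnames(v))
    if (length(absent))
        stop("required panel metric(s) absent: ",
             paste(absent, collapse = ", "))
    cols <- need
    note <- NULL
    if ("faith_pd" %in% colnames(v)) {
        cols <- c(need[1:3], "faith_pd", "shannon")
    } else {
        note <- paste("faith_pd not available: panel covers richness,",
                      "dominance and information only; supply a phylogeny",
                      "to complete it")
        message(note)
    }
    panel <- data.frame(sample_id = rownames(v), v[, cols, drop = FALSE],
                        check.names = FALSE, stringsAsFactors = FALSE)
    summ <- NULL
    if (!is.null(group)) {
        if (is.null(metadata) || !(group %in% colnames(metadata)))
            stop("grouping column '", group, "' not found in metadata")
        g <- metadata[panel$sample_id, group]
        rows <- list()
        for (metric in cols) {
            for (lev in unique(g[!is.na(g)])) {
                q <- stats::quantile(panel[g == lev, metric],
                                     probs = c(0.25, 0.5, 0.75),
                                     na.rm = TRUE, names = FALSE)
                rows[[length(rows) + 1L]] <- data.frame(
                    metric = metric, group = lev, q1 = q[1],
                    median = q[2], q3 = q[3], stringsAsFactors = FALSE)
            }
        }
        summ <- do.call(rbind, rows)
    }
    structure(list(panel = panel, summary = summ, note = note),
              class = "RecommendedPanel")
}

#' @export
print.RecommendedPanel <- function(x, ...) {
    cat("Recommended alpha-diversity panel:",
        paste(setdiff(colnames(x$panel), "sample_id"), collapse = ", "),
        "\n")
    cat(nrow(x$panel), "samples\n")
    if (!is.null(x$note)) cat("note:", x$note, "\n")
    if (!is.null(x$summary)) {
        cat("per-group summary:\n")
        print(x$summary, row.names = FALSE)
    }
    invisible(x)
}
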