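## Abundance-based alpha-diversity metrics. Every function takes one
## sample's count vector; zeros are absences and are dropped before any
## computation, so padding a vector with zeros never changes a value.

# Validate a count vector and return the positive entries.
# integer = TRUE for metrics built on singleton/doubleton tallies or
# factorials, which are meaningless on fractional counts.
.checkCounts <- function(x, integer = FALSE, what = "counts") {
    if (!is.numeric(x) || length(x) == 0L)
        stop(what, " must be a non-empty numeric vector")
    if (anyNA(x) || any(!is.finite(x)))
        stop(what, " contain NA or non-finite values")
    if (any(x < 0))
        stop(what, " must be non-negative (offending index ",
             which(x < 0)[1L], ")")
    if (integer && any(abs(x - round(x)) > 1e-9))
        stop(what, " must be integers for this metric (offending index ",
             which(abs(x - round(x)) > 1e-9)[1L], ")")
    pos <- x[x > 0]
    if (length(pos) == 0L)
        stop("all-zero count vector: no observed taxa")
    pos
}

#' Observed features (richness S)
#'
#' The number of taxa (ASVs/OTUs) with at least one read.
#'
#' @param x non-negative count vector for one sample
#' @return integer S
#' @examples observedFeatures(c(5, 1, 0, 2))
#' @family richness metrics
#' @export
observedFeatures <- function(x) length(.checkCounts(x))

#' Singleton and doubleton counts
#'
#' Taxa observed exactly once (singletons, F1) or exactly twice
#' (doubletons, F2). These drive the unseen-species corrections in
#' [chao1()], [ace()] and [robbins()].
#'
#' @param x non-negative integer count vector
#' @return integer tally
#' @examples singletonCount(c(1, 1, 2, 5)); doubletonCount(c(1, 1, 2, 5))
#' @family richness metrics
#' @export
singletonCount <- function(x) sum(.checkCounts(x, integer = TRUE) == 1)

#' @rdname singletonCount
#' @export
doubletonCount <- function(x) sum(.checkCounts(x, integer = TRUE) == 2)

#' Chao1 richness estimator
#'
#' S + F1^2 / (2 F2), the classic point estimate of total richness from the
#' singleton/doubleton ratio. When no doubletons are present the
#' bias-corrected form S + F1 (F1 - 1) / (2 (F2 + 1)) is used, which is the
#' standard fallback and coincides with the classic form at F1 = 0.
#'
#' @param x non-negative integer count vector
#' @return estimated richness, always >= S
#' @examples chao1(c(4, 3, 2, 2, 1, 1, 1, 1))  # 12
#' @family richness metrics
#' @export
chao1 <- function(x) {
    n <- .checkCounts(x, integer = TRUE)
    s <- length(n)
    f1 <- sum(n == 1); f2 <- sum(n == 2)
    if (f2 > 0) s + f1^2 / (2 * f2)
    else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE (abundance-based coverage estimator)
#'
#' Chao-Lee coverage estimator splitting taxa at \code{rareThreshold} reads
#' into "rare" and "abundant" groups:
#' \deqn{ACE = S_{abund} + S_{rare}/C_{rare} + (F_1/C_{rare}) \gamma^2}
#' where \eqn{C_{rare} = 1 - F_1/N_{rare}} is the sample coverage of the
#' rare group and \eqn{\gamma^2} the rare-group coefficient of variation,
#' floored at zero:
#' \eqn{\gamma^2 = \max(S_{rare}/C_{rare} \sum i(i-1)F_i /
#' (N_{rare}(N_{rare}-1)) - 1,\ 0)}.
#'
#' @param x non-negative integer count vector
#' @param rareThreshold rare/abundant cutoff k (conventionally 10 reads)
#' @return estimated richness; errors with "ACE undefined" when every rare
#'   taxon is a singleton (coverage zero)
#' @examples ace(c(15, 12, 1, 1, 2))  # 8
#' @family richness metrics
#' @export
ace <- function(x, rareThreshold = 10) {
    n <- .checkCounts(x, integer = TRUE)
    k <- rareThreshold
    rare <- n[n <= k]
    sAbund <- sum(n > k)
    sRare <- length(rare)
    if (sRare == 0L) return(sAbund)      # no rare group: nothing to correct
    nRare <- sum(rare)
    f1 <- sum(rare == 1)
    cRare <- 1 - f1 / nRare
    if (cRare == 0)
        stop("ACE undefined: all rare taxa are singletons (rare-group coverage is zero)")
    fi <- tabulate(rare, nbins = k)
    i <- seq_len(k)
    gamma2 <- 0
    if (nRare > 1)
        gamma2 <- max(sRare / cRare * sum(i * (i - 1) * fi) /
                      (nRare * (nRare - 1)) - 1, 0)
    sAbund + sRare / cRare + f1 / cRare * gamma2
}

#' Fisher's log-series alpha
#'
#' The parameter alpha of Fisher's log-series abundance model, i.e. the
#' unique positive root of \eqn{S = \alpha \ln(1 + N/\alpha)}. Solved by
#' bracketed root search on \eqn{[10^{-8}, 10^{8}]}; the returned value
#' satisfies the residual bound \code{|S - alpha*log(1 + N/alpha)| < tol}.
#'
#' @param x non-negative count vector with at least two taxa and N > S
#' @param tol residual tolerance of the root
#' @return alpha > 0
#' @examples fisherAlpha(c(2, 2))
#' @family richness metrics
#' @export
fisherAlpha <- function(x, tol = 1e-10) {
    n <- .checkCounts(x)
    s <- length(n); N <- sum(n)
    if (s < 2) stop("Fisher's alpha requires at least two observed taxa")
    if (N <= s)
        stop("Fisher's alpha diverges: every taxon is a singleton (S = N)")
    f <- function(a) s - a * log1p(N / a)
    # f(a) decreases in a: small alpha underestimates S, large overestimates
    root <- stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = tol * 1e-2,
                           maxiter = 200L)$root
    if (abs(f(root)) >= tol)
        stop("Fisher's alpha root search failed to meet tolerance")
    root
}

#' Margalef richness
#'
#' (S - 1) / ln(N): richness corrected for sampling effort through the
#' total read count. Returns 0 for a single-taxon sample (the numerator is
#' zero; the N = 1 case is handled by the same convention).
#'
#' @inheritParams observedFeatures
#' @examples margalef(c(50, 30, 20))
#' @family richness metrics
#' @export
margalef <- function(x) {
    n <- .checkCounts(x)
    s <- length(n)
    if (s == 1L) return(0)
    (s - 1) / log(sum(n))
}

#' Menhinick richness
#'
#' S / sqrt(N).
#'
#' @inheritParams observedFeatures
#' @examples menhinick(c(8, 4, 2, 2))  # 1
#' @family richness metrics
#' @export
menhinick <- function(x) {
    n <- .checkCounts(x)
    length(n) / sqrt(sum(n))
}

#' Robbins estimator of unseen-taxon probability
#'
#' The probability that the next read belongs to a previously unobserved
#' taxon, estimated from the singleton count. Two denominators are in use:
#' the \code{"reads"} variant F1/(N + 1) is Robbins' original estimator and
#' the form computed by the common amplicon toolchains; the
#' \code{"features"} variant F1/(S + 1) expresses singletons as a share of
#' the observed taxa.
#'
#' @param x non-negative integer count vector
#' @param denominator \code{"reads"} (default) or \code{"features"}
#' @examples
#' robbins(c(1, 1, 1, 5))                       # 3/9
#' robbins(c(1, 1, 1, 5), "features")           # 3/5
#' @family richness metrics
#' @export
robbins <- function(x, denominator = c("reads", "features")) {
    denominator <- match.arg(denominator)
    n <- .checkCounts(x, integer = TRUE)
    f1 <- sum(n == 1)
    if (denominator == "reads") f1 / (sum(n) + 1)
    else f1 / (length(n) + 1)
}

#' Berger-Parker dominance
#'
#' The relative abundance of the single most abundant taxon, max(n_i)/N:
#' the simplest dominance measure, and the reference metric of the
#' dominance category.
#'
#' @inheritParams observedFeatures
#' @return value in (0, 1]
#' @examples bergerParker(c(8, 1, 1))  # 0.8
#' @family dominance metrics
#' @export
bergerParker <- function(x) {
    n <- .checkCounts(x)
    max(n) / sum(n)
}

#' Simpson diversity (1 - D)
#'
#' One minus the probability that two randomly drawn reads belong to the
#' same taxon: \eqn{1 - \sum p_i^2}, in [0, 1).
#'
#' @inheritParams observedFeatures
#' @examples simpson(c(8, 1, 1))  # 0.34
#' @family dominance metrics
#' @export
simpson <- function(x) {
    n <- .checkCounts(x)
    p <- n / sum(n)
    1 - sum(p^2)
}

#' Dominance index (Simpson's D)
#'
#' \eqn{\sum p_i^2}; the complement of [simpson()].
#'
#' @inheritParams observedFeatures
#' @examples dominanceIndex(c(8, 1, 1))  # 0.66
#' @family dominance metrics
#' @export
dominanceIndex <- function(x) {
    n <- .checkCounts(x)
    p <- n / sum(n)
    sum(p^2)
}

#' ENSPIE effective species number
#'
#' The inverse Simpson index \eqn{1 / \sum p_i^2}: the number of equally
#' abundant taxa that would produce the observed probability of
#' interspecific encounter. Ranges over [1, S].
#'
#' @inheritParams observedFeatures
#' @examples enspie(rep(3, 10))  # 10
#' @family dominance metrics
#' @export
enspie <- function(x) {
    n <- .checkCounts(x)
    p <- n / sum(n)
    1 / sum(p^2)
}

#' Gini inequality of the abundance distribution
#'
#' Half the mean absolute difference between abundances, relative to the
#' mean abundance:
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 S^2 \bar{x})},
#' equivalently the area between the sample's Lorenz curve and the perfect
#' evenness diagonal (normalised). 0 means perfect evenness; the maximum
#' for S taxa is 1 - 1/S. Computed via the sorted-rank identity.
#'
#' @inheritParams observedFeatures
#' @examples gini(c(3, 1))  # 0.25
#' @family dominance metrics
#' @export
gini <- function(x) {
    n <- sort(.checkCounts(x))
    s <- length(n)
    if (s == 1L) return(0)
    # G = 2 * sum(i * x_(i)) / (S * sum(x)) - (S + 1)/S  (ascending order)
    2 * sum(seq_len(s) * n) / (s * sum(n)) - (s + 1) / s
}

#' McIntosh dominance
#'
#' \eqn{(N - U)/(N - \sqrt{N})} with \eqn{U = \sqrt{\sum n_i^2}}, the
#' Euclidean distance of the sample from the origin in taxon space. 0 when
#' a single taxon holds all reads, 1 when every read is its own taxon.
#' Undefined for N < 2 (zero denominator).
#'
#' @inheritParams observedFeatures
#' @examples mcintosh(c(8, 1, 1))
#' @family dominance metrics
#' @export
mcintosh <- function(x) {
    n <- .checkCounts(x)
    N <- sum(n)
    if (N < 2) stop("McIntosh is undefined for N < 2 (zero denominator)")
    (N - sqrt(sum(n^2))) / (N - sqrt(N))
}

#' Strong dominance
#'
#' The maximal vertical gap between the sample's cumulative descending
#' abundance curve and the perfect-evenness line:
#' \eqn{\max_i (b_i/N - i/S)} with \eqn{b_i} the cumulative counts after
#' sorting descending. 0 for a perfectly even sample.
#'
#' @inheritParams observedFeatures
#' @examples strongDominance(c(8, 1, 1))
#' @family dominance metrics
#' @export
strongDominance <- function(x) {
    n <- sort(.checkCounts(x), decreasing = TRUE)
    s <- length(n)
    # exact integer cumulative counts before any division
    max(cumsum(n) / sum(n) - seq_len(s) / s)
}

#' Shannon entropy
#'
#' \eqn{-\sum p_i \log_b p_i}. Reported in bits (base 2) by default, the
#' convention of the major amplicon toolchains; \code{base = exp(1)} gives
#' nats.
#'
#' @inheritParams observedFeatures
#' @param base logarithm base
#' @examples shannon(rep(1, 4))  # 2 bits
#' @family information metrics
#' @export
shannon <- function(x, base = 2) {
    n <- .checkCounts(x)
    p <- n / sum(n)
    -sum(p * log(p, base = base))
}

#' Brillouin diversity
#'
#' \eqn{(\ln N! - \sum \ln n_i!)/N}, the exact (finite-population) analogue
#' of Shannon entropy, computed through log-gamma so large counts do not
#' overflow. Requires integer counts.
#'
#' @param x non-negative integer count vector
#' @examples brillouin(c(1, 1))  # log(2)/2
#' @family information metrics
#' @export
brillouin <- function(x) {
    n <- .checkCounts(x, integer = TRUE)
    N <- sum(n)
    (lgamma(N + 1) - sum(lgamma(n + 1))) / N
}

#' Heip evenness
#'
#' \eqn{(e^H - 1)/(S - 1)} with H the natural-log Shannon entropy, so that
#' \eqn{e^H} is an effective species number. 1 for a perfectly even sample.
#' Undefined for S = 1 (0/0): returns \code{NA}.
#'
#' @inheritParams observedFeatures
#' @examples heip(c(8, 1, 1))
#' @family information metrics
#' @export
heip <- function(x) {
    n <- .checkCounts(x)
    s <- length(n)
    if (s < 2) return(NA_real_)
    p <- n / sum(n)
    (exp(-sum(p * log(p))) - 1) / (s - 1)
}

#' Pielou evenness
#'
#' \eqn{H / \ln S}: Shannon entropy as a fraction of its maximum for the
#' observed richness. Base-invariant (the base cancels in the ratio).
#' Undefined for S = 1: returns \code{NA}.
#'
#' @inheritParams observedFeatures
#' @examples pielou(c(8, 1, 1))
#' @family information metrics
#' @export
pielou <- function(x) {
    n <- .checkCounts(x)
    s <- length(n)
    if (s < 2) return(NA_real_)
    p <- n / sum(n)
    -sum(p * log(p)) / log(s)
}
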