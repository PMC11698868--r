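# Naive oracle implementations: literal loop-based transcriptions of the
# metric formulas, kept deliberately independent of the package's code
# paths. Used to cross-check every abundance metric and Faith PD.

o_positive <- function(x) x[x > 0]

o_observed <- function(x) {
    s <- 0L
    for (v in x) if (v > 0) s <- s + 1L
    s
}

o_tally <- function(x, k) {
    t <- 0L
    for (v in x) if (v == k) t <- t + 1L
    t
}

o_chao1 <- function(x) {
    s <- o_observed(x); a <- o_tally(x, 1); b <- o_tally(x, 2)
    if (b > 0) s + a^2 / (2 * b) else s + a * (a - 1) / (2 * (b + 1))
}

o_ace <- function(x, k = 10) {
    x <- o_positive(x)
    rare <- x[x <= k]; abund <- x[x > k]
    if (length(rare) == 0) return(length(abund))
    n_rare <- sum(rare)
    f1 <- o_tally(rare, 1)
    c_rare <- 1 - f1 / n_rare
    if (c_rare == 0) stop("undefined")
    ssum <- 0
    for (i in 1:k) ssum <- ssum + i * (i - 1) * o_tally(rare, i)
    g2 <- 0
    if (n_rare > 1)
        g2 <- max(length(rare) / c_rare * ssum / (n_rare * (n_rare - 1)) - 1, 0)
    length(abund) + length(rare) / c_rare + f1 / c_rare * g2
}

# bisection on S = alpha * ln(1 + N/alpha)
o_fisher <- function(x) {
    s <- o_observed(x); N <- sum(x)
    lo <- 1e-8; hi <- 1e8
    g <- function(a) a * log(1 + N / a) - s
    for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
}

o_margalef <- function(x) {
    s <- o_observed(x)
    if (s == 1) return(0)
    (s - 1) / log(sum(x))
}

o_menhinick <- function(x) o_observed(x) / sqrt(sum(x))

o_robbins_reads <- function(x) o_tally(x, 1) / (sum(x) + 1)
o_robbins_features <- function(x) o_tally(x, 1) / (o_observed(x) + 1)

o_berger_parker <- function(x) max(x) / sum(x)

o_simpson <- function(x) {
    p <- o_positive(x) / sum(x)
    tot <- 0
    for (pi in p) tot <- tot + pi^2
    1 - tot
}

o_dominance <- function(x) {
    p <- o_positive(x) / sum(x)
    tot <- 0
    for (pi in p) tot <- tot + pi * pi
    tot
}
o_enspie <- function(x) 1 / o_dominance(x)

# mean absolute difference over all ordered pairs
o_gini <- function(x) {
    x <- o_positive(x)
    s <- length(x)
    tot <- 0
    for (i in 1:s) for (j in 1:s) tot <- tot + abs(x[i] - x[j])
    tot / (2 * s^2 * mean(x))
}

o_mcintosh <- function(x) {
    x <- o_positive(x)
    N <- sum(x); U <- sqrt(sum(x^2))
    (N - U) / (N - sqrt(N))
}

o_strong <- function(x) {
    x <- sort(o_positive(x), decreasing = TRUE)
    s <- length(x); N <- sum(x)
    best <- -Inf; b <- 0
    for (i in 1:s) {
        b <- b + x[i]
        best <- max(best, b / N - i / s)
    }
    best
}

o_shannon <- function(x, base = 2) {
    p <- o_positive(x) / sum(x)
    h <- 0
    for (pi in p) h <- h - pi * log(pi) / log(base)
    h
}

o_brillouin <- function(x) {
    x <- o_positive(x)
    N <- sum(x)
    logfact <- function(n) if (n < 2) 0 else sum(log(seq_len(n)))
    (logfact(N) - sum(vapply(x, logfact, 0))) / N
}

o_heip <- function(x) {
    s <- o_observed(x)
    if (s < 2) return(NA_real_)
    (exp(o_shannon(x, base = exp(1))) - 1) / (s - 1)
}

o_pielou <- function(x) {
    s <- o_observed(x)
    if (s < 2) return(NA_real_)
    o_shannon(x, base = exp(1)) / log(s)
}

# brute-force Faith PD: mark edges tip by tip walking child -> parent
o_faith <- function(obsTips, tree, includeRoot = TRUE) {
    edge <- tree$edge
    marked <- rep(FALSE, nrow(edge))
    root <- length(tree$tip.label) + 1L
    stopTarget <- if (includeRoot) root else {
        if (length(obsTips) == 1L) match(obsTips, tree$tip.label)
        else ape::getMRCA(tree, obsTips)
    }
    for (tip in obsTips) {
        node <- match(tip, tree$tip.label)
        while (node != stopTarget && node != root) {
            e <- which(edge[, 2] == node)
            marked[e] <- TRUE
            node <- edge[e, 1]
        }
    }
    sum(tree$edge.length[marked])
}

# closed-form OLS via the normal equations
o_ols <- function(x, y) {
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    list(intercept = beta[1], slope = beta[2],
         r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}
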