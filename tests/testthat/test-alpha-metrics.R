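test_that("hand-evaluated reference values are reproduced", {
    # richness
    expect_identical(observedFeatures(c(5, 1, 0, 2)), 3L)
    expect_identical(observedFeatures(7), 1L)
    expect_equal(singletonCount(c(1, 1, 2, 5)), 2)
    expect_equal(doubletonCount(c(1, 1, 2, 5)), 1)
    expect_equal(singletonCount(c(3, 4)), 0)
    expect_equal(chao1(c(4, 3, 2, 2, 1, 1, 1, 1)), 12)   # S=8, a=4, b=2
    expect_equal(chao1(c(1, 1)), 3)                       # bias-corrected, b=0
    expect_equal(chao1(c(4, 3, 2)), 3)                    # a=0: collapses to S
    expect_equal(ace(c(15, 12, 1, 1, 2)), 8)
    expect_equal(margalef(c(50, 30, 20)), 2 / log(100))
    expect_equal(menhinick(c(8, 4, 2, 2)), 1)
    expect_equal(robbins(c(1, 1, 1, 5)), 3 / 9)
    expect_equal(robbins(c(1, 1, 1, 5), "features"), 3 / 5)
    # dominance
    expect_equal(bergerParker(c(8, 1, 1)), 0.8)
    expect_equal(simpson(c(8, 1, 1)), 0.34)
    expect_equal(dominanceIndex(c(8, 1, 1)), 0.66)
    expect_equal(enspie(c(8, 1, 1)), 1 / 0.66)
    expect_equal(gini(c(3, 1)), 0.25)
    expect_equal(mcintosh(c(8, 1, 1)), (10 - sqrt(66)) / (10 - sqrt(10)))
    expect_equal(strongDominance(c(8, 1, 1)), 0.8 - 1 / 3)
    # information (natural-log entropy of [8,1,1] is 0.6390319...)
    h <- -sum(c(0.8, 0.1, 0.1) * log(c(0.8, 0.1, 0.1)))
    expect_equal(shannon(c(8, 1, 1), base = exp(1)), h)
    expect_equal(shannon(rep(1, 4)), 2)                   # bits
    expect_equal(brillouin(c(1, 1)), log(2) / 2)
    expect_equal(heip(c(8, 1, 1)), (exp(h) - 1) / 2)
    expect_equal(pielou(c(8, 1, 1)), h / log(3))
})

test_that("degenerate and error cases follow the stated conventions", {
    expect_error(observedFeatures(c(0, 0)), "all-zero")
    expect_error(chao1(c(1.5, 2)), "integer")
    expect_error(brillouin(c(2.5, 1)), "integer")
    expect_error(ace(c(1, 1, 1)), "ACE undefined")
    expect_equal(ace(c(50, 20, 100)), 3)       # all above threshold: ACE = S
    expect_error(fisherAlpha(c(1, 1)), "diverges")
    expect_error(fisherAlpha(7), "two")
    expect_error(mcintosh(1), "N < 2")
    expect_error(observedFeatures(c(-1, 2)), "non-negative")
    # S = 1 conventions: evenness missing, others collapse to 0 / defined
    expect_equal(margalef(c(0, 9)), 0)
    expect_true(is.na(heip(5)))
    expect_true(is.na(pielou(5)))
    expect_equal(gini(5), 0)
    expect_equal(strongDominance(5), 0)
    expect_equal(shannon(5), 0)
    expect_equal(brillouin(9), 0)
    expect_equal(bergerParker(5), 1)
    expect_equal(simpson(5), 0)
    expect_equal(dominanceIndex(5), 1)
    expect_equal(enspie(5), 1)
    expect_equal(mcintosh(c(5, 0)), 0)         # single taxon holding all reads
})

test_that("uniform communities hit their closed forms", {
    for (S in c(2, 4, 10, 33)) {
        u <- rep(7, S)
        expect_equal(shannon(u), log2(S), tolerance = 1e-12)
        expect_equal(pielou(u), 1, tolerance = 1e-12)
        expect_equal(heip(u), 1, tolerance = 1e-12)
        expect_equal(bergerParker(u), 1 / S, tolerance = 1e-12)
        expect_equal(enspie(u), S, tolerance = 1e-12)
        expect_equal(gini(u), 0, tolerance = 1e-12)
        expect_equal(strongDominance(u), 0, tolerance = 1e-12)
    }
    expect_equal(mcintosh(rep(1, 20)), 1)      # every read its own taxon
})

test_that("metrics are permutation- and zero-padding-invariant", {
    set.seed(42)
    metrics <- list(observedFeatures, chao1, ace, fisherAlpha, margalef,
                    menhinick, robbins, bergerParker, simpson,
                    dominanceIndex, enspie, gini, mcintosh, strongDominance,
                    shannon, brillouin, heip, pielou)
    for (i in 1:25) {
        x <- randomCountVector()
        perm <- sample(x)
        padded <- c(x, rep(0L, 7))
        for (f in metrics) {
            ref <- tryCatch(f(x), error = function(e) NULL)
            if (is.null(ref)) next    # e.g. ACE undefined on this vector
            expect_equal(f(perm), ref, tolerance = 1e-12)
            expect_equal(f(padded), ref, tolerance = 1e-12)
        }
    }
})

test_that("scale behaviour: relative-abundance metrics ignore k * counts", {
    set.seed(7)
    invariant <- list(bergerParker, simpson, dominanceIndex, enspie, gini,
                      strongDominance, shannon, pielou, heip)
    for (i in 1:20) {
        x <- randomCountVector()
        k <- sample(2:6, 1)
        for (f in invariant)
            expect_equal(f(k * x), f(x), tolerance = 1e-12)
        # count-scale metrics move exactly as their formulas dictate
        S <- observedFeatures(x); N <- sum(x)
        expect_equal(margalef(k * x), (S - 1) / log(k * N))
        expect_equal(menhinick(k * x), S / sqrt(k * N))
    }
})

test_that("complementarity identities hold to 1e-12 on random vectors", {
    set.seed(101)
    for (i in 1:300) {
        x <- randomCountVector()
        expect_equal(simpson(x) + dominanceIndex(x), 1, tolerance = 1e-12)
        expect_equal(enspie(x) * dominanceIndex(x), 1, tolerance = 1e-12)
    }
})

test_that("estimator bounds and inequalities hold on random vectors", {
    set.seed(202)
    for (i in 1:200) {
        x <- randomCountVector()
        S <- observedFeatures(x); N <- sum(x)
        expect_gte(chao1(x), S)
        if (singletonCount(x) == 0) expect_equal(chao1(x), S)
        # fisher residual bound (postcondition)
        if (N > S) {
            a <- fisherAlpha(x)
            expect_lt(abs(S - a * log(1 + N / a)), 1e-10)
        }
        # Brillouin never exceeds natural-log Shannon
        expect_lte(brillouin(x), shannon(x, base = exp(1)) + 1e-12)
        expect_lte(strongDominance(x), 1)
        expect_gte(strongDominance(x), 0)
        g <- gini(x)
        expect_gte(g, 0); expect_lte(g, 1 - 1 / S + 1e-12)
    }
})

test_that("every abundance metric matches its naive oracle", {
    set.seed(303)
    pairs <- list(
        list(observedFeatures, o_observed),
        list(chao1, o_chao1),
        list(fisherAlpha, o_fisher),
        list(margalef, o_margalef),
        list(menhinick, o_menhinick),
        list(robbins, o_robbins_reads),
        list(function(x) robbins(x, "features"), o_robbins_features),
        list(bergerParker, o_berger_parker),
        list(simpson, o_simpson),
        list(dominanceIndex, o_dominance),
        list(enspie, o_enspie),
        list(gini, o_gini),
        list(mcintosh, o_mcintosh),
        list(strongDominance, o_strong),
        list(shannon, o_shannon),
        list(brillouin, o_brillouin),
        list(heip, o_heip),
        list(pielou, o_pielou))
    for (i in 1:150) {
        x <- randomCountVector()
        for (p in pairs)
            expect_equal(p[[1]](x), p[[2]](x), tolerance = 1e-9)
        ok <- tryCatch(o_ace(x), error = function(e) NULL)
        if (!is.null(ok)) expect_equal(ace(x), ok, tolerance = 1e-9)
    }
})

test_that("simpson, enspie, shannon and fisher agree with vegan", {
    skip_if_not_installed("vegan")
    set.seed(404)
    for (i in 1:30) {
        x <- randomCountVector()
        expect_equal(simpson(x), unname(vegan::diversity(x, "simpson")),
                     tolerance = 1e-9)
        expect_equal(enspie(x), unname(vegan::diversity(x, "invsimpson")),
                     tolerance = 1e-9)
        expect_equal(shannon(x, base = exp(1)),
                     unname(vegan::diversity(x, "shannon")),
                     tolerance = 1e-9)
        # vegan's nlm-based fit converges less tightly than the root search
        expect_equal(fisherAlpha(x),
                     unname(suppressWarnings(vegan::fisher.alpha(x))),
                     tolerance = 1e-4)
    }
})

test_that("the registry partitions 19 metrics into the four categories", {
    reg <- metricRegistry()
    expect_equal(nrow(reg), 19)
    counts <- table(reg$category)
    expect_equal(as.integer(counts[c("richness", "dominance", "information",
                                     "phylogenetic")]),
                 c(7L, 7L, 4L, 1L))
    expect_false(anyDuplicated(reg$name) > 0)
    reg18 <- metricRegistry(includeTree = FALSE)
    expect_equal(nrow(reg18), 18)
    expect_false(any(reg18$requiresTree))
})
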