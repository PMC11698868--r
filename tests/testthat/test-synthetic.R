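test_that("the design grid follows the singleton schedule and caps", {
    cfg <- generatorConfig()
    grid <- buildDesignGrid(cfg)
    # S = 50: fractional cap 20 binds, schedule {0,3,...,18} -> 7 designs
    g50 <- grid[grid$S == 50, ]
    expect_equal(nrow(g50), 7)
    expect_equal(sort(g50$F1), seq(0, 18, by = 3))
    # S = 500: absolute cap 100 binds
    g500 <- grid[grid$S == 500, ]
    expect_equal(max(g500$F1), 99)        # largest multiple of 3 <= 100
    expect_true(all(grid$F1 <= pmin(100, floor(0.4 * grid$S))))
    # doubletons at 40% of singletons, rounded
    expect_equal(grid$F2, as.integer(round(0.4 * grid$F1)))
    expect_true(all(grid$S - grid$F1 - grid$F2 >= 1))
    expect_equal(max(grid$S), 500)
})

test_that("generated samples realise their rare-class targets exactly", {
    cfg <- generatorConfig(distribution = "negative_binomial", seed = 3)
    design <- list(sample_id = "d1", S = 200, F1 = 60, F2 = 24)
    x <- generateSample(design, cfg, seed = 5)
    expect_equal(sum(x > 0), 200)
    expect_equal(sum(x == 1), 60)
    expect_equal(sum(x == 2), 24)
    expect_equal(sum(x >= 3), 116)
    # determinism: same design + same seed -> identical vector
    expect_identical(x, generateSample(design, cfg, seed = 5))
    # degenerate distribution: uniform(0,0) puts all non-rare counts at 3
    cfg0 <- generatorConfig(distribution = "uniform",
                            distributionParams = list(min = 0, max = 0))
    y <- generateSample(design, cfg0, seed = 1)
    expect_true(all(y[y >= 3] == 3))
})

test_that("every distribution family yields exact rare-class control", {
    for (d in c("normal", "negative_binomial", "uniform", "exponential",
                "poisson")) {
        cfg <- generatorConfig(richnessLevels = c(50L, 120L),
                               distribution = d, seed = 17)
        sds <- generateDataset(cfg)
        dd <- as.data.frame(designTable(sds))
        expect_equal(dd$realized_S, dd$S)
        expect_equal(dd$realized_F1, dd$F1)
        expect_equal(dd$realized_F2, dd$F2)
    }
})

test_that("unevenness rescales the top feature to an exact ratio", {
    x <- stats::setNames(c(40L, 35L, 10L, 2L, 1L), paste0("a", 1:5))
    y <- applyUnevenness(x, 10)
    expect_equal(unname(y["a1"]), 350)
    expect_equal(y[-1], x[-1])                       # others untouched
    expect_equal(sum(y == 1), sum(x == 1))
    expect_identical(applyUnevenness(y, 10), y)      # idempotent in ratio
    expect_error(applyUnevenness(c(a = 5L, b = 2L), 10), "below 3")
    expect_error(applyUnevenness(c(a = 5L), 2), "two")
    expect_error(applyUnevenness(x, 1), "> 1")
})

test_that("unevenness datasets realise the configured fold ratio exactly", {
    for (r in c(2, 100)) {
        cfg <- generatorConfig(richnessLevels = c(50L, 90L),
                               distribution = "negative_binomial",
                               unevennessRatio = r, seed = 23)
        dd <- as.data.frame(designTable(generateDataset(cfg)))
        expect_true(all(dd$top_two_ratio == r))
    }
})

test_that("paired unevenness increases dominance and lowers entropy", {
    cfg <- function(r) generatorConfig(richnessLevels = c(60L, 150L),
                                       distribution = "negative_binomial",
                                       unevennessRatio = r, seed = 31)
    base <- generatorConfig(richnessLevels = c(60L, 150L),
                            distribution = "negative_binomial", seed = 31)
    perSample <- function(config, f) {
        sds <- generateDataset(config)
        m <- counts(sds)
        vapply(seq_len(ncol(m)), function(j) {
            x <- m[, j]; f(x[x > 0])
        }, 0)
    }
    bp <- lapply(list(base, cfg(2), cfg(10), cfg(100)),
                 perSample, f = bergerParker)
    sh <- lapply(list(base, cfg(2), cfg(10), cfg(100)),
                 perSample, f = shannon)
    # the same seed gives paired samples: strict per-sample ordering
    expect_true(all(bp[[2]] < bp[[3]]))
    expect_true(all(bp[[3]] < bp[[4]]))
    expect_true(all(sh[[2]] > sh[[3]]))
    expect_true(all(sh[[3]] > sh[[4]]))
})

test_that("dataset generation is reproducible and seed-sensitive", {
    cfg <- generatorConfig(richnessLevels = c(50L, 70L), seed = 41)
    a <- generateDataset(cfg)
    b <- generateDataset(cfg)
    expect_identical(as.matrix(counts(a)), as.matrix(counts(b)))
    cfg2 <- generatorConfig(richnessLevels = c(50L, 70L), seed = 42)
    c2 <- generateDataset(cfg2)
    expect_identical(as.data.frame(designTable(a))[
                         c("sample_id", "S", "F1", "F2")],
                     as.data.frame(designTable(c2))[
                         c("sample_id", "S", "F1", "F2")])
    expect_false(identical(as.matrix(counts(a)), as.matrix(counts(c2))))
    # byte-identical TSV output for identical configs
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeFeatureTable(featureTable(a), f1)
    writeFeatureTable(featureTable(b), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("features are sample-private and labelled by sample", {
    cfg <- generatorConfig(richnessLevels = c(50L, 60L), seed = 2)
    sds <- generateDataset(cfg)
    m <- counts(sds)
    expect_equal(Matrix::colSums(m > 0),
                 stats::setNames(as.data.frame(designTable(sds))$S,
                                 sampleIDs(featureTable(sds))))
    # each feature appears in exactly one sample
    expect_true(all(Matrix::rowSums(m > 0) == 1))
})

test_that("random trees are reproducible binary phylogenies over the features", {
    tr <- generateRandomTree(paste0("f", 1:4), seed = 9)
    expect_equal(length(tr$tip.label), 4)
    expect_equal(nrow(tr$edge), 6)                   # rooted binary: 2n-2
    expect_true(ape::is.rooted(tr))
    expect_identical(ape::write.tree(tr),
                     ape::write.tree(generateRandomTree(paste0("f", 1:4),
                                                        seed = 9)))
    expect_error(generateRandomTree("only_one", seed = 1), "two")
    # cross-module: PD of all tips is the whole tree
    x <- stats::setNames(rep(1, 4), tr$tip.label)
    expect_equal(faithPD(x, tr), totalBranchLength(tr))
})

test_that("invalid configurations are rejected", {
    expect_error(generatorConfig(richnessLevels = c(2L, 50L)), ">= 3")
    expect_error(generatorConfig(singletonCapFraction = 1.2), "(0, 1)")
    expect_error(generatorConfig(unevennessRatio = 0.5), "exceed 1")
    expect_error(generatorConfig(distribution = "zipf"))
    expect_error(generatorConfig(distributionParams = list(shape = 2)),
                 "unknown parameter")
})
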