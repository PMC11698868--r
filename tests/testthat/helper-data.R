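# Random fixtures, generated in code under fixed seeds.

randomCountVector <- function(maxS = 50, maxCount = 1000) {
    s <- sample(2:maxS, 1)
    counts <- sample.int(maxCount, s, replace = TRUE)
    # sprinkle singletons/doubletons so the rare-class paths get exercised
    nOne <- sample(0:min(5, s - 1), 1)
    if (nOne > 0) counts[seq_len(nOne)] <- 1L
    nTwo <- sample(0:min(3, s - nOne - 1), 1)
    if (nTwo > 0) counts[nOne + seq_len(nTwo)] <- 2L
    sample(counts)    # random order
}

smallFeatureTable <- function() {
    m <- matrix(c(5L, 1L, 0L, 2L,
                  1L, 1L, 2L, 8L,
                  0L, 0L, 3L, 3L), nrow = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"),
                                c("ASV1", "ASV2", "ASV3", "ASV4")))
    FeatureTable(m)
}

quadTree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
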