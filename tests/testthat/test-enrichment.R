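toyGenome <- function(seed = 55, n = 2, len = 3e4, gc = 0.45) {
    set.seed(seed)
    seqs <- vapply(seq_len(n), function(i) randomSeq(len, gc), "")
    Biostrings::DNAStringSet(setNames(seqs, paste0("s", seq_len(n))))
}

test_that("GC fractions ignore N and count case-insensitively", {
    g <- Biostrings::DNAStringSet(c(s = "ATGCGGGGANGCatgc"))
    iv <- GRanges("s", IRanges(c(1, 5, 9, 13), c(4, 8, 12, 16)))
    expect_equal(gcFraction(iv, g), c(0.5, 1, 2 / 3, 0.5))
    allN <- gcFraction(GRanges("s", IRanges(9, 10)), # "AN" -> A only
                       Biostrings::DNAStringSet(c(s = "ATGCGGGGNNGC")))
    expect_true(is.nan(gcFraction(GRanges("s", IRanges(9, 10)),
        Biostrings::DNAStringSet(c(s = "ATGCGGGGNNGC")))))
})

test_that("matched controls preserve length and the GC bound", {
    g <- toyGenome()
    set.seed(77)
    q <- GRanges("s1", IRanges(1001, 1500))
    qgc <- gcFraction(q, g)
    for (i in 1:100) {
        ctrl <- sampleMatchedControl(q, g, gcTolerance = 0.05,
                                     exclude = q)
        expect_equal(width(ctrl), 500L)
        expect_lte(abs(gcFraction(ctrl, g) - qgc), 0.05 + 1e-12)
        expect_false(suppressWarnings(overlapsAny(ctrl, q)))
    }
})

test_that("impossible GC targets trigger tolerance doubling", {
    g <- Biostrings::DNAStringSet(c(
        s1 = paste(rep("AT", 5000), collapse = "")))
    q <- GRanges("s1", IRanges(1, 100))  # GC = 0; trivially matched
    expect_silent(sampleMatchedControl(q, g, gcTolerance = 0,
                                       maxTries = 50))
    # force mismatch: query on a GC-rich genome segment
    g2 <- Biostrings::DNAStringSet(c(
        s1 = paste0(paste(rep("GC", 200), collapse = ""),
                    paste(rep("AT", 5000), collapse = ""))))
    q2 <- GRanges("s1", IRanges(1, 300))
    w <- capture_warnings(sampleMatchedControl(q2, g2,
                                               gcTolerance = 0.01,
                                               maxTries = 200))
    expect_true(any(grepl("doubled", w)))
})

test_that("a whole-genome category saturates fold enrichment at 1", {
    g <- toyGenome(66)
    set.seed(8)
    dmrs <- GRanges(sample(c("s1", "s2"), 10, TRUE),
                    IRanges(sample(25000, 10), width = 300))
    whole <- GRanges(c("s1", "s2"), IRanges(1, 3e4))
    r <- bootstrapEnrichment(dmrs, list(genome = whole), g, nBoot = 50)
    expect_equal(r$observed_frac, 1)
    expect_equal(r$null_mean, 1)
    expect_equal(r$fold_enrichment, 1)
    expect_gte(r$p_emp, 1 / 51)
    expect_error(bootstrapEnrichment(GRanges(), list(genome = whole), g),
                 "empty")
})

test_that("null fractions match exhaustive enumeration for 1 bp queries", {
    g <- Biostrings::DNAStringSet(c(s = randomSeq(10000, 0.5)))
    set.seed(12)
    dmrs <- GRanges("s", IRanges(sample(9000, 12), width = 1))
    cat <- GRanges("s", IRanges(2501, 7500))   # covers 50%
    r <- bootstrapEnrichment(dmrs, list(body = cat), g, nBoot = 400,
                             gcTolerance = 1, exclude = GRanges())
    # tolerance 1 accepts every position: the null is exactly uniform
    # over all 10000 starts; enumerate the expected overlap probability
    pInside <- 5000 / 10000
    expect_equal(r$observed_frac, mean(overlapsAny(dmrs, cat)))
    expect_lt(abs(r$null_mean - pInside), 3 * r$null_sd / sqrt(400) + 0.02)
})

test_that("null DMRs calibrate and planted enrichment is detected", {
    g <- toyGenome(99, n = 2, len = 5e4)
    cat <- GRanges(c("s1", "s2"), IRanges(12501, 37500))  # 50% coverage
    set.seed(21)
    fes <- c(); ps <- c()
    for (i in 1:10) {
        dmrs <- GRanges(sample(c("s1", "s2"), 60, TRUE),
                        IRanges(sample(49500, 60), width = 400))
        r <- bootstrapEnrichment(dmrs, list(cat = cat), g, nBoot = 100)
        fes <- c(fes, r$fold_enrichment); ps <- c(ps, r$p_emp)
    }
    expect_gte(mean(fes >= 0.75 & fes <= 1.25), 0.8)
    expect_gte(mean(ps > 0.05), 0.8)

    # planted: 90% of DMRs inside the category
    inside <- sample(c(sample(12501:37100, 54, TRUE)))
    outside <- sample(c(1:12000, 38000:49500), 6)
    dmrsP <- GRanges(sample(c("s1", "s2"), 60, TRUE),
                     IRanges(c(inside, outside), width = 400))
    rp <- bootstrapEnrichment(dmrsP, list(cat = cat), g, nBoot = 100)
    expect_gt(rp$fold_enrichment, 1.5)
    expect_lt(rp$p_emp, 0.05)
})

test_that("planted enrichment strength orders fold enrichment", {
    g <- toyGenome(123, n = 1, len = 6e4)
    cat <- GRanges("s1", IRanges(15001, 45000))
    set.seed(31)
    medFe <- vapply(c(0.5, 0.7, 0.9), function(frac) {
        fes <- vapply(1:5, function(i) {
            nIn <- round(40 * frac)
            stIn <- sample(15001:44600, nIn, TRUE)
            stOut <- sample(c(1:14500, 45100:59500), 40 - nIn, TRUE)
            dmrs <- GRanges("s1", IRanges(c(stIn, stOut), width = 300))
            bootstrapEnrichment(dmrs, list(cat = cat), g,
                                nBoot = 60)$fold_enrichment
        }, numeric(1))
        median(fes)
    }, numeric(1))
    expect_true(all(diff(medFe) > -1e-9))
})
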