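test_that("gene methylation summaries average CpGs with a floor", {
    genes <- GRanges("s", IRanges(c(2000, 6000, 9000), width = 1000),
                     strand = "+", gene_id = c("g1", "g2", "g3"))
    # g1: promoter CpGs 0.2/0.4/0.6, body 0.8 x3; g2: 2 promoter CpGs
    pos <- c(1100, 1400, 1700, 2100, 2400, 2800,
             5100, 5500, 6200, 6300, 6900,
             8100, 8500, 8900, 9200, 9500, 9900)
    f <- c(0.2, 0.4, 0.6, 0.8, 0.8, 0.8,
           0.3, 0.5, 0.1, 0.3, 0.5,
           0.9, 0.7, 0.5, 0.2, 0.4, 0.6)
    s <- mkMethF("s", pos, f, cov = 10)
    gm <- summarizeGeneMethylation(s, genes, minCpgs = 3)
    expect_equal(gm$promoter_mean_f[1], 0.4)
    expect_equal(gm$body_mean_f[1], 0.8)
    expect_true(is.na(gm$promoter_mean_f[2]))   # 2 covered CpGs < 3
    expect_equal(gm$promoter_n_cpgs[2], 2L)
    expect_equal(gm$body_mean_f[2], 0.3)
    expect_equal(gm$promoter_mean_f[3], mean(c(0.9, 0.7, 0.5)))
    expect_equal(gm$body_mean_f[3], mean(c(0.2, 0.4, 0.6)))
})

test_that("Spearman correlation matches full permutation enumeration", {
    expect_equal(rankCorrelation(1:8, (1:8)^2)$rho, 1)
    expect_equal(rankCorrelation(1:8, -(1:8))$rho, -1)
    const <- rankCorrelation(rep(1, 5), 1:5)
    expect_true(const$degenerate)
    expect_error(rankCorrelation(1:3, 1:3), "4")

    set.seed(6)
    for (rep in 1:3) {
        x <- sample(100, 6); y <- sample(100, 6)
        r <- rankCorrelation(x, y)
        expect_equal(r$rho, stats::cor(rank(x), rank(y)),
                     tolerance = 1e-12)
        expect_equal(r$p, enumSpearmanP(x, y), tolerance = 1e-9)
    }
})

test_that("DMG x DEG enrichment reproduces the hand-computed table", {
    universe <- paste0("g", 1:300)
    dmg <- universe[1:100]
    deg <- universe[c(1:30, 101:120)]   # table [[30,70],[20,180]]
    r <- dmgDegEnrichment(dmg, deg, universe)
    expect_equal(r$fold_enrichment, 3.0)
    O <- matrix(c(30, 20, 70, 180), 2)
    E <- outer(rowSums(O), colSums(O)) / 300
    expect_equal(unname(r$chi2), sum((O - E)^2 / E), tolerance = 1e-9)
    expect_equal(r$p, stats::pchisq(sum((O - E)^2 / E), 1,
                                    lower.tail = FALSE), tolerance = 1e-9)

    # independence at matched proportions: FE = 1, chi2 = 0
    ind <- dmgDegEnrichment(universe[1:100], universe[c(1:20, 101:140)],
                            universe)
    expect_equal(ind$fold_enrichment, 1)
    expect_lt(unname(ind$chi2), 1e-9)

    expect_error(dmgDegEnrichment(universe, universe, universe),
                 "margin")
})

test_that("FE and chi-square are invariant under consistent relabeling", {
    universe <- paste0("g", 1:200)
    dmg <- universe[1:60]; deg <- universe[c(1:25, 61:80)]
    a <- dmgDegEnrichment(dmg, deg, universe)
    nonDmg <- setdiff(universe, dmg)
    b <- dmgDegEnrichment(nonDmg, deg, universe)
    expect_equal(unname(a$chi2), unname(b$chi2), tolerance = 1e-9)
})

test_that("sex expression ratios are pseudocounted log2 fold changes", {
    expect_equal(sexExpressionRatio(5, 5), 0)
    expect_equal(sexExpressionRatio(3, 1), 1)
    expect_equal(sexExpressionRatio(c(a = 7), c(a = 3), pseudocount = 1),
                 c(a = 1))
    expect_error(sexExpressionRatio(-1, 2), "non-negative")
})

test_that("sex-differential methylation-expression coupling is recovered", {
    set.seed(27)
    hits <- 0L
    for (rep in 1:5) {
        n <- 200
        isX <- seq_len(n) <= 66
        bodyDelta <- ifelse(isX, rnorm(n, -0.25, 0.12), 0)
        log2fc <- 0.24 - 1.2 * bodyDelta + rnorm(n, 0, 0.6)
        ids <- paste0("g", 1:n)
        sf <- DataFrame(gene_id = ids, promoter_mean_f = runif(n),
                        promoter_n_cpgs = 5L,
                        body_mean_f = 0.8 + bodyDelta, body_n_cpgs = 10L)
        sm <- DataFrame(gene_id = ids, promoter_mean_f = runif(n),
                        promoter_n_cpgs = 5L, body_mean_f = rep(0.8, n),
                        body_n_cpgs = 10L)
        r <- correlateSexdiffMethExpression(sf, sm,
                                            setNames(log2fc, ids),
                                            "gene_body")
        if (r$rho < 0 && r$p < 0.05) hits <- hits + 1L
    }
    expect_gte(hits, 4L)
})

test_that("excluded genes drop out of the coupling correlation", {
    n <- 30
    ids <- paste0("g", 1:n)
    sf <- DataFrame(gene_id = ids, promoter_mean_f = runif(n),
                    promoter_n_cpgs = 5L, body_mean_f = runif(n),
                    body_n_cpgs = 5L)
    sm <- DataFrame(gene_id = ids, promoter_mean_f = runif(n),
                    promoter_n_cpgs = 5L, body_mean_f = runif(n),
                    body_n_cpgs = 5L)
    fc <- setNames(rnorm(n), ids)
    a <- correlateSexdiffMethExpression(sf, sm, fc, "gene_body")
    b <- correlateSexdiffMethExpression(sf, sm, fc, "gene_body",
                                        exclude = "g1")
    expect_equal(a$n - 1L, b$n)
    expect_error(correlateSexdiffMethExpression(sf, sm, fc, "gene_body",
                                                exclude = ids[-1]), "4")
})
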