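smallCfg <- function(seed, ...) {
    simConfig(seed = seed, nAutosomalScaffolds = 2, nXScaffolds = 1,
              nUnplacedScaffolds = 3, scaffoldLengthBp = 1e5,
              geneCount = 9, tissues = c("brain", "kidney"), ...)
}

test_that("the generator is deterministic given the seed", {
    cfg <- smallCfg(101)
    a <- generateGenome(cfg); b <- generateGenome(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(start(a$sites), start(b$sites))
    expect_identical(a$truth$origin, b$truth$origin)
    ma <- simulateMethylomes(a); mb <- simulateMethylomes(b)
    expect_identical(methCalls(ma$samples[[1]]), methCalls(mb$samples[[1]]))
    ea <- simulateExpression(ma$truth$geneMeth, cfg)
    eb <- simulateExpression(mb$truth$geneMeth, cfg)
    expect_identical(ea$expr_female, eb$expr_female)
    # different seed diverges
    c2 <- generateGenome(smallCfg(102))
    expect_false(identical(as.character(a$genome),
                           as.character(c2$genome)))
})

test_that("generated annotations respect the configuration", {
    cfg <- smallCfg(103)
    sim <- generateGenome(cfg)
    expect_equal(length(sim$genes), cfg$geneCount)
    expect_equal(length(sim$seqlengths), 6L)
    expect_true(all(width(sim$genes) == cfg$geneLengthBp))
    expect_true(!is.na(sim$truth$rsxGene))
    expect_equal(length(sim$truth$rsxCgis), 2L)
    # packing failure is caught
    expect_error(generateGenome(
        simConfig(seed = 104, nAutosomalScaffolds = 2, nXScaffolds = 1,
                  nUnplacedScaffolds = 3, scaffoldLengthBp = 1e5,
                  geneCount = 5000L)), "packing")
    # seed is mandatory
    expect_error(simConfig(), "seed")
})

test_that("simulated reports round-trip through the readers", {
    cfg <- smallCfg(105)
    sim <- generateGenome(cfg, withSequence = FALSE)
    merged <- simulateMethylomes(sim, merged = TRUE)
    split <- simulateMethylomes(sim, merged = FALSE)
    id <- "brain_female"
    p <- tempfile(fileext = ".txt.gz")
    writeCpGReport(split$samples[[id]], p)
    back <- mergeStrands(readCpGReport(p, sex = "female",
                                       tissue = "brain"))
    expect_equal(start(methCalls(back)),
                 start(methCalls(merged$samples[[id]])))
    expect_equal(mcols(methCalls(back))$m,
                 mcols(methCalls(merged$samples[[id]]))$m)
    expect_equal(mcols(methCalls(back))$u,
                 mcols(methCalls(merged$samples[[id]]))$u)
})

test_that("planted X effects and depth ratios land at their targets", {
    deltas <- c(); ratios <- c(); aratios <- c()
    for (seed in 106:108) {
        cfg <- smallCfg(seed)
        sim <- generateGenome(cfg, withSequence = FALSE)
        meth <- simulateMethylomes(sim)
        f <- meth$samples[["brain_female"]]; m <- meth$samples[["brain_male"]]
        xScafs <- names(sim$truth$origin)[sim$truth$origin == "X"]
        wd <- windowDifferences(f, m, 1e4, 3, scaffolds = xScafs)
        # exclude promoter-dominated windows by weighting all: planted
        # shift applies outside promoters/CGIs, so window deltas sit a
        # little above -0.25; compare against the truth surface instead
        tw <- meth$truth$xWindows
        deltas <- c(deltas, mean(tw$true_delta))
        ratios <- c(ratios, coverageRatio(f, m, xScafs[1]))
        aScaf <- grep("chrA", names(sim$truth$origin), value = TRUE)[1]
        aratios <- c(aratios, coverageRatio(f, m, aScaf))
        # measured window deltas correlate with the planted surface
        ov <- findOverlaps(wd, tw)
        expect_gt(stats::cor(wd$delta[S4Vectors::queryHits(ov)],
                             tw$true_delta[S4Vectors::subjectHits(ov)]),
                  0.5)
    }
    expect_lt(abs(mean(deltas) + 0.25), 0.03)
    expect_true(all(ratios >= 1.8 & ratios <= 2.2))
    expect_true(all(aratios >= 0.9 & aratios <= 1.1))
})

test_that("a zero-effect configuration is a calibrated null", {
    cfg <- smallCfg(109, xEffectMu = 0, xEffectSd = 0,
                    femaleXDepthFactor = 1, nDmrsPerTissue = 0L,
                    rsxReduction = 0)
    sim <- generateGenome(cfg, withSequence = FALSE)
    meth <- simulateMethylomes(sim)
    f <- meth$samples[["brain_female"]]; m <- meth$samples[["brain_male"]]
    wd <- windowDifferences(f, m, 1e4, 3)
    se <- stats::sd(wd$delta) / sqrt(length(wd))
    expect_lt(abs(mean(wd$delta)), 3 * se + 1e-3)
    expect_equal(length(meth$truth$dmrs), 0L)
})

test_that("the Rsx-like locus carries its planted female reduction", {
    cfg <- smallCfg(110)
    sim <- generateGenome(cfg, withSequence = FALSE)
    meth <- simulateMethylomes(sim)
    f <- meth$samples[["kidney_female"]]; m <- meth$samples[["kidney_male"]]
    r <- regionSexDifference(f, m, meth$truth$rsxCgis)
    expect_lt(abs(r$reduction_pct - 36), 12)  # ~100 CpGs of noise
    expect_gt(r$n_cpgs, 50)
})

test_that("expression couples to methylation and marks the Rsx analogue", {
    cfg <- smallCfg(111)
    set.seed(1)
    n <- 2000
    gm <- DataFrame(gene_id = paste0("g", 1:n),
                    promoter_f = rbeta(n, 2, 8),
                    body_delta = rep(0, n),
                    is_x = rep(FALSE, n), is_rsx = rep(FALSE, n))
    gm$is_rsx[1] <- TRUE
    expr <- simulateExpression(gm, cfg)
    r <- rankCorrelation(gm$promoter_f[-1], expr$expr_male[-1])
    expect_lt(r$rho, -0.05)
    expect_gt(r$rho, -0.20)
    expect_gt(expr$expr_female[1], 100)
    expect_lt(expr$expr_male[1], 1)
    expect_equal(expr$de_label[1], "female_up")

    # zero coupling gives a null correlation
    cfg0 <- smallCfg(112, methExprRho = 0)
    e0 <- simulateExpression(gm, cfg0)
    r0 <- rankCorrelation(gm$promoter_f[-1], e0$expr_male[-1])
    expect_lt(abs(r0$rho), 0.06)
})

test_that("planted sex bias skews X expression female-wards", {
    cfg <- smallCfg(113)
    set.seed(2)
    n <- 600
    isX <- seq_len(n) <= 200
    gm <- DataFrame(gene_id = paste0("g", 1:n),
                    promoter_f = rbeta(n, 2, 8),
                    body_delta = ifelse(isX, rnorm(n, -0.25, 0.12), 0),
                    is_x = isX, is_rsx = rep(FALSE, n))
    expr <- simulateExpression(gm, cfg)
    fc <- sexExpressionRatio(setNames(expr$expr_female, expr$gene_id),
                             setNames(expr$expr_male, expr$gene_id))
    de <- expr$de_label
    expect_gt(sum(de == "female_up"), sum(de == "male_up"))
    expect_gt(mean(fc[isX]) - mean(fc[!isX]), 0.15)
})

test_that("dataset files are written once and reproducibly", {
    cfg <- smallCfg(114)
    d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
    s1 <- simulateDataset(cfg, dir = d1, merged = FALSE)
    s2 <- simulateDataset(cfg, dir = d2, merged = FALSE)
    for (f in c("genes.gff3", "cgi.bed", "samples.tsv",
                "expression.tsv", "truth.json")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }
    expect_identical(tools::md5sum(file.path(d1, "genome.fa"))[[1]],
                     tools::md5sum(file.path(d2, "genome.fa"))[[1]])
    sheet <- read.table(file.path(d1, "samples.tsv"), header = TRUE,
                        sep = "\t")
    expect_equal(nrow(sheet), 4L)   # 2 tissues x 2 sexes
})
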