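test_that("the smoother reproduces constants and preserves linear trends", {
    pos <- seq(100, 5100, by = 50)
    n <- length(pos)
    s <- mkMethF("s", pos, rep(0.8, n), cov = 10)
    tr <- smoothTrack(s, "s", halfWindowCpgs = 5, minSpanBp = 500)
    expect_equal(tr@smoothF, rep(0.8, n), tolerance = 1e-9)

    ramp <- seq(0, 1, length.out = 101)
    posR <- seq(0, 100) * 100 + 1
    m <- round(ramp * 100); s2 <- mkMeth("s", posR, m, 100 - m)
    tr2 <- smoothTrack(s2, "s", halfWindowCpgs = 5, minSpanBp = 500)
    interior <- 20:80
    expect_lt(max(abs(tr2@smoothF[interior] - tr2@rawF[interior])), 0.02)
})

test_that("a single outlier is pulled towards its neighbourhood", {
    pos <- (1:50) * 60
    f <- rep(0.9, 50); f[25] <- 0
    s <- mkMethF("s", pos, f, cov = 10)
    tr <- smoothTrack(s, "s", halfWindowCpgs = 5, minSpanBp = 300)
    expect_gt(tr@smoothF[25], 0.5)
})

test_that("smoothing disabled passes raw values through", {
    pos <- (1:20) * 100
    f <- runif(20)
    s <- mkMethF("s", pos, round(f, 1), cov = 10)
    tr0 <- smoothTrack(s, "s", halfWindowCpgs = 0)
    expect_identical(tr0@smoothF, tr0@rawF)
    # too few CpGs for the window: raw passthrough
    few <- smoothTrack(mkMethF("s", c(10, 20, 30), c(0.1, 0.9, 0.5)),
                       "s", halfWindowCpgs = 5)
    expect_identical(few@smoothF, few@rawF)
})

test_that("DMR calling finds planted runs and respects the CpG minimum", {
    pos <- (1:48) * 100
    fA <- rep(0.9, 48); fB <- rep(0.9, 48)
    fB[21:28] <- 0.4                      # 8-CpG block at delta 0.5
    ta <- mkTrack(pos, fA); tb <- mkTrack(pos, fB)
    dm <- callDMRs(ta, tb)
    expect_equal(length(dm), 1L)
    expect_equal(dm$n_cpgs, 8L)
    expect_equal(start(dm), pos[21])
    expect_equal(end(dm), pos[28] + 1L)
    expect_equal(dm$mean_diff, 0.5, tolerance = 1e-9)
    expect_equal(dm$direction, 1L)

    # a run of only 4 qualifying CpGs is not a DMR
    fB4 <- rep(0.9, 48); fB4[21:24] <- 0.4
    expect_equal(length(callDMRs(ta, mkTrack(pos, fB4))), 0L)

    # identical tracks yield nothing
    expect_equal(length(callDMRs(ta, ta)), 0L)

    # a region mean exactly at the threshold qualifies
    fBt <- rep(0.9, 48); fBt[21:28] <- 0.6
    dmT <- callDMRs(ta, mkTrack(pos, fBt))
    expect_equal(length(dmT), 1L)
    expect_equal(dmT$mean_diff, 0.3, tolerance = 1e-9)
})

test_that("mismatched position sets demand intersection first", {
    ta <- mkTrack((1:10) * 10, rep(0.5, 10))
    tb <- mkTrack((1:10) * 10 + 5, rep(0.5, 10))
    expect_error(callDMRs(ta, tb), "intersect")
    tr <- intersectTracks(mkTrack(c(10, 20, 30), c(0.1, 0.2, 0.3)),
                          mkTrack(c(20, 30, 40), c(0.5, 0.6, 0.7)))
    expect_equal(tr[[1]]@pos, c(20L, 30L))
    expect_equal(tr[[2]]@rawF, c(0.5, 0.6))
})

test_that("swapping tracks mirrors DMRs with flipped signs", {
    set.seed(11)
    for (rep in 1:5) {
        pos <- sort(sample(1:20000, 150))
        cov <- rpois(150, 10) + 1
        lvl <- rep(rbeta(15, 2, 2), each = 10)
        fA <- rbinom(150, cov, lvl) / cov
        fB <- rbinom(150, cov, pmax(0, lvl - rep(sample(c(0, 0.5), 15,
            TRUE, prob = c(.7, .3)), each = 10))) / cov
        ta <- mkTrack(pos, fA, cov); tb <- mkTrack(pos, fB, cov)
        ab <- callDMRs(ta, tb); ba <- callDMRs(tb, ta)
        expect_equal(start(ab), start(ba))
        expect_equal(end(ab), end(ba))
        expect_equal(ab$mean_diff, -ba$mean_diff, tolerance = 1e-12)
        expect_equal(ab$direction, -ba$direction)
    }
})

test_that("with smoothing disabled the caller equals a brute-force scan", {
    set.seed(23)
    for (rep in 1:10) {
        pos <- sort(sample(1:25000, 200))
        cov <- rpois(200, 10) + 1
        lvl <- rep(rbeta(20, 5, 2), each = 10)
        shift <- rep(sample(c(0, -0.45, 0.45), 20, TRUE,
                            prob = c(.8, .1, .1)), each = 10)
        fA <- rbinom(200, cov, lvl) / cov
        fB <- rbinom(200, cov, pmin(1, pmax(0, lvl + shift))) / cov
        ta <- mkTrack(pos, fA, cov); tb <- mkTrack(pos, fB, cov)
        dm <- callDMRs(ta, tb)
        oracle <- bruteDmrScan(pos, fA, fB, cov, cov)
        if (is.null(oracle)) {
            expect_equal(length(dm), 0L)
        } else {
            expect_equal(length(dm), nrow(oracle))
            expect_equal(start(dm), as.integer(oracle[, 1]))
            expect_equal(end(dm), as.integer(oracle[, 2]))
            expect_equal(dm$n_cpgs, as.integer(oracle[, 3]))
            expect_equal(dm$mean_diff, oracle[, 4], tolerance = 1e-12)
        }
    }
})

test_that("overlap sharing links at the 50% boundary inclusively", {
    a <- GRanges("s", IRanges(1, 100))     # width 100
    b <- GRanges("s", IRanges(51, 150))    # overlap exactly 50
    mcols(a)$n_cpgs <- 5L; mcols(a)$mean_diff <- 0.4; mcols(a)$direction <- 1L
    mcols(b) <- mcols(a)
    sh <- classifySharing(list(t1 = a, t2 = b))
    expect_true(all(sh$sharing == "shared"))
    expect_equal(sh$sharedWith, c("t2", "t1"))

    far <- GRanges("s", IRanges(500, 600)); mcols(far) <- mcols(a)
    sh2 <- classifySharing(list(t1 = a, t2 = far))
    expect_true(all(sh2$sharing == "tissue-specific"))
})

test_that("sharing components group a 3-way trio and leave a singleton", {
    mk <- function(st, en) {
        g <- GRanges("s", IRanges(st, en))
        mcols(g)$n_cpgs <- 5L; mcols(g)$mean_diff <- 0.4
        mcols(g)$direction <- 1L
        g
    }
    sh <- classifySharing(list(
        brain = suppressWarnings(c(mk(1000, 1400), mk(9000, 9300))),
        kidney = mk(1100, 1500),
        lung = mk(1050, 1450)))
    expect_equal(sum(sh$sharing == "shared"), 3L)
    expect_equal(sum(sh$sharing == "tissue-specific"), 1L)
    trio <- sh[sh$sharing == "shared"]
    expect_equal(length(unique(trio$group)), 1L)
})

test_that("consensus DMRs require support in every pairwise comparison", {
    mk <- function(st, en, dir = 1L) {
        g <- GRanges("s", IRanges(st, en))
        mcols(g)$n_cpgs <- 6L; mcols(g)$mean_diff <- 0.4 * dir
        mcols(g)$direction <- dir
        g
    }
    ref <- suppressWarnings(c(mk(100, 300), mk(1000, 1200)))
    other1 <- mk(150, 350)                # overlaps first only
    cons <- tissueConsensusDmrs(list(ref, other1))
    expect_equal(start(cons), 100L)
    # opposite direction does not count as support
    cons2 <- tissueConsensusDmrs(list(ref, mk(150, 350, dir = -1L)))
    expect_equal(length(cons2), 0L)
})

test_that("clustering groups replicate-like samples with high support", {
    set.seed(31)
    pos <- (1:300) * 50
    lvlT1 <- rbeta(300, 5, 5)
    lvlT2 <- pmin(1, pmax(0, lvlT1 + sample(c(-0.25, 0.25), 300, TRUE)))
    mk <- function(lvl, id, t) {
        cov <- rpois(300, 20) + 1
        Methylome("s", pos, rbinom(300, cov, lvl),
                  cov - rbinom(300, cov, lvl) + 1L, # independent noise
                  sampleId = id, sex = "female", tissue = t)
    }
    mk2 <- function(lvl, id, t) {
        cov <- rpois(300, 20) + 5
        m <- rbinom(300, cov, lvl)
        Methylome("s", pos, m, cov - m, sampleId = id, sex = "female",
                  tissue = t)
    }
    ss <- list(mk2(lvlT1, "a1", "t1"), mk2(lvlT1, "a2", "t1"),
               mk2(lvlT2, "b1", "t2"), mk2(lvlT2, "b2", "t2"))
    cl <- clusterMethylomes(ss, nBoot = 200)
    merges <- cl$hclust$merge
    firstPair <- sort(cl$hclust$labels[-merges[1, ]])
    expect_true(identical(firstPair, c("a1", "a2")) ||
                    identical(firstPair, c("b1", "b2")))
    expect_gt(min(cl$confidence[1:2]), 0.95)
    expect_equal(cl$nBoot, 200)
})

test_that("duplicated samples sit at distance zero with full support", {
    pos <- (1:100) * 30
    a <- mkMethF("s", pos, rep(c(0.2, 0.8), 50), cov = 12, id = "a")
    b <- mkMethF("s", pos, rep(c(0.2, 0.8), 50), cov = 12, id = "b")
    c3 <- mkMethF("s", pos, rep(c(0.9, 0.1), 50), cov = 12, id = "c")
    cl <- clusterMethylomes(list(a, b, c3), nBoot = 50)
    expect_equal(sort(cl$hclust$labels[-cl$hclust$merge[1, ]]),
                 c("a", "b"))
    expect_equal(cl$confidence[1], 1)
    expect_error(clusterMethylomes(list(a, b)), "3")
})
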