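test_that("cytosine report rows map to calls and non-CpG rows are skipped", {
    p <- writeReport(list(
        c("chrX", "100", "+", "7", "3", "CpG", "CGA"),
        c("chrX", "150", "+", "2", "1", "CHH", "CAT"),
        c("chrX", "200", "-", "1", "4", "CpG", "CGT"),
        c("chrX", "250", "+", "0", "2", "CHH", "CTT")))
    s <- readCpGReport(p, sex = "female", tissue = "brain")
    expect_equal(length(methCalls(s)), 2L)
    expect_equal(start(methCalls(s)), c(100L, 200L))
    expect_equal(methLevel(s)[1], 0.7)
    expect_equal(as.character(strand(methCalls(s))), c("+", "-"))
})

test_that("gzipped and space-delimited reports are accepted", {
    rows <- list(c("s1", "10", "+", "3", "1", "CpG", "CGG"),
                 c("s1", "20", "+", "1", "3", "CpG", "CGC"))
    gz <- readCpGReport(writeReport(rows, gz = TRUE), sex = "male",
                        tissue = "t")
    expect_equal(length(methCalls(gz)), 2L)
    sp <- tempfile()
    writeLines(c("s1 10 + 3 1 CpG CGG", "s1 20 + 1 3 CpG CGC"), sp)
    s2 <- readCpGReport(sp, sex = "male", tissue = "t")
    expect_equal(mcols(methCalls(s2))$m, c(3L, 1L))
})

test_that("malformed and negative-count rows error with the line number", {
    bad <- writeReport(list(c("s1", "10", "+", "3", "1", "CpG", "CGG"),
                            c("s1", "xx", "+", "1", "1", "CpG", "CGG")))
    expect_error(readCpGReport(bad, sex = "male", tissue = "t"), "line 2")
    neg <- writeReport(list(c("s1", "10", "+", "-3", "1", "CpG", "CGG")))
    expect_error(readCpGReport(neg, sex = "male", tissue = "t"),
                 "negative")
})

test_that("strand merging collapses dyads and conserves counts", {
    s <- Methylome(rep("s1", 3), c(100, 101, 200), m = c(3, 2, 1),
                   u = c(1, 2, 0), strand = c("+", "-", "+"),
                   sex = "female")
    m <- mergeStrands(s)
    gr <- methCalls(m)
    expect_equal(length(gr), 2L)
    expect_equal(start(gr), c(100L, 200L))
    expect_equal(mcols(gr)$m, c(5L, 1L))
    expect_equal(mcols(gr)$u, c(3L, 0L))
    expect_equal(methLevel(m)[1], 0.625)

    # orphan minus call passes through; totals conserved (seeded fixture)
    set.seed(42)
    pos <- sort(sample(1000:9999, 40) * 2)
    st <- sample(c("+", "-"), 40, replace = TRUE)
    mm <- rpois(40, 4) + 1L; uu <- rpois(40, 4)
    x <- Methylome("sc", pos, mm, uu, strand = st, sex = "male")
    y <- mergeStrands(x)
    expect_equal(sum(mcols(methCalls(y))$m), sum(mm))
    expect_equal(sum(mcols(methCalls(y))$u), sum(uu))
})

test_that("coverage filter keeps calls at the threshold and is idempotent", {
    s <- mkMeth("s1", (1:10) * 10, m = rep(1, 10), u = 0:9)
    f3 <- filterMinCoverage(s, 3)
    expect_equal(length(methCalls(f3)), 8L)       # coverages 1..10
    expect_equal(length(methCalls(filterMinCoverage(s, 1))), 10L)
    expect_identical(methCalls(filterMinCoverage(f3, 3)), methCalls(f3))
    expect_error(filterMinCoverage(s, 0), "minReads")
    s2 <- mkMeth("s1", c(5, 6), m = c(1, 2), u = c(1, 1))
    expect_equal(length(methCalls(filterMinCoverage(s2, 3))), 1L)
})

test_that("scaffold length filter drops short scaffolds from every sample", {
    lens <- c(a = 1e6, b = 2e6, c = 3e6)
    s <- mkMeth(rep(c("a", "b", "c"), each = 5),
                rep((1:5) * 100, 3), m = rep(2, 15), u = rep(2, 15))
    f <- filterMinScaffoldLength(s, lens, 2e6)
    expect_equal(length(methCalls(f)), 10L)
    expect_false("a" %in% as.character(seqnames(methCalls(f))))
    expect_identical(methCalls(filterMinScaffoldLength(s, lens, 0)),
                     methCalls(s))
    expect_error(filterMinScaffoldLength(
        mkMeth("zz", 10, 2, 2), lens, 0), "absent")
    # filters commute
    a <- filterMinCoverage(filterMinScaffoldLength(s, lens, 2e6), 4)
    b <- filterMinScaffoldLength(filterMinCoverage(s, 4), lens, 2e6)
    expect_identical(methCalls(a), methCalls(b))
})

test_that("report writing round-trips through the reader", {
    s <- Methylome(rep("s1", 4), c(10, 11, 50, 51), m = c(3, 2, 0, 5),
                   u = c(1, 1, 4, 0), strand = c("+", "-", "+", "-"),
                   sex = "male", tissue = "lung")
    p <- tempfile(fileext = ".txt.gz")
    writeCpGReport(s, p)
    r <- readCpGReport(p, sex = "male", tissue = "lung")
    expect_equal(start(methCalls(r)), start(methCalls(s)))
    expect_equal(mcols(methCalls(r))$m, mcols(methCalls(s))$m)
    expect_equal(mcols(methCalls(r))$u, mcols(methCalls(s))$u)
})

test_that("pooled methylomes sum counts over the union of positions", {
    a <- mkMeth("s", c(10, 20), m = c(3, 1), u = c(1, 1))
    b <- mkMeth("s", c(20, 30), m = c(2, 5), u = c(2, 0))
    p <- poolMethylomes(list(a, b))
    gr <- methCalls(p)
    expect_equal(start(gr), c(10L, 20L, 30L))
    expect_equal(mcols(gr)$m, c(3L, 3L, 5L))
    expect_equal(mcols(gr)$u, c(1L, 3L, 0L))
})

test_that("sample sheets load their reports with metadata", {
    d <- tempdir()
    p1 <- file.path(d, "a.txt")
    writeLines("s1\t10\t+\t3\t1\tCpG\tCGG", p1)
    sheet <- file.path(d, "sheet.tsv")
    writeLines(c("sample_id\tsex\ttissue\tpath\ttotal_mapped_reads",
                 paste("sampA", "female", "brain", "a.txt", "1000",
                       sep = "\t")), sheet)
    ss <- readSampleSheet(sheet)
    expect_named(ss, "sampA")
    expect_equal(sampleSex(ss$sampA), "female")
    expect_equal(ss$sampA@totalMappedReads, 1000)
})

test_that("Methylome validity rejects bad sex and zero-coverage calls", {
    expect_error(Methylome("s", 1, m = 0, u = 0), "m \\+ u")
    expect_error(Methylome("s", 1, m = 1, u = 0, sex = "unknown"),
                 "sex")
})
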