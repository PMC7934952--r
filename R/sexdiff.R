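#' Windowed female minus male methylation differences
#'
#' Scaffolds are divided into fixed-size bins (conventionally 10 kb); in
#' each bin the mean fractional methylation of the CpGs covered in both
#' samples is computed per sex and the difference
#' \eqn{\Delta = f_{female} - f_{male}} reported. Bins with fewer than
#' \code{minCpgsPerWindow} shared CpGs are omitted. Negative \eqn{\Delta}
#' is female hypomethylation.
#'
#' @param female,male strand-merged, coverage-filtered
#'   \code{\link{Methylome}}s.
#' @param binSize bin width in bp (default 10000).
#' @param minCpgsPerWindow minimum shared CpGs per bin (default 1).
#' @param scaffolds optional scaffold subset.
#' @return \code{GRanges} of bins with mcols \code{n_cpgs},
#'   \code{f_female}, \code{f_male}, \code{delta}.
#' @export
windowDifferences <- function(female, male, binSize = 10000L,
                              minCpgsPerWindow = 1L, scaffolds = NULL) {
    gf <- methCalls(female); gm <- methCalls(male)
    kf <- paste0(seqnames(gf), ":", start(gf))
    km <- paste0(seqnames(gm), ":", start(gm))
    i <- match(kf, km)
    sel <- !is.na(i)
    scaf <- as.character(seqnames(gf))[sel]
    pos <- start(gf)[sel]
    ff <- methLevel(female)[sel]
    fm <- methLevel(male)[i[sel]]
    if (!is.null(scaffolds)) {
        keep <- scaf %in% scaffolds
        scaf <- scaf[keep]; pos <- pos[keep]; ff <- ff[keep]; fm <- fm[keep]
    }
    if (!length(pos)) return(GRanges(n_cpgs = integer(),
                                     f_female = numeric(),
                                     f_male = numeric(), delta = numeric()))
    bin <- (pos - 1L) %/% binSize
    key <- paste0(scaf, "\r", bin)
    grp <- factor(key, levels = unique(key))
    n <- as.integer(table(grp))
    mf <- tapply(ff, grp, mean)
    mm <- tapply(fm, grp, mean)
    first <- !duplicated(key)
    out <- GRanges(scaf[first],
                   IRanges(bin[first] * binSize + 1L,
                           width = binSize),
                   n_cpgs = n, f_female = as.numeric(mf),
                   f_male = as.numeric(mm),
                   delta = as.numeric(mf - mm))
    sort(out[out$n_cpgs >= minCpgsPerWindow])
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact when
#' \eqn{n_a n_b \le 400} and the pooled values are tie-free, otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric vectors, each non-empty.
#' @return List with \code{U} (statistic for group \code{a}) and \code{p}.
#' @export
compareGroups <- function(a, b) {
    if (!length(a) || !length(b)) stop("both groups must be non-empty")
    if (length(unique(c(a, b))) == 1L)           # all values tied
        return(list(U = length(a) * length(b) / 2, p = 1))
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) * length(b) <= 400) && !ties
    wt <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value)
}

#' Sex difference of methylation over a set of intervals
#'
#' Mean female minus male fractional methylation over the CpGs shared by
#' both samples within the union of \code{intervals} (e.g. the CpG islands
#' upstream of a locus of interest), plus the relative reduction in
#' females, \eqn{-\bar\Delta / \bar f_{male} \times 100\%}.
#'
#' @param female,male strand-merged \code{\link{Methylome}}s.
#' @param intervals \code{GRanges}.
#' @return List: \code{n_cpgs}, \code{mean_delta}, \code{reduction_pct},
#'   \code{per_cpg} (\code{DataFrame} of scaffold, pos, f_female, f_male,
#'   delta).
#' @export
regionSexDifference <- function(female, male, intervals) {
    gf <- methCalls(female); gm <- methCalls(male)
    inF <- overlapsAny(gf, intervals, ignore.strand = TRUE)
    kf <- paste0(seqnames(gf), ":", start(gf))
    km <- paste0(seqnames(gm), ":", start(gm))
    i <- match(kf, km)
    sel <- which(inF & !is.na(i))
    if (!length(sel)) stop("no shared covered CpGs in the intervals")
    ff <- methLevel(female)[sel]
    fm <- methLevel(male)[i[sel]]
    md <- mean(ff - fm)
    list(n_cpgs = length(sel), mean_delta = md,
         reduction_pct = if (mean(fm) > 0) -md / mean(fm) * 100 else NA_real_,
         per_cpg = DataFrame(scaffold = as.character(seqnames(gf))[sel],
                             pos = start(gf)[sel], f_female = ff,
                             f_male = fm, delta = ff - fm))
}

#' Length-matched autosomal scaffold sample
#'
#' Greedy selection of autosomal scaffolds length-matched to a target
#' scaffold set (within \code{tolerance} relative length per scaffold),
#' used to build a "matched autosome" comparison set for X-versus-autosome
#' contrasts.
#'
#' @param autosomeLengths,targetLengths named numeric vectors of scaffold
#'   lengths.
#' @param tolerance relative length tolerance (default 0.1).
#' @return Character vector of selected autosomal scaffold names (one per
#'   target scaffold where a match exists).
#' @export
matchedAutosomes <- function(autosomeLengths, targetLengths,
                             tolerance = 0.1) {
    avail <- autosomeLengths
    out <- character()
    for (tl in sort(targetLengths, decreasing = TRUE)) {
        if (!length(avail)) break
        rel <- abs(avail - tl) / tl
        j <- which.min(rel)
        if (rel[j] <= tolerance) {
            out <- c(out, names(avail)[j])
            avail <- avail[-j]
        }
    }
    out
}
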