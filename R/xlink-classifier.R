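#' Female/male CpG sequencing-depth ratio on a scaffold
#'
#' Ratio of the median read depth over the two samples' shared CpGs on a
#' scaffold. Because females carry two X chromosomes and males one, the
#' ratio is expected near 2 on X-linked sequence and near 1 on autosomes.
#'
#' @param female,male \code{\link{Methylome}}s.
#' @param scaffold scaffold name.
#' @param minSharedCpgs minimum shared CpGs required (default 20).
#' @return Numeric ratio.
#' @export
coverageRatio <- function(female, male, scaffold, minSharedCpgs = 20L) {
    gf <- methCalls(female); gm <- methCalls(male)
    pf <- start(gf)[as.character(seqnames(gf)) == scaffold]
    pm <- start(gm)[as.character(seqnames(gm)) == scaffold]
    shared <- intersect(pf, pm)
    if (length(shared) < minSharedCpgs)
        stop("fewer than ", minSharedCpgs, " shared CpGs on ", scaffold)
    covF <- cpgCoverage(female)[as.character(seqnames(gf)) == scaffold]
    covM <- cpgCoverage(male)[as.character(seqnames(gm)) == scaffold]
    medM <- median(covM[match(shared, pm)])
    if (medM == 0) stop("male median coverage is zero on ", scaffold)
    median(covF[match(shared, pf)]) / medM
}

#' Fraction of a sample's mapped reads on a scaffold set
#'
#' @param sample \code{\link{Methylome}} with per-scaffold and total
#'   mapped-read counts.
#' @param scaffoldSet character vector of scaffold names.
#' @return Fraction in [0, 1].
#' @export
mappedReadProportion <- function(sample, scaffoldSet) {
    per <- sample@perScaffoldMappedReads
    tot <- sample@totalMappedReads
    if (!length(per) || is.na(tot))
        stop("sample lacks per-scaffold or total mapped-read counts")
    sum(per[intersect(names(per), scaffoldSet)]) / tot
}

#' One-sided test for a female-hypomethylation shift
#'
#' Wilcoxon signed-rank test of per-window female minus male methylation
#' differences against zero, alternative "the median difference is
#' negative": exact when n <= 25 with tie-free, non-zero deltas, otherwise
#' the normal approximation with continuity correction. All-zero deltas
#' return p = 1 with a degenerate flag.
#'
#' @param windowDeltas numeric vector of per-window deltas.
#' @param minWindows minimum number of windows (default 5).
#' @return List: \code{mean_delta}, \code{p}, \code{n},
#'   \code{degenerate}.
#' @export
hypomethylationTest <- function(windowDeltas, minWindows = 5L) {
    n <- length(windowDeltas)
    if (n < minWindows)
        stop("need at least ", minWindows, " windows, got ", n)
    if (all(windowDeltas == 0))
        return(list(mean_delta = 0, p = 1, n = n, degenerate = TRUE))
    nz <- windowDeltas[windowDeltas != 0]
    exact <- length(nz) <= 25L && !anyDuplicated(abs(nz)) &&
        length(nz) == n
    wt <- suppressWarnings(
        wilcox.test(windowDeltas, mu = 0, alternative = "less",
                    exact = exact, correct = TRUE))
    list(mean_delta = mean(windowDeltas), p = wt$p.value, n = n,
         degenerate = FALSE)
}

#' Classify unplaced scaffolds as X-linked, autosomal or ambiguous
#'
#' Formalises a multi-evidence X-linkage call for scaffolds unplaced in
#' the assembly, combining (i) a per-tissue one-sided signed-rank test for
#' a shift of 10 kb-window female-male methylation differences towards
#' female hypomethylation, Benjamini-Hochberg corrected across scaffolds
#' within each tissue, and (ii) the female/male CpG depth ratio expected
#' near 2 on X-linked sequence. A scaffold is labelled \code{"X-linked"}
#' only when every tissue shows q < \code{alpha} with a negative mean
#' delta and the depth ratio falls inside \code{covBand} in every tissue
#' with depth data; \code{"autosomal"} when no tissue is significant and
#' the ratio is inside \code{autoBand}; otherwise \code{"ambiguous"}.
#'
#' @param samplesByTissue named list; each element is a
#'   \code{list(female = , male = )} pair of \code{\link{Methylome}}s for
#'   one tissue.
#' @param scaffolds character vector of scaffold names to classify.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param covBand female/male depth-ratio band for an X call
#'   (default c(1.5, 2.5)).
#' @param autoBand depth-ratio band for an autosomal call
#'   (default c(0.8, 1.2)).
#' @param binSize window size in bp (default 10000).
#' @param minWindows minimum windows per scaffold/tissue (default 5).
#' @param minCpgsPerWindow minimum shared CpGs per window (default 3).
#' @param minSharedCpgs minimum shared CpGs for a depth ratio (default 20).
#' @return \code{DataFrame}: one row per scaffold with \code{label} and
#'   per-tissue \code{mean_delta_*}, \code{q_*}, \code{cov_ratio_*}
#'   columns.
#' @export
classifyScaffolds <- function(samplesByTissue, scaffolds, alpha = 0.05,
                              covBand = c(1.5, 2.5),
                              autoBand = c(0.8, 1.2), binSize = 10000L,
                              minWindows = 5L, minCpgsPerWindow = 3L,
                              minSharedCpgs = 20L) {
    stopifnot(length(samplesByTissue) >= 1L,
              !is.null(names(samplesByTissue)))
    tissues <- names(samplesByTissue)
    nS <- length(scaffolds)
    meanDelta <- qMat <- covR <- matrix(NA_real_, nS, length(tissues),
                                        dimnames = list(scaffolds, tissues))
    for (t in tissues) {
        pair <- samplesByTissue[[t]]
        if (!all(c("female", "male") %in% names(pair)))
            stop("tissue '", t, "' lacks a female/male pair")
        wd <- windowDifferences(pair$female, pair$male, binSize = binSize,
                                minCpgsPerWindow = minCpgsPerWindow,
                                scaffolds = scaffolds)
        wScaf <- as.character(seqnames(wd))
        pvals <- rep(NA_real_, nS)
        for (i in seq_len(nS)) {
            d <- mcols(wd)$delta[wScaf == scaffolds[i]]
            if (length(d) >= minWindows) {
                ht <- hypomethylationTest(d, minWindows)
                meanDelta[i, t] <- ht$mean_delta
                pvals[i] <- ht$p
            }
            covR[i, t] <- tryCatch(
                coverageRatio(pair$female, pair$male, scaffolds[i],
                              minSharedCpgs),
                error = function(e) NA_real_)
        }
        qMat[, t] <- p.adjust(pvals, method = "BH")
    }
    label <- vapply(seq_len(nS), function(i) {
        q <- qMat[i, ]; md <- meanDelta[i, ]; cr <- covR[i, ]
        if (all(is.na(q))) return("ambiguous")
        sigAll <- all(!is.na(q) & q < alpha & md < 0)
        crOk <- is.na(cr) | (cr >= covBand[1] & cr <= covBand[2])
        if (sigAll && all(crOk)) return("X-linked")
        noneSig <- all(is.na(q) | q >= alpha)
        autoOk <- is.na(cr) | (cr >= autoBand[1] & cr <= autoBand[2])
        if (noneSig && all(autoOk)) return("autosomal")
        "ambiguous"
    }, character(1))
    out <- DataFrame(scaffold = scaffolds, label = label)
    for (t in tissues) {
        out[[paste0("mean_delta_", t)]] <- meanDelta[, t]
        out[[paste0("q_", t)]] <- qMat[, t]
        out[[paste0("cov_ratio_", t)]] <- covR[, t]
    }
    out
}
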