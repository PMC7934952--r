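#' Call differentially methylated regions between two smoothed tracks
#'
#' Two-threshold region calling in the style of smoothing-based DMR
#' finders: candidate regions are maximal runs of consecutive CpGs whose
#' smoothed methylation difference (A minus B) has a consistent sign and
#' absolute value at least \code{qualifyDiff} (the candidate cutoff); a
#' candidate becomes a DMR when it contains at least \code{minCpgs} CpGs
#' and its mean smoothed difference is at least \code{minDiff} in
#' absolute value. Values exactly at either threshold qualify. The
#' candidate cutoff defaults to \code{minDiff / 2}, which places the
#' region boundary near the half-height point of a methylation step and
#' so localises block edges well; setting \code{qualifyDiff = minDiff}
#' recovers a plain single-threshold scan. Same-sign candidate runs
#' separated by at most \code{maxGapCpgs} sub-threshold CpGs are bridged
#' (the gap CpGs become members and count towards the region mean), so a
#' single noisy CpG does not split a region; runs qualifying with
#' opposite signs are never bridged. The region filter
#' \code{|mean_diff| >= minDiff} is evaluated on the raw (unsmoothed)
#' differences of the member CpGs, which is an unbiased estimate of the
#' region effect (the smoothed difference is attenuated at region
#' edges); candidate membership uses the smoothed track, but region ends
#' are trimmed back to CpGs whose raw difference itself reaches
#' \code{qualifyDiff} with the region's sign, so smoothing leakage into
#' flanking CpGs does not inflate the interval. The emitted interval
#' spans the first to the last member CpG dyad.
#'
#' @param trackA,trackB \code{\link{SmoothedTrack}}s on the same scaffold
#'   with identical CpG position sets (intersect beforehand if needed, e.g.
#'   with \code{\link{intersectTracks}}).
#' @param minDiff minimum absolute mean smoothed difference per region
#'   (default 0.3).
#' @param minCpgs minimum CpGs per DMR (default 5).
#' @param qualifyDiff per-CpG candidate cutoff (default \code{minDiff/2}).
#' @param maxGapCpgs sub-threshold CpGs bridged between same-sign runs
#'   (default 2).
#' @param trimDiff raw-difference support a region end CpG must show
#'   (default \code{minDiff}); edges are trimmed until supported.
#' @param maxGapBp maximum genomic distance between consecutive member
#'   CpGs (default 300); a candidate region is split at larger gaps, the
#'   usual CpG-clustering rule of region-based callers.
#' @param minZ minimum evidence ratio |mean_diff| / SE, where SE is the
#'   binomial standard error of the region mean difference given the
#'   per-CpG coverages (default 3). Guards against regions assembled
#'   from a few poorly covered, noisy CpGs; set to 0 to disable.
#' @return \code{GRanges} of DMRs with mcols \code{n_cpgs},
#'   \code{mean_diff} (mean smoothed A-B over member CpGs) and
#'   \code{direction} (+1 when A is hypermethylated relative to B).
#' @export
callDMRs <- function(trackA, trackB, minDiff = 0.3, minCpgs = 5L,
                     qualifyDiff = minDiff / 2, maxGapCpgs = 2L,
                     maxGapBp = 300L, trimDiff = minDiff, minZ = 3) {
    if (trackA@scaffold != trackB@scaffold ||
        length(trackA@pos) != length(trackB@pos) ||
        any(trackA@pos != trackB@pos))
        stop("tracks must share an identical CpG position set; ",
             "intersect the tracks first (see intersectTracks())")
    pos <- trackA@pos
    if (!length(pos)) return(.emptyDmrGRanges())
    diff <- trackA@smoothF - trackB@smoothF
    rawDiff <- trackA@rawF - trackB@rawF
    # a member CpG needs a qualifying smoothed excursion whose sign its
    # own raw difference does not contradict (guards against smoothing
    # leakage into flanking CpGs)
    qual <- abs(diff) >= qualifyDiff - 1e-12 & rawDiff * sign(diff) > 0
    s <- ifelse(qual, sign(diff), 0)
    r <- rle(s)
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    qRuns <- which(r$values != 0)
    if (!length(qRuns)) return(.emptyDmrGRanges())
    # bridge same-sign runs over short sub-threshold gaps whose CpGs do
    # not swing to the opposite sign
    si <- integer(); ei <- integer(); sg <- integer()
    cur <- qRuns[1L]
    curStart <- startIdx[cur]; curEnd <- endIdx[cur]; curSign <- r$values[cur]
    if (length(qRuns) > 1L) for (k in qRuns[-1L]) {
        gapLen <- startIdx[k] - curEnd - 1L
        if (r$values[k] == curSign && gapLen <= maxGapCpgs) {
            curEnd <- endIdx[k]
        } else {
            si <- c(si, curStart); ei <- c(ei, curEnd); sg <- c(sg, curSign)
            curStart <- startIdx[k]; curEnd <- endIdx[k]
            curSign <- r$values[k]
        }
    }
    si <- c(si, curStart); ei <- c(ei, curEnd); sg <- c(sg, curSign)
    # split candidate regions at large genomic gaps between member CpGs
    si2 <- integer(); ei2 <- integer(); sg2 <- integer()
    for (k in seq_along(si)) {
        idx <- si[k]:ei[k]
        cut <- which(diff(pos[idx]) > maxGapBp)
        pieceStart <- c(idx[1L], idx[cut + 1L])
        pieceEnd <- c(idx[cut], idx[length(idx)])
        si2 <- c(si2, pieceStart); ei2 <- c(ei2, pieceEnd)
        sg2 <- c(sg2, rep(sg[k], length(pieceStart)))
    }
    si <- si2; ei <- ei2; sg <- sg2
    # trim edges not supported by the raw data: smoothing leaks signal
    # into flanking CpGs, so region ends must themselves show the effect
    for (k in seq_along(si)) {
        while (si[k] <= ei[k] &&
               sg[k] * rawDiff[si[k]] < trimDiff - 1e-12)
            si[k] <- si[k] + 1L
        while (ei[k] >= si[k] &&
               sg[k] * rawDiff[ei[k]] < trimDiff - 1e-12)
            ei[k] <- ei[k] - 1L
    }
    ok <- si <= ei
    si <- si[ok]; ei <- ei[ok]; sg <- sg[ok]
    if (!length(si)) return(.emptyDmrGRanges())
    md <- vapply(seq_along(si),
                 function(k) mean(rawDiff[si[k]:ei[k]]), numeric(1))
    # binomial SE of the region mean difference, pooled per-CpG level
    pbar <- pmin(0.95, pmax(0.05, (trackA@rawF + trackB@rawF) / 2))
    varCpg <- pbar * (1 - pbar) *
        (1 / pmax(trackA@cov, 1) + 1 / pmax(trackB@cov, 1))
    z <- vapply(seq_along(si), function(k) {
        idx <- si[k]:ei[k]
        abs(md[k]) / (sqrt(sum(varCpg[idx])) / length(idx))
    }, numeric(1))
    nC <- ei - si + 1L
    pass <- nC >= minCpgs & abs(md) >= minDiff - 1e-12 &
        sg == sign(md) & z >= minZ
    if (!any(pass)) return(.emptyDmrGRanges())
    si <- si[pass]; ei <- ei[pass]; md <- md[pass]
    GRanges(trackA@scaffold,
            IRanges(pos[si], pos[ei] + 1L),
            n_cpgs = ei - si + 1L, mean_diff = md,
            direction = as.integer(sign(md)))
}

.emptyDmrGRanges <- function() {
    GRanges(n_cpgs = integer(), mean_diff = numeric(), direction = integer())
}

#' Restrict two tracks to their common CpG positions
#'
#' @param trackA,trackB \code{\link{SmoothedTrack}}s on one scaffold.
#' @return List of the two tracks on the intersection grid.
#' @export
intersectTracks <- function(trackA, trackB) {
    common <- intersect(trackA@pos, trackB@pos)
    sub <- function(tr) {
        i <- match(common, tr@pos)
        new("SmoothedTrack", scaffold = tr@scaffold,
            pos = tr@pos[i], rawF = tr@rawF[i],
            smoothF = tr@smoothF[i], cov = tr@cov[i])
    }
    list(sub(trackA), sub(trackB))
}

#' Classify DMRs as tissue-specific or shared across tissues
#'
#' DMRs from different tissues are linked when their overlap, normalised by
#' the shorter interval (or, in reciprocal mode, the longer), is at least
#' \code{minOverlapFrac}; the boundary value itself links. Connected
#' components of the link graph define shared groups; a DMR whose component
#' contains only its own tissue is tissue-specific.
#'
#' @param dmrSets named list (one element per tissue) of DMR \code{GRanges}.
#' @param minOverlapFrac overlap fraction threshold (default 0.5).
#' @param reciprocal normalise by the longer interval instead of the
#'   shorter (default \code{FALSE}).
#' @return A \code{GRanges} of all input DMRs with mcols \code{tissue},
#'   \code{group} (component id), \code{sharing}
#'   (\code{"tissue-specific"} or \code{"shared"}) and \code{sharedWith}.
#' @export
classifySharing <- function(dmrSets, minOverlapFrac = 0.5,
                            reciprocal = FALSE) {
    stopifnot(is.list(dmrSets), !is.null(names(dmrSets)))
    tissues <- rep(names(dmrSets), vapply(dmrSets, length, integer(1)))
    keepMc <- Reduce(intersect, lapply(dmrSets,
                                       function(g) colnames(mcols(g))))
    all <- suppressWarnings(do.call(c, unname(lapply(dmrSets, function(g) {
        mcols(g) <- mcols(g)[, keepMc, drop = FALSE]
        g
    }))))
    mcols(all)$tissue <- tissues
    n <- length(all)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1L) {
        hits <- findOverlaps(all, all)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        keep <- qh < sh & tissues[qh] != tissues[sh]
        qh <- qh[keep]; sh <- sh[keep]
        if (length(qh)) {
            ovl <- width(GenomicRanges::pintersect(all[qh], all[sh]))
            denom <- if (reciprocal) pmax(width(all[qh]), width(all[sh]))
                     else pmin(width(all[qh]), width(all[sh]))
            linked <- ovl / denom >= minOverlapFrac - 1e-12
            for (k in which(linked)) {
                ri <- find(qh[k]); rj <- find(sh[k])
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    comp <- match(comp, unique(comp))
    tisByComp <- split(tissues, comp)
    nTis <- vapply(tisByComp, function(t) length(unique(t)), integer(1))
    mcols(all)$group <- comp
    mcols(all)$sharing <- ifelse(nTis[comp] > 1L, "shared",
                                 "tissue-specific")
    mcols(all)$sharedWith <- vapply(seq_len(n), function(i) {
        others <- setdiff(unique(tisByComp[[comp[i]]]), tissues[i])
        paste(others, collapse = ",")
    }, character(1))
    all
}

#' Consensus DMRs of one tissue against all others
#'
#' A tissue's DMRs are the regions found differential in its pairwise
#' comparison against every other tissue: DMRs of the first comparison are
#' kept when a same-direction DMR in each remaining comparison overlaps
#' them by at least \code{minOverlapFrac} of the shorter interval.
#'
#' @param pairwise named list of DMR \code{GRanges}, one per comparison of
#'   the focal tissue against another tissue (mcol \code{direction}
#'   required).
#' @param minOverlapFrac overlap threshold (default 0.5).
#' @return \code{GRanges} subset of the first comparison's DMRs.
#' @export
tissueConsensusDmrs <- function(pairwise, minOverlapFrac = 0.5) {
    stopifnot(length(pairwise) >= 1L)
    ref <- pairwise[[1L]]
    if (length(pairwise) == 1L || !length(ref)) return(ref)
    keep <- rep(TRUE, length(ref))
    for (other in pairwise[-1L]) {
        if (!length(other)) return(ref[rep(FALSE, length(ref))])
        hits <- findOverlaps(ref, other)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        ovl <- width(GenomicRanges::pintersect(ref[qh], other[sh]))
        ok <- ovl / pmin(width(ref[qh]), width(other[sh])) >=
            minOverlapFrac - 1e-12 &
            mcols(ref)$direction[qh] == mcols(other)$direction[sh]
        keep <- keep & seq_along(ref) %in% qh[ok]
    }
    ref[keep]
}

#' Write DMRs as BED6+3
#'
#' Columns: scaffold, 0-based start, end, name (tissue or comparison
#' label), score = round(1000 * |mean_diff|), strand ".", then n_cpgs,
#' mean_diff and the sharing label when present.
#'
#' @param dmrs DMR \code{GRanges} from \code{\link{callDMRs}} or
#'   \code{\link{classifySharing}}.
#' @param path output file.
#' @param name fallback name column.
#' @return \code{path}, invisibly.
#' @export
writeDmrBed <- function(dmrs, path, name = "dmr") {
    mc <- mcols(dmrs)
    df <- data.frame(
        chrom = as.character(seqnames(dmrs)),
        start = start(dmrs) - 1L, end = end(dmrs),
        name = if ("tissue" %in% colnames(mc)) mc$tissue else name,
        score = round(1000 * abs(mc$mean_diff)),
        strand = ".",
        n_cpgs = mc$n_cpgs, mean_diff = mc$mean_diff,
        sharing = if ("sharing" %in% colnames(mc)) mc$sharing else ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
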