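#' Hierarchical clustering of methylomes with bootstrap confidence
#'
#' Samples are clustered on the fractional methylation of CpGs covered by
#' at least \code{minSharedCov} reads in every sample, using Euclidean
#' distances and Ward's agglomeration. Node support is estimated by an
#' ordinary bootstrap over CpG columns: each replicate resamples the CpG
#' features with replacement, reclusters, and a node's confidence is the
#' fraction of replicates reproducing its leaf bipartition.
#'
#' @param samples list of strand-merged \code{\link{Methylome}}s
#'   (at least 3).
#' @param minSharedCov minimum per-sample coverage for a CpG to enter the
#'   feature matrix (default 1).
#' @param nBoot bootstrap replicates (default 1000).
#' @return List with \code{hclust} (the tree, Ward linkage),
#'   \code{confidence} (per internal node, ordered as
#'   \code{hclust$merge} rows), \code{nCpgs} and \code{nBoot}.
#' @export
clusterMethylomes <- function(samples, minSharedCov = 1L, nBoot = 1000L) {
    stopifnot(length(samples) >= 3L)
    keys <- lapply(samples, function(s) {
        gr <- methCalls(s)
        paste0(seqnames(gr), ":", start(gr))[cpgCoverage(s) >= minSharedCov]
    })
    common <- Reduce(intersect, keys)
    if (length(common) < 2L)
        stop("fewer than 2 CpGs shared at the required coverage")
    M <- vapply(samples, function(s) {
        gr <- methCalls(s)
        k <- paste0(seqnames(gr), ":", start(gr))
        methLevel(s)[match(common, k)]
    }, numeric(length(common)))
    colnames(M) <- vapply(samples, sampleId, character(1))
    hc <- hclust(dist(t(M)), method = "ward.D2")
    clades <- .hclustClades(hc)
    hit <- integer(length(clades))
    for (b in seq_len(nBoot)) {
        idx <- sample.int(nrow(M), nrow(M), replace = TRUE)
        hb <- hclust(dist(t(M[idx, , drop = FALSE])), method = "ward.D2")
        cb <- .hclustClades(hb)
        hit <- hit + (clades %in% cb)
    }
    list(hclust = hc, confidence = hit / nBoot,
         nCpgs = nrow(M), nBoot = nBoot)
}

# canonical string per internal node: sorted leaf labels
.hclustClades <- function(hc) {
    n <- length(hc$labels)
    members <- vector("list", nrow(hc$merge))
    out <- character(nrow(hc$merge))
    for (k in seq_len(nrow(hc$merge))) {
        take <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
        members[[k]] <- c(take(hc$merge[k, 1L]), take(hc$merge[k, 2L]))
        out[k] <- paste(sort(members[[k]]), collapse = "|")
    }
    out
}
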