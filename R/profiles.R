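#' Metagene methylation profile over relative-length bins
#'
#' Each gene region (promoter or gene body) is divided 5'-to-3' into
#' \code{nBins} bins of equal relative length; for every gene and bin the
#' mean fractional methylation of the CpGs falling in the bin is computed
#' per sample group, then averaged across genes. Per bin, female and male
#' gene-level values are compared with a two-sided Mann-Whitney test.
#' Genes shorter than \code{nBins} bp are skipped (count reported in the
#' \code{skipped} attribute).
#'
#' @param samplesBySex list with elements \code{female} and \code{male},
#'   each a \code{\link{Methylome}} or list of them (pooled by averaging
#'   gene-level values across samples).
#' @param genes stranded \code{GRanges} with \code{gene_id}.
#' @param nBins number of bins (default 20).
#' @param region \code{"gene_body"} (the gene interval itself) or
#'   \code{"promoter"} (1 kb upstream).
#' @param promoterWidth promoter extent when \code{region = "promoter"}.
#' @return \code{DataFrame}: bin, mean_f_female, mean_f_male, n_genes, p.
#' @export
metageneProfile <- function(samplesBySex, genes, nBins = 20L,
                            region = c("gene_body", "promoter"),
                            promoterWidth = 1000L) {
    region <- match.arg(region)
    stopifnot(all(c("female", "male") %in% names(samplesBySex)))
    regs <- if (region == "promoter")
        geneRegions(genes, promoterWidth)$promoter else granges(genes)
    ok <- width(regs) >= nBins
    skipped <- sum(!ok)
    regs <- regs[ok]
    ids <- mcols(genes)$gene_id[ok]
    strands <- as.character(strand(genes))[ok]

    geneBinMeans <- function(sample) {
        gr <- methCalls(sample)
        hits <- findOverlaps(gr, regs, ignore.strand = TRUE)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        rel <- (start(gr)[qh] - start(regs)[sh]) / width(regs)[sh]
        neg <- strands[sh] == "-"
        rel[neg] <- 1 - rel[neg] - 1 / width(regs)[sh[neg]]
        bin <- pmin(nBins, floor(rel * nBins) + 1L)
        f <- methLevel(sample)[qh]
        M <- matrix(NA_real_, length(regs), nBins)
        key <- (sh - 1L) * nBins + bin
        means <- tapply(f, key, mean)
        kk <- as.integer(names(means))
        M[cbind((kk - 1L) %/% nBins + 1L, (kk - 1L) %% nBins + 1L)] <- means
        M
    }
    groupMeans <- function(g) {
        ss <- samplesBySex[[g]]
        if (is(ss, "Methylome")) ss <- list(ss)
        mats <- lapply(ss, geneBinMeans)
        Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m))) /
            Reduce(`+`, lapply(mats, function(m) !is.na(m)))
    }
    Mf <- groupMeans("female"); Mm <- groupMeans("male")
    p <- vapply(seq_len(nBins), function(b) {
        a <- Mf[, b]; bb <- Mm[, b]
        cc <- !is.na(a) & !is.na(bb)
        if (sum(cc) < 2L) return(NA_real_)
        compareGroups(a[cc], bb[cc])$p
    }, numeric(1))
    out <- DataFrame(bin = seq_len(nBins),
                     mean_f_female = colMeans(Mf, na.rm = TRUE),
                     mean_f_male = colMeans(Mm, na.rm = TRUE),
                     n_genes = colSums(!is.na(Mf) & !is.na(Mm)),
                     p = p)
    attr(out, "skipped") <- skipped
    out
}

#' Sliding-window methylation profile around transcription start sites
#'
#' For every offset on a grid from \code{-flankBp} to \code{+flankBp} in
#' steps of \code{stepBp}, the mean fractional methylation of CpGs within
#' \code{windowBp/2} of (TSS + offset) is computed per TSS and averaged
#' across TSSs; orientation is strand-aware (offsets run 5' to 3'). At the
#' conventional parameters (5 kb flank, 100 bp window, 10 bp step) the
#' profile has exactly 1001 points. Offsets with no covered CpG at any TSS
#' are \code{NA}.
#'
#' @param sample a strand-merged \code{\link{Methylome}}.
#' @param tss stranded \code{GRanges}; the TSS is the strand-aware start.
#' @param flankBp,windowBp,stepBp profile geometry (defaults 5000, 100, 10).
#' @return \code{DataFrame}: offset, mean_f, n_tss.
#' @export
tssProfile <- function(sample, tss, flankBp = 5000L, windowBp = 100L,
                       stepBp = 10L) {
    offsets <- seq(-flankBp, flankBp, by = stepBp)
    gr <- methCalls(sample)
    f <- methLevel(sample)
    tssPos <- ifelse(as.character(strand(tss)) == "-", end(tss), start(tss))
    tssStrand <- as.character(strand(tss))
    half <- windowBp / 2
    rel <- numeric(); tssIdx <- integer(); fv <- numeric()
    scafC <- as.character(seqnames(gr))
    for (t in seq_along(tss)) {
        sel <- which(scafC == as.character(seqnames(tss))[t] &
                     abs(start(gr) - tssPos[t]) <= flankBp + half)
        if (!length(sel)) next
        r <- start(gr)[sel] - tssPos[t]
        if (tssStrand[t] == "-") r <- -r
        rel <- c(rel, r); tssIdx <- c(tssIdx, rep(t, length(sel)))
        fv <- c(fv, f[sel])
    }
    meanF <- rep(NA_real_, length(offsets))
    nT <- integer(length(offsets))
    if (length(rel)) {
        o <- order(rel)
        rel <- rel[o]; tssIdx <- tssIdx[o]; fv <- fv[o]
        for (k in seq_along(offsets)) {
            lo <- findInterval(offsets[k] - half - 1e-9, rel) + 1L
            hi <- findInterval(offsets[k] + half + 1e-9, rel)
            if (hi < lo) next
            idx <- lo:hi
            perTss <- tapply(fv[idx], tssIdx[idx], mean)
            meanF[k] <- mean(perTss)
            nT[k] <- length(perTss)
        }
    }
    DataFrame(offset = offsets, mean_f = meanF, n_tss = nT)
}
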