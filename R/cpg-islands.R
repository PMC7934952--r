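#' Detect CpG islands by GC content and CpG observed/expected ratio
#'
#' Classic sliding-window CGI detection: every \code{minLen}-bp window
#' (step 1) is scored for GC fraction and observed/expected CpG ratio,
#' where expected CpG = (#C * #G) / window length. Windows meeting all
#' thresholds are merged when they overlap or abut, and each merged
#' interval is re-validated against the same thresholds (failing merges
#' are dropped).
#'
#' @param genome \code{DNAStringSet}.
#' @param minLen minimum island length / window size (default 200).
#' @param minGc minimum GC fraction (default 0.5).
#' @param minOe minimum observed/expected CpG ratio (default 0.6).
#' @return \code{GRanges} with mcols \code{gc_frac}, \code{obs_exp_cpg}.
#' @export
detectCpgIslands <- function(genome, minLen = 200L, minGc = 0.5,
                             minOe = 0.6) {
    accScaf <- character(); accRange <- list()
    accGc <- numeric(); accOe <- numeric()
    for (sc in names(genome)) {
        s <- toupper(as.character(genome[[sc]]))
        L <- nchar(s)
        if (L < minLen) next
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        isC <- ch == "C"; isG <- ch == "G"
        isCpG <- c(isC[-L] & isG[-1L], FALSE)
        cumC <- cumsum(isC); cumG <- cumsum(isG); cumCpG <- cumsum(isCpG)
        starts <- seq_len(L - minLen + 1L)
        ends <- starts + minLen - 1L
        nC <- cumC[ends] - c(0, cumC)[starts]
        nG <- cumG[ends] - c(0, cumG)[starts]
        # CpG dinucleotides fully inside the window
        nCpG <- cumCpG[ends - 1L] - c(0, cumCpG)[starts]
        gc <- (nC + nG) / minLen
        oe <- ifelse(nC * nG > 0, nCpG * minLen / (nC * nG), 0)
        ok <- gc >= minGc & oe >= minOe
        if (!any(ok)) next
        merged <- reduce(IRanges(starts[ok], ends[ok]))
        stat <- function(st, en) {
            w <- en - st + 1L
            nc <- cumC[en] - c(0, cumC)[st]
            ng <- cumG[en] - c(0, cumG)[st]
            ncpg <- cumCpG[en - 1L] - c(0, cumCpG)[st]
            list(gc = (nc + ng) / w,
                 oe = ifelse(nc * ng > 0, ncpg * w / (nc * ng), 0))
        }
        stm <- stat(IRanges::start(merged), IRanges::end(merged))
        pass <- stm$gc >= minGc & stm$oe >= minOe
        if (!any(pass)) next
        accScaf <- c(accScaf, rep(sc, sum(pass)))
        accRange <- c(accRange, list(merged[pass]))
        accGc <- c(accGc, stm$gc[pass])
        accOe <- c(accOe, stm$oe[pass])
    }
    if (!length(accScaf))
        return(GRanges(gc_frac = numeric(), obs_exp_cpg = numeric()))
    GRanges(accScaf, do.call(c, accRange), gc_frac = accGc,
            obs_exp_cpg = accOe)
}
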