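#' Smooth a sample's fractional methylation along one scaffold
#'
#' Coverage-weighted local polynomial smoothing of per-CpG fractional
#' methylation, in the spirit of smoothing-based DMR callers: for each CpG
#' the fit window is the symmetric set of at least \code{2*halfWindowCpgs+1}
#' CpGs, widened if necessary to span at least \code{minSpanBp} bases; a
#' degree-(<=2) polynomial is fitted by weighted least squares with tricube
#' distance weights multiplied by read coverage, and evaluated at the CpG.
#' Values are clipped to [0, 1]. With fewer than \code{2*halfWindowCpgs+1}
#' CpGs on the scaffold, or with \code{halfWindowCpgs = 0} (smoothing
#' disabled), raw values pass through.
#'
#' @param sample a strand-merged \code{\link{Methylome}}.
#' @param scaffold scaffold to smooth.
#' @param halfWindowCpgs CpGs on each side of the centre (default 35).
#' @param minSpanBp minimum window span in bp (default 1000).
#' @param degree maximum polynomial degree, 0-2 (default 2).
#' @return A \code{\link{SmoothedTrack}}.
#' @export
smoothTrack <- function(sample, scaffold, halfWindowCpgs = 35L,
                        minSpanBp = 1000L, degree = 2L) {
    gr <- methCalls(sample)
    gr <- gr[as.character(seqnames(gr)) == scaffold]
    pos <- start(gr)
    o <- order(pos)
    pos <- pos[o]
    m <- mcols(gr)$m[o]; u <- mcols(gr)$u[o]
    cov <- as.numeric(m + u)
    f <- m / cov
    sm <- smoothMethVector(pos, f, cov, halfWindowCpgs, minSpanBp, degree)
    new("SmoothedTrack", scaffold = scaffold, pos = as.integer(pos),
        rawF = f, smoothF = sm, cov = cov)
}

#' Local-polynomial smoother on raw vectors
#'
#' The numerical core of \code{\link{smoothTrack}}, exposed for track
#' construction from arbitrary vectors.
#'
#' @param pos strictly increasing positions.
#' @param f fractional methylation per position.
#' @param cov weights (read coverage) per position.
#' @inheritParams smoothTrack
#' @return Numeric vector of smoothed values, clipped to [0, 1].
#' @export
smoothMethVector <- function(pos, f, cov, halfWindowCpgs = 35L,
                             minSpanBp = 1000L, degree = 2L) {
    n <- length(pos)
    if (n == 0L) return(numeric())
    if (halfWindowCpgs == 0L || n < 2L * halfWindowCpgs + 1L)
        return(f)
    out <- numeric(n)
    hw <- as.integer(halfWindowCpgs)
    for (i in seq_len(n)) {
        lo <- max(1L, i - hw); hi <- min(n, i + hw)
        h <- max(minSpanBp / 2,
                 pos[i] - pos[lo], pos[hi] - pos[i], 1)
        jlo <- lo; while (jlo > 1L && pos[i] - pos[jlo - 1L] <= h) jlo <- jlo - 1L
        jhi <- hi; while (jhi < n && pos[jhi + 1L] - pos[i] <= h) jhi <- jhi + 1L
        d <- (pos[jlo:jhi] - pos[i]) / h
        w <- (1 - abs(d)^3)^3 * cov[jlo:jhi]
        w[w < 0] <- 0
        y <- f[jlo:jhi]
        np <- sum(w > 0)
        deg <- min(degree, if (np >= 5L) 2L else if (np >= 3L) 1L else 0L)
        out[i] <- .wpolyAt0(d, y, w, deg)
    }
    pmin(1, pmax(0, out))
}

# weighted polynomial fit in scaled distance d, evaluated at d = 0
.wpolyAt0 <- function(d, y, w, deg) {
    if (deg == 0L) return(sum(w * y) / sum(w))
    X <- cbind(1, d)
    if (deg == 2L) X <- cbind(X, d * d)
    fit <- tryCatch({
        XtW <- t(X * w)
        solve(XtW %*% X, XtW %*% y)[1L]
    }, error = function(e) sum(w * y) / sum(w))
    as.numeric(fit)
}
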