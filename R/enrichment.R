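#' GC fraction of genomic intervals
#'
#' (G + C) / (number of non-N bases), case-insensitive. Intervals made
#' entirely of N return \code{NaN}.
#'
#' @param intervals \code{GRanges}.
#' @param genome \code{DNAStringSet} keyed by scaffold name.
#' @return Numeric vector parallel to \code{intervals}.
#' @export
gcFraction <- function(intervals, genome) {
    out <- numeric(length(intervals))
    scafs <- as.character(seqnames(intervals))
    for (sc in unique(scafs)) {
        i <- which(scafs == sc)
        v <- Biostrings::Views(genome[[sc]],
                               start = start(intervals)[i],
                               end = end(intervals)[i])
        lf <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
        gc <- lf[, "G"] + lf[, "C"]
        out[i] <- gc / (gc + lf[, "A"] + lf[, "T"])
    }
    out
}

# per-scaffold cumulative GC / non-N counts for O(1) window GC
.gcCumulants <- function(genome) {
    env <- new.env(parent = emptyenv())
    get1 <- function(sc) {
        if (!exists(sc, envir = env)) {
            s <- as.character(genome[[sc]])
            ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
            assign(sc, list(gc = cumsum(ch == "G" | ch == "C"),
                            acgt = cumsum(ch %in% c("A", "C", "G", "T"))),
                   envir = env)
        }
        get(sc, envir = env)
    }
    get1
}

.windowGC <- function(cum, sc, starts, width) {
    cc <- cum(sc)
    ends <- starts + width - 1L
    gc <- cc$gc[ends] - c(0, cc$gc)[starts]
    nn <- cc$acgt[ends] - c(0, cc$acgt)[starts]
    gc / nn
}

#' Draw one length- and GC-matched control interval
#'
#' Uniformly samples an interval of the query's exact length from the
#' retained scaffolds, accepting it when its GC fraction is within
#' \code{gcTolerance} of the query's and it overlaps nothing in
#' \code{exclude}. Rejection sampling is capped; when no draw succeeds the
#' tolerance is doubled (with a warning) up to \code{maxRelax} times.
#'
#' @param query single-interval \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param gcTolerance absolute GC tolerance (default 0.05).
#' @param exclude \code{GRanges} the control must not overlap (typically
#'   the DMRs themselves).
#' @param maxTries rejection draws per tolerance level (default 1000).
#' @param maxRelax tolerance doublings before giving up (default 5).
#' @return Single-interval \code{GRanges} with mcol \code{gc}.
#' @export
sampleMatchedControl <- function(query, genome, gcTolerance = 0.05,
                                 exclude = GRanges(), maxTries = 1000L,
                                 maxRelax = 5L) {
    stopifnot(length(query) == 1L)
    w <- width(query)
    lens <- scaffoldLengths(genome)
    lens <- lens[lens >= w]
    if (!length(lens)) stop("no scaffold can host an interval of width ", w)
    qgc <- gcFraction(query, genome)
    cum <- .gcCumulants(genome)
    tol <- gcTolerance
    for (r in 0:maxRelax) {
        sc <- sample(names(lens), maxTries, replace = TRUE,
                     prob = lens - w + 1)
        st <- floor(runif(maxTries) * (lens[sc] - w + 1)) + 1L
        for (u in unique(sc)) {
            i <- which(sc == u)
            gcs <- .windowGC(cum, u, st[i], w)
            ok <- i[!is.na(gcs) & abs(gcs - qgc) <= tol]
            for (k in ok) {
                cand <- GRanges(sc[k], IRanges(st[k], width = w))
                if (!length(exclude) ||
                    !suppressWarnings(overlapsAny(cand, exclude))) {
                    mcols(cand)$gc <- .windowGC(cum, sc[k], st[k], w)
                    return(cand)
                }
            }
        }
        tol <- tol * 2
        warning("GC tolerance doubled to ", tol, " for control matching")
    }
    stop("no eligible control region after ", maxRelax,
         " tolerance relaxations")
}

# per-width genome preparation: concatenated window-GC vector over all
# scaffolds able to host the width, scaffold offsets, and an exclusion
# mask; shared by every query of that width
.controlField <- function(w, genome, cum, exclude) {
    lens <- scaffoldLengths(genome)
    lens <- lens[lens >= w]
    if (!length(lens)) stop("no scaffold can host width ", w)
    exclByScaf <- if (length(exclude))
        split(IRanges::ranges(exclude), as.character(seqnames(exclude)))
    else NULL
    gcs <- vector("list", length(lens))
    exc <- vector("list", length(lens))
    for (k in seq_along(lens)) {
        u <- names(lens)[k]
        starts <- seq_len(lens[u] - w + 1L)
        gcs[[k]] <- .windowGC(cum, u, starts, w)
        exc[[k]] <- if (!is.null(exclByScaf) && u %in% names(exclByScaf))
            IRanges::overlapsAny(IRanges(starts, width = w),
                                 exclByScaf[[u]])
        else rep(FALSE, length(starts))
    }
    nPer <- lengths(gcs)
    list(scaffolds = names(lens), offsets = cumsum(c(0, nPer[-length(nPer)])),
         nPer = nPer, gc = unlist(gcs, use.names = FALSE),
         excl = unlist(exc, use.names = FALSE))
}

# draw n control starts for one query by vectorized rejection over the
# prepared field; falls back to exact enumeration (with tolerance
# doubling) when the acceptance rate is tiny
.drawControls <- function(field, qgc, tol, n, maxRelax = 5L) {
    total <- length(field$gc)
    ok <- !is.na(field$gc) & abs(field$gc - qgc) <= tol & !field$excl
    for (batch in 1:2) {
        idx <- sample.int(total, max(2L * n, 1000L), replace = TRUE)
        hit <- idx[ok[idx]]
        if (length(hit) >= n) return(sample(hit, n))
    }
    for (r in seq_len(maxRelax + 1L)) {
        elig <- which(ok)
        if (length(elig))
            return(elig[sample.int(length(elig), n, replace = TRUE)])
        tol <- tol * 2
        warning("GC tolerance doubled to ", tol, " for control matching")
        ok <- !is.na(field$gc) & abs(field$gc - qgc) <= tol & !field$excl
    }
    stop("no eligible control region after ", maxRelax,
         " tolerance relaxations")
}

.flatToScafStart <- function(field, flat) {
    k <- findInterval(flat - 0.5, field$offsets)
    list(scaffold = field$scaffolds[k],
         start = as.integer(flat - field$offsets[k]))
}

#' Bootstrap enrichment of DMRs in a functional category
#'
#' Tests whether DMRs overlap a functional category (promoters, gene
#' bodies, intergenic, ...) more or less often than length- and GC-matched
#' control regions. The observed statistic is the fraction of DMRs with at
#' least 1 bp of category overlap. Each of \code{nBoot} replicates redraws
#' one matched control per DMR (identical length, GC within
#' \code{gcTolerance}, not overlapping the DMRs) and records the control
#' overlap fraction. Fold enrichment is observed / null mean; the
#' empirical p-value uses the add-one rule
#' \eqn{p = (1 + \#\{null \ge obs\})/(n_{boot}+1)} per tail, two-sided =
#' 2 min(tails), capped at 1 — so p can never be exactly 0.
#'
#' @param dmrs non-empty \code{GRanges} of query regions.
#' @param categories named \code{GRangesList} or named list of
#'   \code{GRanges}, one per category.
#' @param genome \code{DNAStringSet}.
#' @param nBoot bootstrap replicates (default 10000).
#' @param gcTolerance absolute GC tolerance for control matching
#'   (default 0.05).
#' @param exclude regions controls must avoid; defaults to \code{dmrs}.
#' @return \code{DataFrame}: category, observed_frac, null_mean, null_sd,
#'   fold_enrichment, p_emp, n_boot.
#' @export
bootstrapEnrichment <- function(dmrs, categories, genome, nBoot = 10000L,
                                gcTolerance = 0.05, exclude = dmrs) {
    if (!length(dmrs)) stop("empty DMR set")
    if (is(categories, "GRanges")) categories <- list(category = categories)
    stopifnot(!is.null(names(categories)))
    cum <- .gcCumulants(genome)
    qgc <- gcFraction(dmrs, genome)
    ws <- width(dmrs)
    nD <- length(dmrs)
    fields <- lapply(setNames(nm = unique(ws)), function(w)
        .controlField(w, genome, cum, exclude))
    # draw all controls for all replicates at once, per DMR
    ctrlScaf <- matrix("", nD, nBoot); ctrlStart <- matrix(0L, nD, nBoot)
    for (i in seq_len(nD)) {
        field <- fields[[as.character(ws[i])]]
        flat <- .drawControls(field, qgc[i], gcTolerance, nBoot)
        ss <- .flatToScafStart(field, flat)
        ctrlScaf[i, ] <- ss$scaffold
        ctrlStart[i, ] <- ss$start
    }
    res <- lapply(names(categories), function(catName) {
        cat <- categories[[catName]]
        obs <- mean(overlapsAny(dmrs, cat, ignore.strand = TRUE))
        catByScaf <- split(IRanges::ranges(cat),
                           as.character(seqnames(cat)))
        nullFrac <- numeric(nBoot)
        hitMat <- matrix(FALSE, nD, nBoot)
        for (u in unique(as.vector(ctrlScaf))) {
            sel <- ctrlScaf == u
            if (u %in% names(catByScaf)) {
                cand <- IRanges(ctrlStart[sel],
                                width = rep(ws, nBoot)[as.vector(sel)])
                hitMat[sel] <- IRanges::overlapsAny(cand, catByScaf[[u]])
            }
        }
        nullFrac <- colMeans(hitMat)
        pUp <- (1 + sum(nullFrac >= obs - 1e-12)) / (nBoot + 1)
        pDn <- (1 + sum(nullFrac <= obs + 1e-12)) / (nBoot + 1)
        nm <- mean(nullFrac)
        DataFrame(category = catName, observed_frac = obs,
                  null_mean = nm, null_sd = sd(nullFrac),
                  fold_enrichment = if (nm > 0) obs / nm else NA_real_,
                  p_emp = min(1, 2 * min(pUp, pDn)), n_boot = nBoot)
    })
    do.call(rbind, res)
}
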