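#' Simulate per-sample WGBS methylomes from a synthetic genome
#'
#' Draws, for every CpG site, a true methylation level from a region
#' archetype (promoter/CGI low, Beta(2,8); gene body and intergenic high,
#' Beta(8,2)), then applies the planted effects: tissue-specific DMR
#' blocks (level shifted by +/- \code{dmrDelta} over \code{dmrNCpgs}
#' consecutive non-island CpGs in one tissue, both sexes), a per-10 kb
#' window female hypomethylation shift N(\code{xEffectMu},
#' \code{xEffectSd}) on X-derived scaffolds outside promoters and
#' islands, and a fixed fractional female reduction at the Rsx-like
#' upstream islands. Read counts are beta/binomial: per-strand coverage
#' is Poisson(\code{meanCoverage}/2), doubled for females on X-derived
#' scaffolds; methylated counts are binomial in the true level. Mapped
#' read totals scale with scaffold length and depth factor.
#'
#' One female and one male sample are produced per tissue. With
#' \code{merged = TRUE} (default) dyads are returned pre-merged;
#' otherwise calls are strand-split exactly as a cytosine report would
#' hold them, from the same underlying draws.
#'
#' @param sim a \code{\link{generateGenome}} result.
#' @param merged return strand-merged calls (default \code{TRUE}).
#' @return List: \code{samples} (named list of \code{\link{Methylome}},
#'   names \code{tissue_sex}), \code{truth} (planted DMRs per tissue,
#'   true per-window X deltas, per-gene true methylation summary).
#' @export
simulateMethylomes <- function(sim, merged = TRUE) {
    config <- sim$truth$config
    set.seed(config$seed + 1L)
    sites <- sim$sites
    n <- length(sites)
    scafOfSite <- as.character(seqnames(sites))
    origin <- sim$truth$origin[scafOfSite]
    low <- mcols(sites)$in_cgi | mcols(sites)$in_promoter
    base <- numeric(n)
    base[low] <- rbeta(sum(low), config$promoterBeta[1],
                       config$promoterBeta[2])
    base[!low] <- rbeta(sum(!low), config$bodyBeta[1], config$bodyBeta[2])
    # hypermethylated planted DMRs start from the low archetype so the
    # +delta shift is not lost to clipping at 1
    locus <- mcols(sites)$dmr_locus
    dmrLoci <- sim$dmrLoci
    if (length(dmrLoci)) {
        hyper <- mcols(dmrLoci)$locus_id[mcols(dmrLoci)$sign > 0]
        hy <- !is.na(locus) & locus %in% hyper
        base[hy] <- rbeta(sum(hy), config$promoterBeta[1],
                          config$promoterBeta[2])
    }

    # per-window X effect, shared across tissues
    winKey <- paste0(scafOfSite, "\r", (start(sites) - 1L) %/%
                         as.integer(config$xWindowBp))
    isX <- origin == "X"
    xWins <- unique(winKey[isX])
    winDelta <- setNames(rnorm(length(xWins), config$xEffectMu,
                               config$xEffectSd), xWins)

    # planted tissue-specific DMR effects at the generator's cluster loci
    dmrTruth <- list()
    for (t in config$tissues) {
        ids <- if (length(dmrLoci))
            mcols(dmrLoci)$locus_id[mcols(dmrLoci)$tissue == t]
        else integer(0)
        dmrTruth[[t]] <- list(
            idx = which(!is.na(locus) & locus %in% ids),
            sign = if (length(dmrLoci))
                setNames(mcols(dmrLoci)$sign, mcols(dmrLoci)$locus_id)
            else integer(0))
    }
    rsxIdx <- if (length(sim$truth$rsxCgis))
        which(overlapsAny(sites, sim$truth$rsxCgis, ignore.strand = TRUE))
    else integer(0)

    clip01 <- function(x) pmin(1, pmax(0, x))
    lambdaStrand <- config$meanCoverage / 2
    samples <- list()
    kidneyF <- kidneyM <- NULL
    for (t in config$tissues) {
        lvl <- base
        d <- dmrTruth[[t]]
        if (length(d$idx))
            lvl[d$idx] <- clip01(lvl[d$idx] +
                d$sign[as.character(locus[d$idx])] * config$dmrDelta)
        lvlM <- lvl
        lvlF <- lvl
        shiftable <- isX & !low
        lvlF[shiftable] <- clip01(lvl[shiftable] +
                                      winDelta[winKey[shiftable]])
        promX <- isX & mcols(sites)$in_promoter
        lvlF[promX] <- clip01(lvl[promX] + config$promoterEffect)
        if (length(rsxIdx))
            lvlF[rsxIdx] <- lvlM[rsxIdx] * (1 - config$rsxReduction)
        for (sex in c("female", "male")) {
            lv <- if (sex == "female") lvlF else lvlM
            lam <- rep(lambdaStrand, n)
            if (sex == "female")
                lam[isX] <- lam[isX] * config$femaleXDepthFactor
            covP <- rpois(n, lam); covM <- rpois(n, lam)
            mP <- rbinom(n, covP, lv); mM <- rbinom(n, covM, lv)
            mapped <- round(sim$seqlengths * config$meanCoverage / 100)
            if (sex == "female") {
                xs <- names(sim$truth$origin)[sim$truth$origin == "X"]
                mapped[xs] <- mapped[xs] * config$femaleXDepthFactor
            }
            id <- paste(t, sex, sep = "_")
            if (merged) {
                cov <- covP + covM
                keep <- cov >= 1L
                samples[[id]] <- Methylome(
                    scafOfSite[keep], start(sites)[keep],
                    m = mP[keep] + mM[keep],
                    u = cov[keep] - mP[keep] - mM[keep],
                    sampleId = id, sex = sex, tissue = t,
                    totalMappedReads = sum(mapped),
                    perScaffoldMappedReads = mapped,
                    seqinfo = Seqinfo(names(sim$seqlengths),
                                      sim$seqlengths))
            } else {
                kp <- covP >= 1L; km <- covM >= 1L
                samples[[id]] <- Methylome(
                    c(scafOfSite[kp], scafOfSite[km]),
                    c(start(sites)[kp], start(sites)[km] + 1L),
                    m = c(mP[kp], mM[km]),
                    u = c(covP[kp] - mP[kp], covM[km] - mM[km]),
                    strand = rep(c("+", "-"), c(sum(kp), sum(km))),
                    sampleId = id, sex = sex, tissue = t,
                    totalMappedReads = sum(mapped),
                    perScaffoldMappedReads = mapped,
                    seqinfo = Seqinfo(names(sim$seqlengths),
                                      sim$seqlengths))
            }
            if (t == .captureTissue(config)) {
                if (sex == "female") kidneyF <- lvlF else kidneyM <- lvlM
            }
        }
    }

    dmrGr <- .emptyDmrTruth()
    if (length(dmrLoci)) {
        perLocus <- split(which(!is.na(locus)), locus[!is.na(locus)])
        lid <- as.integer(names(perLocus))
        o <- match(lid, mcols(dmrLoci)$locus_id)
        dmrGr <- GRanges(
            vapply(perLocus, function(i) scafOfSite[i[1L]], ""),
            IRanges(vapply(perLocus, function(i) start(sites)[i[1L]], 0),
                    vapply(perLocus, function(i)
                        start(sites)[i[length(i)]] + 1L, 0)),
            tissue = mcols(dmrLoci)$tissue[o],
            delta = config$dmrDelta * mcols(dmrLoci)$sign[o],
            n_cpgs = lengths(perLocus))
    }

    geneMeth <- .trueGeneMeth(sim, kidneyF, kidneyM)
    winGr <- local({
        parts <- strsplit(xWins, "\r", fixed = TRUE)
        sc <- vapply(parts, `[`, "", 1L)
        wi <- as.integer(vapply(parts, `[`, "", 2L))
        GRanges(sc, IRanges(wi * as.integer(config$xWindowBp) + 1L,
                            width = as.integer(config$xWindowBp)),
                true_delta = unname(winDelta))
    })
    list(samples = samples,
         truth = list(dmrs = dmrGr, xWindows = winGr,
                      geneMeth = geneMeth, origin = sim$truth$origin,
                      rsxGene = sim$truth$rsxGene,
                      rsxCgis = sim$truth$rsxCgis))
}

# expression couples to this tissue's methylation surface
.captureTissue <- function(config) {
    if ("kidney" %in% config$tissues) "kidney" else config$tissues[1L]
}

.emptyDmrTruth <- function() {
    GRanges(tissue = character(), delta = numeric(), n_cpgs = integer())
}

# per-gene true promoter level and body F-M delta (first/kidney tissue)
.trueGeneMeth <- function(sim, lvlF, lvlM) {
    genes <- sim$genes
    config <- sim$truth$config
    regs <- geneRegions(genes, config$promoterWidth)
    sites <- sim$sites
    agg <- function(region, v) {
        hits <- findOverlaps(sites, region, ignore.strand = TRUE)
        out <- rep(NA_real_, length(region))
        mm <- tapply(v[S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits), mean)
        out[as.integer(names(mm))] <- mm
        out
    }
    promF <- agg(regs$promoter, lvlF); promM <- agg(regs$promoter, lvlM)
    bodyF <- agg(regs$body, lvlF); bodyM <- agg(regs$body, lvlM)
    isX <- sim$truth$origin[as.character(seqnames(genes))] == "X"
    DataFrame(gene_id = mcols(genes)$gene_id,
              promoter_f = (promF + promM) / 2,
              body_delta = bodyF - bodyM,
              is_x = unname(isX),
              is_rsx = mcols(genes)$gene_id %in% sim$truth$rsxGene)
}
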