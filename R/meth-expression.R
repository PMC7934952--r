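#' Per-gene promoter and gene-body methylation summaries
#'
#' Unweighted mean of per-CpG fractional methylation over each gene's
#' promoter (1 kb upstream) and gene body (TSS-TES). Regions with fewer
#' than \code{minCpgs} covered CpGs get \code{NA} (genes whose promoters
#' have too few covered CpGs are thereby excluded from downstream
#' correlations).
#'
#' @param sample a strand-merged, coverage-filtered
#'   \code{\link{Methylome}}.
#' @param genes stranded \code{GRanges} with \code{gene_id}.
#' @param minCpgs minimum covered CpGs per region (default 3).
#' @param promoterWidth promoter extent in bp (default 1000).
#' @return \code{DataFrame}: gene_id, promoter_mean_f, promoter_n_cpgs,
#'   body_mean_f, body_n_cpgs.
#' @export
summarizeGeneMethylation <- function(sample, genes, minCpgs = 3L,
                                     promoterWidth = 1000L) {
    regs <- geneRegions(genes, promoterWidth)
    gr <- methCalls(sample)
    f <- methLevel(sample)
    one <- function(region) {
        hits <- findOverlaps(gr, region, ignore.strand = TRUE)
        sh <- S4Vectors::subjectHits(hits)
        fv <- f[S4Vectors::queryHits(hits)]
        n <- tabulate(sh, nbins = length(region))
        mn <- rep(NA_real_, length(region))
        mm <- tapply(fv, sh, mean)
        mn[as.integer(names(mm))] <- mm
        mn[n < minCpgs] <- NA_real_
        list(mean = mn, n = n)
    }
    p <- one(regs$promoter); b <- one(regs$body)
    DataFrame(gene_id = mcols(genes)$gene_id,
              promoter_mean_f = p$mean, promoter_n_cpgs = p$n,
              body_mean_f = b$mean, body_n_cpgs = b$n)
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties; p-value by exact
#' enumeration for n <= 7 without ties, otherwise the t approximation.
#' Constant input yields \code{rho = NA} with \code{degenerate = TRUE}.
#'
#' @param x,y paired numeric vectors, at least 4 complete pairs.
#' @return List: \code{rho}, \code{p}, \code{n}, \code{degenerate}.
#' @export
rankCorrelation <- function(x, y) {
    cc <- complete.cases(x, y)
    x <- x[cc]; y <- y[cc]
    n <- length(x)
    if (n < 4L) stop("need at least 4 complete pairs, got ", n)
    if (sd(x) == 0 || sd(y) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
    ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    ct <- suppressWarnings(
        cor.test(x, y, method = "spearman",
                 exact = (n <= 7L && !ties)))
    list(rho = unname(ct$estimate), p = ct$p.value, n = n,
         degenerate = FALSE)
}

#' Enrichment of differential expression among differentially methylated
#' genes
#'
#' Builds the 2x2 table {DMG, non-DMG} x {DEG, non-DEG} over a gene
#' universe. Fold enrichment is the risk ratio
#' P(DEG | DMG) / P(DEG | non-DMG); significance is the 1-df chi-squared
#' test, without Yates continuity correction by default.
#'
#' @param dmg,deg character vectors of gene ids, subsets of
#'   \code{universe}.
#' @param universe character vector of all genes considered.
#' @param yates apply the continuity correction (default \code{FALSE}).
#' @return List: \code{fold_enrichment}, \code{chi2}, \code{p},
#'   \code{table}.
#' @export
dmgDegEnrichment <- function(dmg, deg, universe, yates = FALSE) {
    stopifnot(all(dmg %in% universe), all(deg %in% universe))
    isDmg <- universe %in% dmg
    isDeg <- universe %in% deg
    tab <- table(factor(isDmg, c(TRUE, FALSE)),
                 factor(isDeg, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate margin in the DMG x DEG table")
    fe <- (tab[1, 1] / sum(tab[1, ])) / (tab[2, 1] / sum(tab[2, ]))
    ch <- suppressWarnings(chisq.test(tab, correct = yates))
    list(fold_enrichment = unname(fe),
         chi2 = unname(ch$statistic), p = ch$p.value, table = tab)
}

#' Log2 female-to-male expression ratio
#'
#' \eqn{\log_2((f + pc)/(m + pc))} per gene, with a pseudocount guarding
#' zero expression.
#'
#' @param exprFemale,exprMale non-negative paired expression values
#'   (named by gene).
#' @param pseudocount default 1.
#' @return Named numeric vector of log2 fold changes (female over male).
#' @export
sexExpressionRatio <- function(exprFemale, exprMale, pseudocount = 1) {
    if (any(exprFemale < 0) || any(exprMale < 0))
        stop("expression values must be non-negative")
    log2((exprFemale + pseudocount) / (exprMale + pseudocount))
}

#' Correlate sex-differential methylation with sex-biased expression
#'
#' Spearman correlation between the per-gene female minus male mean
#' methylation of a region (promoter or gene body) and the log2
#' female/male expression ratio, over complete cases, with an optional
#' exclusion list (e.g. the XCI master locus itself).
#'
#' @param summaryFemale,summaryMale outputs of
#'   \code{\link{summarizeGeneMethylation}} for the two sexes.
#' @param log2fc named log2 female/male expression vector.
#' @param region \code{"gene_body"} or \code{"promoter"}.
#' @param exclude gene ids dropped before correlating.
#' @return List as \code{\link{rankCorrelation}}, plus \code{n}.
#' @export
correlateSexdiffMethExpression <- function(summaryFemale, summaryMale,
                                           log2fc,
                                           region = c("gene_body",
                                                      "promoter"),
                                           exclude = character()) {
    region <- match.arg(region)
    col <- if (region == "promoter") "promoter_mean_f" else "body_mean_f"
    stopifnot(identical(summaryFemale$gene_id, summaryMale$gene_id))
    ids <- summaryFemale$gene_id
    dMeth <- summaryFemale[[col]] - summaryMale[[col]]
    fc <- log2fc[match(ids, names(log2fc))]
    keep <- !(ids %in% exclude) & !is.na(dMeth) & !is.na(fc)
    if (sum(keep) < 4L)
        stop("fewer than 4 complete gene cases")
    rankCorrelation(dMeth[keep], fc[keep])
}
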