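#' Simulation configuration
#'
#' Parameters of the synthetic WGBS study generator. Defaults encode the
#' study conditions the analysis targets: ~10x mean CpG coverage, a
#' twofold female depth excess on X-derived sequence, per-10 kb-window
#' female minus male methylation differences of N(-0.25, 0.12) on X gene
#' bodies and intergenic sequence with no promoter effect, planted
#' tissue-specific DMRs of delta 0.4 over 8 CpGs, a promoter
#' methylation-expression coupling in the rho ~ -0.12 regime, and an
#' Rsx-like locus whose upstream CpG islands are 36% hypomethylated in
#' females and whose transcript is female-only. Methylation levels follow
#' a beta/binomial model (promoter/CGI low, Beta(2,8); gene body and
#' intergenic high, Beta(8,2)) with Poisson coverage.
#'
#' @param seed integer seed; every downstream draw derives from it.
#' @param nAutosomalScaffolds,nXScaffolds placed scaffold counts.
#' @param nUnplacedScaffolds scaffolds with hidden true origin.
#' @param unplacedXFraction fraction of unplaced scaffolds that are truly
#'   X-derived.
#' @param scaffoldLengthBp length of every scaffold.
#' @param cpgRate CpG dyads per bp outside islands (default 0.01, one CpG
#'   per 100 bp, a CpG-depleted genome).
#' @param gcContent background GC fraction (default 0.40).
#' @param geneCount genes placed across the placed scaffolds.
#' @param geneLengthBp,geneSpacingBp gene body length and inter-gene
#'   spacing.
#' @param promoterWidth promoter extent upstream of the TSS.
#' @param cgiLengthBp planted promoter CpG-island length.
#' @param meanCoverage mean read depth per CpG dyad (default 10).
#' @param femaleXDepthFactor female depth multiplier on X-derived
#'   scaffolds (default 2).
#' @param xEffectMu,xEffectSd per-window female minus male difference on X
#'   (defaults -0.25, 0.12).
#' @param xWindowBp window granularity of the planted X effect.
#' @param promoterEffect female minus male difference at X promoters
#'   (default 0).
#' @param nDmrsPerTissue,dmrDelta,dmrNCpgs planted tissue-specific DMRs.
#' @param dmrCpgSpacingBp CpG spacing inside a planted DMR cluster
#'   (default 25; DMRs live in locally CpG-dense sequence, as
#'   regulatory regions do).
#' @param tissues tissue names (one female + one male sample each).
#' @param promoterBeta,bodyBeta beta parameters of the low/high
#'   methylation archetypes.
#' @param methExprRho target Spearman correlation between promoter
#'   methylation and expression.
#' @param sexCouplingSlope log2-expression change per unit of female
#'   minus male gene-body methylation (negative coupling; default 1.2
#'   applied to -delta, chosen to reproduce an X-versus-autosome log2
#'   fold-change gap near 0.3 and a clearly detectable negative
#'   correlation at a few hundred genes).
#' @param log2ExprMean,log2ExprSd,log2fcBaselineMean,log2fcSd expression
#'   baseline model (female-biased baseline shift 0.24).
#' @param fracFemaleUp,fracMaleUp planted differential-expression
#'   fractions among X genes (defaults 36/209 and 11/209).
#' @param rsxReduction female methylation reduction at the Rsx-like
#'   upstream CGIs (default 0.36).
#' @param rsxFemaleExpr,rsxMaleExpr Rsx-like expression (female-only
#'   transcript).
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simConfig <- function(seed,
                      nAutosomalScaffolds = 4L, nXScaffolds = 2L,
                      nUnplacedScaffolds = 6L, unplacedXFraction = 1 / 3,
                      scaffoldLengthBp = 5e5, cpgRate = 0.01,
                      gcContent = 0.40,
                      geneCount = 40L, geneLengthBp = 4000L,
                      geneSpacingBp = 8000L, promoterWidth = 1000L,
                      cgiLengthBp = 300L,
                      meanCoverage = 10, femaleXDepthFactor = 2,
                      xEffectMu = -0.25, xEffectSd = 0.12,
                      xWindowBp = 10000L, promoterEffect = 0,
                      nDmrsPerTissue = 3L, dmrDelta = 0.4,
                      dmrNCpgs = 8L, dmrCpgSpacingBp = 25L,
                      tissues = c("brain", "kidney", "lung", "muscle",
                                  "pancreas"),
                      promoterBeta = c(2, 8), bodyBeta = c(8, 2),
                      methExprRho = -0.12, sexCouplingSlope = 1.2,
                      log2ExprMean = 4, log2ExprSd = 2,
                      log2fcBaselineMean = 0.24, log2fcSd = 0.6,
                      fracFemaleUp = 36 / 209, fracMaleUp = 11 / 209,
                      rsxReduction = 0.36, rsxFemaleExpr = 150,
                      rsxMaleExpr = 0.5) {
    if (missing(seed) || is.na(seed)) stop("seed is mandatory")
    cfg <- as.list(environment())
    probs <- c(cpgRate, gcContent, unplacedXFraction, fracFemaleUp,
               fracMaleUp, rsxReduction)
    if (any(probs < 0 | probs > 1))
        stop("rates and fractions must lie in [0, 1]")
    if (!all(is.finite(c(xEffectMu, xEffectSd, dmrDelta, methExprRho,
                         sexCouplingSlope))))
        stop("effect parameters must be finite")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig (seed ", x$seed, "): ",
        x$nAutosomalScaffolds, " autosomal + ", x$nXScaffolds,
        " X + ", x$nUnplacedScaffolds, " unplaced scaffolds of ",
        x$scaffoldLengthBp, " bp; ", x$geneCount, " genes; ",
        length(x$tissues), " tissues; mean coverage ", x$meanCoverage,
        "\n", sep = "")
    invisible(x)
}
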