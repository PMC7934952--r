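#' Simulate gene expression coupled to the synthetic methylomes
#'
#' Baseline log2 expression is Gaussian; promoter methylation enters with
#' a negative loading calibrated so the Spearman correlation between
#' promoter methylation and expression targets \code{methExprRho}
#' (Pearson loading \eqn{2\sin(\pi\rho_s/6)}). The female/male log2 fold
#' change combines a mildly female-biased baseline with a negative
#' coupling to the true gene-body female minus male methylation
#' difference (so X genes, hypomethylated in females, come out
#' female-biased on average), plus planted strongly differential X genes
#' at the configured female-up/male-up fractions. The Rsx-like gene is
#' expressed in the female only.
#'
#' @param geneMeth \code{DataFrame} with columns \code{gene_id},
#'   \code{promoter_f}, \code{body_delta}, \code{is_x}, \code{is_rsx}
#'   (as produced in \code{\link{simulateMethylomes}} truth).
#' @param config the \code{\link{simConfig}} used throughout.
#' @return \code{DataFrame}: gene_id, expr_female, expr_male,
#'   log2fc_true, de_label (\code{"female_up"}, \code{"male_up"},
#'   \code{"ns"}).
#' @export
simulateExpression <- function(geneMeth, config) {
    set.seed(config$seed + 2L)
    n <- nrow(geneMeth)
    rP <- 2 * sin(pi * config$methExprRho / 6)
    zm <- as.numeric(scale(geneMeth$promoter_f))
    if (any(!is.finite(zm))) zm[!is.finite(zm)] <- 0
    g <- rP * zm + sqrt(1 - rP^2) * rnorm(n)
    log2m <- config$log2ExprMean + config$log2ExprSd * g
    bodyDelta <- ifelse(is.na(geneMeth$body_delta), 0, geneMeth$body_delta)
    log2fc <- config$log2fcBaselineMean -
        config$sexCouplingSlope * bodyDelta +
        rnorm(n, 0, config$log2fcSd)
    de <- rep("ns", n)
    xIdx <- which(geneMeth$is_x & !geneMeth$is_rsx)
    if (length(xIdx)) {
        nFU <- round(length(xIdx) * config$fracFemaleUp)
        nMU <- round(length(xIdx) * config$fracMaleUp)
        pick <- sample(xIdx, min(length(xIdx), nFU + nMU))
        fu <- pick[seq_len(min(nFU, length(pick)))]
        mu <- setdiff(pick, fu)
        log2fc[fu] <- 2 + rnorm(length(fu), 0, 0.3)
        log2fc[mu] <- -2 + rnorm(length(mu), 0, 0.3)
        de[fu] <- "female_up"; de[mu] <- "male_up"
    }
    exprM <- 2^log2m
    exprF <- 2^(log2m + log2fc)
    rsx <- which(geneMeth$is_rsx)
    if (length(rsx)) {
        exprF[rsx] <- config$rsxFemaleExpr
        exprM[rsx] <- config$rsxMaleExpr
        log2fc[rsx] <- log2((exprF[rsx] + 1) / (exprM[rsx] + 1))
        de[rsx] <- "female_up"
    }
    DataFrame(gene_id = geneMeth$gene_id, expr_female = exprF,
              expr_male = exprM, log2fc_true = log2fc, de_label = de)
}

#' Generate a complete synthetic WGBS study
#'
#' Runs \code{\link{generateGenome}}, \code{\link{simulateMethylomes}}
#' and \code{\link{simulateExpression}} under one seed and, optionally,
#' writes all artifacts to disk: genome FASTA, gene GFF3, CpG-island
#' BED, per-sample gzipped cytosine reports, a sample sheet TSV, an
#' expression TSV and the ground truth as JSON. Byte-identical across
#' reruns with the same config.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir output directory; \code{NULL} (default) keeps everything in
#'   memory.
#' @param withSequence forwarded to \code{\link{generateGenome}}.
#' @param merged forwarded to \code{\link{simulateMethylomes}}; writing
#'   reports forces strand-split calls.
#' @return List: \code{sim} (genome object), \code{samples},
#'   \code{truth}, \code{expression}, and \code{files} (named paths when
#'   \code{dir} is given).
#' @export
simulateDataset <- function(config, dir = NULL, withSequence = TRUE,
                            merged = is.null(dir)) {
    sim <- generateGenome(config, withSequence = withSequence)
    meth <- simulateMethylomes(sim, merged = merged)
    expr <- simulateExpression(meth$truth$geneMeth, config)
    files <- NULL
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        files <- list()
        if (!is.null(sim$genome)) {
            files$genome <- file.path(dir, "genome.fa")
            writeXStringSet(sim$genome, files$genome)
        }
        files$genes <- file.path(dir, "genes.gff3")
        g <- sim$genes
        mcols(g)$type <- "gene"
        mcols(g)$ID <- mcols(g)$gene_id
        rtracklayer::export(g, files$genes, format = "gff3")
        files$cgis <- file.path(dir, "cgi.bed")
        cg <- sim$cgis
        mcols(cg)$name <- mcols(cg)$cgi_id
        rtracklayer::export(cg, files$cgis, format = "bed")
        sheet <- data.frame(sample_id = names(meth$samples),
                            sex = vapply(meth$samples, sampleSex, ""),
                            tissue = vapply(meth$samples, sampleTissue, ""),
                            path = paste0(names(meth$samples),
                                          ".CpG_report.txt.gz"),
                            total_mapped_reads =
                                vapply(meth$samples,
                                       function(s) s@totalMappedReads, 0))
        for (id in names(meth$samples))
            writeCpGReport(meth$samples[[id]],
                           file.path(dir, sheet$path[sheet$sample_id == id]))
        files$sampleSheet <- file.path(dir, "samples.tsv")
        utils::write.table(sheet, files$sampleSheet, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        files$expression <- file.path(dir, "expression.tsv")
        utils::write.table(as.data.frame(expr), files$expression,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files$truth <- file.path(dir, "truth.json")
        tr <- meth$truth
        jsonlite::write_json(list(
            origin = as.list(tr$origin),
            rsx_gene = tr$rsxGene,
            dmrs = if (length(tr$dmrs)) data.frame(
                scaffold = as.character(seqnames(tr$dmrs)),
                start = start(tr$dmrs), end = end(tr$dmrs),
                tissue = tr$dmrs$tissue, delta = tr$dmrs$delta)
                else list(),
            x_windows = data.frame(
                scaffold = as.character(seqnames(tr$xWindows)),
                start = start(tr$xWindows), end = end(tr$xWindows),
                true_delta = tr$xWindows$true_delta)),
            files$truth, auto_unbox = TRUE, digits = NA)
    }
    list(sim = sim, samples = meth$samples, truth = meth$truth,
         expression = expr, files = files)
}
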