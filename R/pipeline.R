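#' Validate a pipeline configuration
#'
#' The configuration is a named list (or a YAML file with the same
#' structure) with the sections below; unknown keys anywhere are
#' rejected. All parameters have defaults suited to the synthetic desk
#' scale; real-data scale values (e.g. a 2 Mb scaffold filter, 35-CpG
#' smoothing windows) are set here explicitly.
#'
#' Sections: \code{outdir}, \code{seed}, \code{simulation} (overrides for
#' \code{\link{simConfig}}), \code{io} (\code{min_coverage},
#' \code{min_scaffold_length}), \code{dmr} (\code{half_window_cpgs},
#' \code{min_span_bp}, \code{min_diff}, \code{min_cpgs},
#' \code{min_overlap_frac}), \code{enrichment} (\code{n_boot},
#' \code{gc_tolerance}), \code{sexdiff} (\code{bin_size},
#' \code{min_cpgs_per_window}, \code{n_bins}, \code{flank_bp},
#' \code{window_bp}, \code{step_bp}), \code{xclassify} (\code{alpha},
#' \code{cov_band}, \code{auto_band}, \code{min_windows},
#' \code{unplaced_prefix}), \code{integrate} (\code{min_cpgs},
#' \code{exclude_rsx}).
#'
#' @param config named list or path to a YAML file.
#' @return The completed configuration list.
#' @export
pipelineConfig <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    defaults <- list(
        outdir = "methylscan_out", seed = 1L,
        simulation = list(),
        io = list(min_coverage = 3L, min_scaffold_length = 0),
        dmr = list(half_window_cpgs = 4L, min_span_bp = 200L,
                   min_diff = 0.3, min_cpgs = 5L, min_overlap_frac = 0.5),
        enrichment = list(n_boot = 10000L, gc_tolerance = 0.05),
        sexdiff = list(bin_size = 10000L, min_cpgs_per_window = 3L,
                       n_bins = 20L, flank_bp = 5000L, window_bp = 100L,
                       step_bp = 10L),
        xclassify = list(alpha = 0.05, cov_band = c(1.5, 2.5),
                         auto_band = c(0.8, 1.2), min_windows = 5L,
                         unplaced_prefix = "scaffold_"),
        integrate = list(min_cpgs = 3L, exclude_rsx = TRUE))
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (sec in names(config)) {
        if (is.list(defaults[[sec]]) && !is.null(names(defaults[[sec]]))) {
            bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
            if (length(bad) && sec != "simulation")
                stop("unknown key(s) in '", sec, "': ",
                     paste(bad, collapse = ", "))
            defaults[[sec]][names(config[[sec]])] <- config[[sec]]
        } else defaults[[sec]] <- config[[sec]]
    }
    defaults
}

.provenance <- function(outdir, stage, params, inputs, outputs) {
    rec <- list(stage = stage, params = params,
                package_version = as.character(packageVersion("methylscan")),
                inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
                outputs = as.list(tools::md5sum(
                    outputs[file.exists(outputs)])))
    p <- file.path(outdir, paste0("provenance_", stage, ".json"))
    jsonlite::write_json(rec, p, auto_unbox = TRUE, digits = NA)
    p
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages in dependency order: \code{simulate} (write a
#' synthetic study to disk), \code{io} (read reports, merge strands,
#' coverage and scaffold-length filters), \code{dmr} (pairwise
#' tissue DMRs, consensus and sharing), \code{enrich} (GC/length-matched
#' bootstrap enrichment of DMRs in the functional partition),
#' \code{sexdiff} (10 kb window differences, TSS and metagene profiles,
#' Rsx-locus CGI summary), \code{xclassify} (unplaced-scaffold
#' classification) and \code{integrate} (methylation-expression
#' integration). Each stage writes its outputs plus a JSON provenance
#' record (parameters, package version, input/output checksums) under
#' \code{outdir}; requesting a stage whose prerequisites are missing
#' fails with the name of the stage to run first.
#'
#' @param config list or YAML path, see \code{\link{pipelineConfig}}.
#' @param stages character vector of stage names, or \code{"all"}.
#' @return Invisibly, a manifest list of written files by stage.
#' @export
runPipeline <- function(config = list(), stages = "all") {
    cfg <- pipelineConfig(config)
    order <- c("simulate", "io", "dmr", "enrich", "sexdiff", "xclassify",
               "integrate")
    if (identical(stages, "all")) stages <- order
    stopifnot(all(stages %in% order))
    stages <- order[order %in% stages]
    outdir <- cfg$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    simdir <- file.path(outdir, "sim")
    manifest <- list()
    state <- new.env(parent = emptyenv())

    needSim <- function() {
        if (!file.exists(file.path(simdir, "samples.tsv")))
            stop("missing simulated inputs; run stage 'simulate' first")
    }
    loadSamples <- function() {
        if (!is.null(state$samples)) return(state$samples)
        needSim()
        raw <- readSampleSheet(file.path(simdir, "samples.tsv"))
        lens <- scaffoldLengths(.simSeqlengths(simdir))
        ss <- lapply(raw, function(s) {
            s <- filterMinCoverage(mergeStrands(s), cfg$io$min_coverage)
            filterMinScaffoldLength(s, lens, cfg$io$min_scaffold_length)
        })
        state$samples <- ss
        ss
    }
    for (st in stages) {
        manifest[[st]] <- switch(st,
            simulate = {
                sc <- do.call(simConfig,
                              c(list(seed = cfg$seed), cfg$simulation))
                ds <- simulateDataset(sc, dir = simdir, merged = FALSE)
                state$dataset <- ds
                unlist(ds$files, use.names = FALSE)
            },
            io = {
                ss <- loadSamples()
                p <- file.path(outdir, "io_summary.tsv")
                utils::write.table(data.frame(
                    sample_id = names(ss),
                    n_cpgs = vapply(ss, function(s)
                        length(methCalls(s)), 0L),
                    mean_f = vapply(ss, function(s)
                        mean(methLevel(s)), 0)),
                    p, sep = "\t", quote = FALSE, row.names = FALSE)
                p
            },
            dmr = {
                ss <- loadSamples()
                res <- .stageDmr(ss, cfg, outdir)
                state$dmrs <- res$dmrs
                res$files
            },
            enrich = {
                if (is.null(state$dmrs))
                    stop("missing DMR outputs; run stage 'dmr' first")
                needSim()
                genome <- readDNAStringSet(file.path(simdir, "genome.fa"))
                names(genome) <- sub(" .*", "", names(genome))
                anno <- readAnnotations(file.path(simdir, "genes.gff3"),
                                        genome)
                cats <- list(promoter = annoPromoters(anno),
                             gene_body = annoGeneBodies(anno),
                             intergenic = annoIntergenic(anno))
                enr <- bootstrapEnrichment(state$dmrs, cats, genome,
                                           nBoot = cfg$enrichment$n_boot,
                                           gcTolerance =
                                               cfg$enrichment$gc_tolerance)
                p <- file.path(outdir, "enrichment.tsv")
                utils::write.table(as.data.frame(enr), p, sep = "\t",
                                   quote = FALSE, row.names = FALSE)
                p
            },
            sexdiff = {
                ss <- loadSamples()
                .stageSexdiff(ss, cfg, outdir, simdir)
            },
            xclassify = {
                ss <- loadSamples()
                .stageXclassify(ss, cfg, outdir)
            },
            integrate = {
                ss <- loadSamples()
                .stageIntegrate(ss, cfg, outdir, simdir)
            })
        sect <- c(simulate = "simulation", io = "io", dmr = "dmr",
                  enrich = "enrichment", sexdiff = "sexdiff",
                  xclassify = "xclassify", integrate = "integrate")[st]
        .provenance(outdir, st, params = cfg[[sect]],
                    inputs = file.path(simdir, "samples.tsv"),
                    outputs = unlist(manifest[[st]], use.names = FALSE))
    }
    invisible(manifest)
}

.simSeqlengths <- function(simdir) {
    fa <- file.path(simdir, "genome.fa")
    if (file.exists(fa)) {
        g <- readDNAStringSet(fa)
        names(g) <- sub(" .*", "", names(g))
        return(scaffoldLengths(g))
    }
    # fall back to positions present in the truth record
    tr <- jsonlite::read_json(file.path(simdir, "truth.json"))
    setNames(rep(Inf, length(tr$origin)), names(tr$origin))
}

.stageDmr <- function(ss, cfg, outdir) {
    tissues <- unique(vapply(ss, sampleTissue, ""))
    # pool the sexes of each tissue for tissue-vs-tissue comparisons
    pooled <- lapply(tissues, function(t)
        poolMethylomes(ss[vapply(ss, sampleTissue, "") == t], t))
    names(pooled) <- tissues
    scafs <- sort(unique(unlist(lapply(pooled, function(s)
        unique(as.character(seqnames(methCalls(s))))))))
    scafs <- grep("^chrA_", scafs, value = TRUE)
    d <- cfg$dmr
    callPair <- function(a, b) {
        out <- GRanges()
        for (sc in scafs) {
            ta <- smoothTrack(pooled[[a]], sc, d$half_window_cpgs,
                              d$min_span_bp)
            tb <- smoothTrack(pooled[[b]], sc, d$half_window_cpgs,
                              d$min_span_bp)
            tr <- intersectTracks(ta, tb)
            out <- suppressWarnings(
                c(out, callDMRs(tr[[1]], tr[[2]], d$min_diff,
                                d$min_cpgs)))
        }
        out
    }
    perTissue <- list()
    for (t in tissues) {
        pw <- lapply(setdiff(tissues, t), function(o) callPair(t, o))
        perTissue[[t]] <- tissueConsensusDmrs(pw, d$min_overlap_frac)
    }
    shared <- classifySharing(perTissue, d$min_overlap_frac)
    f1 <- file.path(outdir, "dmrs.bed")
    writeDmrBed(shared, f1)
    list(dmrs = shared, files = f1)
}

.stageSexdiff <- function(ss, cfg, outdir, simdir) {
    sex <- vapply(ss, sampleSex, "")
    tis <- vapply(ss, sampleTissue, "")
    t1 <- tis[1L]
    fem <- ss[[which(sex == "female" & tis == t1)[1L]]]
    mal <- ss[[which(sex == "male" & tis == t1)[1L]]]
    sd <- cfg$sexdiff
    wd <- windowDifferences(fem, mal, sd$bin_size, sd$min_cpgs_per_window)
    f1 <- file.path(outdir, "window_differences.tsv")
    utils::write.table(data.frame(
        scaffold = as.character(seqnames(wd)), start = start(wd) - 1L,
        end = end(wd), n_cpgs = wd$n_cpgs, delta = wd$delta),
        f1, sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- rtracklayer::import(file.path(simdir, "genes.gff3"))
    mcols(genes)$gene_id <- as.character(mcols(genes)$ID)
    xGenes <- genes[grepl("^chrX_", as.character(seqnames(genes)))]
    f2 <- file.path(outdir, "tss_profile.tsv")
    if (length(xGenes)) {
        pr <- tssProfile(fem, xGenes, sd$flank_bp, sd$window_bp,
                         sd$step_bp)
        utils::write.table(as.data.frame(pr), f2, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    f3 <- file.path(outdir, "metagene_profile.tsv")
    mp <- metageneProfile(list(female = fem, male = mal), genes,
                          sd$n_bins)
    utils::write.table(as.data.frame(mp), f3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(f1, f2, f3)
}

.stageXclassify <- function(ss, cfg, outdir) {
    xc <- cfg$xclassify
    tis <- vapply(ss, sampleTissue, "")
    sex <- vapply(ss, sampleSex, "")
    byTissue <- lapply(unique(tis), function(t)
        list(female = ss[[which(tis == t & sex == "female")[1L]]],
             male = ss[[which(tis == t & sex == "male")[1L]]]))
    names(byTissue) <- unique(tis)
    scafs <- sort(unique(unlist(lapply(ss, function(s)
        unique(as.character(seqnames(methCalls(s))))))))
    unplaced <- grep(paste0("^", xc$unplaced_prefix), scafs, value = TRUE)
    if (!length(unplaced)) stop("no unplaced scaffolds found")
    res <- classifyScaffolds(byTissue, unplaced, alpha = xc$alpha,
                             covBand = xc$cov_band,
                             autoBand = xc$auto_band,
                             binSize = cfg$sexdiff$bin_size,
                             minWindows = xc$min_windows)
    p <- file.path(outdir, "xclassify.tsv")
    utils::write.table(as.data.frame(res), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
}

.stageIntegrate <- function(ss, cfg, outdir, simdir) {
    exprPath <- file.path(simdir, "expression.tsv")
    if (!file.exists(exprPath))
        stop("missing expression table; run stage 'simulate' first")
    expr <- utils::read.table(exprPath, header = TRUE, sep = "\t")
    genes <- rtracklayer::import(file.path(simdir, "genes.gff3"))
    mcols(genes)$gene_id <- as.character(mcols(genes)$ID)
    tis <- vapply(ss, sampleTissue, "")
    sex <- vapply(ss, sampleSex, "")
    t1 <- if ("kidney" %in% tis) "kidney" else tis[1L]
    fem <- ss[[which(tis == t1 & sex == "female")[1L]]]
    mal <- ss[[which(tis == t1 & sex == "male")[1L]]]
    sf <- summarizeGeneMethylation(fem, genes, cfg$integrate$min_cpgs)
    sm <- summarizeGeneMethylation(mal, genes, cfg$integrate$min_cpgs)
    fc <- sexExpressionRatio(setNames(expr$expr_female, expr$gene_id),
                             setNames(expr$expr_male, expr$gene_id))
    tr <- jsonlite::read_json(file.path(simdir, "truth.json"))
    excl <- if (isTRUE(cfg$integrate$exclude_rsx) &&
                !is.null(tr$rsx_gene)) tr$rsx_gene else character()
    res <- list(
        promoter_expr_rho = rankCorrelation(
            sm$promoter_mean_f,
            expr$expr_male[match(sm$gene_id, expr$gene_id)]),
        body_sexdiff_rho = tryCatch(
            correlateSexdiffMethExpression(sf, sm, fc, "gene_body",
                                           exclude = excl),
            error = function(e) list(rho = NA, p = NA)))
    p1 <- file.path(outdir, "gene_methylation.tsv")
    utils::write.table(as.data.frame(sf), p1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p2 <- file.path(outdir, "integration.json")
    jsonlite::write_json(lapply(res, function(r)
        list(rho = r$rho, p = r$p)), p2, auto_unbox = TRUE, digits = NA)
    c(p1, p2)
}
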