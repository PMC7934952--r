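#' Generate a synthetic genome with genes, CpG islands and ground truth
#'
#' Builds a small fragmented assembly emulating a marsupial-like WGBS
#' study design: placed autosomal and X scaffolds plus unplaced scaffolds
#' whose true origin (autosomal or X) is hidden in the ground truth.
#' Background sequence has GC near 0.40 with CpG dyads thinned to
#' \code{cpgRate} (a CpG-depleted genome); genes are placed on a
#' non-overlapping grid with randomised strand, each with a CpG-rich
#' island inside its promoter; one X gene is designated the Rsx-like
#' locus and receives a second upstream island. Everything is
#' deterministic given the config seed.
#'
#' With \code{withSequence = FALSE} no nucleotide sequence is built; CpG
#' positions are drawn directly from the same spacing model. Use this for
#' scale work where sequence content (GC matching, island detection) is
#' not needed.
#'
#' @param config a \code{\link{simConfig}}.
#' @param withSequence build actual nucleotide sequence (default
#'   \code{TRUE}).
#' @return List of class \code{"MethSimGenome"}: \code{genome}
#'   (\code{DNAStringSet} or \code{NULL}), \code{seqlengths},
#'   \code{sites} (CpG \code{GRanges} with flags \code{in_cgi},
#'   \code{in_promoter}), \code{genes}, \code{cgis}, \code{truth}
#'   (scaffold origins, Rsx locus, config) .
#' @export
generateGenome <- function(config, withSequence = TRUE) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    L <- as.integer(config$scaffoldLengthBp)
    scafs <- c(
        if (config$nAutosomalScaffolds)
            paste0("chrA_", seq_len(config$nAutosomalScaffolds)),
        if (config$nXScaffolds)
            paste0("chrX_", seq_len(config$nXScaffolds)),
        if (config$nUnplacedScaffolds)
            paste0("scaffold_", seq_len(config$nUnplacedScaffolds)))
    nUx <- round(config$nUnplacedScaffolds * config$unplacedXFraction)
    unplacedOrigin <- sample(rep(c("X", "A"),
                                 c(nUx, config$nUnplacedScaffolds - nUx)))
    origin <- c(rep("A", config$nAutosomalScaffolds),
                rep("X", config$nXScaffolds), unplacedOrigin)
    names(origin) <- scafs
    lens <- setNames(rep(L, length(scafs)), scafs)

    # gene placement on placed scaffolds, grid with randomised strand
    placed <- scafs[seq_len(config$nAutosomalScaffolds + config$nXScaffolds)]
    pitch <- config$geneLengthBp + config$geneSpacingBp
    slotsPer <- (L - 4000L) %/% pitch
    if (config$geneCount > slotsPer * length(placed))
        stop("infeasible gene packing: ", config$geneCount, " genes but ",
             slotsPer * length(placed), " slots")
    scafOfGene <- rep(placed, length.out = config$geneCount)
    slotOfGene <- stats::ave(seq_len(config$geneCount), scafOfGene,
                             FUN = seq_along)
    starts <- 2000L + (slotOfGene - 1L) * pitch + config$promoterWidth
    strands <- sample(c("+", "-"), config$geneCount, replace = TRUE)
    genes <- GRanges(scafOfGene,
                     IRanges(starts, width = config$geneLengthBp),
                     strand = strands,
                     gene_id = sprintf("gene%04d", seq_len(config$geneCount)))
    GenomeInfoDb::seqlevels(genes) <- scafs
    GenomeInfoDb::seqlengths(genes) <- lens

    # promoter CGIs: centred in the 1 kb upstream window
    tss <- ifelse(strands == "-", end(genes), start(genes))
    cgiHalf <- config$cgiLengthBp %/% 2L
    cgiMid <- ifelse(strands == "-", tss + 500L, tss - 500L)
    cgis <- GRanges(scafOfGene, IRanges(cgiMid - cgiHalf,
                                        width = config$cgiLengthBp),
                    cgi_id = paste0("cgi_", mcols(genes)$gene_id))
    # Rsx-like locus: first gene on an X scaffold, second upstream CGI
    xGenes <- which(origin[scafOfGene] == "X")
    rsxGene <- if (length(xGenes)) mcols(genes)$gene_id[xGenes[1L]] else NA
    rsxCgis <- GRanges()
    if (!is.na(rsxGene)) {
        i <- xGenes[1L]
        mid2 <- if (strands[i] == "-") tss[i] + 1500L else tss[i] - 1500L
        extra <- GRanges(scafOfGene[i],
                         IRanges(mid2 - cgiHalf, width = config$cgiLengthBp),
                         cgi_id = paste0("cgi2_", rsxGene))
        cgis <- sort(suppressWarnings(c(cgis, extra)))
        rsxCgis <- cgis[grepl(rsxGene, mcols(cgis)$cgi_id)]
    }
    GenomeInfoDb::seqlevels(cgis) <- scafs
    GenomeInfoDb::seqlengths(cgis) <- lens

    # planted tissue-DMR loci: locally CpG-dense clusters on placed
    # autosomes, clear of islands and promoters, one tissue per locus
    nLoci <- config$nDmrsPerTissue * length(config$tissues)
    autos <- scafs[seq_len(config$nAutosomalScaffolds)]
    clusterSpan <- (config$dmrNCpgs - 1L) * config$dmrCpgSpacingBp + 2L
    avoid <- reduce(c(granges(cgis) + 1000L,
                      granges(genes) + 1500L), ignore.strand = TRUE)
    dmrLoci <- GRanges()
    if (nLoci > 0L && length(autos)) {
        locScaf <- rep(autos, length.out = nLoci)
        locStart <- integer(nLoci)
        for (i in seq_len(nLoci)) {
            for (try in 1:200) {
                s0 <- sample.int(L - clusterSpan - 6000L, 1L) + 3000L
                cand <- GRanges(locScaf[i], IRanges(s0, width = clusterSpan))
                busy <- suppressWarnings(
                    overlapsAny(cand, avoid, ignore.strand = TRUE) ||
                        (length(dmrLoci) &&
                             overlapsAny(cand, dmrLoci + 500L,
                                         ignore.strand = TRUE)))
                if (!busy) break
            }
            locStart[i] <- s0
            dmrLoci <- suppressWarnings(c(dmrLoci, cand))
        }
        mcols(dmrLoci)$locus_id <- seq_len(nLoci)
        mcols(dmrLoci)$tissue <- rep(config$tissues,
                                     each = config$nDmrsPerTissue)
        mcols(dmrLoci)$sign <- sample(c(-1L, 1L), nLoci, replace = TRUE)
        GenomeInfoDb::seqlevels(dmrLoci) <- scafs
        GenomeInfoDb::seqlengths(dmrLoci) <- lens
    }

    genome <- NULL
    sitePos <- vector("list", length(scafs))
    names(sitePos) <- scafs
    if (withSequence) {
        seqs <- character(length(scafs))
        for (k in seq_along(scafs)) {
            ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                         prob = c(0.285, 0.215, 0.215, 0.285))
            cg <- which(ch[-L] == "C" & ch[-1L] == "G")
            drop <- cg[runif(length(cg)) > config$cpgRate / (0.215^2)]
            ch[drop + 1L] <- "A"
            # CpG-rich island sequence
            here <- as.character(seqnames(cgis)) == scafs[k]
            for (j in which(here)) {
                w <- width(cgis)[j]
                isl <- .cgiSequence(w)
                ch[start(cgis)[j]:(start(cgis)[j] + w - 1L)] <- isl
            }
            # DMR cluster CpGs
            hereD <- which(as.character(seqnames(dmrLoci)) == scafs[k])
            for (j in hereD) {
                p <- start(dmrLoci)[j] +
                    (seq_len(config$dmrNCpgs) - 1L) * config$dmrCpgSpacingBp
                ch[p] <- "C"; ch[p + 1L] <- "G"
            }
            sitePos[[k]] <- which(ch[-L] == "C" & ch[-1L] == "G")
            seqs[k] <- paste(ch, collapse = "")
        }
        genome <- DNAStringSet(setNames(seqs, scafs))
    } else {
        for (k in seq_along(scafs)) {
            p <- which(stats::rbinom(L - 1L, 1L, config$cpgRate) == 1L)
            p <- p[c(TRUE, diff(p) >= 2L)]
            here <- which(as.character(seqnames(cgis)) == scafs[k])
            for (j in here)
                p <- c(p, seq(start(cgis)[j], end(cgis)[j] - 1L, by = 4L))
            hereD <- which(as.character(seqnames(dmrLoci)) == scafs[k])
            for (j in hereD)
                p <- c(p, start(dmrLoci)[j] +
                           (seq_len(config$dmrNCpgs) - 1L) *
                               config$dmrCpgSpacingBp)
            sitePos[[k]] <- sort(unique(p))
        }
    }
    sites <- GRanges(rep(scafs, lengths(sitePos)),
                     IRanges(unlist(sitePos, use.names = FALSE), width = 1L))
    GenomeInfoDb::seqlevels(sites) <- scafs
    GenomeInfoDb::seqlengths(sites) <- lens
    mcols(sites)$in_cgi <- overlapsAny(sites, cgis, ignore.strand = TRUE)
    proms <- geneRegions(genes, config$promoterWidth)$promoter
    mcols(sites)$in_promoter <- overlapsAny(sites, proms,
                                            ignore.strand = TRUE)
    mcols(sites)$dmr_locus <- NA_integer_
    if (length(dmrLoci)) {
        hits <- findOverlaps(sites, dmrLoci, ignore.strand = TRUE)
        mcols(sites)$dmr_locus[S4Vectors::queryHits(hits)] <-
            mcols(dmrLoci)$locus_id[S4Vectors::subjectHits(hits)]
    }
    structure(list(genome = genome, seqlengths = lens, sites = sites,
                   genes = genes, cgis = cgis, dmrLoci = dmrLoci,
                   truth = list(origin = origin, rsxGene = rsxGene,
                                rsxCgis = rsxCgis, config = config)),
              class = "MethSimGenome")
}

# island sequence: CG dinucleotide emitted with prob 0.3, GC-rich filler
.cgiSequence <- function(w) {
    out <- character(0)
    while (length(out) < w) {
        if (runif(1) < 0.3) out <- c(out, "C", "G")
        else out <- c(out, sample(c("A", "C", "G", "T"), 1L,
                                  prob = c(0.2, 0.3, 0.3, 0.2)))
    }
    out[seq_len(w)]
}

#' @export
print.MethSimGenome <- function(x, ...) {
    cat("MethSimGenome:", length(x$seqlengths), "scaffolds,",
        length(x$sites), "CpG sites,", length(x$genes), "genes",
        if (is.null(x$genome)) "(no sequence)" else "", "\n")
    invisible(x)
}
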