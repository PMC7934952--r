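#' Read gene annotations and derive the functional partition
#'
#' Imports gene models from GFF3 (1-based, closed) or BED (0-based,
#' half-open; dialect chosen by file extension) and derives, per scaffold:
#' promoters (\code{promoterWidth} bp immediately upstream of the TSS,
#' strand-aware), gene bodies (TSS to TES) and intergenic sequence (the
#' complement). Intervals reaching past a scaffold end are clipped with a
#' warning. Where annotations collide, bases are assigned with precedence
#' gene body > promoter > intergenic, so the three sets are disjoint and
#' jointly tile every scaffold.
#'
#' @param path GFF3 (".gff"/".gff3") or BED (".bed") file.
#' @param genome scaffold lengths (named vector, \code{Seqinfo} or
#'   \code{DNAStringSet}).
#' @param promoterWidth promoter extent upstream of the TSS in bp
#'   (default 1000).
#' @param feature GFF3 feature type to keep (default "gene").
#' @return An \code{\link{AnnotationSet}}.
#' @export
readAnnotations <- function(path, genome, promoterWidth = 1000L,
                            feature = "gene") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    gr <- rtracklayer::import(path)
    if (ext %in% c("gff", "gff3", "gtf")) {
        if ("type" %in% colnames(mcols(gr)) &&
            any(as.character(gr$type) == feature))
            gr <- gr[as.character(gr$type) == feature]
        id <- if ("ID" %in% colnames(mcols(gr)) && !all(is.na(gr$ID)))
            as.character(gr$ID)
        else if ("Name" %in% colnames(mcols(gr))) as.character(gr$Name)
        else paste0("gene", seq_along(gr))
    } else if (ext == "bed") {
        id <- if ("name" %in% colnames(mcols(gr))) as.character(gr$name)
        else paste0("gene", seq_along(gr))
    } else stop("unrecognised annotation extension: ", ext)
    genes <- granges(gr)
    mcols(genes)$gene_id <- id
    buildAnnotationSet(genes, genome, promoterWidth = promoterWidth)
}

#' Build an AnnotationSet from an in-memory gene GRanges
#'
#' @param genes stranded \code{GRanges} with a \code{gene_id} mcol.
#' @inheritParams readAnnotations
#' @return An \code{\link{AnnotationSet}}.
#' @export
buildAnnotationSet <- function(genes, genome, promoterWidth = 1000L) {
    lens <- scaffoldLengths(genome)
    if (any(as.character(strand(genes)) == "*"))
        stop("gene strand must be '+' or '-'")
    unknown <- setdiff(unique(as.character(seqnames(genes))), names(lens))
    if (length(unknown))
        stop("gene scaffold(s) absent from genome: ",
             paste(unknown, collapse = ", "))
    si <- Seqinfo(names(lens), seqlengths = lens)
    GenomeInfoDb::seqlevels(genes) <- names(lens)
    GenomeInfoDb::seqinfo(genes) <- si

    prom <- suppressWarnings(
        GenomicRanges::promoters(genes, upstream = promoterWidth,
                                 downstream = 0L))
    clipped <- start(prom) < 1L | end(prom) > lens[as.character(seqnames(prom))]
    if (any(clipped))
        warning(sum(clipped), " promoter(s) clipped at scaffold boundaries")
    prom <- GenomicRanges::trim(prom)
    prom <- prom[width(prom) > 0L]

    bodies <- genes
    bodyU <- reduce(granges(bodies), ignore.strand = TRUE)
    promU <- reduce(granges(prom), ignore.strand = TRUE)
    # precedence: gene body > promoter > intergenic
    promPart <- GenomicRanges::setdiff(promU, bodyU, ignore.strand = TRUE)
    covered <- reduce(c(bodyU, promPart), ignore.strand = TRUE)
    all <- GRanges(names(lens), IRanges(1L, lens), seqinfo = si)
    inter <- GenomicRanges::setdiff(all, covered, ignore.strand = TRUE)

    new("AnnotationSet", genes = genes, promoters = promPart,
        geneBodies = bodyU, intergenic = inter)
}

#' Promoter and gene-body interval of each gene
#'
#' Per-gene (not partitioned) intervals: the promoter is
#' \code{promoterWidth} bp upstream of the TSS, the body is TSS to TES.
#' Unlike the partition in an \code{AnnotationSet}, these may overlap other
#' genes' regions; they are what per-gene methylation summaries use.
#'
#' @param genes stranded \code{GRanges} with \code{gene_id}.
#' @param promoterWidth promoter extent in bp.
#' @return List with elements \code{promoter} and \code{body}, each a
#'   \code{GRanges} parallel to \code{genes}.
#' @export
geneRegions <- function(genes, promoterWidth = 1000L) {
    prom <- suppressWarnings(GenomicRanges::trim(
        GenomicRanges::promoters(genes, upstream = promoterWidth,
                                 downstream = 0L)))
    list(promoter = prom, body = genes)
}
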