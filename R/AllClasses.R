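#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps countOverlaps reduce gaps promoters resize shift
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb seqlevels seqlengths seqinfo Seqinfo
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet letterFrequency vmatchPattern
#' @importFrom data.table data.table fread fwrite rbindlist
#' @importFrom stats wilcox.test cor.test chisq.test p.adjust rbeta rbinom
#'   rpois rnorm runif median sd quantile hclust dist as.dendrogram setNames
#'   complete.cases
#' @importFrom utils read.table write.table packageVersion
NULL

#' Methylome: per-CpG methylation calls for one WGBS sample
#'
#' A \code{Methylome} holds the cytosine-level methylation calls of a single
#' whole-genome bisulfite sequencing sample as a width-one \code{GRanges}
#' (one range per called cytosine position) with integer metadata columns
#' \code{m} (methylated read count) and \code{u} (unmethylated read count),
#' together with sample metadata: sample identifier, sex, tissue, and
#' optionally the total and per-scaffold mapped-read counts used by the
#' mapped-read-proportion evidence stream.
#'
#' Calls read from a Bismark-style cytosine report are strand-resolved (the
#' two cytosines of a CpG dyad appear as separate \code{+} and \code{-}
#' calls); \code{\link{mergeStrands}} collapses each dyad onto its
#' forward-strand C. Fractional methylation at a call is
#' \eqn{f = m/(m+u) \in [0,1]}.
#'
#' @slot calls \code{GRanges}, width 1, sorted, unique \code{(seqname, pos,
#'   strand)}; mcols \code{m}, \code{u} (non-negative integers, \code{m+u >= 1}).
#' @slot sampleId character(1).
#' @slot sex \code{"female"} or \code{"male"}.
#' @slot tissue character(1).
#' @slot totalMappedReads numeric(1); \code{NA} when unknown.
#' @slot perScaffoldMappedReads named numeric; may be empty.
#'
#' @seealso \code{\link{readCpGReport}}, \code{\link{mergeStrands}},
#'   \code{\link{filterMinCoverage}}
#' @exportClass Methylome
setClass("Methylome",
    representation(
        calls = "GRanges",
        sampleId = "character",
        sex = "character",
        tissue = "character",
        totalMappedReads = "numeric",
        perScaffoldMappedReads = "numeric"
    ),
    prototype(
        sampleId = NA_character_, sex = "female", tissue = NA_character_,
        totalMappedReads = NA_real_, perScaffoldMappedReads = numeric()
    )
)

setValidity("Methylome", function(object) {
    msg <- character()
    gr <- object@calls
    if (length(gr)) {
        mc <- mcols(gr)
        if (!all(c("m", "u") %in% colnames(mc)))
            msg <- c(msg, "calls must carry integer mcols 'm' and 'u'")
        else {
            m <- mc$m; u <- mc$u
            if (any(m < 0) || any(u < 0))
                msg <- c(msg, "negative read counts")
            if (any(m + u < 1))
                msg <- c(msg, "every call needs m + u >= 1")
        }
        if (any(width(gr) != 1L))
            msg <- c(msg, "calls must be width-1 positions")
        if (S4Vectors::isSorted(gr) == FALSE)
            msg <- c(msg, "calls must be sorted by (scaffold, position)")
        key <- paste(seqnames(gr), start(gr), strand(gr))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (scaffold, position, strand) calls")
    }
    if (!(object@sex %in% c("female", "male")))
        msg <- c(msg, "sex must be 'female' or 'male'")
    if (length(msg)) msg else TRUE
})

#' Construct a Methylome from positions and counts
#'
#' @param scaffold character vector of scaffold names.
#' @param pos 1-based position of the cytosine (forward-strand C for merged
#'   calls).
#' @param m,u methylated / unmethylated read counts.
#' @param strand call strand; \code{"*"} for strand-merged calls.
#' @param sampleId,sex,tissue sample metadata.
#' @param totalMappedReads,perScaffoldMappedReads optional mapping statistics.
#' @param seqinfo optional \code{Seqinfo} carrying scaffold lengths.
#' @return A \code{Methylome}.
#' @examples
#' Methylome("chr1", c(100, 200), m = c(3, 1), u = c(1, 4),
#'           sampleId = "s1", sex = "female", tissue = "brain")
#' @export
Methylome <- function(scaffold, pos, m, u, strand = "*",
                      sampleId = NA_character_, sex = "female",
                      tissue = NA_character_, totalMappedReads = NA_real_,
                      perScaffoldMappedReads = numeric(), seqinfo = NULL) {
    gr <- GRanges(scaffold, IRanges(pos, width = 1L), strand = strand,
                  m = as.integer(m), u = as.integer(u))
    if (!is.null(seqinfo)) {
        si <- as(seqinfo, "Seqinfo")
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
        GenomeInfoDb::seqinfo(gr) <- si
    }
    new("Methylome", calls = sort(gr), sampleId = sampleId, sex = sex,
        tissue = tissue, totalMappedReads = as.numeric(totalMappedReads),
        perScaffoldMappedReads = perScaffoldMappedReads)
}

setMethod("show", "Methylome", function(object) {
    n <- length(object@calls)
    cat("Methylome '", object@sampleId, "' (", object@sex, " ",
        object@tissue, ")\n", sep = "")
    cat("  ", n, " CpG calls on ",
        length(unique(as.character(seqnames(object@calls)))),
        " scaffold(s)", sep = "")
    if (n) {
        f <- methLevel(object)
        cat("; mean fractional methylation ", round(mean(f), 3), sep = "")
    }
    cat("\n")
    if (!is.na(object@totalMappedReads))
        cat("  total mapped reads: ", object@totalMappedReads, "\n", sep = "")
})

#' AnnotationSet: gene models with the derived functional partition
#'
#' Gene annotations plus the three-way functional partition used throughout:
#' promoters (1000 bp upstream of the TSS, strand-aware), gene bodies
#' (TSS to TES) and intergenic sequence (complement of the union). Where a
#' promoter of one gene overlaps the body of another, the base is assigned
#' with precedence gene body > promoter > intergenic, so the three region
#' sets partition each scaffold exactly.
#'
#' @slot genes \code{GRanges} with mcols \code{gene_id}; stranded.
#' @slot promoters,geneBodies,intergenic disjoint \code{GRanges} covering
#'   each scaffold.
#' @seealso \code{\link{readAnnotations}}
#' @exportClass AnnotationSet
setClass("AnnotationSet",
    representation(
        genes = "GRanges",
        promoters = "GRanges",
        geneBodies = "GRanges",
        intergenic = "GRanges"
    )
)

setValidity("AnnotationSet", function(object) {
    if (length(object@genes) &&
        !("gene_id" %in% colnames(mcols(object@genes))))
        return("genes must carry a 'gene_id' mcol")
    if (any(as.character(strand(object@genes)) == "*"))
        return("gene strand must be '+' or '-'")
    TRUE
})

setMethod("show", "AnnotationSet", function(object) {
    cat("AnnotationSet:", length(object@genes), "genes;",
        length(object@promoters), "promoter,",
        length(object@geneBodies), "gene-body and",
        length(object@intergenic), "intergenic intervals\n")
})

#' SmoothedTrack: smoothed fractional methylation along one scaffold
#'
#' Raw and locally-smoothed fractional methylation at the CpGs of a single
#' scaffold for one sample, the substrate of DMR calling.
#'
#' @slot scaffold character(1).
#' @slot pos sorted integer CpG positions (forward-strand C).
#' @slot rawF,smoothF fractional methylation per CpG, \code{smoothF} in [0,1].
#' @slot cov read coverage per CpG.
#' @seealso \code{\link{smoothTrack}}, \code{\link{callDMRs}}
#' @exportClass SmoothedTrack
setClass("SmoothedTrack",
    representation(
        scaffold = "character",
        pos = "integer",
        rawF = "numeric",
        smoothF = "numeric",
        cov = "numeric"
    )
)

setValidity("SmoothedTrack", function(object) {
    n <- length(object@pos)
    if (length(object@rawF) != n || length(object@smoothF) != n ||
        length(object@cov) != n)
        return("pos, rawF, smoothF and cov must have equal length")
    if (n && is.unsorted(object@pos, strictly = TRUE))
        return("pos must be strictly increasing")
    if (n && (min(object@smoothF) < -1e-9 || max(object@smoothF) > 1 + 1e-9))
        return("smoothF must lie in [0, 1]")
    TRUE
})

setMethod("show", "SmoothedTrack", function(object) {
    cat("SmoothedTrack on", object@scaffold, "with", length(object@pos),
        "CpGs\n")
})

setMethod("length", "SmoothedTrack", function(x) length(x@pos))
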