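#' Read a Bismark-style cytosine report
#'
#' Parses a Bismark CpG report (plain or gzipped, tab- or space-delimited)
#' with columns scaffold, 1-based position, strand, methylated count,
#' unmethylated count, context and (optionally) trinucleotide. Only rows in
#' CpG context are kept; the result is strand-resolved (one call per
#' cytosine, so a covered CpG dyad contributes a \code{+} and a \code{-}
#' row). Rows with zero total coverage are dropped: an uncovered cytosine
#' carries no call.
#'
#' @param path report file.
#' @param sampleId,sex,tissue sample metadata attached to the result.
#' @param totalMappedReads,perScaffoldMappedReads optional mapping stats.
#' @return A strand-resolved \code{\link{Methylome}}.
#' @seealso \code{\link{mergeStrands}} to collapse dyads,
#'   \code{\link{filterMinCoverage}} for the minimum-read filter.
#' @export
readCpGReport <- function(path, sampleId = basename(path), sex, tissue,
                          totalMappedReads = NA_real_,
                          perScaffoldMappedReads = numeric()) {
    dt <- if (grepl("\\.gz$", path)) {
        con <- gzfile(path, "rt")
        on.exit(close(con))
        data.table::fread(text = readLines(con), header = FALSE,
                          sep = "auto", colClasses = list(character = 1),
                          fill = TRUE, showProgress = FALSE)
    } else {
        data.table::fread(path, header = FALSE, sep = "auto",
                          colClasses = list(character = 1),
                          fill = TRUE, showProgress = FALSE)
    }
    if (ncol(dt) < 6L)
        stop("cytosine report must have at least 6 columns, got ", ncol(dt))
    names(dt)[1:6] <- c("scaffold", "pos", "strand", "m", "u", "context")
    bad <- which(is.na(suppressWarnings(as.integer(dt$pos))) |
                 is.na(suppressWarnings(as.numeric(dt$m))) |
                 is.na(suppressWarnings(as.numeric(dt$u))) |
                 !(dt$strand %in% c("+", "-")))
    if (length(bad))
        stop("malformed cytosine report row at line ", bad[1L], " of ", path)
    if (any(dt$m < 0) || any(dt$u < 0))
        stop("negative read counts in ", path, " (line ",
             which(dt$m < 0 | dt$u < 0)[1L], ")")
    keep <- toupper(dt$context) %in% c("CPG", "CG") & (dt$m + dt$u) >= 1
    dt <- dt[keep, ]
    Methylome(dt$scaffold, as.integer(dt$pos), dt$m, dt$u,
              strand = dt$strand, sampleId = sampleId, sex = sex,
              tissue = tissue, totalMappedReads = totalMappedReads,
              perScaffoldMappedReads = perScaffoldMappedReads)
}

#' Write calls back out as a Bismark-style CpG report
#'
#' Inverse of \code{\link{readCpGReport}} up to the dropped zero-coverage
#' rows; used by the pipeline and the simulator.
#'
#' @param x a \code{Methylome}.
#' @param path output path (".gz" suffix writes gzipped).
#' @return \code{path}, invisibly.
#' @export
writeCpGReport <- function(x, path) {
    gr <- methCalls(x)
    st <- as.character(strand(gr))
    st[st == "*"] <- "+"
    dt <- data.table::data.table(
        scaffold = as.character(seqnames(gr)), pos = start(gr), strand = st,
        m = mcols(gr)$m, u = mcols(gr)$u, context = "CpG", tri = "CGN")
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       compress = if (grepl("\\.gz$", path)) "gzip" else "none")
    invisible(path)
}

#' Merge strand-resolved CpG calls onto the forward-strand cytosine
#'
#' A CpG dyad is the palindromic CG: the \code{+} call at position p and the
#' \code{-} call at p+1 report the same dyad. This collapses each dyad to a
#' single call at the forward-strand C with summed methylated and
#' unmethylated counts. Minus-strand calls without a covered partner are
#' still assigned to their dyad's forward-strand C (position minus one),
#' as cytosine-report coordinates dictate; unpaired plus-strand and
#' already-merged (\code{"*"}) calls pass through unchanged. Total m and u
#' are conserved exactly.
#'
#' @param x a strand-resolved \code{Methylome}.
#' @return A \code{Methylome} with one call per dyad, strand \code{"*"}.
#' @export
mergeStrands <- function(x) {
    gr <- methCalls(x)
    if (!length(gr)) return(x)
    st <- as.character(strand(gr))
    plus <- which(st == "+"); minus <- which(st == "-")
    other <- which(st == "*")
    keyP <- paste0(seqnames(gr)[plus], ":", start(gr)[plus])
    keyM <- paste0(seqnames(gr)[minus], ":", start(gr)[minus] - 1L)
    hit <- match(keyM, keyP)
    paired <- !is.na(hit)
    m <- mcols(gr)$m; u <- mcols(gr)$u
    # merged records live at the forward-strand C; orphan minus calls
    # are re-anchored there too (their C sits at pos - 1 on the + strand)
    mOut <- m[plus]; uOut <- u[plus]
    mOut[hit[paired]] <- mOut[hit[paired]] + m[minus][paired]
    uOut[hit[paired]] <- uOut[hit[paired]] + u[minus][paired]
    keepIdx <- c(plus, minus[!paired], other)
    outScaf <- as.character(seqnames(gr))[keepIdx]
    outPos <- c(start(gr)[plus], start(gr)[minus][!paired] - 1L,
                start(gr)[other])
    outM <- c(mOut, m[minus][!paired], m[other])
    outU <- c(uOut, u[minus][!paired], u[other])
    key <- paste0(outScaf, ":", outPos)
    if (anyDuplicated(key)) {
        outM <- as.integer(rowsum(outM, key)[unique(key), ])
        outU <- as.integer(rowsum(outU, key)[unique(key), ])
        first <- !duplicated(key)
        outScaf <- outScaf[first]; outPos <- outPos[first]
    }
    Methylome(outScaf, outPos, outM, outU, strand = "*",
              sampleId = x@sampleId, sex = x@sex, tissue = x@tissue,
              totalMappedReads = x@totalMappedReads,
              perScaffoldMappedReads = x@perScaffoldMappedReads,
              seqinfo = seqinfo(gr))
}

#' Pool several samples into one methylome by summing read counts
#'
#' Combines samples (e.g. the female and male of one tissue, for
#' tissue-versus-tissue comparisons) by summing methylated and
#' unmethylated counts per CpG over the union of called positions.
#'
#' @param samples list of strand-merged \code{\link{Methylome}}s.
#' @param sampleId,tissue metadata for the pooled result.
#' @return A \code{Methylome} with sex \code{"female"} by convention
#'   (pooled samples have no single sex).
#' @export
poolMethylomes <- function(samples, sampleId = "pooled",
                           tissue = sampleTissue(samples[[1]])) {
    stopifnot(length(samples) >= 1L)
    dt <- data.table::rbindlist(lapply(samples, function(s) {
        gr <- methCalls(s)
        data.table::data.table(scaffold = as.character(seqnames(gr)),
                               pos = start(gr), m = mcols(gr)$m,
                               u = mcols(gr)$u)
    }))
    agg <- dt[, list(m = sum(m), u = sum(u)), by = c("scaffold", "pos")]
    Methylome(agg$scaffold, agg$pos, agg$m, agg$u,
              sampleId = sampleId, sex = "female", tissue = tissue)
}

#' Drop CpG calls below a minimum read coverage
#'
#' Retains only calls with \eqn{m + u \ge} \code{minReads}; with the
#' conventional threshold of three reads this removes the poorly covered
#' CpGs whose fractional methylation is essentially noise. Order is
#' preserved and the filter is idempotent. Whether to merge strands before
#' filtering is the caller's choice; the pipeline merges first, then
#' filters, so that a dyad's two low-covered strands can jointly rescue it.
#'
#' @param x a \code{Methylome}.
#' @param minReads minimum total reads per call (default 3).
#' @return The filtered \code{Methylome}.
#' @export
filterMinCoverage <- function(x, minReads = 3L) {
    if (minReads < 1) stop("minReads must be >= 1")
    gr <- methCalls(x)
    keep <- (mcols(gr)$m + mcols(gr)$u) >= minReads
    initialize(x, calls = gr[keep])
}

#' Drop calls on scaffolds shorter than a minimum length
#'
#' Removes all calls on scaffolds below \code{minLen} (conventionally 2 Mb)
#' from every sample, restricting analyses to scaffolds long enough for
#' regional statistics.
#'
#' @param samples a \code{Methylome} or list of them.
#' @param genome scaffold lengths: a named numeric vector, a
#'   \code{Seqinfo}, or a \code{DNAStringSet}.
#' @param minLen minimum scaffold length in bp (default 2e6).
#' @return Object of the same shape as \code{samples}.
#' @export
filterMinScaffoldLength <- function(samples, genome, minLen = 2e6) {
    lens <- scaffoldLengths(genome)
    one <- function(x) {
        gr <- methCalls(x)
        scafs <- as.character(seqnames(gr))
        unknown <- setdiff(unique(scafs), names(lens))
        if (length(unknown))
            stop("scaffold(s) absent from genome: ",
                 paste(unknown, collapse = ", "))
        initialize(x, calls = gr[lens[scafs] >= minLen])
    }
    if (is(samples, "Methylome")) one(samples) else lapply(samples, one)
}

#' Scaffold lengths from a genome-like object
#'
#' @param genome named numeric vector, \code{Seqinfo} or \code{DNAStringSet}.
#' @return Named numeric vector of lengths.
#' @export
scaffoldLengths <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        setNames(Biostrings::width(genome), names(genome))
    } else if (is(genome, "Seqinfo")) {
        setNames(as.numeric(seqlengths(genome)), seqlevels(genome))
    } else if (is.numeric(genome) && !is.null(names(genome))) {
        genome
    } else stop("cannot derive scaffold lengths from ", class(genome)[1L])
}

#' Read a sample sheet and its cytosine reports
#'
#' The sheet is a TSV with columns \code{sample_id}, \code{sex},
#' \code{tissue}, \code{path} and optionally \code{total_mapped_reads};
#' report paths are resolved relative to the sheet.
#'
#' @param path sample sheet TSV.
#' @return Named list of strand-resolved \code{\link{Methylome}} objects.
#' @export
readSampleSheet <- function(path) {
    sheet <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    need <- c("sample_id", "sex", "tissue", "path")
    if (!all(need %in% names(sheet)))
        stop("sample sheet needs columns: ", paste(need, collapse = ", "))
    out <- lapply(seq_len(nrow(sheet)), function(i) {
        p <- sheet$path[i]
        if (!file.exists(p)) p <- file.path(dirname(path), sheet$path[i])
        readCpGReport(p, sampleId = sheet$sample_id[i], sex = sheet$sex[i],
                      tissue = sheet$tissue[i],
                      totalMappedReads =
                          if ("total_mapped_reads" %in% names(sheet))
                              sheet$total_mapped_reads[i] else NA_real_)
    })
    names(out) <- sheet$sample_id
    out
}
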