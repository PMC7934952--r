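# shared fixtures and independent oracles

library(GenomicRanges)
library(IRanges)
library(S4Vectors)

# quick strand-merged methylome from parallel vectors
mkMeth <- function(scaffold, pos, m, u, sex = "female", tissue = "t",
                   id = "s", ...) {
    Methylome(scaffold, pos, m, u, sampleId = id, sex = sex,
              tissue = tissue, ...)
}

# methylome whose calls realise exact fractional levels f at coverage cov
mkMethF <- function(scaffold, pos, f, cov = 10L, ...) {
    m <- round(f * cov)
    mkMeth(scaffold, pos, m, cov - m, ...)
}

# write a Bismark-style cytosine report; rows = list of character vectors
writeReport <- function(rows, gz = FALSE) {
    path <- tempfile(fileext = if (gz) ".txt.gz" else ".txt")
    con <- if (gz) gzfile(path, "wt") else file(path, "wt")
    writeLines(vapply(rows, paste, "", collapse = "\t"), con)
    close(con)
    path
}

# SmoothedTrack directly from vectors (raw == smooth unless given)
mkTrack <- function(pos, rawF, cov = rep(10, length(pos)),
                    smoothF = rawF, scaffold = "s") {
    new("SmoothedTrack", scaffold = scaffold, pos = as.integer(pos),
        rawF = rawF, smoothF = smoothF, cov = as.numeric(cov))
}

# independent reimplementation of the DMR region rule with simple loops
bruteDmrScan <- function(pos, rawA, rawB, covA, covB, minDiff = 0.3,
                         minCpgs = 5L, qualifyDiff = minDiff / 2,
                         maxGapCpgs = 2L, maxGapBp = 300L, minZ = 3) {
    d <- rawA - rawB
    n <- length(d)
    memb <- integer(n) # candidate sign per CpG
    for (i in seq_len(n))
        if (abs(d[i]) >= qualifyDiff - 1e-12 && d[i] != 0)
            memb[i] <- sign(d[i])
    regions <- list()
    i <- 1L
    while (i <= n) {
        if (memb[i] == 0) { i <- i + 1L; next }
        s <- memb[i]; start <- i; end <- i
        j <- i + 1L
        gap <- 0L
        while (j <= n) {
            if (memb[j] == s) { end <- j; gap <- 0L }
            else if (memb[j] == -s) break
            else { gap <- gap + 1L; if (gap > maxGapCpgs) break }
            j <- j + 1L
        }
        regions[[length(regions) + 1L]] <- c(start, end, s)
        i <- end + 1L
        while (i <= n && memb[i] != -s && memb[i] != s) i <- i + 1L
    }
    out <- list()
    for (r in regions) {
        pieces <- list(c(r[1], r[2]))
        # split at big gaps
        k <- 1L
        while (k <= length(pieces)) {
            p <- pieces[[k]]
            idx <- p[1]:p[2]
            gaps <- which(diff(pos[idx]) > maxGapBp)
            if (length(gaps)) {
                pieces[[k]] <- c(idx[1], idx[gaps[1]])
                pieces[[length(pieces) + 1L]] <- c(idx[gaps[1] + 1],
                                                   idx[length(idx)])
            }
            k <- k + 1L
        }
        for (p in pieces) {
            a <- p[1]; b <- p[2]
            while (a <= b && r[3] * d[a] < minDiff - 1e-12) a <- a + 1L
            while (b >= a && r[3] * d[b] < minDiff - 1e-12) b <- b - 1L
            if (a > b) next
            md <- mean(d[a:b])
            pbar <- pmin(0.95, pmax(0.05, (rawA[a:b] + rawB[a:b]) / 2))
            vv <- pbar * (1 - pbar) *
                (1 / pmax(covA[a:b], 1) + 1 / pmax(covB[a:b], 1))
            z <- abs(md) / (sqrt(sum(vv)) / (b - a + 1))
            if ((b - a + 1) >= minCpgs && abs(md) >= minDiff - 1e-12 &&
                sign(md) == r[3] && z >= minZ)
                out[[length(out) + 1L]] <-
                    c(pos[a], pos[b] + 1L, b - a + 1L, md)
        }
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
}

# exact two-sided Mann-Whitney p by enumerating all group-A rank subsets
enumMannWhitneyP <- function(a, b) {
    na <- length(a); nb <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    combs <- utils::combn(na + nb, na)
    us <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    mu <- na * nb / 2
    mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

# exact two-sided Spearman p by full permutation enumeration
enumSpearmanP <- function(x, y) {
    n <- length(x)
    rhoObs <- stats::cor(rank(x), rank(y))
    perms <- gtoolsPerms(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rank(x), rank(y)[p]))
    mean(abs(rhos) >= abs(rhoObs) - 1e-9)
}

# all permutations of 1..n (n small)
gtoolsPerms <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- gtoolsPerms(n - 1L)
    out <- matrix(0L, 0, n)
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
    }
    unname(out)
}

# base-level Jaccard of two GRanges sets
jaccardBp <- function(a, b) {
    a <- reduce(a, ignore.strand = TRUE); b <- reduce(b, ignore.strand = TRUE)
    i <- sum(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
    u <- sum(width(GenomicRanges::union(a, b, ignore.strand = TRUE)))
    if (u == 0) return(1)
    i / u
}

# small deterministic random DNA
randomSeq <- function(n, gc = 0.4) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}
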