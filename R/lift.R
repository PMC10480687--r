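## The lift engine: liftIn (genomic intervals -> consensus segments,
## multi-mapper-safe) and liftOut (consensus locus -> per-instance genomic
## sequences).

#' Lift genomic intervals onto repeat consensus coordinates
#'
#' Piecewise-exact mapping: each interval is intersected with the blocks of
#' every overlapping chain; each intersected piece maps linearly onto the
#' consensus (through the reverse-complement frame for minus-strand chains),
#' abutting pieces from the same chain are merged, and bases falling into
#' target-only gaps (\code{dt}) map nowhere. An interval overlapping no chain
#' contributes nothing.
#'
#' @param chains A \linkS4class{ChainSet} (genome -> consensus).
#' @param gr GRanges of genomic intervals; an mcols column \code{name} (or
#'   the names of \code{gr}) is carried through as the read id.
#' @return GRanges on consensus coordinates: seqnames = consensus id, ranges
#'   1-based inclusive on the forward consensus strand, with metadata
#'   columns \code{name} (read id or NA), \code{readStrand} (strand of the
#'   input interval), \code{alnStrand} (strand of the chain used),
#'   \code{oChrom}, \code{oStart}, \code{oEnd} (genomic origin) and
#'   \code{chainId}.
#' @export
#' @seealso [liftReads()], [liftOut()]
liftIntervals <- function(chains, gr) {
    idx <- .blockIndex(chains)
    empty <- GRanges()
    mcols(empty) <- DataFrame(name = character(), readStrand = character(),
                              alnStrand = character(), oChrom = character(),
                              oStart = integer(), oEnd = integer(),
                              chainId = integer())
    if (!length(gr) || !length(idx)) return(empty)
    nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
          else if (!is.null(names(gr))) names(gr)
          else rep(NA_character_, length(gr))
    # disjoint seqlevels between reads and chains are a valid no-overlap case
    hits <- suppressWarnings(findOverlaps(gr, idx, ignore.strand = TRUE))
    if (!length(hits)) return(empty)
    qh <- queryHits(hits)
    sh <- subjectHits(hits)
    s <- pmax(start(gr)[qh], start(idx)[sh])
    e <- pmin(end(gr)[qh], end(idx)[sh])
    off <- s - start(idx)[sh]                  # 0-based offset into block
    qps <- mcols(idx)$qp[sh] + off             # 0-based q' piece start
    qpe <- qps + (e - s)                       # 0-based q' piece end (incl.)
    ch <- mcols(idx)$chain[sh]
    o <- order(qh, ch, qps)
    qh <- qh[o]; sh <- sh[o]; s <- s[o]; e <- e[o]
    qps <- qps[o]; qpe <- qpe[o]; ch <- ch[o]
    n <- length(qh)
    newGrp <- c(TRUE, qh[-1L] != qh[-n] | ch[-1L] != ch[-n] |
                      qps[-1L] != qpe[-n] + 1L)
    first <- which(newGrp)
    last <- c(first[-1L] - 1L, n)
    qh <- qh[first]; sh <- sh[first]; ch <- ch[first]
    gs <- qps[first]                           # merged q' interval
    ge <- qpe[last]
    oStart <- s[first]
    oEnd <- e[last]
    minus <- mcols(idx)$qStrand[sh] == "-"
    qSize <- mcols(idx)$qSize[sh]
    fs <- ifelse(minus, qSize - ge, gs + 1L)   # 1-based forward consensus
    fe <- ifelse(minus, qSize - gs, ge + 1L)
    out <- GRanges(seqnames = mcols(idx)$qName[sh], ranges = IRanges(fs, fe))
    mcols(out) <- DataFrame(name = nm[qh],
                            readStrand = as.character(strand(gr))[qh],
                            alnStrand = mcols(idx)$qStrand[sh],
                            oChrom = as.character(seqnames(gr))[qh],
                            oStart = oStart, oEnd = oEnd,
                            chainId = mcols(idx)$chainId[sh])
    out
}

#' Lift one genomic interval
#'
#' Convenience wrapper around [liftIntervals()] for a single interval.
#'
#' @param chains A \linkS4class{ChainSet}.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive genomic coordinates.
#' @return GRanges of lifted segments (possibly empty); see
#'   [liftIntervals()].
#' @export
liftInterval <- function(chains, chrom, start, end) {
    liftIntervals(chains, GRanges(chrom, IRanges(start, end)))
}

#' Lift reads onto consensus coordinates, deduplicating multi-mappers
#'
#' Applies [liftIntervals()] to every read. With \code{dedup = TRUE}
#' (default), among all lifted segments sharing a (read id, consensus) pair
#' only the segments from one chain are kept, so each read contributes at
#' most once per consensus regardless of how many genomic copies it aligned
#' to. The winning chain is the one whose lifted segment starts at the
#' smallest forward consensus position, ties broken by genomic chromosome
#' then genomic start — a deterministic, input-order-free rule. A read
#' overlapping two different consensus names still contributes once to each.
#'
#' @param reads GRanges of reads (e.g. \code{rtracklayer::import} of a BED6
#'   file); the \code{name} column is the read id.
#' @param chains A \linkS4class{ChainSet}.
#' @param dedup logical; collapse multi-mapped copies per consensus.
#' @return GRanges of lifted segments as in [liftIntervals()].
#' @export
liftReads <- function(reads, chains, dedup = TRUE) {
    segs <- liftIntervals(chains, reads)
    if (!dedup || !length(segs)) return(segs)
    nm <- mcols(segs)$name
    if (anyNA(nm))
        stop("reads must carry a name to deduplicate; name the reads or use dedup = FALSE")
    o <- order(nm, as.factor(seqnames(segs)), start(segs),
               mcols(segs)$oChrom, mcols(segs)$oStart, mcols(segs)$chainId)
    segs <- segs[o]
    key <- paste(mcols(segs)$name, as.character(seqnames(segs)), sep = "\r")
    winner <- !duplicated(key)                # best chain per (read, consensus)
    winKey <- paste(key, mcols(segs)$chainId, sep = "\r")[winner]
    keep <- paste(key, mcols(segs)$chainId, sep = "\r") %in% winKey
    segs[keep]
}

## Map a consensus locus through one alignment record.
## Returns NULL when the record does not fully cover the locus; otherwise a
## list with the genomic interval (forward strand, 1-based inclusive)
## spanned by the mapped bases, whether the locus region contains indels,
## the site characters (consensus orientation; "-" at deleted positions,
## genomic insertions dropped) and the consensus characters of the locus.
.mapLocus <- function(ag, ac, gStart, gEnd, strand, cStart, cEnd, lstart, lend) {
    if (cStart > lstart || cEnd < lend) return(NULL)
    g <- .gapMask(ag)
    q <- .gapMask(ac)
    cpos <- cumsum(q)                       # consensus offset per column
    o1 <- lstart - cStart + 1L
    o2 <- lend - cStart + 1L
    colsel <- which(q & cpos >= o1 & cpos <= o2)
    region <- colsel[1L]:colsel[length(colsel)]
    hasIndel <- any(!g[region]) || any(!q[region])
    gidx <- cumsum(g)
    mapped <- gidx[region][g[region]]       # stored-frame genome indices
    i1 <- mapped[1L]
    i2 <- mapped[length(mapped)]
    if (strand == "-") {
        gs <- gEnd - i2 + 1L
        ge <- gEnd - i1 + 1L
    } else {
        gs <- gStart + i1 - 1L
        ge <- gStart + i2 - 1L
    }
    agc <- strsplit(ag, "")[[1]]
    acc <- strsplit(ac, "")[[1]]
    list(gs = gs, ge = ge, hasIndel = hasIndel,
         siteChars = agc[colsel],           # one char per consensus position
         consChars = acc[colsel])
}

#' Extract the genomic sequences underlying a consensus locus (liftOut)
#'
#' For every repeat instance whose alignment fully covers
#' \code{[start, end]} on the consensus, maps each consensus position to its
#' genomic position and returns the underlying genomic sequence in consensus
#' orientation (reverse-complemented for minus-strand instances). Instances
#' only partially covering the locus are skipped and counted. Instances with
#' an indel inside the locus are skipped and counted unless
#' \code{allowIndel = TRUE}, in which case deleted consensus positions are
#' reported as \code{-} and genomic insertions are dropped, keeping every
#' returned sequence at the locus length (the default keeps site sets
#' ungapped so PFM/PEM arithmetic applies).
#'
#' @param x A \linkS4class{RepeatAlignments} object.
#' @param repeatId consensus name of the locus.
#' @param start,end 1-based inclusive locus on the forward consensus.
#' @param genome named DNAStringSet with the genomic sequence (used to fetch
#'   indel-free sites, so returned sequences are guaranteed to equal the
#'   genome).
#' @param allowIndel admit instances with indels inside the locus.
#' @return A \linkS4class{SiteSet}.
#' @export
#' @seealso [buildPFM()], [scoreSites()], [writeSiteSet()]
liftOut <- function(x, repeatId, start, end, genome, allowIndel = FALSE) {
    mc <- mcols(x)
    sel <- which(mc$repeatId == repeatId)
    if (!length(sel))
        stop("no alignment records for repeat: ", repeatId)
    if (start < 1L || start > end)
        stop("need 1 <= start <= end")
    L <- end - start + 1L
    str <- as.character(strand(x))
    entries <- list()
    consChars <- NULL
    nPartial <- 0L
    nIndel <- 0L
    for (k in sel) {
        m <- .mapLocus(mc$alignedGenome[k], mc$alignedConsensus[k],
                       GenomicRanges::start(x)[k], GenomicRanges::end(x)[k],
                       str[k], mc$cStart[k], mc$cEnd[k], start, end)
        if (is.null(m)) { nPartial <- nPartial + 1L; next }
        if (is.null(consChars)) consChars <- m$consChars
        if (m$hasIndel && !allowIndel) { nIndel <- nIndel + 1L; next }
        seq <- if (m$hasIndel) paste(m$siteChars, collapse = "")
               else genomeSlice(genome, as.character(seqnames(x))[k],
                                m$gs, m$ge, str[k])
        entries[[length(entries) + 1L]] <-
            list(recordId = mc$recordId[k],
                 chrom = as.character(seqnames(x))[k],
                 gStart = m$gs, gEnd = m$ge, strand = str[k],
                 seq = seq,
                 nMismatch = sum(strsplit(seq, "")[[1]] != m$consChars),
                 hasIndel = m$hasIndel)
    }
    if (is.null(consChars))
        consChars <- rep("N", L)   # no instance covers the locus at all
    if (length(entries)) {
        g <- function(f, proto) vapply(entries, `[[`, proto, f)
        sites <- DNAStringSet(g("seq", ""))
        names(sites) <- g("recordId", "")
        info <- DataFrame(recordId = g("recordId", ""),
                          chrom = g("chrom", ""),
                          gStart = g("gStart", 1L), gEnd = g("gEnd", 1L),
                          strand = g("strand", ""),
                          nMismatch = g("nMismatch", 1L),
                          hasIndel = g("hasIndel", TRUE))
    } else {
        sites <- DNAStringSet()
        info <- DataFrame(recordId = character(), chrom = character(),
                          gStart = integer(), gEnd = integer(),
                          strand = character(), nMismatch = integer(),
                          hasIndel = logical())
    }
    new("SiteSet", repeatId = repeatId, lstart = as.integer(start),
        lend = as.integer(end), sites = sites, info = info,
        consensusSeq = paste(consChars, collapse = ""),
        skipped = c(partial = nPartial, indel = nIndel))
}

## Genomic projections of a consensus locus across all covering instances;
## used by the read simulator and by liftOut round-trip checks.
.locusProjections <- function(x, repeatId, start, end) {
    mc <- mcols(x)
    sel <- which(mc$repeatId == repeatId)
    str <- as.character(strand(x))
    rows <- list()
    for (k in sel) {
        m <- .mapLocus(mc$alignedGenome[k], mc$alignedConsensus[k],
                       GenomicRanges::start(x)[k], GenomicRanges::end(x)[k],
                       str[k], mc$cStart[k], mc$cEnd[k], start, end)
        if (is.null(m)) next
        rows[[length(rows) + 1L]] <-
            list(chrom = as.character(seqnames(x))[k], gs = m$gs, ge = m$ge,
                 strand = str[k], recordId = mc$recordId[k],
                 hasIndel = m$hasIndel)
    }
    if (!length(rows)) return(GRanges())
    g <- function(f, proto) vapply(rows, `[[`, proto, f)
    gr <- GRanges(g("chrom", ""), IRanges(g("gs", 1L), g("ge", 1L)),
                  strand = g("strand", ""))
    mcols(gr) <- DataFrame(recordId = g("recordId", ""),
                           hasIndel = g("hasIndel", TRUE))
    gr
}

#' Write a SiteSet as FASTA (and optionally TSV)
#'
#' FASTA headers follow \code{recordId|chrom:start-end|strand|nm=K}.
#'
#' @param x A \linkS4class{SiteSet}.
#' @param file FASTA output path.
#' @param tsv optional TSV output path for the provenance table.
#' @return Invisibly, \code{x}.
#' @export
writeSiteSet <- function(x, file, tsv = NULL) {
    sites <- x@sites
    info <- x@info
    names(sites) <- sprintf("%s|%s:%d-%d|%s|nm=%d", info$recordId,
                            info$chrom, info$gStart, info$gEnd,
                            info$strand, info$nMismatch)
    writeXStringSet(sites, file)
    if (!is.null(tsv))
        write.table(as.data.frame(info), tsv, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    invisible(x)
}
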