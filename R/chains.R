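## Compile RepeatMasker pairwise alignments into UCSC chain coordinate maps
## (target = genome, forward strand; query = repeat consensus) and serialize
## them bit-exactly in the UCSC chain format, consumable by the external
## liftOver tool.

.revString <- function(s) {
    vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
           USE.NAMES = FALSE)
}

#' Convert one gapped alignment to chain blocks
#'
#' Scans aligned columns left to right: columns with a base in both
#' sequences (matches and substitutions alike) extend the current block; a
#' gap in the consensus consumes target-only bases (\code{dt}); a gap in the
#' genome consumes query-only bases (\code{dq}). Substitutions therefore stay
#' inside blocks and only indels break them, matching liftOver semantics.
#' Adjacent blocks are merged canonically, so the block list (and hence the
#' serialized chain) is unique for a given alignment.
#'
#' @param alignedGenome,alignedConsensus equal-length gapped strings over
#'   \code{A,C,G,T,N,-}. The alignment must begin and end on aligned (non-gap)
#'   columns, as RepeatMasker alignments do.
#' @return Integer matrix with columns \code{size}, \code{dt}, \code{dq};
#'   the final row has \code{dt = dq = 0}.
#' @export
#' @examples
#' alignmentToBlocks("ACGTACGTAC", "ACGT-CGTAC")  # one inserted genomic base
alignmentToBlocks <- function(alignedGenome, alignedConsensus) {
    if (nchar(alignedGenome) != nchar(alignedConsensus))
        stop("aligned strings differ in length")
    g <- .gapMask(alignedGenome)
    q <- .gapMask(alignedConsensus)
    if (any(!g & !q))
        stop("column gapped in both sequences")
    m <- g & q
    r <- rle(m)
    nr <- length(r$values)
    if (!r$values[1L] || !r$values[nr])
        stop("alignment must begin and end on aligned columns")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nb <- sum(r$values)
    size <- r$lengths[r$values]
    dt <- integer(nb)
    dq <- integer(nb)
    # runs alternate match/gap starting with match: gap run 2j follows block j
    for (j in seq_len(nb - 1L)) {
        cols <- starts[2L * j]:ends[2L * j]
        dt[j] <- sum(g[cols])
        dq[j] <- sum(q[cols])
    }
    cbind(size = size, dt = dt, dq = dq)
}

#' Build genome-to-consensus chains from RepeatMasker alignments
#'
#' One chain per alignment record, mapping the genomic span (target, forward
#' strand) onto the repeat consensus (query). Minus-strand instances produce
#' chains with \code{qStrand = "-"} whose query coordinates are expressed in
#' the reversed-strand frame, per the UCSC chain convention. Chain scores are
#' the Smith-Waterman scores; chain ids are sequential in input order, so
#' identical inputs always serialize byte-identically. Fragmented instances
#' (one element split over several records) are deliberately not stitched;
#' the \code{recordId} keeps the correspondence.
#'
#' @param x A \linkS4class{RepeatAlignments} object.
#' @param consensusSizes named integer vector of consensus lengths (e.g.
#'   \code{setNames(width(fa), names(fa))} for a consensus FASTA).
#' @param chromSizes named integer vector of chromosome lengths.
#' @return A \linkS4class{ChainSet}.
#' @export
#' @seealso [writeChainFile()], [liftIntervals()]
buildChains <- function(x, consensusSizes, chromSizes) {
    validObject(x)
    mc <- mcols(x)
    missQ <- setdiff(unique(mc$repeatId), names(consensusSizes))
    if (length(missQ))
        stop("no consensus size for: ", paste(missQ, collapse = ", "))
    missT <- setdiff(unique(as.character(seqnames(x))), names(chromSizes))
    if (length(missT))
        stop("no chromosome size for: ", paste(missT, collapse = ", "))
    n <- length(x)
    blocks <- vector("list", n)
    qStart <- qEnd <- integer(n)
    qStrand <- character(n)
    qSize <- as.integer(consensusSizes[mc$repeatId])
    tSize <- as.integer(chromSizes[as.character(seqnames(x))])
    bad <- mc$cEnd > qSize
    if (any(bad))
        stop("consensus coordinates exceed consensus length (stale consensus FASTA?) for: ",
             paste(mc$recordId[bad], collapse = ", "))
    str <- as.character(strand(x))
    for (k in seq_len(n)) {
        if (str[k] == "-") {
            # chain blocks walk the target forward; reversing the aligned
            # columns turns the stored (revcomp-genome vs forward-consensus)
            # alignment into (forward-genome vs reversed-frame consensus)
            blocks[[k]] <- alignmentToBlocks(.revString(mc$alignedGenome[k]),
                                             .revString(mc$alignedConsensus[k]))
            qStrand[k] <- "-"
            qStart[k] <- qSize[k] - mc$cEnd[k]
            qEnd[k] <- qSize[k] - mc$cStart[k] + 1L
        } else {
            blocks[[k]] <- alignmentToBlocks(mc$alignedGenome[k],
                                             mc$alignedConsensus[k])
            qStrand[k] <- "+"
            qStart[k] <- mc$cStart[k] - 1L
            qEnd[k] <- mc$cEnd[k]
        }
    }
    header <- DataFrame(score = mc$swScore,
                        tName = as.character(seqnames(x)),
                        tSize = tSize,
                        tStart = start(x) - 1L,
                        tEnd = end(x),
                        qName = mc$repeatId,
                        qSize = qSize,
                        qStrand = qStrand,
                        qStart = qStart,
                        qEnd = qEnd,
                        chainId = seq_len(n))
    new("ChainSet", header = header, blocks = blocks)
}

#' Serialize chains in UCSC chain format
#'
#' Writes the standard format consumed by the UCSC liftOver tool: a header
#' line \code{chain score tName tSize tStrand tStart tEnd qName qSize
#' qStrand qStart qEnd id}, one \code{size dt dq} line per block with the
#' final line carrying \code{size} only, and a blank line between chains.
#' Serialization is canonical: the same ChainSet always yields byte-identical
#' output.
#'
#' @param x A \linkS4class{ChainSet}.
#' @param file output path or connection; if NULL the text is returned.
#' @return Invisibly (or visibly for \code{file = NULL}), the chain text as
#'   a character vector of lines.
#' @export
writeChainFile <- function(x, file = NULL) {
    validObject(x)
    h <- x@header
    out <- vector("list", length(x))
    for (k in seq_len(nrow(h))) {
        b <- x@blocks[[k]]
        n <- nrow(b)
        hdr <- sprintf("chain %d %s %d + %d %d %s %d %s %d %d %d",
                       h$score[k], h$tName[k], h$tSize[k], h$tStart[k],
                       h$tEnd[k], h$qName[k], h$qSize[k], h$qStrand[k],
                       h$qStart[k], h$qEnd[k], h$chainId[k])
        lines <- if (n > 1L)
            c(sprintf("%d %d %d", b[-n, "size"], b[-n, "dt"], b[-n, "dq"]),
              sprintf("%d", b[n, "size"]))
        else sprintf("%d", b[n, "size"])
        out[[k]] <- c(hdr, lines, "")
    }
    txt <- unlist(out)
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

#' Parse a UCSC chain file
#'
#' Inverse of [writeChainFile()]. Span equations (sum of block sizes plus
#' gaps against the header spans) are verified for every chain; a violation
#' raises an error naming the chain id.
#'
#' @param file path, connection, or character vector of chain-format lines.
#' @return A \linkS4class{ChainSet}.
#' @export
readChainFile <- function(file) {
    lines <- if (is.character(file) && length(file) > 1L) file
             else readLines(file)
    hdrIdx <- grep("^chain\\b", lines)
    if (!length(hdrIdx))
        stop("no chain records found")
    n <- length(hdrIdx)
    rows <- vector("list", n)
    blocks <- vector("list", n)
    bounds <- c(hdrIdx, length(lines) + 1L)
    for (k in seq_len(n)) {
        tok <- strsplit(trimws(lines[hdrIdx[k]]), "\\s+")[[1]]
        if (length(tok) != 13L)
            stop(sprintf("chain header at line %d: expected 13 fields, got %d",
                         hdrIdx[k], length(tok)))
        if (tok[5] != "+")
            stop(sprintf("chain at line %d: target strand must be +", hdrIdx[k]))
        num <- suppressWarnings(as.integer(tok[c(2, 4, 6, 7, 9, 11, 12, 13)]))
        if (anyNA(num))
            stop(sprintf("chain header at line %d: non-integer field", hdrIdx[k]))
        rows[[k]] <- DataFrame(score = num[1], tName = tok[3], tSize = num[2],
                               tStart = num[3], tEnd = num[4], qName = tok[8],
                               qSize = num[5], qStrand = tok[10],
                               qStart = num[6], qEnd = num[7], chainId = num[8])
        body <- lines[(hdrIdx[k] + 1L):(bounds[k + 1L] - 1L)]
        body <- body[nzchar(trimws(body))]
        if (!length(body))
            stop(sprintf("chain %d: no block lines", num[8]))
        parts <- strsplit(trimws(body), "\\s+")
        nf <- lengths(parts)
        if (any(nf[-length(nf)] != 3L) || nf[length(nf)] != 1L)
            stop(sprintf("chain %d: malformed block lines", num[8]))
        m <- matrix(0L, nrow = length(parts), ncol = 3L,
                    dimnames = list(NULL, c("size", "dt", "dq")))
        for (j in seq_along(parts)) {
            v <- suppressWarnings(as.integer(parts[[j]]))
            if (anyNA(v)) stop(sprintf("chain %d: non-integer block field", num[8]))
            m[j, seq_along(v)] <- v
        }
        if (sum(m[, "size"]) + sum(m[, "dt"]) != num[4] - num[3] ||
            sum(m[, "size"]) + sum(m[, "dq"]) != num[7] - num[6])
            stop(sprintf("chain %d: span equations violated", num[8]))
        blocks[[k]] <- m
    }
    new("ChainSet", header = do.call(rbind, rows), blocks = blocks)
}

## Per-block interval index used by the lift engine: one GRanges row per
## chain block on the genome (target), annotated with the 0-based query
## offset of the block start in the qStrand frame.
.blockIndex <- function(chains) {
    h <- chains@header
    per <- lapply(seq_len(nrow(h)), function(k) {
        b <- chains@blocks[[k]]
        tOff <- cumsum(c(0L, (b[, "size"] + b[, "dt"])[-nrow(b)]))
        qOff <- cumsum(c(0L, (b[, "size"] + b[, "dq"])[-nrow(b)]))
        list(start = h$tStart[k] + tOff + 1L,
             end = h$tStart[k] + tOff + b[, "size"],
             qp = h$qStart[k] + qOff,
             chain = rep(k, nrow(b)))
    })
    idx <- GRanges(seqnames = rep(h$tName, vapply(per, function(p) length(p$start), 1L)),
                   ranges = IRanges(start = unlist(lapply(per, `[[`, "start")),
                                    end = unlist(lapply(per, `[[`, "end"))))
    k <- unlist(lapply(per, `[[`, "chain"))
    mcols(idx) <- DataFrame(chain = k,
                            qp = unlist(lapply(per, `[[`, "qp")),
                            qName = h$qName[k],
                            qStrand = h$qStrand[k],
                            qSize = h$qSize[k],
                            chainId = h$chainId[k])
    idx
}
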