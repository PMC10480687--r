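## RepeatMasker .align / .out I/O.
##
## The .align dialect read and written here (documented in the README):
## per record one header line
##   score div del ins chrom gBeg gEnd (gLeft) [C] name#class/family <cfields> id
## where <cfields> is "cBeg cEnd (cLeft)" for plus-strand records and
## "(cLeft) cEnd cBeg" for complement ("C") records, all coordinates 1-based
## inclusive; followed by interleaved aligned-line pairs
##   name beg SEQ end         (genome line, then consensus line)
## wrapped at 50 columns. For C records the genome line carries the reverse
## complement of the forward genomic sequence with descending coordinates;
## the consensus line is always the forward consensus, ascending. Lines
## starting with Matrix/Transitions/Gap_init/Kimura and blank lines are
## skipped; other unrecognized lines are skipped with a warning.

.ALIGN_HEADER_RE <- "^[0-9]+\\s+[0-9.]+\\s+[0-9.]+\\s+[0-9.]+\\s+\\S+\\s+[0-9]+\\s+[0-9]+\\s+\\([0-9]+\\)\\s"
.ALIGN_BODY_RE <- "^\\s*\\S+\\s+[0-9]+\\s+[ACGTNacgtn-]+\\s+[0-9]+\\s*$"
.ALIGN_BODY_SEQ_RE <- "^\\s*\\S+\\s+[0-9]+\\s+([ACGTNacgtn-]+)\\s+[0-9]+\\s*$"
.ALIGN_SKIP_RE <- "^(Matrix|Transitions|Gap_init|Kimura)"

.splitRepeatName <- function(x) {
    hash <- regexpr("#", x, fixed = TRUE)
    id <- ifelse(hash > 0L, substr(x, 1L, hash - 1L), x)
    cls <- ifelse(hash > 0L, substring(x, hash + 1L), "Unknown")
    list(id = id, class = cls)
}

.parseAlignHeader <- function(line, lineno) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    bad <- function(why)
        stop(sprintf("line %d: malformed .align header (%s): %s",
                     lineno, why, line), call. = FALSE)
    if (length(tok) < 12L) bad("too few fields")
    score <- suppressWarnings(as.integer(tok[1]))
    div <- suppressWarnings(as.numeric(tok[2]))
    gBeg <- suppressWarnings(as.integer(tok[6]))
    gEnd <- suppressWarnings(as.integer(tok[7]))
    if (anyNA(c(score, div, gBeg, gEnd))) bad("non-numeric coordinate field")
    isC <- tok[9] == "C"
    if (isC) {
        if (length(tok) < 14L) bad("too few fields for C record")
        nm <- .splitRepeatName(tok[10])
        cEnd <- suppressWarnings(as.integer(tok[12]))
        cBeg <- suppressWarnings(as.integer(tok[13]))
        id <- tok[14]
    } else {
        nm <- .splitRepeatName(tok[9])
        cBeg <- suppressWarnings(as.integer(tok[10]))
        cEnd <- suppressWarnings(as.integer(tok[11]))
        id <- tok[13]
    }
    if (anyNA(c(cBeg, cEnd))) bad("non-numeric consensus coordinate")
    if (cBeg > cEnd) bad("consensus begin > end after normalization")
    list(score = score, divergence = div, chrom = tok[5],
         gStart = gBeg, gEnd = gEnd, strand = if (isC) "-" else "+",
         repeatId = nm$id, repeatClass = nm$class,
         cStart = cBeg, cEnd = cEnd, recordId = id)
}

#' Read a RepeatMasker alignment (.align) file
#'
#' Parses per-instance gapped pairwise alignments between genomic repeat
#' copies and their consensus into a \linkS4class{RepeatAlignments} object.
#' Coordinates are normalized to 1-based inclusive with genomic locations on
#' the forward strand; complement ("C") records get strand \code{-} with
#' consensus coordinates on the forward consensus strand and the aligned
#' genomic sequence stored as the strand that aligns to the forward
#' consensus. Soft-masked (lowercase) bases are uppercased.
#'
#' @param file path to a \code{.align} file (or connection).
#' @return A \linkS4class{RepeatAlignments} object.
#' @export
#' @seealso [writeRepeatAlignments()], [buildChains()]
readRepeatAlignments <- function(file) {
    lines <- readLines(file)
    isHeader <- grepl(.ALIGN_HEADER_RE, lines)
    isBody <- !isHeader & grepl(.ALIGN_BODY_RE, lines)
    ignorable <- !isHeader & !isBody &
        (!nzchar(trimws(lines)) | grepl(.ALIGN_SKIP_RE, lines))
    junk <- which(!isHeader & !isBody & !ignorable)
    if (length(junk))
        warning(sprintf("skipped %d unrecognized line(s) (first at line %d): %s",
                        length(junk), junk[1L],
                        substr(lines[junk[1L]], 1, 40)))
    recIdx <- cumsum(isHeader)
    orphan <- isBody & recIdx == 0L
    if (any(orphan)) {
        warning(sprintf("line %d: alignment line before any header; skipped",
                        which(orphan)[1L]))
        isBody[orphan] <- FALSE
    }
    hdrAt <- which(isHeader)
    recs <- lapply(seq_along(hdrAt),
                   function(k) .parseAlignHeader(lines[hdrAt[k]], hdrAt[k]))
    if (length(recs)) {
        seqTok <- sub(.ALIGN_BODY_SEQ_RE, "\\1", lines[isBody])
        bodyRec <- recIdx[isBody]
        # aligned-line pairs alternate genome/consensus within each record
        posInRec <- sequence(rle(bodyRec)$lengths)
        agBy <- vapply(split(seqTok[posInRec %% 2L == 1L],
                             bodyRec[posInRec %% 2L == 1L]),
                       paste, "", collapse = "")
        acBy <- vapply(split(seqTok[posInRec %% 2L == 0L],
                             bodyRec[posInRec %% 2L == 0L]),
                       paste, "", collapse = "")
        for (k in seq_along(recs)) {
            ag <- toupper(if (!is.na(agBy[as.character(k)]))
                agBy[[as.character(k)]] else "")
            ac <- toupper(if (!is.na(acBy[as.character(k)]))
                acBy[[as.character(k)]] else "")
            cur <- recs[[k]]
            if (nchar(ag) != nchar(ac))
                stop(sprintf("record %s: aligned genome/consensus strings differ in length",
                             cur$recordId), call. = FALSE)
            ngG <- nchar(gsub("-", "", ag, fixed = TRUE))
            ngC <- nchar(gsub("-", "", ac, fixed = TRUE))
            if (ngG != cur$gEnd - cur$gStart + 1L)
                stop(sprintf("record %s: %d aligned genome bases but header span %d",
                             cur$recordId, ngG, cur$gEnd - cur$gStart + 1L),
                     call. = FALSE)
            if (ngC != cur$cEnd - cur$cStart + 1L)
                stop(sprintf("record %s: %d aligned consensus bases but header span %d",
                             cur$recordId, ngC, cur$cEnd - cur$cStart + 1L),
                     call. = FALSE)
            if (grepl("[^ACGTN-]", ag) || grepl("[^ACGTN-]", ac))
                stop(sprintf("record %s: ambiguity codes other than N are not supported",
                             cur$recordId), call. = FALSE)
            recs[[k]]$alignedGenome <- ag
            recs[[k]]$alignedConsensus <- ac
        }
    }
    if (!length(recs)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(repeatId = character(), repeatClass = character(),
                               cStart = integer(), cEnd = integer(),
                               swScore = integer(), divergence = numeric(),
                               alignedGenome = character(),
                               alignedConsensus = character(),
                               recordId = character())
        return(new("RepeatAlignments", gr))
    }
    g <- function(f) vapply(recs, `[[`, recs[[1]][[f]], f)
    RepeatAlignments(chrom = g("chrom"), gStart = g("gStart"),
                     gEnd = g("gEnd"), strand = g("strand"),
                     repeatId = g("repeatId"), repeatClass = g("repeatClass"),
                     cStart = g("cStart"), cEnd = g("cEnd"),
                     swScore = g("score"), divergence = g("divergence"),
                     alignedGenome = g("alignedGenome"),
                     alignedConsensus = g("alignedConsensus"),
                     recordId = g("recordId"))
}

.wrapAligned <- function(s, width = 50L) {
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    substring(s, starts, pmin(starts + width - 1L, n))
}

#' Write a RepeatMasker-style alignment (.align) file
#'
#' Serializes a \linkS4class{RepeatAlignments} object in the dialect read by
#' [readRepeatAlignments()]; the round trip reproduces every field exactly.
#'
#' @param x A \linkS4class{RepeatAlignments} object.
#' @param file output path or connection.
#' @return Invisibly, the lines written.
#' @export
writeRepeatAlignments <- function(x, file) {
    validObject(x)
    mc <- mcols(x)
    chroms <- as.character(seqnames(x))
    strands <- as.character(strand(x))
    recs <- vector("list", length(x))
    for (k in seq_along(x)) {
        minus <- strands[k] == "-"
        nm <- paste0(mc$repeatId[k], "#", mc$repeatClass[k])
        hdr <- if (minus)
            sprintf("%d %.1f 0.0 0.0 %s %d %d (0) C %s (0) %d %d %s",
                    mc$swScore[k], mc$divergence[k], chroms[k], start(x)[k],
                    end(x)[k], nm, mc$cEnd[k], mc$cStart[k], mc$recordId[k])
        else
            sprintf("%d %.1f 0.0 0.0 %s %d %d (0) %s %d %d (0) %s",
                    mc$swScore[k], mc$divergence[k], chroms[k], start(x)[k],
                    end(x)[k], nm, mc$cStart[k], mc$cEnd[k], mc$recordId[k])
        gChunks <- .wrapAligned(mc$alignedGenome[k])
        cChunks <- .wrapAligned(mc$alignedConsensus[k])
        ngG <- nchar(gsub("-", "", gChunks, fixed = TRUE))
        ngC <- nchar(gsub("-", "", cChunks, fixed = TRUE))
        # genome-line coordinates: ascending forward for "+", descending
        # (reverse-complement frame) for "-"; consensus always ascending.
        if (minus) {
            gFrom <- end(x)[k] - cumsum(c(0L, ngG[-length(ngG)]))
            gTo <- gFrom - pmax(ngG - 1L, 0L)
        } else {
            gFrom <- start(x)[k] + cumsum(c(0L, ngG[-length(ngG)]))
            gTo <- gFrom + pmax(ngG - 1L, 0L)
        }
        cFrom <- mc$cStart[k] + cumsum(c(0L, ngC[-length(ngC)]))
        cTo <- cFrom + pmax(ngC - 1L, 0L)
        gLines <- sprintf("  %-15s %8d %s %d", chroms[k], gFrom, gChunks, gTo)
        cLines <- sprintf("  %-15s %8d %s %d", mc$repeatId[k], cFrom,
                          cChunks, cTo)
        recs[[k]] <- c(hdr, "", as.vector(rbind(gLines, cLines)), "")
    }
    out <- unlist(recs)
    writeLines(out, file)
    invisible(out)
}

#' Read a RepeatMasker annotation (.out) file
#'
#' @param file path to a standard RepeatMasker \code{.out} file (3 header
#'   lines, whitespace-separated columns).
#' @return A GRanges of repeat instances (forward genomic coordinates,
#'   strand \code{-} for complement records) with metadata columns
#'   \code{swScore}, \code{divergence}, \code{repeatId}, \code{repeatClass},
#'   \code{cStart}, \code{cEnd} (1-based inclusive, forward consensus) and
#'   \code{recordId}.
#' @export
#' @seealso [annotatePeaks()]
readRepeatOut <- function(file) {
    lines <- readLines(file)
    if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character()
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(swScore = integer(), divergence = numeric(),
                               repeatId = character(), repeatClass = character(),
                               cStart = integer(), cEnd = integer(),
                               recordId = character())
        return(gr)
    }
    parse1 <- function(ln, lineno) {
        tok <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(tok) < 15L)
            stop(sprintf("line %d: too few columns in .out body", lineno + 3L),
                 call. = FALSE)
        ints <- suppressWarnings(as.integer(tok[c(1, 6, 7)]))
        if (anyNA(ints))
            stop(sprintf("line %d: non-integer coordinate column", lineno + 3L),
                 call. = FALSE)
        strand <- tok[9]
        if (strand == "C") {
            cEnd <- suppressWarnings(as.integer(tok[13]))
            cBeg <- suppressWarnings(as.integer(tok[14]))
            strand <- "-"
        } else {
            cBeg <- suppressWarnings(as.integer(tok[12]))
            cEnd <- suppressWarnings(as.integer(tok[13]))
        }
        if (anyNA(c(cBeg, cEnd)))
            stop(sprintf("line %d: non-integer consensus coordinate", lineno + 3L),
                 call. = FALSE)
        list(swScore = ints[1], divergence = as.numeric(tok[2]),
             chrom = tok[5], gStart = ints[2], gEnd = ints[3],
             strand = strand, repeatId = tok[10], repeatClass = tok[11],
             cStart = cBeg, cEnd = cEnd, recordId = tok[15])
    }
    recs <- lapply(seq_along(lines), function(i) parse1(lines[i], i))
    g <- function(f) vapply(recs, `[[`, recs[[1]][[f]], f)
    gr <- GRanges(seqnames = g("chrom"),
                  ranges = IRanges(g("gStart"), g("gEnd")),
                  strand = g("strand"))
    mcols(gr) <- DataFrame(swScore = g("swScore"), divergence = g("divergence"),
                           repeatId = g("repeatId"), repeatClass = g("repeatClass"),
                           cStart = g("cStart"), cEnd = g("cEnd"),
                           recordId = g("recordId"))
    gr
}

#' Write a RepeatMasker-style annotation (.out) file
#'
#' @param x GRanges as returned by [readRepeatOut()].
#' @param file output path or connection.
#' @return Invisibly, the lines written.
#' @export
writeRepeatOut <- function(x, file) {
    mc <- mcols(x)
    hdr <- c("   SW  perc perc perc  query     position in query     matching repeat      position in repeat",
             "score  div. del. ins.  sequence  begin  end   (left)   repeat  class/family  begin  end (left)  ID",
             "")
    body <- vapply(seq_along(x), function(k) {
        if (as.character(strand(x))[k] == "-") {
            sprintf("%6d %5.1f  0.0  0.0  %s %d %d (0) C %s %s (0) %d %d %s",
                    mc$swScore[k], mc$divergence[k],
                    as.character(seqnames(x))[k], start(x)[k], end(x)[k],
                    mc$repeatId[k], mc$repeatClass[k],
                    mc$cEnd[k], mc$cStart[k], mc$recordId[k])
        } else {
            sprintf("%6d %5.1f  0.0  0.0  %s %d %d (0) + %s %s %d %d (0) %s",
                    mc$swScore[k], mc$divergence[k],
                    as.character(seqnames(x))[k], start(x)[k], end(x)[k],
                    mc$repeatId[k], mc$repeatClass[k],
                    mc$cStart[k], mc$cEnd[k], mc$recordId[k])
        }
    }, character(1))
    writeLines(c(hdr, body), file)
    invisible(c(hdr, body))
}

#' Fetch a genomic sequence slice
#'
#' @param genome a named DNAStringSet (e.g. from
#'   \code{Biostrings::readDNAStringSet}).
#' @param chrom sequence name.
#' @param start,end 1-based inclusive coordinates on the forward strand.
#' @param strand \code{"+"} or \code{"-"}; minus returns the reverse
#'   complement.
#' @return Uppercase character string of length \code{end - start + 1}.
#' @export
genomeSlice <- function(genome, chrom, start, end, strand = "+") {
    if (!chrom %in% names(genome))
        stop("chromosome not in genome: ", chrom)
    if (start < 1L || end > length(genome[[chrom]]) || start > end)
        stop(sprintf("slice %s:%d-%d outside genome bounds", chrom, start, end))
    s <- subseq(genome[[chrom]], start, end)
    if (strand == "-") s <- reverseComplement(s)
    toupper(as.character(s))
}
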