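## Central S4 classes. Validity methods enforce the alignment/chain algebra
## that the rest of the package relies on, so corrupt inputs fail early.

.GAP <- as.raw(45L)  # "-"

.gapMask <- function(s) charToRaw(s) != .GAP

#' RepeatAlignments: RepeatMasker pairwise alignments as a GRanges extension
#'
#' Each element is one genomic repeat instance together with its gapped
#' pairwise alignment to a repeat consensus. The genomic location lives in
#' the GRanges part (always on the forward genomic strand; the GRanges strand
#' records the orientation of the instance relative to the consensus).
#' Required metadata columns:
#' \describe{
#'   \item{repeatId}{consensus name as in the \code{.align} file, with any
#'     \code{#class/family} suffix split off into \code{repeatClass}.}
#'   \item{cStart, cEnd}{1-based inclusive span on the forward consensus.}
#'   \item{swScore, divergence}{Smith-Waterman score and percent divergence.}
#'   \item{alignedGenome, alignedConsensus}{equal-length gapped strings over
#'     \code{A,C,G,T,N,-}. \code{alignedGenome} is stored as the strand that
#'     aligns to the \emph{forward} consensus, i.e. for minus-strand
#'     instances it is the reverse complement of the forward genomic
#'     sequence.}
#'   \item{recordId}{stable per-record identifier.}
#' }
#'
#' @seealso [readRepeatAlignments()], [buildChains()], [liftOut()]
#' @exportClass RepeatAlignments
setClass("RepeatAlignments", contains = "GRanges")

.ALN_COLS <- c("repeatId", "repeatClass", "cStart", "cEnd", "swScore",
               "divergence", "alignedGenome", "alignedConsensus", "recordId")

.validRepeatAlignments <- function(object) {
    msgs <- character()
    miss <- setdiff(.ALN_COLS, colnames(mcols(object)))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (!length(object))
        return(TRUE)
    mc <- mcols(object)
    ag <- as.character(mc$alignedGenome)
    ac <- as.character(mc$alignedConsensus)
    if (any(strand(object) == "*"))
        msgs <- c(msgs, "strand must be '+' or '-'")
    if (any(nchar(ag) != nchar(ac)))
        msgs <- c(msgs, "alignedGenome and alignedConsensus differ in length")
    if (any(grepl("[^ACGTN-]", ag)) || any(grepl("[^ACGTN-]", ac)))
        msgs <- c(msgs, "aligned strings restricted to A,C,G,T,N,-")
    ngG <- nchar(gsub("-", "", ag, fixed = TRUE))
    ngC <- nchar(gsub("-", "", ac, fixed = TRUE))
    if (any(ngG != width(object)))
        msgs <- c(msgs, "non-gap genome bases must equal genomic span width")
    if (any(ngC != mc$cEnd - mc$cStart + 1L))
        msgs <- c(msgs, "non-gap consensus bases must equal consensus span width")
    if (any(mc$cStart < 1L) || any(mc$cStart > mc$cEnd))
        msgs <- c(msgs, "need 1 <= cStart <= cEnd")
    bothGap <- vapply(seq_along(ag), function(i) {
        any(charToRaw(ag[i]) == .GAP & charToRaw(ac[i]) == .GAP)
    }, logical(1))
    if (any(bothGap))
        msgs <- c(msgs, paste("column gapped in both sequences in record(s):",
                              paste(mc$recordId[bothGap], collapse = ", ")))
    if (length(msgs)) msgs else TRUE
}

setValidity("RepeatAlignments", .validRepeatAlignments)

#' Construct a RepeatAlignments object from its fields
#'
#' @param chrom,gStart,gEnd genomic location, 1-based inclusive, forward
#'   strand.
#' @param strand "+" or "-" (orientation of the instance vs the consensus).
#' @param repeatId,repeatClass consensus name and RepeatMasker class/family.
#' @param cStart,cEnd 1-based inclusive span on the forward consensus.
#' @param swScore,divergence alignment score and percent divergence.
#' @param alignedGenome,alignedConsensus gapped alignment strings (see
#'   \linkS4class{RepeatAlignments} for the strand convention).
#' @param recordId unique record identifiers.
#' @return A \linkS4class{RepeatAlignments} object.
#' @export
#' @examples
#' RepeatAlignments("chr1", 101, 110, "+", "L1toy", "LINE/L1", 1, 10,
#'                  swScore = 20, divergence = 0,
#'                  alignedGenome = "ACGTACGTAC",
#'                  alignedConsensus = "ACGTACGTAC", recordId = "r1")
RepeatAlignments <- function(chrom, gStart, gEnd, strand, repeatId,
                             repeatClass = "Unknown", cStart, cEnd,
                             swScore = 0L, divergence = 0,
                             alignedGenome, alignedConsensus, recordId) {
    gr <- GRanges(seqnames = chrom,
                  ranges = IRanges(start = as.integer(gStart),
                                   end = as.integer(gEnd)),
                  strand = strand)
    mcols(gr) <- DataFrame(repeatId = as.character(repeatId),
                           repeatClass = as.character(repeatClass),
                           cStart = as.integer(cStart),
                           cEnd = as.integer(cEnd),
                           swScore = as.integer(swScore),
                           divergence = as.numeric(divergence),
                           alignedGenome = toupper(alignedGenome),
                           alignedConsensus = toupper(alignedConsensus),
                           recordId = as.character(recordId))
    new("RepeatAlignments", gr)
}

setMethod("show", "RepeatAlignments", function(object) {
    cat("RepeatAlignments with", length(object), "record(s) over",
        length(unique(mcols(object)$repeatId)), "consensus name(s)\n")
    if (length(object)) {
        callNextMethod(as(object, "GRanges")[, c("repeatId", "cStart",
                                                 "cEnd", "recordId")])
    }
})

#' ChainSet: UCSC-chain-style coordinate maps from genome to consensus
#'
#' One chain per repeat instance. The header slot holds the UCSC chain header
#' fields (target = genome, forward strand; query = repeat consensus;
#' coordinates in the 0-based half-open convention of the chain file format,
#' with \code{qStart}/\code{qEnd} expressed on \code{qStrand} as UCSC
#' requires). The blocks slot holds one integer matrix per chain with columns
#' \code{size}, \code{dt}, \code{dq}.
#'
#' @seealso [buildChains()], [writeChainFile()], [liftIntervals()]
#' @exportClass ChainSet
setClass("ChainSet", representation(header = "DFrame", blocks = "list"))

.CHAIN_COLS <- c("score", "tName", "tSize", "tStart", "tEnd", "qName",
                 "qSize", "qStrand", "qStart", "qEnd", "chainId")

.validChainSet <- function(object) {
    h <- object@header
    msgs <- character()
    miss <- setdiff(.CHAIN_COLS, colnames(h))
    if (length(miss))
        return(paste("missing header column(s):", paste(miss, collapse = ", ")))
    if (nrow(h) != length(object@blocks))
        return("header rows and block list differ in length")
    for (k in seq_len(nrow(h))) {
        b <- object@blocks[[k]]
        if (!is.matrix(b) || !all(c("size", "dt", "dq") %in% colnames(b))) {
            msgs <- c(msgs, sprintf("chain %d: malformed block matrix", h$chainId[k]))
            next
        }
        if (any(b[, "size"] <= 0L) || any(b[, c("dt", "dq")] < 0L))
            msgs <- c(msgs, sprintf("chain %d: invalid block sizes/gaps", h$chainId[k]))
        n <- nrow(b)
        if (b[n, "dt"] != 0L || b[n, "dq"] != 0L)
            msgs <- c(msgs, sprintf("chain %d: final block must have dt=dq=0", h$chainId[k]))
        if (n > 1L && any(b[-n, "dt"] == 0L & b[-n, "dq"] == 0L))
            msgs <- c(msgs, sprintf("chain %d: unmerged adjacent blocks", h$chainId[k]))
        if (sum(b[, "size"]) + sum(b[, "dt"]) != h$tEnd[k] - h$tStart[k])
            msgs <- c(msgs, sprintf("chain %d: target span equation violated", h$chainId[k]))
        if (sum(b[, "size"]) + sum(b[, "dq"]) != h$qEnd[k] - h$qStart[k])
            msgs <- c(msgs, sprintf("chain %d: query span equation violated", h$chainId[k]))
        if (h$tStart[k] < 0L || h$tStart[k] >= h$tEnd[k] || h$tEnd[k] > h$tSize[k])
            msgs <- c(msgs, sprintf("chain %d: target interval outside [0, tSize]", h$chainId[k]))
        if (h$qStart[k] < 0L || h$qStart[k] >= h$qEnd[k] || h$qEnd[k] > h$qSize[k])
            msgs <- c(msgs, sprintf("chain %d: query interval outside [0, qSize]", h$chainId[k]))
        if (!h$qStrand[k] %in% c("+", "-"))
            msgs <- c(msgs, sprintf("chain %d: qStrand must be + or -", h$chainId[k]))
    }
    if (length(msgs)) msgs else TRUE
}

setValidity("ChainSet", .validChainSet)

#' @describeIn ChainSet-class number of chains
#' @param x A ChainSet.
#' @export
setMethod("length", "ChainSet", function(x) nrow(x@header))

#' @describeIn ChainSet-class subset chains
#' @param i index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ChainSet", function(x, i, j, ..., drop = FALSE) {
    new("ChainSet", header = x@header[i, , drop = FALSE], blocks = x@blocks[i])
})

setMethod("show", "ChainSet", function(object) {
    cat("ChainSet with", length(object), "chain(s);",
        length(unique(object@header$qName)), "consensus name(s)\n")
    if (length(object)) {
        nb <- vapply(object@blocks, nrow, integer(1))
        cat("  blocks per chain:", paste(range(nb), collapse = "-"), "\n")
        show(head(object@header, 5L))
    }
})

#' Chain header fields
#' @param x A \linkS4class{ChainSet}.
#' @return A DataFrame of UCSC chain header fields (0-based half-open).
#' @export
chainHeader <- function(x) x@header

#' Chain block matrices
#' @param x A \linkS4class{ChainSet}.
#' @return List of integer matrices with columns size, dt, dq.
#' @export
chainBlocks <- function(x) x@blocks

#' SignalTrack: windowed ChIP/input/F.C.C. signal on consensus coordinates
#'
#' Windows tile the consensus from position 1 in steps of \code{window};
#' the last window may be partial. \code{chip} and \code{input} are raw sums
#' of per-base read coverage inside the window; \code{fcc} is the library-
#' size-normalized fold change over control,
#' \deqn{fcc_k = ((chip_k + \alpha)/N_{chip}) / ((input_k + \alpha)/N_{input}).}
#' With \code{alpha = 0} a window with zero input coverage has \code{fcc = NA}
#' and is flagged, never silently infinite. \code{lowConfidence} also flags
#' windows whose input coverage is below \code{minInput}.
#'
#' @seealso [computeFCC()], [signalTrack()], [exportTrack()]
#' @exportClass SignalTrack
setClass("SignalTrack",
         representation(qName = "character", window = "integer",
                        stats = "DFrame", nChip = "numeric",
                        nInput = "numeric", alpha = "numeric",
                        minInput = "numeric"))

.validSignalTrack <- function(object) {
    st <- object@stats
    req <- c("start", "end", "chip", "input", "fcc", "lowConfidence")
    miss <- setdiff(req, colnames(st))
    if (length(miss))
        return(paste("missing stats column(s):", paste(miss, collapse = ", ")))
    msgs <- character()
    if (object@window < 1L) msgs <- c(msgs, "window must be >= 1")
    if (object@nChip <= 0 || object@nInput <= 0)
        msgs <- c(msgs, "library sizes must be positive")
    if (any(st$fcc < 0, na.rm = TRUE)) msgs <- c(msgs, "fcc must be >= 0")
    if (any(st$chip < 0) || any(st$input < 0))
        msgs <- c(msgs, "counts must be >= 0")
    if (nrow(st) && any(st$start != seq(1L, by = object@window, length.out = nrow(st))))
        msgs <- c(msgs, "window grid must be anchored at position 1")
    if (length(msgs)) msgs else TRUE
}

setValidity("SignalTrack", .validSignalTrack)

setMethod("show", "SignalTrack", function(object) {
    st <- object@stats
    cat("SignalTrack on", object@qName, "-", nrow(st), "windows of",
        object@window, "nt\n")
    cat(sprintf("  N_chip=%g N_input=%g alpha=%g; max fcc=%s (%d low-confidence windows)\n",
                object@nChip, object@nInput, object@alpha,
                format(suppressWarnings(max(st$fcc, na.rm = TRUE)), digits = 4),
                sum(st$lowConfidence)))
})

#' Per-window statistics of a SignalTrack
#' @param x A \linkS4class{SignalTrack}.
#' @return DataFrame with columns start, end, chip, input, fcc,
#'   lowConfidence (1-based inclusive windows).
#' @export
trackWindows <- function(x) x@stats

#' F.C.C. values of a SignalTrack
#' @param x A \linkS4class{SignalTrack}.
#' @return Numeric vector of per-window fold change over control.
#' @export
fcc <- function(x) x@stats$fcc

#' SiteSet: genomic sequences lifted out of one consensus locus
#'
#' Holds, for a consensus locus (repeatId, start, end), the genomic sequence
#' aligned to that locus in every repeat instance whose alignment fully
#' covers it, together with provenance and the number of mismatches to the
#' consensus. Sequences are reported in consensus orientation (minus-strand
#' instances reverse-complemented) and all have the locus length; when
#' indel-containing instances are admitted, deleted consensus positions
#' appear as \code{-}.
#'
#' @seealso [liftOut()], [buildPFM()], [scoreSites()]
#' @exportClass SiteSet
setClass("SiteSet",
         representation(repeatId = "character", lstart = "integer",
                        lend = "integer", sites = "DNAStringSet",
                        info = "DFrame", consensusSeq = "character",
                        skipped = "integer"))

.validSiteSet <- function(object) {
    msgs <- character()
    if (object@lstart < 1L || object@lstart > object@lend)
        msgs <- c(msgs, "need 1 <= lstart <= lend")
    L <- object@lend - object@lstart + 1L
    if (length(object@sites) && any(width(object@sites) != L))
        msgs <- c(msgs, "every site must have the locus length")
    if (nchar(object@consensusSeq) != L)
        msgs <- c(msgs, "consensusSeq must have the locus length")
    if (length(object@sites) != nrow(object@info))
        msgs <- c(msgs, "sites and info differ in length")
    if (!all(c("partial", "indel") %in% names(object@skipped)))
        msgs <- c(msgs, "skipped must have elements 'partial' and 'indel'")
    if (length(msgs)) msgs else TRUE
}

setValidity("SiteSet", .validSiteSet)

#' @describeIn SiteSet-class number of extracted sites
#' @param x A SiteSet.
#' @export
setMethod("length", "SiteSet", function(x) length(x@sites))

setMethod("show", "SiteSet", function(object) {
    cat(sprintf("SiteSet: %s:%d-%d (%d nt), %d site(s); skipped %d partial, %d with indels\n",
                object@repeatId, object@lstart, object@lend,
                object@lend - object@lstart + 1L, length(object),
                object@skipped[["partial"]], object@skipped[["indel"]]))
    cat("  consensus:", object@consensusSeq, "\n")
})

#' Site sequences of a SiteSet
#' @param x A \linkS4class{SiteSet}.
#' @return DNAStringSet named by record id.
#' @export
siteSequences <- function(x) x@sites

#' Provenance table of a SiteSet
#' @param x A \linkS4class{SiteSet}.
#' @return DataFrame with recordId, chrom, gStart, gEnd, strand, nMismatch,
#'   hasIndel.
#' @export
siteInfo <- function(x) x@info

#' Consensus sequence of the lifted-out locus
#' @param x A \linkS4class{SiteSet}.
#' @return Character scalar.
#' @export
locusConsensus <- function(x) x@consensusSeq

.BASES <- c("A", "C", "G", "T")

#' PFM: position frequency matrix
#'
#' 4 x L matrix of per-position base frequencies (rows A, C, G, T). Columns
#' sum to 1. Built with pseudocount \code{beta}:
#' \eqn{f(b,i) = (count(b,i) + \beta) / (n_i + 4\beta)} where \eqn{n_i}
#' counts the non-N bases observed at position i.
#'
#' @seealso [buildPFM()], [readMatrixTSV()]
#' @exportClass PFM
setClass("PFM", representation(profile = "matrix", nSites = "integer",
                               beta = "numeric"))

.validProfile <- function(m) {
    if (!is.numeric(m)) return("profile must be numeric")
    if (!identical(rownames(m), .BASES)) return("profile rows must be A,C,G,T")
    if (ncol(m) < 1L) return("profile must have at least one column")
    TRUE
}

setValidity("PFM", function(object) {
    v <- .validProfile(object@profile)
    if (!isTRUE(v)) return(v)
    m <- object@profile
    if (any(m < 0)) return("frequencies must be >= 0")
    if (any(abs(colSums(m) - 1) > 1e-9))
        return("PFM columns must sum to 1 (tolerance 1e-9)")
    TRUE
})

#' PEM: position energy matrix
#'
#' 4 x L matrix of additive binding energy contributions in kT units
#' (rows A, C, G, T); lower energy means stronger binding. The predicted
#' energy of a site s is the positional sum \eqn{E(s) = \sum_i \epsilon(s_i, i)}.
#'
#' @seealso [predictEnergy()], [scanConsensus()], [readMatrixTSV()]
#' @exportClass PEM
setClass("PEM", representation(profile = "matrix"))

setValidity("PEM", function(object) {
    v <- .validProfile(object@profile)
    if (!isTRUE(v)) return(v)
    if (!all(is.finite(object@profile))) return("energies must be finite")
    TRUE
})

#' Numeric profile of a PFM or PEM
#' @param x A \linkS4class{PFM} or \linkS4class{PEM}.
#' @return 4 x L numeric matrix with rows A, C, G, T.
#' @export
profileMatrix <- function(x) x@profile

#' Motif length of a PFM or PEM
#' @param x A \linkS4class{PFM} or \linkS4class{PEM}.
#' @return Integer number of positions.
#' @export
motifLength <- function(x) ncol(x@profile)

setMethod("show", "PFM", function(object) {
    cat("PFM of length", ncol(object@profile), "built from",
        object@nSites, "site(s), beta =", object@beta, "\n")
    print(round(object@profile, 3))
})

setMethod("show", "PEM", function(object) {
    cat("PEM of length", ncol(object@profile), "(kT; lower = stronger)\n")
    print(round(object@profile, 3))
    best <- paste(.BASES[apply(object@profile, 2, which.min)], collapse = "")
    cat("  minimum-energy sequence:", best, "\n")
})

#' EnergySummary: predicted binding energies of a site set
#'
#' Energies (kT) of all scoreable sites, the threshold theta, and the
#' fraction of sites with energy strictly below theta. Sites containing N
#' are excluded from scoring and counted in \code{nExcluded}.
#'
#' @seealso [scoreSites()]
#' @exportClass EnergySummary
setClass("EnergySummary",
         representation(energies = "numeric", theta = "numeric",
                        fractionBelow = "numeric", nExcluded = "integer"))

setValidity("EnergySummary", function(object) {
    if (!length(object@energies)) return("no energies")
    fb <- mean(object@energies < object@theta)
    if (abs(fb - object@fractionBelow) > 1e-12)
        return("fractionBelow inconsistent with energies and theta")
    TRUE
})

setMethod("show", "EnergySummary", function(object) {
    cat(sprintf("EnergySummary: %d site(s), %d excluded (N); theta = %g kT; %.1f%% below threshold\n",
                length(object@energies), object@nExcluded, object@theta,
                100 * object@fractionBelow))
})

#' Energies of an EnergySummary
#' @param x An \linkS4class{EnergySummary}.
#' @return Numeric vector of per-site energies (kT).
#' @export
siteEnergies <- function(x) x@energies

#' Fraction of sites below the energy threshold
#' @param x An \linkS4class{EnergySummary}.
#' @return Numeric scalar in [0, 1].
#' @export
fractionBelow <- function(x) x@fractionBelow
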