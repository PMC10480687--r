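## Windowed coverage and Fold Change over Control (F.C.C.) on consensus
## coordinates.

.windowGrid <- function(consensusLength, window) {
    starts <- seq(1L, consensusLength, by = window)
    list(start = starts,
         end = pmin(starts + window - 1L, as.integer(consensusLength)))
}

#' Windowed base coverage of lifted segments on one consensus
#'
#' Per-base coverage is incremented by every segment base; the count of
#' window k is the sum of base coverage in the k-th window. Windows tile the
#' consensus from position 1 in steps of \code{window}; the last (possibly
#' partial) window is kept.
#'
#' @param segments GRanges of lifted segments (from [liftIntervals()] /
#'   [liftReads()]).
#' @param consensusLength length of the consensus in nt.
#' @param window window size in nt (default 10).
#' @param qName optional consensus name to filter \code{segments} by; if
#'   NULL, all segments are assumed to belong to one consensus.
#' @return Integer vector of per-window coverage sums, length
#'   \code{ceiling(consensusLength / window)}.
#' @export
consensusCoverage <- function(segments, consensusLength, window = 10L,
                              qName = NULL) {
    if (!is.null(qName))
        segments <- segments[as.character(seqnames(segments)) == qName]
    consensusLength <- as.integer(consensusLength)
    window <- as.integer(window)
    if (length(segments) &&
        (any(start(segments) < 1L) || any(end(segments) > consensusLength)))
        stop("segment outside [1, consensus length]: corrupt chain or wrong length")
    cov <- coverage(ranges(segments), width = consensusLength)
    wg <- .windowGrid(consensusLength, window)
    as.integer(viewSums(Views(cov, start = wg$start, end = wg$end)))
}

#' Compute a Fold Change over Control track from window counts
#'
#' \deqn{fcc_k = ((chip_k + \alpha) / N_{chip}) / ((input_k + \alpha) / N_{input})}
#' Library sizes are the \emph{total} read counts of each library before
#' lifting, which keeps F.C.C. values comparable across repeat families.
#' With \code{alpha = 0}, windows with zero input coverage get
#' \code{fcc = NA} and are flagged; windows with input coverage below
#' \code{minInput} are flagged low-confidence.
#'
#' @param chipCounts,inputCounts integer vectors of per-window coverage on
#'   the same window grid (see [consensusCoverage()]).
#' @param nChip,nInput total read counts of the ChIP and input libraries.
#' @param alpha pseudocount added to both window counts (default 1).
#' @param minInput input coverage below which a window is flagged (default 5).
#' @param qName consensus name stored in the track.
#' @param window window size in nt.
#' @return A \linkS4class{SignalTrack}.
#' @export
#' @examples
#' computeFCC(c(16, 3), c(2, 3), nChip = 1e6, nInput = 1e6, alpha = 0)
computeFCC <- function(chipCounts, inputCounts, nChip, nInput, alpha = 1,
                       minInput = 5, qName = "consensus", window = 10L) {
    if (length(chipCounts) != length(inputCounts))
        stop("chip and input window grids differ in length")
    if (nChip <= 0 || nInput <= 0)
        stop("library sizes must be positive")
    n <- length(chipCounts)
    window <- as.integer(window)
    fccv <- ((chipCounts + alpha) / nChip) / ((inputCounts + alpha) / nInput)
    zero <- alpha == 0 & inputCounts == 0
    fccv[zero] <- NA_real_
    low <- inputCounts < minInput | zero
    starts <- seq(1L, by = window, length.out = n)
    stats <- DataFrame(start = starts, end = starts + window - 1L,
                       chip = as.integer(chipCounts),
                       input = as.integer(inputCounts),
                       fcc = fccv, lowConfidence = low)
    new("SignalTrack", qName = qName, window = window, stats = stats,
        nChip = as.numeric(nChip), nInput = as.numeric(nInput),
        alpha = as.numeric(alpha), minInput = as.numeric(minInput))
}

#' Build an F.C.C. SignalTrack from lifted ChIP and input segments
#'
#' Convenience composition of [consensusCoverage()] for both libraries and
#' [computeFCC()].
#'
#' @param chipSegments,inputSegments GRanges of lifted segments.
#' @param qName consensus name.
#' @param consensusLength consensus length in nt.
#' @param nChip,nInput total (pre-lift) library read counts.
#' @param window window size in nt (default 10).
#' @param alpha,minInput see [computeFCC()].
#' @return A \linkS4class{SignalTrack}.
#' @export
signalTrack <- function(chipSegments, inputSegments, qName, consensusLength,
                        nChip, nInput, window = 10L, alpha = 1, minInput = 5) {
    chip <- consensusCoverage(chipSegments, consensusLength, window, qName)
    input <- consensusCoverage(inputSegments, consensusLength, window, qName)
    tr <- computeFCC(chip, input, nChip, nInput, alpha = alpha,
                     minInput = minInput, qName = qName, window = window)
    # trim the trailing partial window's end to the consensus length
    tr@stats$end[nrow(tr@stats)] <- as.integer(consensusLength)
    tr
}

#' Export a SignalTrack as bedGraph on consensus coordinates
#'
#' Writes a 4-column bedGraph (chrom = consensus name, 0-based half-open
#' windows, value = F.C.C.). Windows with undefined F.C.C. (zero input at
#' \code{alpha = 0}) are omitted from the bedGraph; all low-confidence
#' windows are listed in a companion BED mask file.
#'
#' @param x A \linkS4class{SignalTrack}.
#' @param file bedGraph output path.
#' @param maskFile companion mask BED path (default \code{<file>.mask.bed}).
#' @return Invisibly, the bedGraph lines.
#' @export
exportTrack <- function(x, file, maskFile = paste0(file, ".mask.bed")) {
    st <- x@stats
    ok <- !is.na(st$fcc)
    lines <- sprintf("%s\t%d\t%d\t%s", x@qName, st$start[ok] - 1L, st$end[ok],
                     format(st$fcc[ok], digits = 15, scientific = FALSE,
                            trim = TRUE))
    writeLines(lines, file)
    mask <- st[st$lowConfidence, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\tlow_confidence", x@qName,
                       mask$start - 1L, mask$end), maskFile)
    invisible(lines)
}

#' Export a SignalTrack as a TSV table
#'
#' Columns: qName, winStart, winEnd (1-based inclusive), chip, input, fcc,
#' lowConfidence.
#'
#' @param x A \linkS4class{SignalTrack}.
#' @param file output path.
#' @return Invisibly, the data.frame written.
#' @export
exportTrackTSV <- function(x, file) {
    df <- data.frame(qName = x@qName, winStart = x@stats$start,
                     winEnd = x@stats$end, chip = x@stats$chip,
                     input = x@stats$input, fcc = x@stats$fcc,
                     lowConfidence = x@stats$lowConfidence)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
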