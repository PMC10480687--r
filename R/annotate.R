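## Annotate peaks / binding-site intervals with their containing or nearest
## repeat instance and the corresponding consensus coordinates.

#' Annotate genomic intervals with repeat instances and consensus positions
#'
#' Each peak is assigned the repeat instance with maximal overlap (ties
#' broken by smallest distance, then alphabetical repeat name, then genomic
#' position, so the result is independent of instance order). Status is
#' \code{within} when the overlap is positive, \code{near} when the
#' edge-to-edge distance to the nearest instance is at most \code{maxDist},
#' and \code{none} otherwise; the three statuses partition the peaks. For
#' \code{within} peaks the overlapping part is lifted through the chains to
#' report the consensus interval (NA when the overlap falls entirely into
#' alignment gaps).
#'
#' @param peaks GRanges of peaks or binding sites (e.g. imported from BED);
#'   a \code{name} column is carried through.
#' @param instances GRanges of repeat instances (from [readRepeatOut()]).
#' @param chains optional \linkS4class{ChainSet} used to lift the overlap
#'   onto consensus coordinates.
#' @param maxDist maximum distance (bp) for status \code{near}; default 500.
#' @return DataFrame with one row per peak: \code{name}, \code{chrom},
#'   \code{start}, \code{end}, \code{status}, \code{repeatId},
#'   \code{repeatClass}, \code{overlap}, \code{distance}, \code{qName},
#'   \code{qStart}, \code{qEnd}.
#' @export
annotatePeaks <- function(peaks, instances, chains = NULL, maxDist = 500L) {
    if (maxDist < 0L) stop("maxDist must be >= 0")
    n <- length(peaks)
    nm <- if (!is.null(mcols(peaks)$name)) as.character(mcols(peaks)$name)
          else if (!is.null(names(peaks))) names(peaks)
          else sprintf("peak%d", seq_len(n))
    status <- rep("none", n)
    repId <- repCls <- rep(NA_character_, n)
    ovl <- rep(0L, n)
    dist <- rep(NA_integer_, n)
    qName <- rep(NA_character_, n)
    qStart <- qEnd <- rep(NA_integer_, n)
    if (n && length(instances)) {
        hits <- suppressWarnings(findOverlaps(peaks, instances, ignore.strand = TRUE))
        if (length(hits)) {
            qh <- queryHits(hits); sh <- subjectHits(hits)
            w <- width(pintersect(ranges(peaks)[qh], ranges(instances)[sh]))
            # best hit per peak: max overlap, then repeat name, then position
            o <- order(qh, -w, mcols(instances)$repeatId[sh],
                       as.factor(seqnames(instances))[sh],
                       start(instances)[sh])
            best <- o[!duplicated(qh[o])]
            bq <- qh[best]; bs <- sh[best]
            status[bq] <- "within"
            repId[bq] <- mcols(instances)$repeatId[bs]
            repCls[bq] <- mcols(instances)$repeatClass[bs]
            ovl[bq] <- w[best]
            dist[bq] <- 0L
            if (!is.null(chains)) {
                for (i in seq_along(bq)) {
                    p <- bq[i]
                    ov <- GenomicRanges::intersect(
                        peaks[p], instances[bs[i]], ignore.strand = TRUE)
                    seg <- liftIntervals(chains, ov)
                    seg <- seg[as.character(seqnames(seg)) == repId[p]]
                    if (length(seg)) {
                        qName[p] <- repId[p]
                        qStart[p] <- min(start(seg))
                        qEnd[p] <- max(end(seg))
                    }
                }
            }
        }
        away <- which(status == "none")
        if (length(away)) {
            nearest <- suppressWarnings(distanceToNearest(peaks[away], instances,
                                                          ignore.strand = TRUE))
            if (length(nearest)) {
                qh <- queryHits(nearest)
                d <- mcols(nearest)$distance
                ok <- d <= maxDist
                idx <- away[qh[ok]]
                status[idx] <- "near"
                dist[idx] <- d[ok]
                # distanceToNearest picks one nearest arbitrarily; re-resolve
                # ties deterministically by repeat name then position
                for (i in seq_along(idx)) {
                    p <- idx[i]
                    dd <- suppressWarnings(distance(peaks[p], instances, ignore.strand = TRUE))
                    cand <- which(dd == dist[p])
                    o <- cand[order(mcols(instances)$repeatId[cand],
                                    as.character(seqnames(instances))[cand],
                                    start(instances)[cand])][1L]
                    repId[p] <- mcols(instances)$repeatId[o]
                    repCls[p] <- mcols(instances)$repeatClass[o]
                }
            }
        }
    }
    DataFrame(name = nm, chrom = as.character(seqnames(peaks)),
              start = start(peaks), end = end(peaks), status = status,
              repeatId = repId, repeatClass = repCls, overlap = ovl,
              distance = dist, qName = qName, qStart = qStart, qEnd = qEnd)
}
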