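## Ground-truthed synthetic data: consensus sequences, diverged genomic
## repeat instances with exactly known alignments, and ChIP/input read sets
## with a planted enrichment ratio. The emitted .align/.out files agree with
## the in-memory truth by construction, which makes every other module
## testable without external data.

.randomDNA <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic repeat consensus
#'
#' Random sequence of the requested length, optionally with a fixed motif
#' planted at a given position (e.g. a zinc-finger binding site inside an
#' ORF-like consensus).
#'
#' @param length consensus length in nt.
#' @param motif optional motif string to plant.
#' @param at 1-based start position of the motif (required with
#'   \code{motif}).
#' @param name consensus name.
#' @param seed optional RNG seed.
#' @return Named DNAStringSet of length 1.
#' @export
syntheticConsensus <- function(length, motif = NULL, at = NULL,
                               name = "L1toy", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    s <- strsplit(.randomDNA(length), "")[[1]]
    if (!is.null(motif)) {
        if (is.null(at)) stop("supply 'at' with 'motif'")
        chars <- strsplit(toupper(motif), "")[[1]]
        if (at < 1L || at + length(chars) - 1L > length)
            stop("motif does not fit at the requested position")
        s[at:(at + length(chars) - 1L)] <- chars
    }
    out <- DNAStringSet(paste(s, collapse = ""))
    names(out) <- name
    out
}

## Mutate one consensus segment into a diverged instance, returning the
## gapped alignment (consensus forward vs instance) built alongside the
## edits so the truth is exact. Indels have geometric length (mean 2) and
## never touch the segment ends, keeping coordinate bookkeeping exact.
.mutateSegment <- function(consChars, subRate, indelRate) {
    n <- length(consChars)
    genChars <- consChars
    subs <- which(runif(n) < subRate)
    if (length(subs)) {
        # uniform among the three non-matching bases
        shift <- sample.int(3L, length(subs), replace = TRUE)
        bi <- match(genChars[subs], .BASES)
        genChars[subs] <- .BASES[((bi - 1L + shift) %% 4L) + 1L]
    }
    del <- rep(FALSE, n)
    ins <- vector("list", n)
    if (indelRate > 0 && n > 2L) {
        evpos <- which(runif(n) < indelRate)
        evpos <- evpos[evpos > 1L & evpos < n]
        for (p in evpos) {
            len <- rgeom(1L, 0.5) + 1L
            if (runif(1) < 0.5) {
                pe <- min(p + len - 1L, n - 1L)
                if (!any(del[p:pe])) del[p:pe] <- TRUE
            } else {
                ins[[p]] <- sample(.BASES, len, replace = TRUE)
            }
        }
    }
    gcols <- genChars
    gcols[del] <- "-"
    insAt <- which(lengths(ins) > 0L)
    if (!length(insAt)) {
        ag <- paste(gcols, collapse = "")
        ac <- paste(consChars, collapse = "")
    } else {
        bounds <- c(0L, insAt, n)
        gParts <- cParts <- character()
        for (k in seq_len(length(bounds) - 1L)) {
            span <- (bounds[k] + 1L):bounds[k + 1L]
            gParts <- c(gParts, paste(gcols[span], collapse = ""))
            cParts <- c(cParts, paste(consChars[span], collapse = ""))
            if (k < length(bounds) - 1L) {
                gParts <- c(gParts, paste(ins[[insAt[k]]], collapse = ""))
                cParts <- c(cParts, strrep("-", length(ins[[insAt[k]]])))
            }
        }
        ag <- paste(gParts, collapse = "")
        ac <- paste(cParts, collapse = "")
    }
    list(alignedGenome = ag, alignedConsensus = ac,
         instSeq = gsub("-", "", ag, fixed = TRUE),
         divergence = 100 * mean(genChars[!del] != consChars[!del]))
}

#' Simulate a genome of diverged repeat instances with exact truth
#'
#' Plants \code{nInstances} independently mutated copies of the consensus
#' on one synthetic chromosome, separated by random spacer sequence.
#' Mutations are per-base substitutions (probability \code{subRate}) and
#' geometric-length indels (per-base event probability \code{indelRate},
#' mean length 2, never at instance ends). A fraction of instances is
#' reverse-complemented and a fraction is 5'-truncated (as real LINE-1
#' copies typically are). The returned alignments are exact by
#' construction, so chains and lifts built from them have a known ground
#' truth.
#'
#' @param consensus named DNAStringSet of consensus sequence(s); instances
#'   sample among them uniformly.
#' @param nInstances number of repeat copies to plant.
#' @param subRate per-base substitution probability in [0, 1).
#' @param indelRate per-base indel event probability in [0, 1).
#' @param minusFraction fraction of instances on the minus strand.
#' @param truncFraction fraction of instances 5'-truncated (consensus start
#'   moved to a random position in the first half).
#' @param spacerLen mean spacer length between instances (actual lengths
#'   uniform in [0.5, 1.5] times this).
#' @param chromName name of the synthetic chromosome.
#' @param seed optional RNG seed.
#' @return List with \code{genome} (named DNAStringSet),
#'   \code{alignments} (\linkS4class{RepeatAlignments}; the ground truth),
#'   \code{instances} (GRanges in \code{.out} layout), \code{consensus}.
#' @export
#' @seealso [simulateReads()], [writeRepeatAlignments()], [writeRepeatOut()]
simulateRepeatGenome <- function(consensus, nInstances = 50L, subRate = 0.05,
                                 indelRate = 0.01, minusFraction = 0.3,
                                 truncFraction = 0.2, spacerLen = 500L,
                                 chromName = "chrS", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (subRate < 0 || subRate >= 1 || indelRate < 0 || indelRate >= 1)
        stop("rates must lie in [0, 1)")
    if (is.null(names(consensus)))
        stop("consensus must be a named DNAStringSet")
    pieces <- character(2L * nInstances + 1L)
    rec <- vector("list", nInstances)
    pos <- 0L
    spc <- function() .randomDNA(sample(max(1L, round(spacerLen * 0.5)):
                                        round(spacerLen * 1.5), 1L))
    for (i in seq_len(nInstances)) {
        sp <- spc()
        pieces[2L * i - 1L] <- sp
        pos <- pos + nchar(sp)
        ci <- sample(length(consensus), 1L)
        L <- width(consensus)[ci]
        cStart <- if (runif(1) < truncFraction && L >= 8L)
            sample(2L:max(2L, floor(L / 2)), 1L) else 1L
        consChars <- strsplit(as.character(subseq(consensus[[ci]], cStart, L)),
                              "")[[1]]
        m <- .mutateSegment(consChars, subRate, indelRate)
        if (!nchar(m$instSeq))
            stop("parameters produced a zero-length instance")
        minus <- runif(1) < minusFraction
        embedded <- if (minus)
            as.character(reverseComplement(DNAString(m$instSeq)))
        else m$instSeq
        pieces[2L * i] <- embedded
        rec[[i]] <- list(gStart = pos + 1L, gEnd = pos + nchar(embedded),
                         strand = if (minus) "-" else "+",
                         repeatId = names(consensus)[ci],
                         cStart = cStart,
                         cEnd = cStart +
                             nchar(gsub("-", "", m$alignedConsensus,
                                        fixed = TRUE)) - 1L,
                         divergence = m$divergence,
                         alignedGenome = m$alignedGenome,
                         alignedConsensus = m$alignedConsensus)
        pos <- pos + nchar(embedded)
    }
    pieces[2L * nInstances + 1L] <- spc()
    genome <- DNAStringSet(paste(pieces, collapse = ""))
    names(genome) <- chromName
    g <- function(f, proto) vapply(rec, `[[`, proto, f)
    aln <- RepeatAlignments(chrom = chromName,
                            gStart = g("gStart", 1L), gEnd = g("gEnd", 1L),
                            strand = g("strand", ""),
                            repeatId = g("repeatId", ""),
                            repeatClass = "LINE/L1",
                            cStart = g("cStart", 1L), cEnd = g("cEnd", 1L),
                            swScore = pmax(1L, round(2 * (g("cEnd", 1L) -
                                                          g("cStart", 1L) + 1L) *
                                                     (1 - g("divergence", 1) / 100))),
                            divergence = round(g("divergence", 1), 1),
                            alignedGenome = g("alignedGenome", ""),
                            alignedConsensus = g("alignedConsensus", ""),
                            recordId = sprintf("inst%04d", seq_len(nInstances)))
    inst <- granges(aln)
    mcols(inst) <- mcols(aln)[, c("swScore", "divergence", "repeatId",
                                  "repeatClass", "cStart", "cEnd", "recordId")]
    list(genome = genome, alignments = aln, instances = inst,
         consensus = consensus)
}

#' Simulate ChIP and input read sets with a planted enrichment
#'
#' Input reads are uniform over the genome at \code{depth}-fold base
#' coverage. ChIP reads are the same uniform background plus, for every
#' genomic projection of the planted consensus locus, extra reads at
#' \code{enrichment - 1} times the local background rate, so the expected
#' ChIP:input coverage ratio over the planted locus is \code{enrichment}
#' and 1 elsewhere. All read names are unique; total library sizes are
#' returned for library-size normalization.
#'
#' @param genome named DNAStringSet (single chromosome) from
#'   [simulateRepeatGenome()].
#' @param alignments \linkS4class{RepeatAlignments} truth for the genome.
#' @param repeatId,start,end the planted consensus locus.
#' @param enrichment planted ChIP enrichment ratio r >= 1.
#' @param depth background per-base coverage of each library.
#' @param readLen read length in nt.
#' @param seed optional RNG seed.
#' @return List with \code{chip} and \code{input} (GRanges with \code{name}
#'   metadata and random strands) and library sizes \code{nChip},
#'   \code{nInput}.
#' @export
simulateReads <- function(genome, alignments, repeatId, start, end,
                          enrichment = 8, depth = 50, readLen = 36L,
                          seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (enrichment < 1) stop("enrichment must be >= 1")
    chrom <- names(genome)[1L]
    G <- width(genome)[1L]
    proj <- .locusProjections(alignments, repeatId, start, end)
    if (!length(proj))
        stop("planted locus is not covered by any instance")
    nBg <- max(1L, round(depth * G / readLen))
    uniformReads <- function(n, prefix) {
        s <- sample.int(G - readLen + 1L, n, replace = TRUE)
        GRanges(chrom, IRanges(s, width = readLen),
                strand = sample(c("+", "-"), n, replace = TRUE),
                name = sprintf("%s%07d", prefix, seq_len(n)))
    }
    input <- uniformReads(nBg, "input")
    chip <- uniformReads(nBg, "chip")
    if (enrichment > 1) {
        extras <- list()
        for (k in seq_along(proj)) {
            w <- width(proj)[k] + readLen - 1L   # starts overlapping the locus
            lo <- max(1L, start(proj)[k] - readLen + 1L)
            hi <- min(G - readLen + 1L, end(proj)[k])
            nx <- rpois(1L, (enrichment - 1) * nBg * w / G)
            if (nx > 0L)
                extras[[length(extras) + 1L]] <-
                    sample(seq.int(lo, hi), nx, replace = TRUE)
        }
        if (length(extras)) {
            s <- unlist(extras)
            ex <- GRanges(chrom, IRanges(s, width = readLen),
                          strand = sample(c("+", "-"), length(s),
                                          replace = TRUE),
                          name = sprintf("chipx%07d", seq_along(s)))
            chip <- c(chip, ex)
        }
    }
    list(chip = chip, input = input, nChip = length(chip), nInput = nBg)
}
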