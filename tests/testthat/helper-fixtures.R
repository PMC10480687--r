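## Shared fixtures. Everything is generated in code under fixed seeds; the
## independent oracles below deliberately re-derive coordinate maps and
## energies with naive per-column / per-position walks so they share no code
## path with the package implementation they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
})

## A small hand-checkable pair of alignment records: one plus-strand
## ungapped, one minus-strand with a 2-nt deletion (gap in genome).
tinyAlignments <- function() {
    RepeatAlignments(
        chrom = c("chr1", "chr1"),
        gStart = c(101L, 201L),
        gEnd = c(110L, 208L),
        strand = c("+", "-"),
        repeatId = c("L1toy", "L1toy"),
        repeatClass = "LINE/L1",
        cStart = c(1L, 3L),
        cEnd = c(10L, 12L),
        swScore = c(90L, 60L),
        divergence = c(0, 10),
        alignedGenome = c("ACGTACGTAC", "ACGT--GTAC"),
        alignedConsensus = c("ACGTACGTAC", "ACGTCAGTAC"),
        recordId = c("r1", "r2"))
}

## Standard simulated fixture used across modules.
simFixture <- function(nInstances = 15, subRate = 0.08, indelRate = 0.02,
                       minusFraction = 0.4, truncFraction = 0.2,
                       consLen = 400, spacerLen = 300, seed = 42,
                       motif = "TCTCACA", motifAt = 301) {
    cons <- syntheticConsensus(consLen, motif = motif, at = motifAt,
                               name = "L1toy", seed = seed + 1000)
    sim <- simulateRepeatGenome(cons, nInstances = nInstances,
                                subRate = subRate, indelRate = indelRate,
                                minusFraction = minusFraction,
                                truncFraction = truncFraction,
                                spacerLen = spacerLen, seed = seed)
    sim$chains <- buildChains(sim$alignments,
                              setNames(width(cons), names(cons)),
                              setNames(width(sim$genome), names(sim$genome)))
    sim
}

## Independent oracle: per-base genome -> consensus map for one alignment
## record, computed by walking the aligned columns one by one.
oracleMap <- function(aln, k) {
    mc <- mcols(aln)
    agc <- strsplit(mc$alignedGenome[k], "")[[1]]
    acc <- strsplit(mc$alignedConsensus[k], "")[[1]]
    gpos <- 0L
    cpos <- 0L
    ccoord <- rep(NA_integer_, end(aln)[k] - start(aln)[k] + 1L)
    for (j in seq_along(agc)) {
        gB <- agc[j] != "-"
        cB <- acc[j] != "-"
        if (gB) gpos <- gpos + 1L
        if (cB) cpos <- cpos + 1L
        if (gB && cB) ccoord[gpos] <- mc$cStart[k] + cpos - 1L
    }
    gcoord <- if (as.character(strand(aln))[k] == "-")
        end(aln)[k] - seq_along(ccoord) + 1L
    else
        start(aln)[k] + seq_along(ccoord) - 1L
    o <- order(gcoord)
    data.frame(gcoord = gcoord[o], ccoord = ccoord[o], row.names = NULL)
}

## Chain-based per-base map for the same record, via the lift engine.
chainMap <- function(chains, aln, k) {
    gr <- GRanges(seqnames(aln)[k],
                  IRanges(start(aln)[k]:end(aln)[k], width = 1L))
    names(gr) <- as.character(start(gr))
    segs <- liftIntervals(chains[k], gr)
    ccoord <- rep(NA_integer_, length(gr))
    if (length(segs))
        ccoord[match(mcols(segs)$name, names(gr))] <- start(segs)
    data.frame(gcoord = start(gr), ccoord = ccoord)
}

## Bulk version: per-base maps for every record in one lift call. Valid for
## fixtures whose instances do not overlap genomically (chainId == record
## index is enforced by filtering).
chainMapAll <- function(chains, aln) {
    per <- lapply(seq_along(aln), function(k) start(aln)[k]:end(aln)[k])
    gr <- GRanges(rep(as.character(seqnames(aln)), lengths(per)),
                  IRanges(unlist(per), width = 1L))
    rec <- rep(seq_along(aln), lengths(per))
    mcols(gr)$name <- as.character(seq_along(gr))
    segs <- liftIntervals(chains, gr)
    segs <- segs[mcols(segs)$chainId == rec[as.integer(mcols(segs)$name)]]
    ccoord <- rep(NA_integer_, length(gr))
    ccoord[as.integer(mcols(segs)$name)] <- start(segs)
    lapply(seq_along(aln), function(k) {
        i <- which(rec == k)
        data.frame(gcoord = start(gr)[i], ccoord = ccoord[i])
    })
}

## Naive per-sequence additive energy, independent of predictEnergy().
oracleEnergy <- function(pem, seqs) {
    prof <- profileMatrix(pem)
    vapply(seqs, function(s) {
        chars <- strsplit(s, "")[[1]]
        tot <- 0
        for (i in seq_along(chars))
            tot <- tot + prof[chars[i], i]
        tot
    }, numeric(1), USE.NAMES = FALSE)
}

revcompStr <- function(s) as.character(reverseComplement(DNAString(s)))

allKmers <- function(L) {
    do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L),
                                stringsAsFactors = FALSE))
}
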