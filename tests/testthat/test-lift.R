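## A two-block chain used for hand-forced mapping checks:
## genomic positions 1-4 map to consensus 1-4, position 5 is an inserted
## genomic base (dt gap), positions 6-10 map to consensus 5-9.
.handChain <- function() {
    aln <- RepeatAlignments(
        chrom = "chr1", gStart = 1L, gEnd = 10L, strand = "+",
        repeatId = "cons", repeatClass = "c", cStart = 1L, cEnd = 9L,
        swScore = 1L, divergence = 0,
        alignedGenome = "ACGTACGTAC", alignedConsensus = "ACGT-CGTAC",
        recordId = "h1")
    buildChains(aln, c(cons = 20L), c(chr1 = 100L))
}

test_that("liftInterval maps piecewise-exactly across block gaps", {
    ch <- .handChain()
    s1 <- liftInterval(ch, "chr1", 1, 4)
    expect_equal(start(s1), 1L)
    expect_equal(end(s1), 4L)
    s2 <- liftInterval(ch, "chr1", 6, 10)
    expect_equal(start(s2), 5L)
    expect_equal(end(s2), 9L)
    ## an interval spanning the inserted base: the two pieces merge and the
    ## inserted base maps nowhere
    s3 <- liftInterval(ch, "chr1", 4, 6)
    expect_length(s3, 1L)
    expect_equal(start(s3), 4L)
    expect_equal(end(s3), 5L)
    ## no overlap is a valid empty result
    expect_length(liftInterval(ch, "chr1", 50, 60), 0L)
    expect_length(liftInterval(ch, "chr9", 1, 4), 0L)
})

test_that("lifted bases agree with the column-walk oracle on random fixtures", {
    sim <- simFixture(nInstances = 20, subRate = 0.2, indelRate = 0.05,
                      minusFraction = 0.5, seed = 71)
    maps <- chainMapAll(sim$chains, sim$alignments)
    for (k in seq_along(sim$alignments)) {
        expect_identical(maps[[k]], oracleMap(sim$alignments, k))
    }
})

test_that("conservation: lifted lengths never exceed the read length", {
    sim <- simFixture(nInstances = 20, subRate = 0.15, indelRate = 0.05,
                      seed = 73)
    G <- width(sim$genome)[1]
    set.seed(74)
    reads <- GRanges("chrS", IRanges(start = sample(G - 40L, 300L), width = 36L),
                     name = sprintf("r%03d", 1:300))
    segs <- liftReads(reads, sim$chains, dedup = FALSE)
    tot <- tapply(width(segs), mcols(segs)$name, sum)
    expect_true(all(tot <= 36L))
})

test_that("deduplication keeps one copy per consensus for any multiplicity", {
    ## k exact genomic copies of the consensus; the same read name at the
    ## equivalent offset in each copy must contribute exactly one segment
    for (k in c(2L, 3L, 6L)) {
        cons <- syntheticConsensus(120, name = "L1toy", seed = 80 + k)
        sim <- simulateRepeatGenome(cons, nInstances = k, subRate = 0,
                                    indelRate = 0, minusFraction = 0,
                                    truncFraction = 0, spacerLen = 100,
                                    seed = 90 + k)
        ch <- buildChains(sim$alignments, setNames(120L, "L1toy"),
                          setNames(width(sim$genome), "chrS"))
        reads <- GRanges("chrS", IRanges(start(sim$alignments) + 49L, width = 36L),
                         name = "multiread")
        segs <- liftReads(reads, ch, dedup = TRUE)
        expect_length(segs, 1L)
        expect_equal(start(segs), 50L)
        expect_equal(end(segs), 85L)
        expect_length(liftReads(reads, ch, dedup = FALSE), k)
    }
})

test_that("dedup requires read names and is copy-order independent", {
    sim <- simFixture(nInstances = 5, seed = 101)
    reads <- GRanges("chrS", IRanges(start(sim$alignments)[1], width = 20L))
    expect_error(liftReads(reads, sim$chains, dedup = TRUE), "name")
    expect_silent(liftReads(reads, sim$chains, dedup = FALSE))
})

test_that("liftOut extracts genome-backed sequences in consensus orientation", {
    g <- DNAStringSet(c(chr1 = "TTTTTACGTACGTACGTTTTT"))
    aln <- RepeatAlignments(
        chrom = "chr1", gStart = 6L, gEnd = 17L, strand = "+",
        repeatId = "cons", repeatClass = "c", cStart = 1L, cEnd = 12L,
        swScore = 1L, divergence = 0,
        alignedGenome = "ACGTACGTACGT", alignedConsensus = "ACGTACGTACGT",
        recordId = "p")
    ss <- liftOut(aln, "cons", 3, 8, g)
    expect_equal(as.character(siteSequences(ss)[[1]]), "GTACGT")
    expect_equal(siteInfo(ss)$gStart, 8L)
    expect_equal(siteInfo(ss)$gEnd, 13L)

    ## same instance placed on the minus strand: stored alignment is the
    ## revcomp of the forward genomic slice
    g2 <- DNAStringSet(c(chr1 = paste0("TTTTT",
                                       revcompStr("ACGTACGTACGT"), "TTTTT")))
    strand(aln) <- "-"
    ss2 <- liftOut(aln, "cons", 3, 8, g2)
    expect_equal(as.character(siteSequences(ss2)[[1]]), "GTACGT")
    expect_equal(siteInfo(ss2)$strand, "-")

    expect_error(liftOut(aln, "nope", 3, 8, g2), "no alignment records")
})

test_that("liftOut skips partial and indel instances, or projects gaps", {
    sim <- simFixture(nInstances = 25, subRate = 0.08, indelRate = 0.05,
                      seed = 103)
    ss <- liftOut(sim$alignments, "L1toy", 301, 320, sim$genome)
    expect_true(all(width(siteSequences(ss)) == 20L))
    mc <- mcols(sim$alignments)
    nCover <- sum(mc$cStart <= 301L & mc$cEnd >= 320L)
    expect_equal(length(ss) + ss@skipped[["indel"]], nCover)
    expect_equal(ss@skipped[["partial"]], length(sim$alignments) - nCover)
    ## every reported sequence equals the genome fetch
    info <- siteInfo(ss)
    for (i in seq_len(length(ss))) {
        expect_equal(as.character(siteSequences(ss)[[i]]),
                     genomeSlice(sim$genome, info$chrom[i], info$gStart[i],
                                 info$gEnd[i], info$strand[i]))
    }
    ## allowIndel admits the skipped instances, keeping the locus length
    ssi <- liftOut(sim$alignments, "L1toy", 301, 320, sim$genome,
                   allowIndel = TRUE)
    expect_equal(length(ssi), nCover)
    expect_true(all(width(siteSequences(ssi)) == 20L))
    expect_true(any(grepl("-", as.character(siteSequences(ssi)), fixed = TRUE)) ||
                ss@skipped[["indel"]] == 0L)
})

test_that("liftIn and liftOut are inverse for indel-free sites", {
    sim <- simFixture(nInstances = 30, subRate = 0.1, indelRate = 0.03,
                      seed = 107)
    ss <- liftOut(sim$alignments, "L1toy", 301, 320, sim$genome)
    info <- siteInfo(ss)
    for (i in seq_len(nrow(info))) {
        segs <- liftInterval(sim$chains, info$chrom[i], info$gStart[i],
                             info$gEnd[i])
        segs <- segs[as.character(seqnames(segs)) == "L1toy"]
        expect_equal(min(start(segs)), 301L)
        expect_equal(max(end(segs)), 320L)
        expect_equal(sum(width(segs)), 20L)
    }
})

test_that("copy-number amplification leaves deduplicated coverage unchanged", {
    ## identical consensus copies: per-position deduplicated coverage of a
    ## read set must not depend on how many copies exist
    covFor <- function(k) {
        cons <- syntheticConsensus(150, name = "L1toy", seed = 300)
        sim <- simulateRepeatGenome(cons, nInstances = k, subRate = 0,
                                    indelRate = 0, minusFraction = 0,
                                    truncFraction = 0, spacerLen = 120,
                                    seed = 301)
        ch <- buildChains(sim$alignments, setNames(150L, "L1toy"),
                          setNames(width(sim$genome), "chrS"))
        ## one read at the same consensus offset in every copy
        starts <- unlist(lapply(start(sim$alignments), function(s) s + c(10L, 60L)))
        reads <- GRanges("chrS", IRanges(starts, width = 30L),
                         name = rep(c("ra", "rb"), k))
        segs <- liftReads(reads, ch, dedup = TRUE)
        consensusCoverage(segs, 150L, window = 1L)
    }
    expect_identical(covFor(2L), covFor(5L))
})
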