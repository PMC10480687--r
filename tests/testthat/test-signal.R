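.seg <- function(starts, ends, qname = "cons") {
    GRanges(qname, IRanges(starts, ends))
}

test_that("window coverage follows per-base overlap arithmetic", {
    expect_equal(consensusCoverage(.seg(1, 10), 40, 10),
                 c(10L, 0L, 0L, 0L))
    expect_equal(consensusCoverage(.seg(6, 15), 20, 10), c(5L, 5L))
    expect_equal(consensusCoverage(.seg(c(6, 6), c(15, 15)), 20, 10),
                 c(10L, 10L))
    ## partial last window is kept
    expect_equal(length(consensusCoverage(.seg(1, 5), 25, 10)), 3L)
    expect_error(consensusCoverage(.seg(1, 30), 20, 10), "outside")
})

test_that("coverage of uniform simulated depth is near depth * window", {
    sim <- simFixture(nInstances = 10, subRate = 0, indelRate = 0,
                      truncFraction = 0, minusFraction = 0, seed = 111)
    rd <- simulateReads(sim$genome, sim$alignments, "L1toy", 301, 320,
                        enrichment = 1, depth = 30, readLen = 30, seed = 112)
    segs <- liftReads(rd$input, sim$chains, dedup = TRUE)
    cov <- consensusCoverage(segs, 400L, window = 10L)
    ## each consensus base is covered by 10 identical copies at depth 30
    expected <- 30 * 10 * 10
    inner <- cov[2:39]   # edge windows lose read overhang
    expect_true(all(abs(inner - expected) / expected < 0.25))
})

test_that("fcc formula, sentinels and flags behave as specified", {
    tr <- computeFCC(c(16L, 5L, 0L), c(2L, 0L, 0L), nChip = 1e6, nInput = 1e6,
                     alpha = 0)
    expect_equal(fcc(tr), c(8, NA, NA))
    expect_true(all(trackWindows(tr)$lowConfidence))
    tr2 <- computeFCC(c(16L, 5L), c(20L, 20L), nChip = 2e6, nInput = 1e6,
                      alpha = 0)
    expect_equal(fcc(tr2), c(16 / 20 / 2, 5 / 20 / 2))
    expect_false(any(trackWindows(tr2)$lowConfidence))
    expect_error(computeFCC(1:3, 1:2, 1, 1), "grids")
    expect_error(computeFCC(1:3, 1:3, 0, 1), "positive")
})

test_that("identical chip and input libraries give fcc exactly 1", {
    sim <- simFixture(nInstances = 12, seed = 115)
    rd <- simulateReads(sim$genome, sim$alignments, "L1toy", 301, 320,
                        enrichment = 1, depth = 5, seed = 116)
    segs <- liftReads(rd$input, sim$chains, dedup = TRUE)
    cov <- consensusCoverage(segs, 400L)
    tr <- computeFCC(cov, cov, rd$nInput, rd$nInput, alpha = 0)
    covered <- cov > 0
    expect_true(all(fcc(tr)[covered] == 1))
    expect_true(all(is.na(fcc(tr)[!covered])))
})

test_that("fcc is invariant under k-fold library duplication", {
    ## duplicating every read with fresh ids (dedup off) rescales both the
    ## counts and the library size, leaving every fcc unchanged exactly
    sim <- simFixture(nInstances = 8, seed = 121)
    rd <- simulateReads(sim$genome, sim$alignments, "L1toy", 301, 320,
                        enrichment = 4, depth = 4, seed = 122)
    lift1 <- function(r) liftReads(r, sim$chains, dedup = FALSE)
    dup <- function(gr, k) {
        out <- rep(gr, k)
        mcols(out)$name <- sprintf("%s.%d", mcols(out)$name,
                                   rep(seq_len(k), each = length(gr)))
        out
    }
    c1 <- consensusCoverage(lift1(rd$chip), 400L)
    i1 <- consensusCoverage(lift1(rd$input), 400L)
    c3 <- consensusCoverage(lift1(dup(rd$chip, 3L)), 400L)
    i3 <- consensusCoverage(lift1(dup(rd$input, 3L)), 400L)
    t1 <- computeFCC(c1, i1, rd$nChip, rd$nInput, alpha = 0)
    t3 <- computeFCC(c3, i3, 3 * rd$nChip, 3 * rd$nInput, alpha = 0)
    expect_equal(fcc(t1), fcc(t3))
})

test_that("fcc is monotone in chip counts and antitone in input counts", {
    base <- computeFCC(c(10L, 10L), c(10L, 10L), 1e6, 1e6, alpha = 1)
    up <- computeFCC(c(11L, 10L), c(10L, 10L), 1e6, 1e6, alpha = 1)
    dn <- computeFCC(c(10L, 10L), c(11L, 10L), 1e6, 1e6, alpha = 1)
    expect_gt(fcc(up)[1], fcc(base)[1])
    expect_lt(fcc(dn)[1], fcc(base)[1])
})

test_that("planted enrichment is recovered at the planted locus", {
    cons <- syntheticConsensus(2000, motif = "TCTCACA", at = 1501,
                               name = "L1toy", seed = 131)
    sim <- simulateRepeatGenome(cons, nInstances = 12, subRate = 0.05,
                                indelRate = 0.01, minusFraction = 0.3,
                                truncFraction = 0.2, spacerLen = 4000,
                                seed = 132)
    ch <- buildChains(sim$alignments, setNames(2000L, "L1toy"),
                      setNames(width(sim$genome), "chrS"))
    rd <- simulateReads(sim$genome, sim$alignments, "L1toy", 1501, 1520,
                        enrichment = 6, depth = 25, seed = 133)
    tr <- signalTrack(liftReads(rd$chip, ch), liftReads(rd$input, ch),
                      "L1toy", 2000L, rd$nChip, rd$nInput, alpha = 0)
    v <- fcc(tr)
    st <- trackWindows(tr)
    atLocus <- which(st$start >= 1501 & st$end <= 1520)
    expect_true(all(abs(v[atLocus] - 6) / 6 < 0.2))
    ## max window sits at the planted locus
    expect_true(which.max(v) %in% which(st$start >= 1501 - 40 & st$end <= 1520 + 40))
    ## background windows (far from the locus) sit near 1
    bg <- which(st$end < 1300)
    bg <- bg[!st$lowConfidence[bg]]
    expect_lt(abs(median(v[bg], na.rm = TRUE) - 1), 0.15)
})

test_that("bedGraph export round-trips through rtracklayer", {
    skip_if_not_installed("rtracklayer")
    tr <- computeFCC(c(16L, 8L, 0L, 2L), c(2L, 8L, 0L, 8L), 1e6, 1e6,
                     alpha = 0, qName = "L1toy")
    f <- withr::local_tempfile(fileext = ".bedGraph")
    exportTrack(tr, f)
    lines <- readLines(f)
    expect_length(lines, 3L)   # the NA window is masked out
    back <- rtracklayer::import(f, format = "bedGraph")
    expect_equal(back$score, fcc(tr)[!is.na(fcc(tr))], tolerance = 1e-9)
    expect_equal(start(back), trackWindows(tr)$start[!is.na(fcc(tr))])
    mask <- readLines(paste0(f, ".mask.bed"))
    expect_length(mask, 2L)  # zero-input and below-minInput windows
    ## empty track exports an empty bedGraph
    tr0 <- computeFCC(integer(0), integer(0), 1, 1, qName = "L1toy")
    f0 <- withr::local_tempfile()
    exportTrack(tr0, f0)
    expect_length(readLines(f0), 0L)
})
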