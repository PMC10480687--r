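.toyPEM <- function(L = 2) {
    m <- matrix(rep(c(0, 1, 2, 3), L), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    new("PEM", profile = m)
}

test_that("PFM frequencies follow the pseudocount formula", {
    pfm <- buildPFM(c("AC", "AC", "AG", "AT"), beta = 0)
    f <- profileMatrix(pfm)
    expect_equal(unname(f["A", 1]), 1)
    expect_equal(unname(f["C", 2]), 0.5)
    expect_equal(unname(f["G", 2]), 0.25)
    expect_equal(unname(f["T", 2]), 0.25)
    expect_equal(unname(colSums(f)), c(1, 1))

    pfm1 <- buildPFM("A", beta = 1)
    expect_equal(unname(profileMatrix(pfm1)["A", 1]), 2 / 5)

    ## N excluded from numerator and denominator
    pfmN <- buildPFM(c("AN", "AC", "AC"), beta = 0)
    expect_equal(unname(profileMatrix(pfmN)["C", 2]), 1)

    expect_error(buildPFM(c("A-", "AC")), "allowIndel")
    expect_error(buildPFM(c("AC", "ACG")), "same length")
})

test_that("increasing beta shrinks frequencies toward uniform, order-preserved", {
    sites <- c("AAAC", "AAAG", "AACC", "AAAC", "ATAC")
    f0 <- profileMatrix(buildPFM(sites, beta = 0.5))
    f1 <- profileMatrix(buildPFM(sites, beta = 2))
    expect_true(all(abs(f1 - 0.25) < abs(f0 - 0.25) | f0 == 0.25))
    for (i in 1:4)
        expect_equal(order(f0[, i]), order(f1[, i]))
    expect_true(all(abs(colSums(f1) - 1) < 1e-9))
})

test_that("PFM of uniformly drawn sites carries no information", {
    set.seed(141)
    sites <- vapply(1:4000, function(i)
        paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""), "")
    ic <- informationContent(buildPFM(sites))
    expect_true(all(ic < 0.01))
})

test_that("predictEnergy is the exact additive sum", {
    pem <- .toyPEM(2)
    expect_equal(predictEnergy(pem, "AA"), 0)
    expect_equal(predictEnergy(pem, "CT"), 4)
    di <- allKmers(2)
    e <- predictEnergy(pem, di)
    expect_equal(e, oracleEnergy(pem, di))
    expect_equal(sum(e < 2), 3L)  # AA, AC, CA
    expect_error(predictEnergy(pem, "A"), "length")
    expect_error(predictEnergy(pem, "AN"), "N not allowed")
})

test_that("energies match exhaustive enumeration for a random 8-mer matrix", {
    set.seed(151)
    m <- matrix(rnorm(32, sd = 1.5), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pem <- new("PEM", profile = m)
    seqs <- allKmers(8)
    expect_equal(predictEnergy(pem, seqs), oracleEnergy(pem, seqs))
})

test_that("energy differences decompose over mismatched positions", {
    set.seed(153)
    m <- matrix(rnorm(40), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pem <- new("PEM", profile = m)
    consensus <- "ACGTACGTAC"
    eC <- predictEnergy(pem, consensus)
    for (rep in 1:25) {
        s <- strsplit(consensus, "")[[1]]
        k <- sample(10, sample(3, 1))
        for (p in k) s[p] <- sample(c("A", "C", "G", "T"), 1)
        sq <- paste(s, collapse = "")
        delta <- sum(vapply(seq_len(10), function(i) {
            m[substr(sq, i, i), i] - m[substr(consensus, i, i), i]
        }, numeric(1)))
        expect_equal(predictEnergy(pem, sq) - eC, delta)
    }
})

test_that("single-mismatch substitutions with larger epsilon never lower E", {
    set.seed(155)
    m <- matrix(rnorm(24), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pem <- new("PEM", profile = m)
    s0 <- "AAACGT"
    for (i in 1:6) {
        b0 <- substr(s0, i, i)
        for (b in c("A", "C", "G", "T")) {
            if (m[b, i] < m[b0, i]) next
            s1 <- s0
            substr(s1, i, i) <- b
            expect_gte(predictEnergy(pem, s1), predictEnergy(pem, s0))
        }
    }
})

test_that("scoreSites counts the below-threshold fraction and excludes N", {
    pem <- pemFromMotif("ACGT", mismatch = 2)
    sites <- c("ACGT", "ACGA", "TTTT", "ACNT")
    es <- scoreSites(pem, sites, theta = 1)
    expect_equal(siteEnergies(es), c(0, 2, 6))
    expect_equal(fractionBelow(es), 1 / 3)
    expect_equal(es@nExcluded, 1L)
    expect_equal(fractionBelow(scoreSites(pem, sites[1:3], theta = Inf)), 1)
    expect_error(scoreSites(pem, "ANNT", theta = 0), "no scoreable")
    ## direct-counting oracle on a larger random set
    set.seed(161)
    m <- matrix(rnorm(28), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pem2 <- new("PEM", profile = m)
    ss <- vapply(1:500, function(i)
        paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = ""), "")
    es2 <- scoreSites(pem2, ss, theta = -1)
    expect_equal(fractionBelow(es2),
                 sum(oracleEnergy(pem2, ss) < -1) / 500)
})

test_that("scanConsensus finds planted minima on both strands", {
    pem <- pemFromMotif("TCTCACA", mismatch = 3)
    cons <- syntheticConsensus(200, motif = "TCTCACA", at = 120, seed = 171)
    hit <- scanConsensus(pem, cons)
    expect_equal(hit$offset, 120L)
    expect_equal(hit$strand, "+")
    expect_equal(hit$energy, 0)

    ## plant only the reverse complement
    cons2 <- syntheticConsensus(200, motif = revcompStr("TCTCACA"), at = 120,
                                seed = 172)
    ## fixture sanity: the forward motif must not arise by chance
    expect_equal(gregexpr("TCTCACA", as.character(cons2[[1]]))[[1]][1], -1L)
    hit2 <- scanConsensus(pem, cons2)
    expect_equal(hit2$offset, 120L)
    expect_equal(hit2$strand, "-")
})

test_that("scanConsensus equals brute-force evaluation of every window", {
    set.seed(175)
    m <- matrix(rnorm(36), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pem <- new("PEM", profile = m)
    cons <- as.character(syntheticConsensus(400, seed = 176)[[1]])
    hit <- scanConsensus(pem, cons)
    L <- 9L
    n <- nchar(cons)
    best <- list(e = Inf)
    for (off in seq_len(n - L + 1L)) {
        w <- substr(cons, off, off + L - 1L)
        for (st in c("+", "-")) {
            s <- if (st == "+") w else revcompStr(w)
            e <- oracleEnergy(pem, s)
            if (e < best$e) best <- list(e = e, off = off, strand = st)
        }
    }
    expect_equal(hit$energy, best$e)
    expect_equal(hit$offset, best$off)
    expect_equal(hit$strand, best$strand)
})

test_that("matrix TSV round-trips and rejects malformed files", {
    set.seed(181)
    m <- matrix(rnorm(20), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pem <- new("PEM", profile = m)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeMatrixTSV(pem, f)
    back <- readMatrixTSV(f, "pem")
    expect_equal(profileMatrix(back), profileMatrix(pem), tolerance = 1e-12)

    pfm <- buildPFM(c("ACGT", "ACGG", "TCGA"), beta = 0.5)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeMatrixTSV(pfm, f2)
    back2 <- readMatrixTSV(f2, "pfm")
    expect_equal(profileMatrix(back2), profileMatrix(pfm), tolerance = 1e-12)

    writeLines(c("base\t1\t2", "A\t0\t0", "C\t1\t1", "G\t2\t2"), f2)
    expect_error(readMatrixTSV(f2, "pem"), "4 data rows")
})

test_that("reanchorPEM zeroes positional minima without changing rankings", {
    set.seed(185)
    m <- matrix(rnorm(24), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pem <- new("PEM", profile = m)
    re <- reanchorPEM(pem)
    expect_equal(unname(apply(profileMatrix(re), 2, min)), rep(0, 6))
    seqs <- allKmers(3)
    seqs <- paste0(seqs, "AAA")
    expect_equal(order(predictEnergy(pem, seqs)),
                 order(predictEnergy(re, seqs)))
})

test_that("sites planted with core mismatches shift energy by the epsilon sum", {
    ## construction: consensus sites with k known substitutions must move by
    ## exactly the summed energy differences
    pem <- pemFromMotif("TCTCACAGCAG", mismatch = 1.5)
    cons <- "TCTCACAGCAG"
    e0 <- predictEnergy(pem, cons)
    s <- cons
    substr(s, 3, 3) <- "A"
    substr(s, 7, 7) <- "G"
    expect_equal(predictEnergy(pem, s) - e0, 2 * 1.5)
})
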