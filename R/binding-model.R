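## Position frequency matrices from lifted-out site sets and additive
## position-energy binding predictions.

.asSeqChar <- function(sites) {
    if (is(sites, "SiteSet")) sites <- siteSequences(sites)
    if (is(sites, "XStringSet")) sites <- as.character(sites)
    toupper(as.character(sites))
}

#' Build a position frequency matrix from aligned sites
#'
#' \eqn{f(b,i) = (count(b,i) + \beta) / (n_i + 4\beta)} where \eqn{n_i} is
#' the number of non-N bases observed at position i — N bases are excluded
#' from both numerator and denominator rather than imputed, so they cannot
#' bias the frequencies.
#'
#' @param sites A \linkS4class{SiteSet}, DNAStringSet or character vector of
#'   equal-length ungapped sequences.
#' @param beta pseudocount (default 0).
#' @return A \linkS4class{PFM}.
#' @export
#' @examples
#' buildPFM(c("AC", "AC", "AG", "AT"))
buildPFM <- function(sites, beta = 0) {
    seqs <- .asSeqChar(sites)
    if (!length(seqs)) stop("need at least one site")
    if (length(unique(nchar(seqs))) != 1L)
        stop("all sites must have the same length")
    if (any(grepl("-", seqs, fixed = TRUE)))
        stop("gapped sites cannot enter a PFM; extract with allowIndel = FALSE")
    if (any(grepl("[^ACGTN]", seqs)))
        stop("sites restricted to A,C,G,T,N")
    if (beta < 0) stop("beta must be >= 0")
    counts <- consensusMatrix(DNAStringSet(seqs))[.BASES, , drop = FALSE]
    nEff <- colSums(counts)                  # excludes N automatically
    if (any(nEff + 4 * beta == 0))
        stop("position with no observed base and beta = 0")
    f <- sweep(counts + beta, 2L, nEff + 4 * beta, "/")
    new("PFM", profile = f, nSites = length(seqs), beta = as.numeric(beta))
}

#' Predict additive binding energies of sites
#'
#' \eqn{E(s) = \sum_i \epsilon(s_i, i)} in kT units, exactly; lower energy
#' means stronger predicted binding. Sequences must match the matrix length
#' and contain no N (no implicit trimming or imputation).
#'
#' @param pem A \linkS4class{PEM}.
#' @param sites character vector or DNAStringSet of sequences of the matrix
#'   length over \code{A,C,G,T}.
#' @return Numeric vector of energies (kT), one per sequence.
#' @export
predictEnergy <- function(pem, sites) {
    seqs <- .asSeqChar(sites)
    L <- motifLength(pem)
    if (any(nchar(seqs) != L))
        stop("sequence length must equal the matrix length (", L, ")")
    if (any(grepl("[^ACGT]", seqs)))
        stop("sequences must be over A,C,G,T (N not allowed)")
    n <- length(seqs)
    m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = n, byrow = TRUE)
    bi <- match(m, .BASES)
    vals <- matrix(pem@profile[cbind(as.vector(bi),
                                     rep(seq_len(L), each = n))], nrow = n)
    as.numeric(rowSums(vals))
}

#' Score a site set against an energy threshold
#'
#' Predicts the energy of every scoreable site and reports the fraction with
#' energy strictly below \code{theta}. Sites containing N are excluded from
#' scoring and counted separately; gapped sites are an error.
#'
#' @param pem A \linkS4class{PEM}.
#' @param sites A \linkS4class{SiteSet}, DNAStringSet or character vector.
#' @param theta energy threshold in kT (e.g. -4.5).
#' @return An \linkS4class{EnergySummary}.
#' @export
scoreSites <- function(pem, sites, theta) {
    seqs <- .asSeqChar(sites)
    if (any(grepl("-", seqs, fixed = TRUE)))
        stop("gapped sites cannot be scored; extract with allowIndel = FALSE")
    hasN <- grepl("N", seqs, fixed = TRUE)
    keep <- seqs[!hasN]
    if (!length(keep)) stop("no scoreable sites (all contain N or empty)")
    e <- predictEnergy(pem, keep)
    new("EnergySummary", energies = e, theta = as.numeric(theta),
        fractionBelow = mean(e < theta), nExcluded = sum(hasN))
}

#' Locate the minimum-energy window on a consensus sequence
#'
#' Slides the energy matrix over both strands of the consensus in steps of
#' 1 and returns the lowest-energy window. Ties are broken by the smallest
#' forward-strand offset, then by the plus strand. Windows containing N are
#' not scoreable and are skipped.
#'
#' @param pem A \linkS4class{PEM}.
#' @param consensus DNAString, DNAStringSet of length 1, or character
#'   scalar; must be at least the matrix length.
#' @return List with \code{offset} (1-based start of the window on the
#'   forward strand), \code{strand} and \code{energy} (kT).
#' @export
scanConsensus <- function(pem, consensus) {
    if (is(consensus, "DNAStringSet")) consensus <- consensus[[1L]]
    s <- toupper(as.character(consensus))
    L <- motifLength(pem)
    n <- nchar(s)
    if (n < L) stop("consensus shorter than the matrix length")
    scan1 <- function(chars) {
        v <- match(chars, .BASES)            # NA for N
        nw <- length(chars) - L + 1L
        E <- numeric(nw)
        for (i in seq_len(L))
            E <- E + pem@profile[, i][v[i:(i + nw - 1L)]]
        E
    }
    fwd <- strsplit(s, "")[[1]]
    Ef <- scan1(fwd)
    rev <- strsplit(as.character(reverseComplement(DNAString(s))), "")[[1]]
    Er <- scan1(rev)
    # window j on the reverse-complement starts at forward position
    # n - j - L + 2 (its last base is forward position n - j + 1)
    offF <- seq_along(Ef)
    offR <- n - seq_along(Er) - L + 2L
    off <- c(offF, offR)
    strandv <- rep(c("+", "-"), c(length(Ef), length(Er)))
    E <- c(Ef, Er)
    ok <- !is.na(E)
    if (!any(ok)) stop("no scoreable window (all contain N)")
    o <- order(E[ok], off[ok], match(strandv[ok], c("+", "-")))[1L]
    list(offset = off[ok][o], strand = strandv[ok][o],
         energy = as.numeric(E[ok][o]))
}

#' Re-anchor a PEM so each position's minimum contribution is zero
#'
#' Subtracts the per-position minimum; relative energies between sequences
#' are unchanged. Never applied implicitly — thresholds such as -4.5 kT are
#' interpreted on the matrix's own scale.
#'
#' @param pem A \linkS4class{PEM}.
#' @return A \linkS4class{PEM} with per-position minima at 0.
#' @export
reanchorPEM <- function(pem) {
    new("PEM", profile = sweep(pem@profile, 2L, apply(pem@profile, 2L, min)))
}

#' Build a sharp PEM from a motif string
#'
#' Assigns energy 0 to the motif base and \code{mismatch} kT to every other
#' base at each position, so the motif is the unique minimum-energy
#' sequence. Useful for simulations and as a simple stand-in specificity
#' model when no experimentally derived matrix is available.
#'
#' @param motif character scalar over \code{A,C,G,T}.
#' @param mismatch energy penalty per mismatching base in kT (default 2).
#' @return A \linkS4class{PEM}.
#' @export
#' @examples
#' pemFromMotif("TCTCACA")
pemFromMotif <- function(motif, mismatch = 2) {
    chars <- strsplit(toupper(motif), "")[[1]]
    if (any(!chars %in% .BASES)) stop("motif must be over A,C,G,T")
    m <- matrix(mismatch, nrow = 4L, ncol = length(chars),
                dimnames = list(.BASES, NULL))
    m[cbind(match(chars, .BASES), seq_along(chars))] <- 0
    new("PEM", profile = m)
}

#' Read a PFM or PEM from TSV
#'
#' Expects the format written by [writeMatrixTSV()]: a header row of 1-based
#' positions, then four rows labelled A, C, G, T in that order. PFM column
#' sums are checked on read.
#'
#' @param file input path.
#' @param type \code{"pem"} (energies, kT) or \code{"pfm"} (frequencies).
#' @return A \linkS4class{PEM} or \linkS4class{PFM}.
#' @export
readMatrixTSV <- function(file, type = c("pem", "pfm")) {
    type <- match.arg(type)
    df <- read.delim(file, header = TRUE, check.names = FALSE)
    if (nrow(df) != 4L)
        stop("matrix TSV must have exactly 4 data rows (A, C, G, T); got ",
             nrow(df))
    if (!identical(toupper(as.character(df[[1L]])), .BASES))
        stop("matrix TSV rows must be labelled A, C, G, T in order")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("matrix TSV values must be numeric")
    rownames(m) <- .BASES
    colnames(m) <- NULL
    if (type == "pem") new("PEM", profile = m)
    else new("PFM", profile = m, nSites = NA_integer_, beta = NA_real_)
}

#' Write a PFM or PEM as TSV
#'
#' Header row of 1-based positions; four rows labelled A, C, G, T.
#'
#' @param x A \linkS4class{PFM} or \linkS4class{PEM}.
#' @param file output path.
#' @return Invisibly, \code{x}.
#' @export
writeMatrixTSV <- function(x, file) {
    m <- profileMatrix(x)
    df <- data.frame(base = .BASES, m, check.names = FALSE)
    colnames(df) <- c("base", seq_len(ncol(m)))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(x)
}

#' Information content per PFM position
#'
#' \eqn{IC_i = 2 + \sum_b f(b,i) \log_2 f(b,i)} bits, the quantity displayed
#' by sequence logos (uniform background).
#'
#' @param x A \linkS4class{PFM}.
#' @return Numeric vector of per-position information content in bits.
#' @export
informationContent <- function(x) {
    f <- profileMatrix(x)
    ic <- 2 + colSums(ifelse(f > 0, f * log2(f), 0))
    as.numeric(ic)
}
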