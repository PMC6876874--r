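# Independent brute-force oracle and fixture builders used across tests.
# The oracle deliberately avoids Biostrings: it checks per-position base-set
# containment against its own IUPAC table.

IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"))

# 0-based start positions where `motif` matches `seq`; any sequence letter
# outside the motif position's base set (including N) blocks the match.
oracleScan <- function(seq, motif) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    mchars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
    k <- length(mchars)
    n <- length(chars)
    if (n < k) return(integer(0))
    ok <- rep(TRUE, n - k + 1L)
    for (j in seq_len(k))
        ok <- ok & chars[j:(n - k + j)] %in% IUPAC_SETS[[mchars[j]]]
    which(ok) - 1L
}

# Oracle hits for a panel, mirroring the scanSequence contract (0-based pos,
# enzyme, sorted by pos then enzyme; reverse strand for non-palindromic
# motifs when bothStrands).
oracleScanPanel <- function(seq, panel, bothStrands = TRUE) {
    motifs <- recognitionMotifs(panel)
    pos <- integer(0); enz <- character(0)
    for (nm in names(motifs)) {
        p <- oracleScan(seq, motifs[[nm]])
        if (bothStrands) {
            rc <- reverseComplementMotif(motifs[[nm]])
            if (!identical(rc, toupper(motifs[[nm]])))
                p <- union(p, oracleScan(seq, rc))
        }
        p <- sort(p)
        pos <- c(pos, p)
        enz <- c(enz, rep(nm, length(p)))
    }
    df <- data.frame(pos = pos, enzyme = enz, stringsAsFactors = FALSE)
    df <- df[order(df$pos, df$enzyme), , drop = FALSE]
    rownames(df) <- NULL
    df
}

randomDNA <- function(n, prob = rep(0.25, 4)) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = "")
}

# Build a FragmentSet with the given fragment lengths on one chromosome.
fragmentSetFromLengths <- function(lengths, chrom = "chrT",
                                   gaps = GenomicRanges::GRanges()) {
    ends <- cumsum(as.numeric(lengths))
    starts <- c(1, ends[-length(ends)] + 1)
    si <- GenomeInfoDb::Seqinfo(seqnames = chrom,
                                seqlengths = ends[length(ends)])
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                                 seqinfo = si)
    if (length(gaps) > 0) GenomeInfoDb::seqinfo(gaps) <- si
    else gaps <- GenomicRanges::GRanges(seqinfo = si)
    new("FragmentSet", fragments = gr, gaps = gaps)
}

grT <- function(starts1, ends1, chrom = "chrT", ...) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts1, ends1), ...)
}
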