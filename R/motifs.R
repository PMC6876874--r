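#' @include AllClasses.R
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   matchPattern reverseComplement alphabetFrequency IUPAC_CODE_MAP
#' @importFrom IRanges reduce ranges countOverlaps
NULL

# 0-based position of the first non-IUPAC character, NA if the motif is clean.
.invalidIupacPosition <- function(motif) {
    chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% names(Biostrings::IUPAC_CODE_MAP)))
    if (length(bad)) bad[1L] else NA_integer_
}

.checkMotif <- function(motif) {
    if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
        stopValidation("recognition motif must be a single non-empty string")
    bad <- .invalidIupacPosition(motif)
    if (!is.na(bad))
        stopValidation(sprintf("invalid IUPAC code '%s' at position %d of motif '%s'",
                               substr(motif, bad, bad), bad, motif))
    toupper(motif)
}

#' Expand an IUPAC-degenerate motif into its concrete DNA sequences
#'
#' Every IUPAC code denotes a set of bases (W = A/T, N = any base, ...);
#' a degenerate recognition motif therefore stands for the Cartesian product
#' of its per-position base sets. `CCWGG` expands to `CCAGG` and `CCTGG`;
#' `GANTC` expands to the four sequences `GAATC`, `GACTC`, `GAGTC`, `GATTC`.
#'
#' @param motif a single IUPAC string.
#' @return character vector of all concrete expansions, sorted.
#' @examples
#' expandMotif("CCWGG")
#' expandMotif("GANTC")
#' @export
expandMotif <- function(motif) {
    motif <- .checkMotif(motif)
    sets <- strsplit(Biostrings::IUPAC_CODE_MAP[
        strsplit(motif, "", fixed = TRUE)[[1L]]], "", fixed = TRUE)
    if (prod(lengths(sets)) > 65536)
        stopValidation("motif '", motif, "' expands to more than 65536 sequences")
    grid <- expand.grid(sets, stringsAsFactors = FALSE)
    sort(do.call(paste0, grid))
}

#' Reverse complement of an IUPAC motif
#'
#' Complements each code (degenerate codes map to the complement of their
#' base set, e.g. W -> W, R -> Y) and reverses the string. Applying it twice
#' returns the input.
#'
#' @param motif a single IUPAC string.
#' @return the reverse-complement IUPAC string.
#' @examples
#' reverseComplementMotif("GGATC")  # "GATCC"
#' reverseComplementMotif("CCWGG")  # "CCWGG"
#' @export
reverseComplementMotif <- function(motif) {
    motif <- .checkMotif(motif)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
}

#' Is a recognition motif palindromic?
#'
#' A motif is palindromic (self-reverse-complementary) when it equals its
#' reverse complement at the IUPAC-code level, as all type II recognition
#' sites of the default panel do. Palindromic motifs match both strands at
#' the same positions, so scanning one strand suffices.
#'
#' @param motif a single IUPAC string.
#' @return logical.
#' @examples
#' isPalindromicMotif("TTAA")   # TRUE
#' isPalindromicMotif("GANTC")  # TRUE
#' isPalindromicMotif("GGATC")  # FALSE
#' @export
isPalindromicMotif <- function(motif) {
    motif <- .checkMotif(motif)
    identical(motif, reverseComplementMotif(motif))
}

#' Construct an enzyme panel
#'
#' @param enzyme character vector of enzyme names.
#' @param recognition IUPAC recognition motifs, one per enzyme.
#' @param cutOffset optional integer cut positions within the motif
#'   (0-based, top strand); `NA` where unknown. Metadata only — fragment
#'   boundaries default to recognition-site starts.
#' @return an [EnzymePanel-class].
#' @examples
#' EnzymePanel("AluI", "AGCT", 2L)
#' @export
EnzymePanel <- function(enzyme, recognition, cutOffset = NA_integer_) {
    cutOffset <- rep_len(as.integer(cutOffset), length(enzyme))
    new("EnzymePanel", enzyme = as.character(enzyme),
        recognition = toupper(as.character(recognition)),
        cutOffset = cutOffset)
}

#' Built-in restriction enzyme registry
#'
#' The frequently cutting 4-5 bp enzymes used for restriction-based
#' chromatin fragmentation: AluI (AGCT), SaqAI (TTAA), HinfI (GANTC),
#' MvaI (CCWGG) and BsuRI (GGCC). Cut offsets come from standard
#' enzymology (AluI AG^CT, SaqAI T^TAA, HinfI G^ANTC, MvaI CC^WGG,
#' BsuRI GG^CC) and are metadata only.
#'
#' @param enzymes optional character vector selecting a subset by name.
#' @return an [EnzymePanel-class].
#' @examples
#' defaultEnzymes()
#' defaultEnzymes(c("AluI", "SaqAI", "HinfI", "MvaI"))
#' @export
defaultEnzymes <- function(enzymes = NULL) {
    reg <- EnzymePanel(
        enzyme      = c("AluI", "SaqAI", "HinfI", "MvaI", "BsuRI"),
        recognition = c("AGCT", "TTAA", "GANTC", "CCWGG", "GGCC"),
        cutOffset   = c(2L, 1L, 1L, 2L, 2L))
    if (is.null(enzymes))
        return(reg)
    missing <- setdiff(enzymes, reg@enzyme)
    if (length(missing))
        stopValidation("unknown enzyme(s): ", paste(missing, collapse = ", "))
    idx <- match(enzymes, reg@enzyme)
    EnzymePanel(reg@enzyme[idx], reg@recognition[idx], reg@cutOffset[idx])
}

#' Read an enzyme panel from a tab-separated config file
#'
#' The file must have a header with columns `enzyme` and `recognition`, and
#' optionally `cut_offset`.
#'
#' @param path path to the TSV file.
#' @return an [EnzymePanel-class].
#' @export
readEnzymeConfig <- function(path) {
    if (!file.exists(path))
        stopIO("enzyme config not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("enzyme", "recognition") %in% names(tab)))
        stopValidation("enzyme config needs 'enzyme' and 'recognition' columns")
    off <- if ("cut_offset" %in% names(tab)) tab$cut_offset else NA_integer_
    EnzymePanel(tab$enzyme, tab$recognition, off)
}

# Coerce input to a DNAString and reject letters outside {A,C,G,T,N}
# (case-folded). Reports the coordinate of the first offender.
.asScannableDNA <- function(seq) {
    if (!is(seq, "DNAString")) {
        seq <- as.character(seq)
        bad <- regexpr("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", seq)
        if (bad > 0L)
            stopValidation(sprintf("non-nucleotide character '%s' at position %d",
                                   substr(seq, bad, bad), bad))
    }
    s <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(seq)
    af <- Biostrings::alphabetFrequency(s)
    extra <- af[!names(af) %in% c("A", "C", "G", "T", "N")]
    if (sum(extra) > 0) {
        chars <- strsplit(as.character(s), "", fixed = TRUE)[[1L]]
        bad <- which(!chars %in% c("A", "C", "G", "T", "N"))[1L]
        stopValidation(sprintf("non-nucleotide character '%s' at position %d",
                               chars[bad], bad))
    }
    s
}

# Ambiguity (N) runs of a DNAString, as a reduced IRanges.
.ambiguityRuns <- function(s) {
    IRanges::reduce(IRanges::ranges(Biostrings::matchPattern("N", s, fixed = TRUE)))
}

# Scan one DNAString for one motif; returns 1-based start positions.
# Hits overlapping ambiguous letters are suppressed: the recognition
# sequence of a real enzyme cannot span unresolved assembly sequence.
.matchStarts <- function(motif, s, nRuns) {
    m <- Biostrings::matchPattern(motif, s, fixed = "subject")
    st <- BiocGenerics::start(m)
    if (length(st) && length(nRuns)) {
        hitR <- IRanges::IRanges(st, width = nchar(motif))
        st <- st[IRanges::countOverlaps(hitR, nRuns) == 0L]
    }
    st
}

#' Scan a DNA sequence for recognition sites of an enzyme panel
#'
#' Reports every position where a panel motif matches exactly, including
#' overlapping occurrences. Matching is IUPAC-aware on the motif side only:
#' a degenerate motif position matches any base of its set, but ambiguous
#' sequence letters (N) never match, so hits cannot lie inside or span
#' assembly gaps. Soft-masked lowercase sequence is treated as ordinary
#' sequence. For non-palindromic motifs, `bothStrands = TRUE` also scans the
#' reverse-complement motif (reporting the minus strand); palindromic motifs
#' match both strands at identical positions and are scanned once.
#'
#' @param seq a DNAString or character string over A/C/G/T/N (any case).
#' @param panel an [EnzymePanel-class].
#' @param bothStrands scan reverse complements of non-palindromic motifs.
#' @return data.frame with columns `pos` (0-based start of the occurrence),
#'   `enzyme` and `strand`, sorted by `pos` then enzyme name.
#' @examples
#' scanSequence("TTAAGCTT", defaultEnzymes(c("AluI", "SaqAI")))
#' @export
scanSequence <- function(seq, panel, bothStrands = TRUE) {
    if (!is(panel, "EnzymePanel"))
        stopValidation("panel must be an EnzymePanel")
    s <- .asScannableDNA(seq)
    nRuns <- .ambiguityRuns(s)
    pos <- integer(0); enz <- character(0); strd <- character(0)
    for (i in seq_along(panel@enzyme)) {
        motif <- panel@recognition[i]
        st <- .matchStarts(motif, s, nRuns)
        pos <- c(pos, st)
        enz <- c(enz, rep(panel@enzyme[i], length(st)))
        strd <- c(strd, rep("+", length(st)))
        if (bothStrands && !isPalindromicMotif(motif)) {
            rcst <- .matchStarts(reverseComplementMotif(motif), s, nRuns)
            pos <- c(pos, rcst)
            enz <- c(enz, rep(panel@enzyme[i], length(rcst)))
            strd <- c(strd, rep("-", length(rcst)))
        }
    }
    hits <- data.frame(pos = pos - 1L, enzyme = enz, strand = strd,
                       stringsAsFactors = FALSE)
    hits <- hits[order(hits$pos, hits$enzyme, hits$strand), , drop = FALSE]
    # a degenerate motif can match both strands at one position; keep one
    hits <- hits[!duplicated(hits[c("pos", "enzyme")]), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Map recognition sites of an enzyme panel across a genome
#'
#' Reads a (possibly gzipped) multi-FASTA assembly and scans each sequence
#' in turn, so memory use is bounded by one chromosome's hit list at a time
#' on top of the sequence set. Ambiguous-base runs (assembly gaps,
#' hard-masked regions) are recorded alongside the sites.
#'
#' @param genome path to a FASTA file, or a `DNAStringSet`.
#' @param panel an [EnzymePanel-class]; default the four-enzyme panel
#'   AluI + SaqAI + HinfI + MvaI.
#' @param bothStrands as in [scanSequence()].
#' @param verbose print per-chromosome progress to stderr.
#' @return a [CutSiteIndex-class].
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 5000), seed = 1)
#' scanGenome(g$genome, defaultEnzymes("AluI"))
#' @export
scanGenome <- function(genome,
                       panel = defaultEnzymes(c("AluI", "SaqAI", "HinfI", "MvaI")),
                       bothStrands = TRUE, verbose = FALSE) {
    if (!is(panel, "EnzymePanel"))
        stopValidation("panel must be an EnzymePanel")
    if (is.character(genome)) {
        if (!file.exists(genome))
            stopIO("FASTA file not found: ", genome)
        genome <- tryCatch(Biostrings::readDNAStringSet(genome),
                           error = function(e) stopIO("cannot read FASTA: ",
                                                      conditionMessage(e)))
        # FASTA headers may carry descriptions after the identifier
        names(genome) <- sub("\\s.*$", "", names(genome))
    }
    if (!is(genome, "DNAStringSet"))
        stopValidation("genome must be a FASTA path or a DNAStringSet")
    if (length(genome) == 0L)
        stopValidation("genome contains no sequences")
    if (anyDuplicated(names(genome)))
        stopValidation("duplicate sequence names in genome")
    sl <- stats::setNames(Biostrings::width(genome), names(genome))
    si <- GenomeInfoDb::Seqinfo(seqnames = names(genome), seqlengths = sl)

    grl <- vector("list", length(genome))
    gapl <- vector("list", length(genome))
    for (k in seq_along(genome)) {
        chrom <- names(genome)[k]
        s <- .asScannableDNA(genome[[k]])
        hits <- scanSequence(s, panel, bothStrands = bothStrands)
        motifLen <- unname(nchar(recognitionMotifs(panel))[hits$enzyme])
        grl[[k]] <- GRanges(rep(chrom, nrow(hits)),
                            IRanges(hits$pos + 1L, width = motifLen),
                            strand = hits$strand,
                            enzyme = hits$enzyme, seqinfo = si)
        nr <- .ambiguityRuns(s)
        gapl[[k]] <- GRanges(rep(chrom, length(nr)), nr, seqinfo = si)
        if (verbose)
            message(sprintf("%s: %d site(s)", chrom, length(grl[[k]])))
    }
    sites <- do.call(c, grl)
    gaps <- do.call(c, gapl)
    if (verbose)
        message(sprintf("total: %d site(s)", length(sites)))
    new("CutSiteIndex", sites = sites, gaps = gaps, panel = panel,
        bothStrands = bothStrands)
}
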