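#' @import methods
#' @importFrom BiocGenerics start end width strand sort
#' @importFrom S4Vectors mcols mcols<- DataFrame split
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo seqinfo<- Seqinfo
#'   seqlevelsInUse
NULL

# Condition helpers: validation errors carry their own class so callers
# (and the command-line dispatcher) can distinguish bad input from I/O
# failures or internal bugs.
stopValidation <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("silicoDigestValidationError", "error")))
}

stopIO <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("silicoDigestIOError", "error")))
}

#' EnzymePanel: a set of restriction enzymes with degenerate recognition motifs
#'
#' An `EnzymePanel` holds one or more restriction endonucleases, each defined
#' by a name, an IUPAC recognition motif (possibly degenerate, e.g. `CCWGG`
#' where W is A or T), and an optional cut offset — the 0-based position of
#' the top-strand cut within the recognition site. The cut offset is carried
#' as metadata only: fragment boundaries are placed at recognition-site start
#' coordinates by default (see [digestFragments()]), which is the convention
#' used when predicting chromatin fragmentation from recognition-site maps.
#'
#' @slot enzyme character vector of unique enzyme names.
#' @slot recognition IUPAC motif per enzyme (length >= 4).
#' @slot cutOffset integer cut position within the motif, or `NA` if unknown.
#' @seealso [EnzymePanel()], [defaultEnzymes()], [scanGenome()]
#' @exportClass EnzymePanel
setClass("EnzymePanel",
    representation(enzyme = "character",
                   recognition = "character",
                   cutOffset = "integer"))

setValidity("EnzymePanel", function(object) {
    n <- length(object@enzyme)
    if (length(object@recognition) != n || length(object@cutOffset) != n)
        return("enzyme, recognition and cutOffset must have equal length")
    if (n == 0L)
        return("an EnzymePanel must contain at least one enzyme")
    if (anyDuplicated(object@enzyme))
        return("enzyme names must be unique")
    for (i in seq_len(n)) {
        bad <- .invalidIupacPosition(object@recognition[i])
        if (!is.na(bad))
            return(sprintf("recognition motif of %s has a non-IUPAC character at position %d",
                           object@enzyme[i], bad))
        if (nchar(object@recognition[i]) < 4L)
            return(sprintf("recognition motif of %s is shorter than 4 bases",
                           object@enzyme[i]))
        off <- object@cutOffset[i]
        if (!is.na(off) && (off < 0L || off > nchar(object@recognition[i])))
            return(sprintf("cut offset of %s outside [0, motif length]",
                           object@enzyme[i]))
    }
    TRUE
})

#' CutSiteIndex: genome-wide recognition-site coordinates for an enzyme panel
#'
#' Produced by [scanGenome()]. Sites are stored as a `GRanges` (one range per
#' recognition-site occurrence, width equal to the motif length) whose
#' `seqinfo` carries the chromosome lengths; the enzyme responsible for each
#' hit is in `mcols(sites)$enzyme`. Runs of ambiguous bases (assembly gaps,
#' hard-masked sequence) found during scanning are kept in `gaps` so that
#' downstream statistics can use a gap-excluded denominator.
#'
#' @slot sites GRanges of recognition-site occurrences, sorted by
#'   (chromosome, start, enzyme name).
#' @slot gaps GRanges of N-runs (ambiguous-base runs) in the scanned genome.
#' @slot panel the [EnzymePanel-class] that was scanned.
#' @slot bothStrands logical; whether reverse-complement motifs of
#'   non-palindromic enzymes were also scanned.
#' @seealso [siteRanges()], [gapRanges()], [digestFragments()]
#' @exportClass CutSiteIndex
setClass("CutSiteIndex",
    representation(sites = "GRanges",
                   gaps = "GRanges",
                   panel = "EnzymePanel",
                   bothStrands = "logical"))

setValidity("CutSiteIndex", function(object) {
    s <- object@sites
    if (length(s)) {
        if (is.null(mcols(s)$enzyme))
            return("sites must carry an 'enzyme' metadata column")
        if (!all(mcols(s)$enzyme %in% object@panel@enzyme))
            return("sites refer to enzymes absent from the panel")
        sl <- seqlengths(s)
        if (any(is.na(sl)))
            return("seqlengths must be defined for all chromosomes")
        if (any(end(s) > sl[as.character(seqnames(s))]))
            return("a site extends beyond its chromosome")
        o <- order(as.integer(seqnames(s)), start(s), mcols(s)$enzyme)
        if (!identical(o, seq_along(s)))
            return("sites must be sorted by (chromosome, position, enzyme)")
    }
    TRUE
})

#' FragmentSet: the fragment intervals implied by a set of cut sites
#'
#' Fragments tile each chromosome exactly: the first fragment starts at the
#' chromosome 5' end, consecutive fragments abut, and the last fragment ends
#' at the chromosome length, so fragment lengths always sum to the assembly
#' length. Interior boundaries are recognition-site start coordinates.
#'
#' @slot fragments GRanges tiling every chromosome.
#' @slot gaps GRanges of ambiguous-base runs, propagated from the scan.
#' @seealso [digestFragments()], [fragmentRanges()], [refractoryRegions()]
#' @exportClass FragmentSet
setClass("FragmentSet",
    representation(fragments = "GRanges",
                   gaps = "GRanges"))

setValidity("FragmentSet", function(object) {
    fr <- object@fragments
    if (length(fr) == 0L)
        return("a FragmentSet must contain at least one fragment")
    sl <- seqlengths(fr)
    if (any(is.na(sl[seqlevelsInUse(fr)])))
        return("seqlengths must be defined for all chromosomes in use")
    if (any(width(fr) <= 0L))
        return("zero-length fragments are not allowed")
    for (chr in seqlevelsInUse(fr)) {
        f <- fr[seqnames(fr) == chr]
        f <- f[order(start(f))]
        if (start(f)[1L] != 1L)
            return(sprintf("%s: first fragment does not start at the chromosome end", chr))
        if (end(f)[length(f)] != sl[[chr]])
            return(sprintf("%s: last fragment does not end at the chromosome length", chr))
        if (length(f) > 1L &&
            !all(start(f)[-1L] == end(f)[-length(f)] + 1L))
            return(sprintf("%s: fragments do not abut", chr))
        if (sum(as.numeric(width(f))) != as.numeric(sl[[chr]]))
            return(sprintf("%s: fragment lengths do not sum to the chromosome length", chr))
    }
    TRUE
})

#' DigestReport: aggregate statistics of an in silico digestion
#'
#' Headline statistics of a digest: total recognition sites, fragment-size
#' histogram, mean/median fragment length, the fraction of the genome falling
#' in fragments shorter than a size threshold (reported under both a
#' full-assembly and a gap-excluded denominator), and the refractory regions —
#' fragments remaining strictly longer than the refractory cutoff. Fragments
#' exactly at the threshold belong to neither headline class and are counted
#' separately in `atThreshold`.
#'
#' @slot genomeLength total assembly length in bp.
#' @slot totalSites number of recognition-site occurrences (all enzymes).
#' @slot threshold size threshold in bp for the "fraction below" statistic.
#' @slot meanLength,medianLength fragment-length summary in bp.
#' @slot fractionBelow named numeric: fraction of the genome in fragments
#'   shorter than `threshold`, under `assembly` and `nonGap` denominators.
#' @slot atThreshold count of fragments whose length equals `threshold`.
#' @slot histogram data.frame of binned fragment counts (last bin open-ended).
#' @slot refractory GRanges of fragments longer than the refractory cutoff.
#' @seealso [digestReport()], [genomeFractionBelow()], [refractoryRegions()]
#' @exportClass DigestReport
setClass("DigestReport",
    representation(genomeLength = "numeric",
                   totalSites = "numeric",
                   threshold = "numeric",
                   meanLength = "numeric",
                   medianLength = "numeric",
                   fractionBelow = "numeric",
                   atThreshold = "numeric",
                   histogram = "data.frame",
                   refractory = "GRanges"))

setValidity("DigestReport", function(object) {
    if (any(object@fractionBelow < 0) || any(object@fractionBelow > 1))
        return("fractionBelow must lie in [0, 1]")
    TRUE
})
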