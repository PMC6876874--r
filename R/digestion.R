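#' @include AllClasses.R motifs.R
NULL

#' Fragment intervals implied by cut positions on one chromosome
#'
#' Cutting a chromosome of length `L` at `n` distinct interior positions
#' yields `n + 1` half-open fragments `[0, p1), [p1, p2), ..., [pn, L)`.
#' Boundaries are recognition-site start coordinates; a site at coordinate 0
#' and duplicate coordinates are dropped so no zero-length fragment can
#' arise, and fragment lengths always sum to the chromosome length.
#'
#' @param chromLength chromosome length in bp.
#' @param sites sorted 0-based cut coordinates (duplicates tolerated).
#' @return an `IRanges` of fragments (1-based closed, as usual in
#'   Bioconductor); widths are the fragment lengths.
#' @examples
#' width(fragmentsFromSites(100, c(20, 50)))  # 20 30 50
#' @export
fragmentsFromSites <- function(chromLength, sites = integer(0)) {
    chromLength <- as.numeric(chromLength)
    if (length(chromLength) != 1L || is.na(chromLength) || chromLength < 1)
        stopValidation("chromLength must be a single positive number")
    sites <- as.numeric(sites)
    if (any(is.na(sites)))
        stopValidation("cut positions must not be NA")
    if (any(sites < 0) || any(sites >= chromLength))
        stopValidation("cut positions must lie in [0, chromLength)")
    if (is.unsorted(sites))
        stopValidation("cut positions must be sorted")
    bounds <- unique(sites[sites > 0])
    starts0 <- c(0, bounds)
    ends0 <- c(bounds, chromLength)
    IRanges(start = starts0 + 1, end = ends0)
}

#' Derive the fragment set of a digestion
#'
#' Turns the recognition-site coordinates of a [CutSiteIndex-class] into the
#' fragment intervals they imply on every chromosome. Sites of all enzymes
#' are pooled and deduplicated; each distinct site start becomes a fragment
#' boundary. Chromosomes with no site yield a single full-length fragment.
#'
#' @param index a [CutSiteIndex-class] from [scanGenome()].
#' @param useCutOffsets place boundaries at the chemical cut position
#'   (site start + enzyme cut offset) instead of the recognition-site start.
#'   Requires cut offsets for every enzyme in the panel.
#' @return a [FragmentSet-class].
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 5000), seed = 1)
#' fs <- digestFragments(scanGenome(g$genome, defaultEnzymes("AluI")))
#' sum(width(fragmentRanges(fs))) == 5000
#' @export
digestFragments <- function(index, useCutOffsets = FALSE) {
    if (!is(index, "CutSiteIndex"))
        stopValidation("index must be a CutSiteIndex")
    s <- index@sites
    pos0 <- start(s) - 1L
    if (useCutOffsets) {
        offs <- cutOffsets(index@panel)
        if (any(is.na(offs[mcols(s)$enzyme])))
            stopValidation("useCutOffsets requires a cut offset for every enzyme")
        pos0 <- pos0 + offs[mcols(s)$enzyme]
    }
    si <- seqinfo(s)
    sl <- seqlengths(si)
    frl <- lapply(seqlevels(si), function(chr) {
        p <- sort(unique(pos0[as.character(seqnames(s)) == chr]))
        p <- p[p < sl[[chr]]]   # cut-offset mode may push a boundary past the end
        ir <- fragmentsFromSites(sl[[chr]], p)
        GRanges(rep(chr, length(ir)), ir, seqinfo = si)
    })
    new("FragmentSet", fragments = do.call(c, frl), gaps = index@gaps)
}

#' Fraction of the genome in fragments below a size threshold
#'
#' The headline digestibility statistic: the summed length of all fragments
#' strictly shorter than `threshold`, divided by either the full assembly
#' length (`"assembly"`, the default) or the assembly length minus
#' ambiguous-base runs (`"nonGap"`). Fragments exactly at the threshold are
#' excluded from the numerator (strict inequality).
#'
#' @param fragset a [FragmentSet-class].
#' @param threshold size threshold in bp (default 1000).
#' @param denominator `"assembly"` or `"nonGap"`.
#' @return a proportion in \eqn{[0, 1]}.
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 1e5), seed = 1)
#' fs <- digestFragments(scanGenome(g$genome, defaultEnzymes("AluI")))
#' genomeFractionBelow(fs, 1000)
#' @export
genomeFractionBelow <- function(fragset, threshold = 1000,
                                denominator = c("assembly", "nonGap")) {
    if (!is(fragset, "FragmentSet"))
        stopValidation("fragset must be a FragmentSet")
    if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
        stopValidation("threshold must be a single positive number")
    denominator <- match.arg(denominator)
    w <- as.numeric(width(fragset@fragments))
    num <- sum(w[w < threshold])
    den <- sum(as.numeric(seqlengths(fragset@fragments)[
        seqlevelsInUse(fragset@fragments)]))
    if (denominator == "nonGap")
        den <- den - sum(as.numeric(width(IRanges::reduce(fragset@gaps))))
    if (den <= 0)
        stopValidation("denominator is not positive")
    num / den
}

#' Regions refractory to digestion
#'
#' Fragments remaining strictly longer than `minLength` after the digest:
#' the stretches of genome an enzyme panel cannot break into ChIP-sized
#' pieces. In real assemblies these are dominated by assembly gaps (N runs
#' contain no recognition site by construction), blacklisted regions and
#' repeats; [classifyRegions()] attaches those labels.
#'
#' @param fragset a [FragmentSet-class].
#' @param minLength refractory size cutoff in bp (default 1000).
#' @return a `GRanges` in BED-sortable order with a `length` metadata column.
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 1e5), seed = 1)
#' fs <- digestFragments(scanGenome(g$genome, defaultEnzymes("MvaI")))
#' refractoryRegions(fs, minLength = 1000)
#' @export
refractoryRegions <- function(fragset, minLength = 1000) {
    if (!is(fragset, "FragmentSet"))
        stopValidation("fragset must be a FragmentSet")
    if (length(minLength) != 1L || !is.finite(minLength) || minLength <= 0)
        stopValidation("minLength must be a single positive number")
    r <- fragset@fragments[width(fragset@fragments) > minLength]
    mcols(r)$length <- width(r)
    r
}

#' Expected distance between consecutive recognition sites
#'
#' Under an i.i.d. base model with composition \eqn{p = (p_A, p_C, p_G,
#' p_T)}, the probability that a given position starts a recognition site of
#' a panel is, by linearity of expectation (edge effects ignored),
#' \deqn{d = \sum_{e} \sum_{m \in expand(e)} \prod_{j} p_{m_j},}
#' and the expected spacing between consecutive sites is \eqn{1/d}. A single
#' fully specified 4-bp cutter under uniform composition gives
#' \eqn{1/(1/4)^4 = 256} bp; the four-enzyme default panel gives
#' \eqn{512/7 \approx 73} bp.
#'
#' @param panel an [EnzymePanel-class], or a character vector of IUPAC motifs.
#' @param baseComposition probabilities for A, C, G, T (must sum to 1).
#' @return expected spacing in bp.
#' @examples
#' expectedSiteSpacing("AGCT")  # 256
#' expectedSiteSpacing(defaultEnzymes(c("AluI", "SaqAI", "HinfI", "MvaI")))
#' @export
expectedSiteSpacing <- function(panel,
                                baseComposition = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25)) {
    motifs <- if (is(panel, "EnzymePanel")) panel@recognition
              else vapply(panel, .checkMotif, character(1))
    p <- baseComposition
    if (length(p) != 4L || any(is.na(p)) || any(p < 0))
        stopValidation("baseComposition must be 4 non-negative probabilities")
    if (is.null(names(p))) names(p) <- c("A", "C", "G", "T")
    if (!setequal(names(p), c("A", "C", "G", "T")))
        stopValidation("baseComposition must be named with A, C, G, T")
    if (abs(sum(p) - 1) > 1e-9)
        stopValidation("baseComposition must sum to 1")
    density <- sum(vapply(motifs, function(m) {
        sum(vapply(expandMotif(m), function(word) {
            prod(p[strsplit(word, "", fixed = TRUE)[[1L]]])
        }, numeric(1)))
    }, numeric(1)))
    if (density <= 0)
        stopValidation("no motif can occur under this base composition")
    1 / density
}

#' Fragment-size histogram
#'
#' Counts fragment lengths into the half-open bins `[e1, e2), [e2, e3), ...`
#' plus an open-ended overflow bin `[e_last, Inf)`. Bin counts (including
#' overflow) sum to the number of fragments when no length falls below the
#' first edge; any such lengths are reported in the `underflow` attribute.
#'
#' @param fragset a [FragmentSet-class], or a numeric vector of lengths.
#' @param binEdges strictly increasing bin edges in bp.
#' @return data.frame with columns `lower`, `upper`, `count`; the attribute
#'   `underflow` counts lengths below the first edge.
#' @examples
#' fragmentSizeHistogram(c(10, 20, 3000), binEdges = c(0, 100, 1000))
#' @export
fragmentSizeHistogram <- function(fragset,
                                  binEdges = c(seq(0, 1000, by = 100),
                                               2000, 5000, 10000)) {
    lens <- if (is(fragset, "FragmentSet"))
        as.numeric(width(fragset@fragments)) else as.numeric(fragset)
    if (length(binEdges) < 2L || any(diff(binEdges) <= 0))
        stopValidation("binEdges must be at least two strictly increasing values")
    edges <- c(binEdges, Inf)
    counts <- vapply(seq_len(length(edges) - 1L), function(i) {
        sum(lens >= edges[i] & lens < edges[i + 1L])
    }, numeric(1))
    out <- data.frame(lower = edges[-length(edges)],
                      upper = edges[-1L],
                      count = counts)
    attr(out, "underflow") <- sum(lens < edges[1L])
    out
}

#' Assemble a digestion report
#'
#' Composes the digest statistics into one [DigestReport-class]: total site
#' count, fragment-length mean/median and histogram, the fraction of the
#' genome in fragments shorter than `threshold` under both denominators, the
#' count of fragments exactly at the threshold, and the refractory regions
#' (fragments strictly longer than `minRefractory`).
#'
#' @param index a [CutSiteIndex-class].
#' @param fragset optionally, a precomputed [FragmentSet-class] for `index`.
#' @param threshold size threshold in bp for the fraction-below statistic.
#' @param minRefractory refractory region cutoff in bp.
#' @param binEdges histogram bin edges, as in [fragmentSizeHistogram()].
#' @return a [DigestReport-class].
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 1e5), seed = 1)
#' digestReport(scanGenome(g$genome, defaultEnzymes("AluI")))
#' @export
digestReport <- function(index, fragset = digestFragments(index),
                         threshold = 1000, minRefractory = 1000,
                         binEdges = c(seq(0, 1000, by = 100),
                                      2000, 5000, 10000)) {
    if (!is(index, "CutSiteIndex"))
        stopValidation("index must be a CutSiteIndex")
    w <- as.numeric(width(fragset@fragments))
    new("DigestReport",
        genomeLength = sum(as.numeric(seqlengths(fragset@fragments)[
            seqlevelsInUse(fragset@fragments)])),
        totalSites = as.numeric(length(index@sites)),
        threshold = threshold,
        meanLength = mean(w),
        medianLength = stats::median(w),
        fractionBelow = c(
            assembly = genomeFractionBelow(fragset, threshold, "assembly"),
            nonGap = genomeFractionBelow(fragset, threshold, "nonGap")),
        atThreshold = sum(w == threshold),
        histogram = fragmentSizeHistogram(fragset, binEdges),
        refractory = refractoryRegions(fragset, minRefractory))
}
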