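#' @include AllClasses.R motifs.R
NULL

#' Simulate a genome with known gap runs and planted recognition sites
#'
#' Generates i.i.d. background sequence of a configurable base composition,
#' overwrites the requested intervals with N runs (emulating assembly gaps),
#' and finally plants concrete recognition-site occurrences at known
#' coordinates. Planting happens last so background chance occurrences of
#' the motifs remain in place and countable — the truth table records where
#' sites were planted, not every site present. Fully deterministic for a
#' given seed.
#'
#' @param lengths named vector of chromosome lengths in bp.
#' @param baseComposition probabilities for A, C, G, T (sum to 1).
#' @param gaps `NULL`, a `GRanges`, or a data.frame with columns `chrom`,
#'   `start`, `end` (0-based half-open) of N runs to write.
#' @param plant `NULL` or a data.frame with columns `chrom`, `pos` (0-based
#'   start) and `enzyme` (a panel name) of sites to plant. A degenerate
#'   motif is planted as one of its concrete expansions, drawn under the
#'   same seed. Planted sites must not overlap gap runs.
#' @param panel [EnzymePanel-class] resolving the `enzyme` column of `plant`.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a list with `genome` (`DNAStringSet`), `planted` (`GRanges` with
#'   an `enzyme` metadata column) and `gaps` (`GRanges`).
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 1000),
#'                     plant = data.frame(chrom = "chr1", pos = 100,
#'                                        enzyme = "AluI"),
#'                     seed = 7)
#' scanSequence(g$genome[["chr1"]], defaultEnzymes("AluI"))
#' @export
simulateGenome <- function(lengths = c(chr1 = 10000),
                           baseComposition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                           gaps = NULL, plant = NULL,
                           panel = defaultEnzymes(), seed = NULL) {
    if (is.null(names(lengths)) || any(names(lengths) == ""))
        stopValidation("lengths must be a named vector of chromosome lengths")
    if (any(lengths < 1))
        stopValidation("chromosome lengths must be positive")
    p <- baseComposition
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
        stopValidation("baseComposition must be 4 probabilities summing to 1")
    if (is.null(names(p))) names(p) <- c("A", "C", "G", "T")
    si <- GenomeInfoDb::Seqinfo(seqnames = names(lengths),
                                seqlengths = unname(lengths))
    gapGR <- if (is.null(gaps)) GRanges(seqinfo = si)
             else if (is(gaps, "GRanges")) gaps
             else GRanges(as.character(gaps$chrom),
                          IRanges(as.numeric(gaps$start) + 1,
                                  as.numeric(gaps$end)))
    if (length(gapGR)) {
        if (!all(as.character(seqnames(gapGR)) %in% names(lengths)) ||
            any(end(gapGR) > lengths[as.character(seqnames(gapGR))]))
            stopValidation("a gap run extends beyond its chromosome")
        gapGR <- GRanges(as.character(seqnames(gapGR)),
                         IRanges::ranges(gapGR), seqinfo = si)
    } else gapGR <- GRanges(seqinfo = si)

    plantGR <- GRanges(seqinfo = si)
    if (!is.null(plant) && nrow(plant) > 0) {
        motifs <- recognitionMotifs(panel)
        if (!all(plant$enzyme %in% names(motifs)))
            stopValidation("plant refers to enzymes absent from the panel")
        wid <- unname(nchar(motifs[plant$enzyme]))
        if (!all(as.character(plant$chrom) %in% names(lengths)) ||
            any(as.numeric(plant$pos) + wid > lengths[as.character(plant$chrom)]))
            stopValidation("a planted site extends beyond its chromosome")
        plantGR <- GRanges(as.character(plant$chrom),
                           IRanges(as.numeric(plant$pos) + 1, width = wid),
                           enzyme = as.character(plant$enzyme), seqinfo = si)
        if (length(gapGR) &&
            any(IRanges::overlapsAny(plantGR, gapGR, ignore.strand = TRUE)))
            stopValidation("planted sites must not overlap gap runs")
    }

    if (!is.null(seed)) set.seed(as.integer(seed))
    seqs <- lapply(names(lengths), function(chr) {
        L <- lengths[[chr]]
        chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                        prob = p[c("A", "C", "G", "T")])
        g <- gapGR[seqnames(gapGR) == chr]
        for (i in seq_along(g))
            chars[start(g)[i]:end(g)[i]] <- "N"
        pl <- plantGR[seqnames(plantGR) == chr]
        for (i in seq_along(pl)) {
            words <- expandMotif(recognitionMotifs(panel)[[mcols(pl)$enzyme[i]]])
            word <- if (length(words) == 1L) words else sample(words, 1L)
            chars[start(pl)[i]:end(pl)[i]] <- strsplit(word, "", fixed = TRUE)[[1L]]
        }
        paste(chars, collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(lengths)
    list(genome = genome, planted = plantGR, gaps = gapGR)
}

#' Simulate paired-end templates with known per-class length distributions
#'
#' Draws template intervals whose midpoints fall inside the intervals of a
#' labelled class track and whose lengths follow a per-class distribution,
#' so that [observedFragmentLengths()] can be checked against generator
#' truth. The total of `n` templates is split across classes in proportion
#' to merged class length; template midpoints are uniform within the class.
#'
#' @param track labelled `GRanges` (labels in `mcols()$name`).
#' @param lengthDists named list, one entry per class label: either a single
#'   number (constant template length) or a `function(n)` returning `n`
#'   lengths.
#' @param n total number of templates.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param readLength nominal read length for the BEDPE representation.
#' @return a list with `templates` (`GRanges` with a `label` metadata
#'   column), `truth` (data.frame of per-class generating `n` and median)
#'   and `readLength`.
#' @export
simulateFragmentsBedpe <- function(track, lengthDists, n, seed = NULL,
                                   readLength = 50L) {
    classes <- .splitByLabel(track, character(0))
    if (!all(names(classes) %in% names(lengthDists)))
        stopValidation("lengthDists must cover every class label")
    if (n < 0)
        stopValidation("n must be non-negative")
    if (!is.null(seed)) set.seed(as.integer(seed))
    merged <- lapply(classes, IRanges::reduce, ignore.strand = TRUE)
    clen <- vapply(merged, function(m) sum(as.numeric(width(m))), numeric(1))
    if (any(clen == 0))
        stopValidation("every class must have positive length")
    # deterministic proportional allocation of n across classes
    alloc <- diff(c(0, floor(cumsum(clen / sum(clen)) * n)))
    names(alloc) <- names(classes)

    out <- list(); truth <- list()
    for (lab in names(classes)) {
        k <- alloc[[lab]]
        ld <- lengthDists[[lab]]
        lens <- if (k == 0L) numeric(0)
                else if (is.function(ld)) as.numeric(ld(k))
                else rep(as.numeric(ld), k)
        if (any(lens < 1))
            stopValidation("template lengths must be >= 1")
        m <- merged[[lab]]
        if (k > 0L) {
            # pick an interval weighted by length, then a uniform offset
            iv <- sample(length(m), k, replace = TRUE,
                         prob = as.numeric(width(m)))
            mids <- start(m)[iv] +
                floor(stats::runif(k) * width(m)[iv])  # 1-based midpoint
            chrom <- as.character(seqnames(m))[iv]
            sl <- seqlengths(m)[chrom]
            st <- pmax(1, mids - floor(lens / 2))
            en <- st + lens - 1
            over <- which(!is.na(sl) & en > sl)
            if (length(over)) {   # shift left rather than truncate
                en[over] <- sl[over]
                st[over] <- pmax(1, en[over] - lens[over] + 1)
            }
            out[[lab]] <- GRanges(chrom, IRanges(st, en), label = lab,
                                  seqinfo = seqinfo(track))
        }
        truth[[lab]] <- data.frame(label = lab, n = k,
                                   median_length = if (k) stats::median(lens)
                                                   else NA_real_,
                                   stringsAsFactors = FALSE)
    }
    templates <- if (length(out)) do.call(c, unname(out))
                 else GRanges(seqinfo = seqinfo(track))
    list(templates = sort(templates, ignore.strand = TRUE),
         truth = do.call(rbind, truth), readLength = readLength)
}
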