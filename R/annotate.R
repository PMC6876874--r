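#' @include AllClasses.R digestion.R
#' @importFrom IRanges overlapsAny
#' @importFrom GenomicRanges resize
NULL

# Warn (once per track) about chromosome names present in the query but
# absent from the track; silent renaming (chr1 vs 1) is never attempted.
.warnChromMismatch <- function(query, track, trackName) {
    missing <- setdiff(seqlevelsInUse(query), GenomeInfoDb::seqlevels(track))
    if (length(missing))
        warning(sprintf("track '%s' lacks chromosome(s): %s",
                        trackName, paste(missing, collapse = ", ")),
                call. = FALSE)
}

# Split a labelled track (labels in mcols()$name) into a named list of
# GRanges, dropping excluded labels. Exclusions match either the full label
# or its leading token before "_" (so "14" drops "14_Repetitive/CNV").
.splitByLabel <- function(track, excludeLabels = character(0)) {
    if (is.null(mcols(track)$name))
        stopValidation("track must carry labels in its 'name' metadata column")
    lab <- as.character(mcols(track)$name)
    keep <- !(lab %in% excludeLabels |
              sub("_.*$", "", lab) %in% excludeLabels)
    track <- track[keep]
    lab <- lab[keep]
    if (length(track) == 0L)
        stopValidation("no class intervals remain after exclusions")
    split(track, factor(lab, levels = unique(lab)))
}

#' Classify refractory regions against annotation tracks
#'
#' A region receives a track's label when it overlaps any interval of that
#' track by at least 1 bp. Labels are not mutually exclusive — a region
#' spanning both a gap and a repeat carries both — so per-label counts can
#' sum to more than the number of labelled regions. Regions matching no
#' track are the "unlabelled" (unique) set: genome that resists digestion
#' without an annotation excuse.
#'
#' @param regions a `GRanges` of regions (e.g. from [refractoryRegions()]).
#' @param tracks a named list of `GRanges` annotation tracks
#'   (e.g. `list(gap = ..., blacklist = ..., repeat_ = ...)`).
#' @return a list with `regions` (the input with a comma-joined `labels`
#'   metadata column, `NA` where unlabelled) and `summary` (data.frame of
#'   per-label counts plus `unlabelled` and `total` rows).
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
#' trk <- list(gap = GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 600)))
#' classifyRegions(r, trk)$summary
#' @export
classifyRegions <- function(regions, tracks) {
    if (!is(regions, "GRanges"))
        stopValidation("regions must be a GRanges")
    if (!is.list(tracks) || length(tracks) == 0L ||
        is.null(names(tracks)) || any(names(tracks) == ""))
        stopValidation("tracks must be a non-empty named list of GRanges")
    hitMat <- vapply(names(tracks), function(nm) {
        trk <- tracks[[nm]]
        if (!is(trk, "GRanges"))
            stopValidation("track '", nm, "' is not a GRanges")
        .warnChromMismatch(regions, trk, nm)
        # disjoint seqlevels already produce the explicit warning above
        suppressWarnings(IRanges::overlapsAny(regions, trk,
                                              ignore.strand = TRUE))
    }, logical(length(regions)))
    hitMat <- matrix(hitMat, nrow = length(regions),
                     dimnames = list(NULL, names(tracks)))
    labels <- apply(hitMat, 1L, function(row) {
        if (any(row)) paste(colnames(hitMat)[row], collapse = ",")
        else NA_character_
    })
    out <- regions
    mcols(out)$labels <- labels
    perLabel <- colSums(hitMat)
    summary <- data.frame(
        label = c(names(perLabel), "unlabelled", "total"),
        count = c(unname(perLabel), sum(is.na(labels)), length(regions)),
        stringsAsFactors = FALSE)
    list(regions = out, summary = summary)
}

#' Recognition-site density per annotation class
#'
#' Computes, for every class label of a segmentation track, the number of
#' recognition sites whose start coordinate falls inside the class and the
#' density in sites per kb over the merged class length. Used to ask whether
#' an enzyme panel covers all chromatin states evenly.
#'
#' @param index a [CutSiteIndex-class].
#' @param track a `GRanges` with class labels in `mcols()$name`
#'   (e.g. a chromHMM segmentation read with [readBedTrack()]).
#' @param excludeLabels labels to drop before computing (matched against the
#'   full label or its leading token before `_`, so `c("14", "15")` drops
#'   the repeat-associated chromHMM states).
#' @return data.frame with columns `label`, `class_length` (merged bp),
#'   `sites` and `density_per_kb` (= 1000 * sites / class_length).
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 5e4), seed = 1)
#' idx <- scanGenome(g$genome, defaultEnzymes("AluI"))
#' trk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e4), name = "all")
#' siteDensityPerClass(idx, trk)
#' @export
siteDensityPerClass <- function(index, track, excludeLabels = character(0)) {
    if (!is(index, "CutSiteIndex"))
        stopValidation("index must be a CutSiteIndex")
    classes <- .splitByLabel(track, excludeLabels)
    pts <- GenomicRanges::resize(index@sites, width = 1L, fix = "start")
    .warnChromMismatch(pts, track, "classes")
    res <- lapply(names(classes), function(lab) {
        merged <- IRanges::reduce(classes[[lab]], ignore.strand = TRUE)
        len <- sum(as.numeric(width(merged)))
        n <- sum(IRanges::overlapsAny(pts, merged, ignore.strand = TRUE))
        data.frame(label = lab, class_length = len, sites = n,
                   density_per_kb = 1000 * n / len,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

# Fragment/template midpoints as width-1 GRanges.
.midpoints <- function(gr) {
    GRanges(seqnames(gr),
            IRanges(IRanges::mid(IRanges::ranges(gr)), width = 1L),
            seqinfo = seqinfo(gr))
}

# Shared midpoint-assignment summary over a labelled track.
.lengthsPerClass <- function(gr, track, excludeLabels) {
    classes <- .splitByLabel(track, excludeLabels)
    mids <- .midpoints(gr)
    w <- as.numeric(width(gr))
    res <- lapply(names(classes), function(lab) {
        merged <- IRanges::reduce(classes[[lab]], ignore.strand = TRUE)
        inside <- IRanges::overlapsAny(mids, merged, ignore.strand = TRUE)
        lens <- w[inside]
        enclosing <- FALSE
        if (length(lens) == 0L) {
            # class smaller than any fragment: report the fragments that
            # enclose it rather than an empty summary
            lens <- w[IRanges::overlapsAny(gr, merged, ignore.strand = TRUE)]
            enclosing <- TRUE
        }
        data.frame(label = lab, n = sum(inside),
                   mean_length = if (length(lens)) mean(lens) else NA_real_,
                   median_length = if (length(lens)) stats::median(lens) else NA_real_,
                   enclosing = enclosing, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Predicted fragment lengths per annotation class
#'
#' Assigns each in silico fragment to every class its midpoint falls in and
#' summarises fragment lengths per class. Midpoint assignment keeps the
#' per-class counts a partition whenever the classes partition the genome.
#' A class too small to contain any midpoint is summarised by its enclosing
#' fragments (flagged in the `enclosing` column).
#'
#' @param fragset a [FragmentSet-class].
#' @param track labelled `GRanges` as in [siteDensityPerClass()].
#' @param excludeLabels as in [siteDensityPerClass()].
#' @return data.frame with columns `label`, `n` (fragments assigned),
#'   `mean_length`, `median_length`, `enclosing`.
#' @export
fragmentLengthPerClass <- function(fragset, track,
                                   excludeLabels = character(0)) {
    if (!is(fragset, "FragmentSet"))
        stopValidation("fragset must be a FragmentSet")
    .lengthsPerClass(fragset@fragments, track, excludeLabels)
}

#' Observed template lengths per annotation class
#'
#' Summarises sequenced template (fragment) lengths per class, assigning
#' each template to the class containing its midpoint. Templates come from
#' paired-end data as the outermost interval of each read pair
#' ([readBedpe()]) or from a 6-column BED of template intervals.
#'
#' @param templates a `GRanges` of template intervals, or a path to a BEDPE
#'   file (passed to [readBedpe()]).
#' @param track labelled `GRanges` as in [siteDensityPerClass()].
#' @param excludeLabels as in [siteDensityPerClass()].
#' @return data.frame as in [fragmentLengthPerClass()].
#' @export
observedFragmentLengths <- function(templates, track,
                                    excludeLabels = character(0)) {
    if (is.character(templates))
        templates <- readBedpe(templates)
    if (!is(templates, "GRanges"))
        stopValidation("templates must be a GRanges or a BEDPE path")
    .lengthsPerClass(templates, track, excludeLabels)
}
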