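#' @include AllClasses.R motifs.R digestion.R annotate.R io.R
NULL

# Write a run manifest: configuration, package version, input checksums.
.writeManifest <- function(outDir, config, inputs = character(0)) {
    lines <- c(sprintf("package\tSilicoDigest %s",
                       as.character(utils::packageVersion("SilicoDigest"))),
               vapply(names(config), function(k) {
                   sprintf("%s\t%s", k, paste(config[[k]], collapse = ","))
               }, character(1)))
    inputs <- inputs[file.exists(inputs)]
    if (length(inputs))
        lines <- c(lines, sprintf("md5:%s\t%s", basename(inputs),
                                  unname(tools::md5sum(inputs))))
    writeLines(lines, file.path(outDir, "manifest.tsv"))
}

.reportAsKeyValue <- function(report) {
    data.frame(
        key = c("genome_length_bp", "total_sites", "mean_fragment_bp",
                "median_fragment_bp", "fraction_below_assembly",
                "fraction_below_nongap", "threshold_bp",
                "fragments_at_threshold", "refractory_regions"),
        value = c(report@genomeLength, report@totalSites, report@meanLength,
                  report@medianLength, report@fractionBelow[["assembly"]],
                  report@fractionBelow[["nonGap"]], report@threshold,
                  report@atThreshold, length(report@refractory)),
        stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Run a full in silico digest of a genome
#'
#' End-to-end orchestration: scan the genome for the panel's recognition
#' sites, derive fragments, and assemble a [DigestReport-class]. When
#' `outDir` is given, writes `sites.bed`, `fragments.bed`,
#' `refractory.bed`, `histogram.tsv`, `report.tsv` and a `manifest.tsv`
#' recording the configuration and input checksums.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param enzymes registry enzyme names (ignored when `panel` is given).
#' @param panel an [EnzymePanel-class] overriding `enzymes`.
#' @param threshold,minRefractory,binEdges passed to [digestReport()].
#' @param bothStrands passed to [scanGenome()].
#' @param outDir optional output directory (created if absent).
#' @param verbose per-chromosome progress to stderr.
#' @return a list with `index` ([CutSiteIndex-class]), `fragments`
#'   ([FragmentSet-class]) and `report` ([DigestReport-class]).
#' @examples
#' g <- simulateGenome(lengths = c(chr1 = 5e4), seed = 1)
#' res <- runDigest(g$genome, enzymes = c("AluI", "SaqAI"))
#' res$report
#' @export
runDigest <- function(genome, enzymes = c("AluI", "SaqAI", "HinfI", "MvaI"),
                      panel = defaultEnzymes(enzymes), threshold = 1000,
                      minRefractory = 1000,
                      binEdges = c(seq(0, 1000, by = 100), 2000, 5000, 10000),
                      bothStrands = TRUE, outDir = NULL, verbose = FALSE) {
    index <- scanGenome(genome, panel, bothStrands = bothStrands,
                        verbose = verbose)
    fragset <- digestFragments(index)
    report <- digestReport(index, fragset, threshold = threshold,
                           minRefractory = minRefractory, binEdges = binEdges)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeSitesBed(index, file.path(outDir, "sites.bed"))
        fr <- fragmentRanges(fragset)
        mcols(fr)$length <- width(fr)
        writeRegionsBed(fr, file.path(outDir, "fragments.bed"), "length")
        writeRegionsBed(report@refractory,
                        file.path(outDir, "refractory.bed"), "length")
        .writeTsv(report@histogram, file.path(outDir, "histogram.tsv"))
        .writeTsv(.reportAsKeyValue(report), file.path(outDir, "report.tsv"))
        .writeManifest(outDir,
                       list(enzymes = enzymeNames(panel),
                            threshold = threshold,
                            minRefractory = minRefractory,
                            bothStrands = bothStrands),
                       if (is.character(genome)) genome else character(0))
    }
    list(index = index, fragments = fragset, report = report)
}

#' Classify refractory regions against gap/blacklist/repeat tracks
#'
#' Orchestrates [refractoryRegions()] + [classifyRegions()]: regions are
#' taken from a [FragmentSet-class] (or passed directly as a `GRanges`),
#' tracks are `GRanges` or BED paths. With `outDir`, writes the labelled
#' regions as BED (comma-joined labels in the name field) and the
#' classification summary as TSV.
#'
#' @param regions a [FragmentSet-class], [DigestReport-class] or `GRanges`.
#' @param tracks named list of `GRanges` or BED file paths.
#' @param minLength refractory cutoff when `regions` is a FragmentSet.
#' @param outDir optional output directory.
#' @return the list from [classifyRegions()].
#' @export
runRefractory <- function(regions, tracks, minLength = 1000, outDir = NULL) {
    if (is(regions, "FragmentSet"))
        regions <- refractoryRegions(regions, minLength)
    else if (is(regions, "DigestReport"))
        regions <- regions@refractory
    tracks <- lapply(tracks, function(t) {
        if (is.character(t)) readBedTrack(t) else t
    })
    cls <- classifyRegions(regions, tracks)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeRegionsBed(cls$regions,
                        file.path(outDir, "refractory_labeled.bed"), "labels")
        .writeTsv(cls$summary, file.path(outDir, "classification.tsv"))
        .writeManifest(outDir, list(minLength = minLength,
                                    tracks = names(tracks)))
    }
    cls
}

#' Per-chromatin-state digestion metrics
#'
#' Orchestrates [siteDensityPerClass()] and [fragmentLengthPerClass()] over
#' a chromatin-state (or any labelled) segmentation, optionally adding
#' observed template-length summaries from a BEDPE file. Repeat-associated
#' chromHMM states are excluded by default (`excludeLabels = c("14", "15")`,
#' matched against the state label or its leading number).
#'
#' @param index a [CutSiteIndex-class].
#' @param track labelled `GRanges` or BED path (state in column 4).
#' @param fragset optional precomputed [FragmentSet-class] for `index`.
#' @param bedpe optional BEDPE path or template `GRanges`.
#' @param excludeLabels states to drop (default the repeat-associated pair).
#' @param outDir optional output directory.
#' @return data.frame with one row per state: site density, predicted
#'   fragment-length summaries and, when `bedpe` is given, observed medians.
#' @export
runStatewise <- function(index, track, fragset = digestFragments(index),
                         bedpe = NULL, excludeLabels = c("14", "15"),
                         outDir = NULL) {
    if (is.character(track))
        track <- readBedTrack(track)
    dens <- siteDensityPerClass(index, track, excludeLabels)
    insil <- fragmentLengthPerClass(fragset, track, excludeLabels)
    out <- merge(dens,
                 stats::setNames(insil, c("label", "n_fragments",
                                          "mean_fragment_bp",
                                          "median_fragment_bp", "enclosing")),
                 by = "label", sort = FALSE)
    if (!is.null(bedpe)) {
        obs <- observedFragmentLengths(bedpe, track, excludeLabels)
        out <- merge(out,
                     stats::setNames(obs[c("label", "n", "median_length")],
                                     c("label", "n_templates",
                                       "median_observed_bp")),
                     by = "label", sort = FALSE)
    }
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        .writeTsv(out, file.path(outDir, "statewise.tsv"))
        .writeManifest(outDir, list(excludeLabels = excludeLabels))
    }
    out
}
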