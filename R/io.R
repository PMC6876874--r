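#' @include AllClasses.R
#' @importFrom rtracklayer import export
NULL

#' Read an annotation track from a BED file
#'
#' Thin wrapper over [rtracklayer::import()] for BED3/BED4/BED6 tracks
#' (assembly gaps, blacklists, RepeatMasker intervals, chromHMM
#' segmentations with the state label in column 4). BED coordinates are
#' 0-based half-open on disk and arrive 1-based closed in the returned
#' `GRanges`, as everywhere in Bioconductor.
#'
#' @param path path to a BED file (plain or gzipped).
#' @return a `GRanges`; column 4, if present, is in `mcols()$name`.
#' @export
readBedTrack <- function(path) {
    if (!file.exists(path))
        stopIO("BED file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stopIO("cannot read BED ", path, ": ",
                                              conditionMessage(e)))
    sort(gr, ignore.strand = TRUE)
}

#' Read paired-end templates from a BEDPE file
#'
#' Each BEDPE record contributes one template interval: the outermost
#' coordinates of its two reads, which must lie on the same chromosome.
#' Malformed records (wrong column count, non-numeric or inverted
#' coordinates, interchromosomal pairs) are skipped and counted; if more
#' than 10 percent of records are malformed the file is rejected.
#'
#' @param path path to a BEDPE file (at least 6 columns; tab-separated).
#' @return a `GRanges` of template intervals; the number of skipped records
#'   is in the `malformed` attribute.
#' @export
readBedpe <- function(path) {
    if (!file.exists(path))
        stopIO("BEDPE file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) {
        out <- GRanges()
        attr(out, "malformed") <- 0L
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    parsed <- lapply(fields, function(f) {
        if (length(f) < 6L) return(NULL)
        s1 <- suppressWarnings(as.numeric(f[2L])); e1 <- suppressWarnings(as.numeric(f[3L]))
        s2 <- suppressWarnings(as.numeric(f[5L])); e2 <- suppressWarnings(as.numeric(f[6L]))
        if (anyNA(c(s1, e1, s2, e2)) || f[1L] != f[4L] ||
            s1 >= e1 || s2 >= e2) return(NULL)
        c(chrom = f[1L], start0 = min(s1, s2), end0 = max(e1, e2))
    })
    ok <- !vapply(parsed, is.null, logical(1))
    nBad <- sum(!ok)
    if (nBad / length(lines) > 0.10)
        stopValidation(sprintf("%d of %d BEDPE records are malformed (> 10%%)",
                               nBad, length(lines)))
    if (nBad > 0)
        message(sprintf("readBedpe: skipped %d malformed record(s)", nBad))
    rec <- do.call(rbind, parsed[ok])
    out <- GRanges(rec[, "chrom"],
                   IRanges(as.numeric(rec[, "start0"]) + 1,
                           as.numeric(rec[, "end0"])))
    out <- sort(out, ignore.strand = TRUE)
    attr(out, "malformed") <- nBad
    out
}

#' Write recognition sites as BED6
#'
#' One record per site: chrom, 0-based motif start, motif end, enzyme name,
#' score 0, and the matching strand ("+" for palindromic motifs).
#'
#' @param index a [CutSiteIndex-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSitesBed <- function(index, path) {
    if (!is(index, "CutSiteIndex"))
        stopValidation("index must be a CutSiteIndex")
    gr <- index@sites
    mcols(gr) <- DataFrame(name = mcols(gr)$enzyme, score = 0L)
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Write genomic regions as BED
#'
#' Exports a `GRanges` as BED4, with the name column taken from `nameCol`
#' (comma-joined labels of classified refractory regions, or the fragment
#' length). Regions without a value in `nameCol` are written with name ".".
#'
#' @param regions a `GRanges`.
#' @param path output path.
#' @param nameCol metadata column to use as the BED name field.
#' @return the path, invisibly.
#' @export
writeRegionsBed <- function(regions, path, nameCol = NULL) {
    if (!is(regions, "GRanges"))
        stopValidation("regions must be a GRanges")
    gr <- regions
    nm <- if (!is.null(nameCol) && !is.null(mcols(gr)[[nameCol]]))
        as.character(mcols(gr)[[nameCol]]) else rep(".", length(gr))
    nm[is.na(nm)] <- "."
    mcols(gr) <- DataFrame(name = nm)
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Write paired-end templates as BEDPE
#'
#' Emits one record per template: two abutting "reads" of `readLength` bp at
#' the template ends (clipped to the template when it is shorter), matching
#' how sequenced read pairs delimit a template.
#'
#' @param templates a `GRanges` of template intervals.
#' @param path output path.
#' @param readLength nominal read length in bp.
#' @return the path, invisibly.
#' @export
writeBedpe <- function(templates, path, readLength = 50L) {
    if (!is(templates, "GRanges"))
        stopValidation("templates must be a GRanges")
    s0 <- start(templates) - 1L
    e0 <- end(templates)
    r <- pmin(as.integer(readLength), e0 - s0)
    df <- data.frame(chrom1 = as.character(seqnames(templates)),
                     start1 = s0, end1 = s0 + r,
                     chrom2 = as.character(seqnames(templates)),
                     start2 = e0 - r, end2 = e0,
                     name = sprintf("template%d", seq_along(templates)),
                     score = 0L, strand1 = "+", strand2 = "-")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome a `DNAStringSet`.
#' @param path output path (".gz" suffix compresses).
#' @return the path, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    if (!is(genome, "DNAStringSet"))
        stopValidation("genome must be a DNAStringSet")
    Biostrings::writeXStringSet(genome, path,
                                compress = grepl("\\.gz$", path))
    invisible(path)
}
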