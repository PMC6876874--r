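#' @include AllClasses.R
NULL

#' Accessors for SilicoDigest classes
#'
#' Small accessor generics so that user code never touches slots directly:
#' `enzymeNames`, `recognitionMotifs` and `cutOffsets` read an
#' [EnzymePanel-class]; `siteRanges` and `gapRanges` read a
#' [CutSiteIndex-class]; `fragmentRanges` (and `gapRanges`) read a
#' [FragmentSet-class]; `totalSites` counts recognition-site occurrences.
#'
#' @param x an EnzymePanel, CutSiteIndex or FragmentSet.
#' @return `enzymeNames`, `recognitionMotifs`: character vectors;
#'   `cutOffsets`: named integer vector (`NA` where unknown);
#'   `siteRanges`, `gapRanges`, `fragmentRanges`: `GRanges`;
#'   `totalSites`: a single number; `enzymePanel`: an `EnzymePanel`.
#' @examples
#' p <- defaultEnzymes()
#' enzymeNames(p)
#' recognitionMotifs(p)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("enzymeNames", function(x) standardGeneric("enzymeNames"))

#' @rdname accessors
#' @export
setGeneric("recognitionMotifs", function(x) standardGeneric("recognitionMotifs"))

#' @rdname accessors
#' @export
setGeneric("cutOffsets", function(x) standardGeneric("cutOffsets"))

#' @rdname accessors
#' @export
setGeneric("enzymePanel", function(x) standardGeneric("enzymePanel"))

#' @rdname accessors
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname accessors
#' @export
setGeneric("gapRanges", function(x) standardGeneric("gapRanges"))

#' @rdname accessors
#' @export
setGeneric("fragmentRanges", function(x) standardGeneric("fragmentRanges"))

#' @rdname accessors
#' @export
setGeneric("totalSites", function(x) standardGeneric("totalSites"))

#' @rdname accessors
setMethod("enzymeNames", "EnzymePanel", function(x) x@enzyme)

#' @rdname accessors
setMethod("recognitionMotifs", "EnzymePanel",
          function(x) stats::setNames(x@recognition, x@enzyme))

#' @rdname accessors
setMethod("cutOffsets", "EnzymePanel",
          function(x) stats::setNames(x@cutOffset, x@enzyme))

#' @rdname accessors
setMethod("enzymePanel", "CutSiteIndex", function(x) x@panel)

#' @rdname accessors
setMethod("siteRanges", "CutSiteIndex", function(x) x@sites)

#' @rdname accessors
setMethod("gapRanges", "CutSiteIndex", function(x) x@gaps)

#' @rdname accessors
setMethod("gapRanges", "FragmentSet", function(x) x@gaps)

#' @rdname accessors
setMethod("fragmentRanges", "FragmentSet", function(x) x@fragments)

#' @rdname accessors
setMethod("totalSites", "CutSiteIndex", function(x) length(x@sites))

setMethod("show", "EnzymePanel", function(object) {
    cat(sprintf("EnzymePanel with %d enzyme(s)\n", length(object@enzyme)))
    off <- ifelse(is.na(object@cutOffset), "-", object@cutOffset)
    cat(sprintf("  %-8s %-8s cut_offset=%s\n",
                object@enzyme, object@recognition, off), sep = "")
})

setMethod("show", "CutSiteIndex", function(object) {
    cat(sprintf("CutSiteIndex: %d site(s) on %d sequence(s), panel of %d enzyme(s)%s\n",
                length(object@sites),
                length(seqlevelsInUse(object@sites)),
                length(object@panel@enzyme),
                if (object@bothStrands) " (both strands)" else ""))
    if (length(object@gaps))
        cat(sprintf("  %d ambiguous-base run(s) totalling %.0f bp\n",
                    length(object@gaps), sum(as.numeric(width(object@gaps)))))
})

setMethod("show", "FragmentSet", function(object) {
    w <- width(object@fragments)
    cat(sprintf("FragmentSet: %d fragment(s) on %d sequence(s); mean %.1f bp, median %.0f bp\n",
                length(w), length(seqlevelsInUse(object@fragments)),
                mean(w), stats::median(w)))
})

setMethod("show", "DigestReport", function(object) {
    cat("In silico digestion report\n")
    cat(sprintf("  genome length        : %.0f bp\n", object@genomeLength))
    cat(sprintf("  recognition sites    : %.0f\n", object@totalSites))
    cat(sprintf("  mean fragment length : %.1f bp\n", object@meanLength))
    cat(sprintf("  median fragment      : %.0f bp\n", object@medianLength))
    cat(sprintf("  fraction < %d bp    : %.1f%% (assembly), %.1f%% (gap-excluded)\n",
                as.integer(object@threshold),
                100 * object@fractionBelow[["assembly"]],
                100 * object@fractionBelow[["nonGap"]]))
    cat(sprintf("  fragments = %d bp   : %d\n",
                as.integer(object@threshold), as.integer(object@atThreshold)))
    cat(sprintf("  refractory (> %d bp): %d region(s)\n",
                as.integer(object@threshold), length(object@refractory)))
})
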