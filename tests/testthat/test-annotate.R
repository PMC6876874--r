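test_that("regions are labelled by any 1-bp overlap, multi-label allowed", {
    r <- grT(1, 2000)
    tracks <- list(gap = grT(501, 600), repeat_ = grT(1501, 1600))
    cls <- classifyRegions(r, tracks)
    expect_identical(cls$regions$labels, "gap,repeat_")
    s <- cls$summary
    expect_identical(s$count[s$label == "unlabelled"], 0)
    expect_identical(s$count[s$label == "total"], 1)

    none <- classifyRegions(r, list(gap = grT(5001, 6000)))
    expect_true(is.na(none$regions$labels))
    expect_identical(none$summary$count[none$summary$label == "unlabelled"], 1)

    # single-base touch counts; abutting does not
    expect_identical(classifyRegions(grT(100, 200),
                                     list(x = grT(200, 300)))$regions$labels, "x")
    expect_true(is.na(classifyRegions(grT(100, 200),
                                      list(x = grT(201, 300)))$regions$labels))
    expect_error(classifyRegions(r, list()), "non-empty")
    expect_warning(classifyRegions(grT(1, 10, chrom = "chr9"),
                                   list(gap = grT(1, 10))), "chr9")
})

test_that("classification agrees with brute-force all-pairs intersection", {
    set.seed(301)
    for (rep in 1:5) {
        n <- 200
        rs <- sample(1:50000, n)
        regions <- grT(rs, rs + sample(10:1000, n, replace = TRUE))
        tracks <- lapply(stats::setNames(1:3, c("a", "b", "c")), function(i) {
            ts <- sample(1:50000, 150)
            grT(ts, ts + sample(5:500, 150, replace = TRUE))
        })
        got <- suppressWarnings(classifyRegions(regions, tracks))
        # brute force: compare every region against every track interval
        want <- vapply(seq_len(n), function(i) {
            labs <- names(tracks)[vapply(tracks, function(trk) {
                any(BiocGenerics::start(regions)[i] <= BiocGenerics::end(trk) &
                    BiocGenerics::end(regions)[i] >= BiocGenerics::start(trk))
            }, logical(1))]
            if (length(labs)) paste(labs, collapse = ",") else NA_character_
        }, character(1))
        expect_identical(got$regions$labels, want)
        # label-count identities
        s <- got$summary
        total <- s$count[s$label == "total"]
        unlab <- s$count[s$label == "unlabelled"]
        per <- s$count[!s$label %in% c("total", "unlabelled")]
        expect_gte(sum(per), total - unlab)
        expect_identical(unlab + sum(!is.na(got$regions$labels)), total)
    }
})

test_that("site density per class is sites per merged kb, start-assigned", {
    # 8 planted sites in a 2000-bp class -> 4 per kb
    sim <- simulateGenome(
        lengths = c(chr1 = 4000),
        baseComposition = c(A = 0.5, C = 0.5, G = 0, T = 0),
        plant = data.frame(chrom = "chr1", pos = seq(100, 1850, by = 250),
                           enzyme = "AluI"),
        seed = 302)
    idx <- scanGenome(sim$genome, defaultEnzymes("AluI"))
    trk <- grT(c(1, 2001), c(2000, 4000), chrom = "chr1",
               name = c("inside", "outside"))
    d <- siteDensityPerClass(idx, trk)
    expect_identical(d$sites[d$label == "inside"], 8L)
    expect_identical(d$density_per_kb[d$label == "inside"], 4.0)
    expect_identical(d$sites[d$label == "outside"], 0L)
    expect_identical(d$density_per_kb[d$label == "outside"], 0)
    # assignment is by start coordinate: a site straddling the class border
    # belongs to the class containing its start
    sim2 <- simulateGenome(lengths = c(chr1 = 100),
                           baseComposition = c(A = 0.5, C = 0.5, G = 0, T = 0),
                           plant = data.frame(chrom = "chr1", pos = 49,
                                              enzyme = "AluI"),
                           seed = 303)
    idx2 <- scanGenome(sim2$genome, defaultEnzymes("AluI"))
    trk2 <- grT(c(1, 51), c(50, 100), chrom = "chr1", name = c("L", "R"))
    d2 <- siteDensityPerClass(idx2, trk2)
    expect_identical(d2$sites, c(1L, 0L))
})

test_that("site density is invariant to pre-merging overlapping class intervals", {
    sim <- simulateGenome(lengths = c(chr1 = 20000), seed = 304)
    idx <- scanGenome(sim$genome, defaultEnzymes(c("AluI", "MvaI")))
    raw <- grT(c(1, 4001, 3000, 12001), c(5000, 8000, 4500, 20000),
               chrom = "chr1", name = c("s1", "s1", "s1", "s2"))
    merged <- IRanges::reduce(raw[raw$name == "s1"])
    merged$name <- "s1"
    pre <- grT(12001, 20000, chrom = "chr1", name = "s2")
    mergedTrack <- c(merged, pre)
    expect_identical(siteDensityPerClass(idx, raw),
                     siteDensityPerClass(idx, mergedTrack))
})

test_that("label exclusions drop chromHMM repeat states by number or name", {
    trk <- grT(c(1, 1001, 2001, 3001), c(1000, 2000, 3000, 4000),
               chrom = "chr1",
               name = c("1_Active_Promoter", "13_Heterochrom",
                        "14_Repetitive/CNV", "15_Repetitive/CNV"))
    sim <- simulateGenome(lengths = c(chr1 = 4000), seed = 305)
    idx <- scanGenome(sim$genome, defaultEnzymes("AluI"))
    d <- siteDensityPerClass(idx, trk, excludeLabels = c("14", "15"))
    expect_setequal(d$label, c("1_Active_Promoter", "13_Heterochrom"))
    expect_error(siteDensityPerClass(idx, trk,
                                     excludeLabels = c("1_Active_Promoter",
                                                       "13", "14", "15")),
                 "exclusions")
})

test_that("fragment lengths per class follow the midpoint rule", {
    fs <- fragmentSetFromLengths(c(100, 200))
    trk <- grT(1, 300, name = "all")
    m <- fragmentLengthPerClass(fs, trk)
    expect_identical(m$mean_length, 150)
    expect_identical(m$median_length, 150)
    # class covering only the first 100 bp sees one fragment
    m1 <- fragmentLengthPerClass(fs, grT(1, 100, name = "first"))
    expect_identical(m1$n, 1L)
    expect_identical(m1$mean_length, 100)
    # a class smaller than its enclosing fragment falls back to it
    m2 <- fragmentLengthPerClass(fs, grT(120, 140, name = "tiny"))
    expect_identical(m2$n, 0L)
    expect_true(m2$enclosing)
    expect_identical(m2$median_length, 200)
})

test_that("midpoint assignment partitions fragments over a genome partition", {
    sim <- simulateGenome(lengths = c(chr1 = 50000), seed = 306)
    fs <- digestFragments(scanGenome(sim$genome,
                                     defaultEnzymes(c("AluI", "SaqAI"))))
    cuts <- c(1, sort(sample(2:49999, 6)), 50001)
    trk <- grT(cuts[-length(cuts)], cuts[-1] - 1, chrom = "chr1",
               name = paste0("part", seq_len(length(cuts) - 1)))
    m <- fragmentLengthPerClass(fs, trk)
    expect_identical(sum(m$n), length(fragmentRanges(fs)))
})

test_that("observed template lengths are summarised per midpoint class", {
    trk <- grT(c(1, 1001), c(1000, 2000), chrom = "chr1", name = c("X", "Y"))
    tpl <- grT(c(101, 301, 1401), c(200, 500, 1900), chrom = "chr1")
    m <- observedFragmentLengths(tpl, trk)
    expect_identical(m$median_length[m$label == "X"], 150)  # lengths 100, 200
    expect_identical(m$n[m$label == "Y"], 1L)
    # a template straddling both classes counts only where its midpoint lies
    straddle <- grT(901, 1100, chrom = "chr1")   # midpoint 1000 -> class X
    ms <- observedFragmentLengths(straddle, trk)
    expect_identical(ms$n, c(1L, 0L))
})

test_that("BEDPE parsing skips malformed records and rejects bad files", {
    good <- c("chr1\t100\t250\tchr1\t300\t400",
              "chr1\t500\t560\tchr1\t520\t600")
    bad <- c("chr1\t100\t50\tchr1\t300\t400",    # inverted
             "chr1\t100\t250\tchr2\t300\t400",   # interchromosomal
             "chr1\tfoo\t250\tchr1\t300\t400")   # non-numeric
    f <- withr::local_tempfile(fileext = ".bedpe")
    writeLines(c(good, rep(good, 10), bad[1]), f)
    tpl <- suppressMessages(readBedpe(f))
    expect_identical(attr(tpl, "malformed"), 1L)
    expect_length(tpl, 22L)
    # outermost template coordinates: [100,400) -> width 300
    expect_identical(BiocGenerics::width(tpl)[1], 300L)

    f2 <- withr::local_tempfile(fileext = ".bedpe")
    writeLines(c(good, bad), f2)                 # 3 of 5 malformed
    expect_error(readBedpe(f2), "malformed")
    f3 <- withr::local_tempfile(fileext = ".bedpe")
    writeLines(character(0), f3)
    expect_length(readBedpe(f3), 0L)
})
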