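test_that("cut positions imply tiling fragments with conserved length", {
    expect_identical(BiocGenerics::width(fragmentsFromSites(100)), 100L)
    fr <- fragmentsFromSites(100, c(20, 50))
    expect_identical(BiocGenerics::width(fr), c(20L, 30L, 50L))
    expect_identical(BiocGenerics::start(fr), c(1L, 21L, 51L))
    # a site at coordinate 0 produces no zero-length fragment
    expect_identical(BiocGenerics::width(fragmentsFromSites(8, 0)), 8L)
    # duplicates collapse
    expect_identical(BiocGenerics::width(fragmentsFromSites(10, c(4, 4))),
                     c(4L, 6L))
    expect_error(fragmentsFromSites(100, c(50, 20)), "sorted")
    expect_error(fragmentsFromSites(100, 100), "chromLength")
    expect_error(fragmentsFromSites(100, -1), "chromLength")

    # conservation on random site sets
    set.seed(201)
    for (i in 1:25) {
        L <- sample(10:5000, 1)
        sites <- sort(sample(0:(L - 1), sample(0:min(L, 50), 1)))
        expect_identical(sum(BiocGenerics::width(fragmentsFromSites(L, sites))),
                         L)
    }
})

test_that("digestFragments tiles every chromosome exactly", {
    sim <- simulateGenome(lengths = c(chr1 = 40000, chr2 = 15000), seed = 202)
    idx <- scanGenome(sim$genome, defaultEnzymes(c("AluI", "SaqAI")))
    fs <- digestFragments(idx)
    fr <- fragmentRanges(fs)
    for (chr in c("chr1", "chr2")) {
        w <- BiocGenerics::width(fr[GenomicRanges::seqnames(fr) == chr])
        expect_identical(sum(w),
                         unname(GenomeInfoDb::seqlengths(fr)[chr]))
    }
    # interior boundaries are exactly the deduplicated site starts
    sites1 <- sort(unique(BiocGenerics::start(
        siteRanges(idx)[GenomicRanges::seqnames(siteRanges(idx)) == "chr1"])))
    frag1 <- fr[GenomicRanges::seqnames(fr) == "chr1"]
    expect_identical(BiocGenerics::start(frag1)[-1], sites1)
    # a chromosome with no site is a single fragment
    simA <- simulateGenome(lengths = c(chrA = 500),
                           baseComposition = c(A = 1, C = 0, G = 0, T = 0),
                           seed = 1)
    fsA <- digestFragments(scanGenome(simA$genome, defaultEnzymes("AluI")))
    expect_identical(BiocGenerics::width(fragmentRanges(fsA)), 500L)
})

test_that("cut-offset mode shifts boundaries by the enzyme offset", {
    sim <- simulateGenome(lengths = c(chr1 = 2000),
                          baseComposition = c(A = 0.5, C = 0.5, G = 0, T = 0),
                          plant = data.frame(chrom = "chr1", pos = 600,
                                             enzyme = "AluI"),
                          seed = 203)
    idx <- scanGenome(sim$genome, defaultEnzymes("AluI"))
    expect_identical(BiocGenerics::start(fragmentRanges(
        digestFragments(idx)))[-1], 601L)        # boundary at site start
    expect_identical(BiocGenerics::start(fragmentRanges(
        digestFragments(idx, useCutOffsets = TRUE)))[-1], 603L)  # AG^CT
})

test_that("genome fraction below a threshold uses strict inequality and both denominators", {
    fs <- fragmentSetFromLengths(c(500, 500, 1000))
    expect_identical(genomeFractionBelow(fs, 1000), 0.5)
    expect_identical(genomeFractionBelow(fragmentSetFromLengths(c(10, 20, 30)),
                                         1000), 1.0)
    # gap-excluded denominator removes N-run length
    gaps <- grT(101, 500)
    fsg <- fragmentSetFromLengths(c(500, 500, 1000), gaps = gaps)
    expect_identical(genomeFractionBelow(fsg, 1000, "nonGap"),
                     1000 / (2000 - 400))
    expect_error(genomeFractionBelow(fs, 0), "threshold")
})

test_that("refractory regions are fragments strictly longer than the cutoff", {
    fs <- fragmentSetFromLengths(c(500, 1500, 999, 1001))
    r <- refractoryRegions(fs, 1000)
    expect_length(r, 2L)
    expect_identical(sort(r$length), c(1001L, 1500L))
    expect_length(refractoryRegions(fragmentSetFromLengths(rep(1000, 5)), 1000),
                  0L)
    # strict-below / exactly-at / strict-above partition the fragments
    set.seed(204)
    lens <- sample(c(1:2000, 1000), 300, replace = TRUE)
    fs2 <- fragmentSetFromLengths(lens)
    w <- BiocGenerics::width(fragmentRanges(fs2))
    below <- sum(w[w < 1000])
    above <- sum(BiocGenerics::width(refractoryRegions(fs2, 1000)))
    at <- sum(w[w == 1000])
    expect_equal(below + above + at, sum(lens))
})

test_that("expected spacing follows the linearity-of-expectation density", {
    expect_identical(expectedSiteSpacing("AGCT"), 256)
    expect_identical(expectedSiteSpacing("GANTC"), 256)  # 4 * (1/4)^5
    expect_equal(expectedSiteSpacing(
        defaultEnzymes(c("AluI", "SaqAI", "HinfI", "MvaI"))), 512 / 7)
    # composition sensitivity: AGCT under GC-rich composition
    p <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
    expect_equal(expectedSiteSpacing("AGCT", p), 1 / (0.2 * 0.3 * 0.3 * 0.2))
    expect_error(expectedSiteSpacing("AGCT", c(A = 1, C = 0, G = 0, T = 0.1)),
                 "sum to 1")
    expect_error(expectedSiteSpacing("AGCT", c(A = 1, C = 0, G = 0, T = 0)),
                 "no motif")
})

test_that("observed mean spacing on i.i.d. sequence matches the prediction", {
    sim <- simulateGenome(lengths = c(chr1 = 2e6), seed = 205)
    for (enz in list("AluI", c("AluI", "SaqAI", "HinfI", "MvaI"))) {
        idx <- scanGenome(sim$genome, defaultEnzymes(enz))
        pos <- sort(unique(BiocGenerics::start(siteRanges(idx))))
        sp <- diff(pos)
        pred <- expectedSiteSpacing(defaultEnzymes(enz))
        se <- stats::sd(sp) / sqrt(length(sp))
        expect_lt(abs(mean(sp) - pred), 3 * se)
    }
})

test_that("adding enzymes never loses sites nor lengthens fragments", {
    sim <- simulateGenome(lengths = c(chr1 = 3e5), seed = 206)
    panels <- list(c("AluI"), c("AluI", "SaqAI"),
                   c("AluI", "SaqAI", "HinfI"),
                   c("AluI", "SaqAI", "HinfI", "MvaI"),
                   c("AluI", "SaqAI", "HinfI", "MvaI", "BsuRI"))
    sites <- meanLen <- numeric(length(panels))
    for (i in seq_along(panels)) {
        idx <- scanGenome(sim$genome, defaultEnzymes(panels[[i]]))
        sites[i] <- totalSites(idx)
        meanLen[i] <- mean(BiocGenerics::width(
            fragmentRanges(digestFragments(idx))))
    }
    expect_true(all(diff(sites) >= 0))
    expect_true(all(diff(meanLen) <= 0))
})

test_that("fragment-size histograms bin half-open with an overflow bin", {
    h <- fragmentSizeHistogram(c(10, 20, 3000), binEdges = c(0, 100, 1000))
    expect_identical(h$count, c(2, 0, 1))
    expect_identical(h$upper[3], Inf)
    expect_identical(attr(h, "underflow"), 0L)
    h1 <- fragmentSizeHistogram(42, binEdges = c(0, 100))
    expect_identical(h1$count, c(1, 0))
    # boundary values land in the right-open bin
    hb <- fragmentSizeHistogram(c(100, 99.999), binEdges = c(0, 100, 200))
    expect_identical(hb$count, c(1, 1, 0))
    expect_error(fragmentSizeHistogram(1:3, binEdges = 5), "binEdges")
    expect_error(fragmentSizeHistogram(1:3, binEdges = c(5, 5)), "binEdges")
    # counts always sum to the fragment count
    sim <- simulateGenome(lengths = c(chr1 = 1e5), seed = 207)
    fs <- digestFragments(scanGenome(sim$genome, defaultEnzymes("AluI")))
    h2 <- fragmentSizeHistogram(fs)
    expect_equal(sum(h2$count), length(fragmentRanges(fs)))
})

test_that("digestReport composes consistent headline statistics", {
    sim <- simulateGenome(lengths = c(chr1 = 2e5, chr2 = 5e4),
                          gaps = data.frame(chrom = "chr1", start = 10000,
                                            end = 15000),
                          seed = 208)
    idx <- scanGenome(sim$genome,
                      defaultEnzymes(c("AluI", "SaqAI", "HinfI", "MvaI")))
    rep <- digestReport(idx)
    expect_s4_class(rep, "DigestReport")
    expect_identical(rep@genomeLength, 250000)
    expect_identical(rep@totalSites, as.numeric(totalSites(idx)))
    expect_equal(sum(rep@histogram$count),
                 length(fragmentRanges(digestFragments(idx))))
    expect_true(rep@fractionBelow[["nonGap"]] >= rep@fractionBelow[["assembly"]])
    # the 5-kb gap survives as a refractory region
    expect_true(any(rep@refractory$length >= 5000))
    expect_output(show(rep), "refractory")
})
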