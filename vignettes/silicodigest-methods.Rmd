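---
title: "In silico restriction digestion: models, conventions and design choices"
author: "SilicoDigest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico restriction digestion: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SilicoDigest)
```

## The problem

Low-input ChIP-seq protocols can replace sonication with restriction
endonuclease digestion: frequently cutting 4–5 bp enzymes fragment
chromatin between nucleosomes, in tiny volumes, without over-digestion.
Because restriction enzymes are sequence-specific, the fragmentation they
can achieve is predictable from the genome sequence alone. SilicoDigest
implements that prediction: it maps every recognition site of an enzyme
panel across an assembly, derives the implied fragment intervals, and asks
the assay-design questions — how much of the genome breaks into ChIP-sized
pieces, which regions resist digestion and why, and whether coverage is
even across chromatin states.

## The model

### Recognition sites as degenerate motifs

An enzyme is a named IUPAC motif (`AluI = AGCT`, `SaqAI = TTAA`,
`HinfI = GANTC`, `MvaI = CCWGG`, `BsuRI = GGCC` in the built-in registry).
A degenerate motif denotes the Cartesian product of its per-position base
sets; `expandMotif("CCWGG")` is `CCAGG, CCTGG`. Scanning
(`scanSequence()`, `scanGenome()`) reports *every* occurrence, including
overlapping ones — no suppression rule is applied, because none is implied
by the biology: each occurrence is a potential cut. Matching is
IUPAC-aware on the motif side only; an ambiguous letter in the *sequence*
(N) never matches, so recognition sites cannot lie inside or span
assembly gaps. Soft-masked lowercase sequence is scanned as ordinary
sequence: repeats are masked for alignment reasons, not because enzymes
ignore them — and treating them as sequence is what lets gap regions, and
only gap regions, surface as sequence-free refractory blocks.

All five registry motifs are palindromic (self-reverse-complementary), so
single-strand scanning already describes double-strand cutting. For
non-palindromic user-defined motifs, `bothStrands = TRUE` (the default)
also scans the reverse-complement motif and reports minus-strand hits;
for palindromic motifs the two modes are provably identical, which the
test suite asserts.

The matcher itself is `Biostrings::matchPattern(fixed = "subject")`, with
a post-filter removing hits that overlap ambiguity runs (Biostrings lets
a motif N match a sequence N, which is wrong for this purpose: an enzyme
cannot recognise unresolved sequence). The test suite holds the scanner to
a brute-force per-position base-set containment oracle, written
independently of Biostrings, over a thousand seeded random sequences.

### Fragments

Fragment boundaries are recognition-site **start** coordinates, pooled
over the panel and deduplicated. Cutting a chromosome of length $L$ at
$n$ distinct positions yields $n+1$ half-open fragments
$[0,p_1), [p_1,p_2), \dots, [p_n, L)$, which tile the chromosome exactly;
length conservation ($\sum \text{widths} = L$) is enforced by the
`FragmentSet` validity method after every digestion. A site at coordinate
0 contributes no boundary, so zero-length fragments cannot exist. The
registry also carries each enzyme's chemical cut offset (e.g. AluI AG^CT),
but these are metadata: recognition-site starts are the convention that a
site-coordinate list supports directly, and for 4–5 bp motifs the
difference (1–2 bp per boundary) is negligible against fragment-scale
statistics. An opt-in `useCutOffsets = TRUE` mode in `digestFragments()`
shifts boundaries by the offset instead.

### Headline statistics

* **Fraction below threshold** (`genomeFractionBelow()`): summed length
  of fragments *strictly* shorter than the threshold (default 1,000 bp,
  the practical upper bound for ChIP fragments), divided by a
  denominator. Two denominators are reported side by side: the full
  assembly length, and the assembly minus ambiguity runs. Assembly gaps
  are genuine genome that cannot be cut, but they are also not real
  sequence; reporting both bounds the ambiguity instead of hiding it.
* **Refractory regions** (`refractoryRegions()`): whole fragments
  *strictly* longer than the cutoff — the fragments are the regions, not
  clipped sub-intervals, because a fragment either is or is not too large
  for ChIP as a unit. With both inequalities strict, fragments exactly at
  the threshold belong to neither class; they are counted separately in
  the `DigestReport` (`atThreshold`) so the two headline numbers plus
  that class always partition the genome.
* **Expected spacing** (`expectedSiteSpacing()`): under an i.i.d. base
  model with composition $p$, the per-position density of panel sites is
  $d=\sum_e \sum_{m \in \text{expand}(e)} \prod_j p_{m_j}$ by linearity
  of expectation (edge effects ignored), and the expected spacing is
  $1/d$. A fully specified 4-bp cutter under uniform composition gives
  $4^4 = 256$ bp; HinfI's `GANTC` gives $1/(4 \cdot 4^{-5}) = 256$ bp as
  well; the four-enzyme panel gives $1/(3/256 + 1/512) = 512/7 \approx
  73.1$ bp. Overlap between occurrences makes consecutive spacings
  non-geometric in detail, but leaves the mean exact; the tests confirm
  agreement with seeded simulations within three standard errors.

### Annotation and per-class metrics

Refractory regions are classified against annotation tracks (assembly
gaps, ENCODE-style blacklists, RepeatMasker intervals) by **any-overlap**:
one shared base pair attaches the label. Labels are deliberately not
exclusive — a region spanning a gap flanked by repeats carries both — so
per-label counts may sum to more than the number of labelled regions;
regions carrying no label are the interesting residue: sequence that
resists digestion without an annotation excuse.

Per-class digestion metrics over a chromatin-state segmentation use two
assignment rules, chosen where the choice was genuinely open:

* **sites → class by start coordinate** — the site coordinate *is* its
  start, and a 4–5 bp motif straddling a class border is an edge case not
  worth double-counting;
* **fragments and sequenced templates → class by midpoint** — midpoint
  assignment is total and single-valued, so per-class fragment counts
  partition the genome whenever the classes do (asserted in the tests);
  any-overlap would double-count every boundary-spanning fragment.

Both rules are documented behaviour rather than toggles; the headline
per-class statistics (densities per merged kb, median lengths) are robust
to the choice at genome scale. Repeat-associated chromHMM states are
excluded by default (`excludeLabels = c("14", "15")`, matching either the
full label or its leading number), since repeat copies inflate per-state
statistics without informing assay design; the exclusion list is a plain
argument. Chromosome-name mismatches between regions and tracks produce
an explicit warning naming the missing chromosomes — never a silent
`chr1`/`1` renaming.

Observed fragment sizes come from paired-end data: each BEDPE record
yields one template interval (outermost coordinates of the pair, same
chromosome required). Malformed records are skipped and counted; a file
with more than 10% malformed records is rejected outright rather than
summarised from its readable remainder.

## The simulator

`simulateGenome()` emulates exactly the features the analyses consume:
i.i.d. background sequence of configurable base composition, N-run gaps,
and recognition sites planted at known coordinates (a degenerate motif is
planted as one concrete expansion drawn under the same seed). Planting
happens **after** background generation, so chance background occurrences
remain present and countable — the truth table records where sites were
planted, not every site in the sequence; planted-site precision is
therefore checked against the brute-force scanner, not against the truth
table. Gap/plant collisions are rejected at validation. One integer seed
drives all randomness through R's global generator, so outputs are
byte-identical across runs.

What the simulator does **not** emulate — and what passing tests on it
therefore cannot show — includes: real genomes' long-range composition
structure (isochores, CpG suppression, repeat families), which makes real
site spacing over-dispersed relative to i.i.d.; nucleosome positioning
and chromatin accessibility, which govern *actual* cutting efficiency in
the assay; and sequencing artefacts behind blacklists. The hg19-scale
claims (tens of millions of sites, ~87% of the genome below 1 kb, a few
thousand refractory regions dominated by gaps/blacklist/repeats) are
reproducible with this package by users who download the assembly and the
UCSC/ENCODE tracks, but they are properties of that data, not of the
simulator.

`simulateFragmentsBedpe()` draws templates with per-class length
distributions and midpoints uniform within a labelled track, splitting
the total deterministically across classes in proportion to merged class
length, and returns the generating medians so recovery can be asserted.

## Numerical and interface conventions

* Coordinates are 0-based half-open at every file boundary (BED, BEDPE,
  reported `pos` in `scanSequence()`), and 1-based closed inside R
  containers, as everywhere in Bioconductor; conversion happens only in
  I/O (`rtracklayer` for BED, a dedicated reader for BEDPE, which has no
  Bioconductor reader).
* Validation failures and I/O failures raise distinct condition classes
  (`silicoDigestValidationError`, `silicoDigestIOError`); the
  command-line dispatcher (`inst/scripts/silicodigest.R`) maps them to
  exit codes 2 and 3, reserving 1 for internal errors.
* Run directories written by `runDigest()`/`runRefractory()`/
  `runStatewise()` include a `manifest.tsv` with the configuration,
  package version and input-file MD5 checksums; machine outputs are never
  mixed with log text, so identical inputs give byte-identical outputs.
* The histogram uses right-open bins plus an explicit overflow bin, with
  default edges at 100-bp steps to 1 kb then 2/5/10 kb, matching how
  predicted fragment-size distributions are usually displayed.

## Scales used in the test suite

Statistical assertions are made at sizes where their standard errors are
decisive while a full run stays comfortable on a laptop: scanner-oracle
equivalence over 1,000 random sequences of up to 10 kb; spacing,
density and composition checks on 2-Mb i.i.d. genomes (≈ 7,800 AluI
sites, giving a standard error of ~1.5 bp on the mean spacing); the
acceptance cross-check of the analytic 256-bp expectation on a 10-Mb
genome (≈ 39,000 sites, SE ≈ 1.3 bp, three-SE band ≈ ±3.9 bp); and the
end-to-end refractory-classification test on a 2-Mb assembly with
planted gaps and motif-free A-runs. At the four-enzyme panel's ~73-bp
mean spacing, a background fragment exceeding 1 kb by chance has
probability on the order of $e^{-1000/73} \approx 10^{-6}$, so planted
structure cleanly dominates the refractory list.

## Known limitations

* Cutting probability is modelled as 0 or 1 per site: no partial
  digestion, star activity, or methylation sensitivity.
* Chromatin context is out of scope: predicted fragmentation is an upper
  bound on what the assay achieves in nuclei.
* The expected-spacing formula assumes i.i.d. bases; it is a design-time
  estimate, not a model of any particular genome.
* `scanGenome()` holds the sequence set in memory and processes one
  chromosome's hits at a time; assemblies far beyond mammalian scale
  would need a streaming FASTA source.
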