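---
title: "Detecting enhancer hijacking: models, parameters and design choices"
author: "hijackscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting enhancer hijacking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hijackscan)
```

# The problem

Some tumors are driven not by a mutated oncogene but by a relocated one:
a structural variant moves a cluster of strong, tissue-specific enhancers
into the neighborhood of a proto-oncogene promoter, and the gene is
switched on in a tissue where it has no business being active. The
archetype modeled here is a salivary gland carcinoma in which a recurrent
translocation fuses part of the chromosome-4 SCPP salivary gene cluster —
broadly decorated with active H3K27ac/H3K4me3 chromatin and bounded by
convergent CTCF sites — to the region directly upstream of the *NR4A3*
proto-oncogene on chromosome 9, whose own upstream CTCF insulator ends up
on the other side of the junction.

hijackscan implements the full derived analysis for such a study as
reusable, tested R functions: ChIP-seq density tracks, super-enhancer
calling, tumor-vs-normal differential regions, consensus TAD boundaries,
oriented CTCF motif maps, translocation filtering and breakpoint-pattern
classification, derived-chromosome reconstruction, expression
quantification and FISH cohort scoring. All interval data travel as
`GRanges`; three S4 classes (`LocusModel`, `DensityTrack`, `PWMotif`)
hold what `GRanges` does not.

# Coverage model

ChIP-seq fragments are observed only through the 5′ ends of their reads
("tags"). Each tag is therefore extended at its 3′ end to the average
fragment length of the size-selected library (150–250 bp; default
200 bp; a warning is emitted outside that range, since values there
usually indicate a unit mistake rather than a real library). The
extension length is data-dependent in practice, so it is exposed as a
parameter rather than estimated — estimating it well requires the
cross-strand correlation of the full library, which is out of scope.

For a `-` tag the recorded coordinate is taken to be the 5′ (rightmost)
base, so a tag at position *p* extends to `[p+1-L, p+1)`; fragments are
clipped at chromosome ends. Density is counted in fixed 32-bp bins, and a
fragment increments **every** bin it overlaps. The alternative (assigning
each fragment to a single bin) would underweight long fragments and break
the visual equivalence with a bedGraph coverage track; with overlap
counting, the sum over bins is ≥ the fragment count, with equality only
when every fragment fits inside one bin (a property the test suite
asserts).

Depth normalization is by downsampling every sample of an IP, uniformly
without replacement under one seed, to the tag count of the smallest
sample. This follows the simplest exchangeability argument — after
downsampling, all libraries are draws of equal size — and keeps peak
calling comparable across samples without model-based scaling.

# Peaks, super-enhancers and differential regions

The built-in detector (`detectEnrichedRegions`) exists to close the
synthetic testing loop and deliberately stays simple: bins whose count
reaches `foldThreshold` × (genome-wide median of nonzero bins) are
enriched, and maximal runs of at least `minBins` such bins are peaks
(signal = mean bin count, summit = center of the highest bin). Real
studies will import MACS/SICER calls as BED; nothing downstream depends
on the detector.

Super-enhancer calling follows the ROSE recipe: stitch peaks whose gap is
at most 12,500 bp (gap measured end-exclusively, so two peaks exactly
12,500 bp apart do merge — the boundary is covered by a dedicated test),
aggregate signal as Σ signal × length, rank descending, flag the top 5 %.
"Top 5 %" is undefined for fewer than 20 regions, so the count rule is
`max(1, floor(0.05 · N))`; ties at the cutoff break toward the
earlier-start region, making the ranking total and deterministic.

Differential classification works over the union of peaks across samples
("extended regions"): per region and sample, the mean bin density; the
tumor statistic is the arithmetic mean over tumor samples (the comparison
is stated as tumors vs. the normal sample without an aggregation rule;
the mean is the symmetric default, and the per-sample matrix is returned
alongside so a user can apply any other rule); the region's ratio is
`log2((tumor + eps)/(normal + eps))` with class `up` at ≥ 2 and `down` at
≤ −2. The pseudocount `eps` (default 0.25 bin-count units) only matters
for near-empty regions; with `eps = 0` the thresholds are boundary-exact,
which is how the noise-free recovery test plants 4-fold and 0.25-fold
regions. Note that a *planted fold of exactly 4 sits on the decision
boundary*: under any noise, half of such regions fall below the
threshold. The noisy recovery experiment therefore plants 8-fold (and
1/8-fold) regions — one log2 unit of margin — at 5 expected tags per bin
over 20-bin regions and 3 tumor replicates, where the log-ratio standard
deviation is ≈ 0.3 and ≥ 95 % recovery is a property of the method rather
than a coin flip.

# Consensus TAD boundaries

Given boundary call sets from many Hi-C samples (29 in the emulated
collection), each chromosome is cut into 40-kb bins and, per bin, we
count how many samples have a boundary in the bin *or its direct
neighbors* — each sample contributing at most once per bin. A bin whose
count strictly exceeds 2 ("exceeded" is read literally, so ≥ 3 samples)
opens a boundary region; the region extends while subsequent bins keep
exceeding the count, and closes otherwise; its reported position is
start + length/2 (integer floor, since base-pair positions are
integers).

One ambiguity had to be resolved: whether the extension step re-tests
"the next bin and its direct neighbors" against raw counts or against the
already-smoothed counts. We smooth once (in the counting step) and extend
on the smoothed counts; smoothing again during extension would widen
every boundary region by construction. The consensus caller is verified
against an independent brute-force implementation (mark qualifying bins,
take maximal runs, midpoint) on 1,000 random 29-sample, 500-bin
instances in the acceptance suite. Adding calls can only grow the
smoothed counts, so consensus *coverage* is monotone in the input — but
two neighboring regions can merge into one, so the number of boundaries
is not; the monotonicity test asserts coverage, not count.

# Motif scanning

PFMs are regularized with pseudocounts proportional to the scanning
background — A = T = 0.30, C = G = 0.20, matching a genome of roughly
40 % GC — with total weight 1 per column by default, then converted to
log2-odds against that same background.

The score threshold is calibrated to a target false-positive rate
(default 1e-4 per window) by dynamic programming over the distribution of
quantized position scores under an i.i.d. background: the score range is
cut into `precision` = 1e4 steps ("precision 1e4" in the
TFM-pvalue sense), per-position scores are floored onto the grid, their
distributions convolved, and the threshold is the smallest *achievable*
quantized score whose tail probability is within the FPR (if even the
best word is too probable, one step above it). For motif lengths ≤ 8 the
DP result is checked against exhaustive 4^L enumeration — both the
validity (tail ≤ FPR) and minimality (one achievable step lower violates
it) of the returned threshold — and the empirical background hit rate at
FPR 1e-4 is measured over 100 seeds × 10 kb, where the expected hit count
is 2 · (10000 − L + 1) · 1e-4 across both strands.

Scanning is case-insensitive, skips every window containing a non-ACGT
base, and reports `-` strand hits (scored with the reverse-complement
matrix) at their forward-sequence interval. CTCF peaks take the
orientation of their *best-scoring* contained hit — one arrow per site,
as such maps are drawn — and a pair of adjacent oriented sites is
convergent ("inversely oriented") when the left is `+` and the right `-`.
Enrichment of a motif in differential regions is a one-sided exact
binomial test of the hit-containing fraction against the full
extended-region background; unlike HOMER's `-size given` protocol the
background is not length-matched, which is noted as a limitation rather
than silently approximated.

# Rearrangements

Translocation calls are filtered at quality ≥ 255 and ≥ 15 supporting
reads, both inclusive. Donor breakends are classified by genomic
containment: pattern 3 within the FDCSP-like first intron, pattern 1
between the convergent CTCF pair and outside any gene, pattern 2 within
the STATH/HTN3/HTN1-like triple-gene span. Precedence is 3 > 1 > 2 — the
most specific containment wins; the real patterns never overlap, so
precedence only disambiguates synthetic edge cases. The acceptor breakend
is separately flagged when it falls in the ~600-bp window directly
upstream of the TSS.

Derived-chromosome reconstruction uses an explicit breakend convention,
documented in the SV table header: strand `+` means the segment to the
*left* of the position is retained, `-` the segment to the right. The
acceptor side must retain the TSS (otherwise the reconstruction errors —
there is no gene left to hijack). Each donor feature surviving on the
derived chromosome is reported with distance-to-TSS = (breakend→TSS
distance on the acceptor) + (feature's nearest-edge distance to the donor
breakend along the retained side); features straddling the junction get
donor-side distance 0. Measuring from the nearest edge matches how
"peak at ~90 kb upstream of the breakpoint" is read off a browser track.
Mirroring the donor chromosome and flipping the breakend strand leaves
every distance unchanged — an exact symmetry the tests exercise on
hundreds of random configurations, alongside an independent
coordinate-concatenation oracle.

The insulator check flags a call when an acceptor CTCF site and the TSS
lie on opposite sides of the acceptor breakend — e.g. the site 13.5 kb
upstream of the TSS is separated by any junction within the 600-bp
upstream window.

# Quantification and cohorts

FPKM and TPM are computed with library sizes (and TPM rate sums) over
*included* genes only: genes on chrX, chrY and the mitochondrial genome
and genes of rRNA/tRNA biotype are excluded because they bias library-size
estimation; excluded genes still receive values against the included-only
denominator. TPM over included genes sums to 1e6 and both measures are
invariant under global count scaling — identities asserted directly.
Per-gene log2 fold change of mean TPM is provided as descriptive plumbing
only; proper differential testing belongs to count-model tools and is
out of scope.

Peak–gene association, used to summarize which genes have up/down
regulatory regions nearby, is deliberately simple because no published
rule exists to copy: a gene is flagged for a class when at least one
region of that class has its midpoint within 50 kb (configurable) of the
gene's TSS. Midpoint-in-window is order-independent and testable against
an all-pairs oracle.

Break-apart FISH cases are scored rearranged when the aberrant-cell
fraction strictly exceeds 20 % of the (default 50) inspected cells.
Cohort summaries exclude non-evaluable cases from denominators and round
percentages half away from zero — the convention that turns 24/28 into
86 % and 28/29 into 97 %.

# The synthetic-data module

`generateLocus` builds the study configuration: two 1-Mb synthetic
chromosomes (`chr4s`, `chr9s`; the *s* avoids any confusion with a real
genome build). The donor carries an eight-gene cluster across ~340 kb
including an FDCSP-like gene with introns and the triple span of the
three most abundantly expressed genes; a convergent CTCF pair at
470/500 kb bounding the pattern-1 window; and five planted enhancers
(fold 5–15 over background, seeded jitter). The acceptor has a TSS at
500 kb with a CTCF site 13.5 kb upstream. All downstream generators draw
from this model, so every record traces to planted truth.

Noise models are the simplest matching the assumed structure: tag
positions are multinomial draws proportional to the per-bp rate
(background × planted fold), which conditional on totals is the Poisson
background model; read counts are negative binomial (dispersion 0.05,
planted 4-fold tumor change in the proto-oncogene analogue); FISH tallies
are binomial (aberrant-cell probability 0.6 for planted-positive cases,
0.02 for negative, 50 cells); boundary calls get integer Gaussian jitter
and Bernoulli dropout. Tag strand assignment mimics the real ChIP shift:
forward tags sit half a fragment length left of fragment centers, reverse
tags right. The tumor condition adds a strong (fold 8) 2-kb region
directly upstream of the acceptor TSS, emulating the acquired regulatory
activity. Translocation pattern calls place the acceptor breakend in the
600-bp upstream window with probability 1 by default (configurable), so
planted-truth recovery is deterministic; noise calls each fail exactly
one of the two filter criteria.

What the generator does **not** emulate: read sequences, sequencing
error, mappability and blacklist structure, GC bias, replicate structure
beyond seeds, copy-number changes, and real breakpoint microhomology.
Passing the planted-truth tests therefore demonstrates algorithmic
correctness under the stated statistical models — not robustness to the
full messiness of real libraries, which is what the parameter defaults
(blacklist input, downsampling, quality/support filters) are for.

# Problem sizes and determinism

The test and acceptance suites run at desk scale by design: 1,000 random
instances (29 samples × 500 bins) for the TAD oracle, exhaustive 4^L
enumeration up to L = 8, 100 × 10-kb sequences for the empirical FPR,
50 seeds × 10 regions for noisy differential recovery, 500 random fusion
configurations for the reconstruction oracle, and a 15-call planted
cohort (4/10/1 across patterns, plus sub-threshold noise). Every
generator takes an explicit seed and restores the caller's RNG state;
identical seeds give byte-identical outputs.

# Known limitations

* The enrichment detector is a stand-in, not a peak caller; use MACS or
  SICER output for real data.
* Motif enrichment does not length-match its background.
* The fragment extension length is a parameter, not estimated from the
  data.
* Differential classification reports a single aggregate class per
  region; per-sample ratios are returned but not summarized into any
  heterogeneity statistic.
* BAM input is not parsed; tag tables are plain TSV (convert with
  `samtools view` upstream).
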