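---
title: "Promoter motif enrichment and gene-set overlap: models and design"
author: "regscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter motif enrichment and gene-set overlap: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscan)
```

# Scope

`regscan` implements the computational core of a promoter-level analysis
of transcriptional response: motif scanning and over-representation in
promoter sets, canonical E-box positional analysis, a
differential-expression filter cascade with two-cell-line
cross-comparison, observed-vs-expected overlap with clustered
target-gene catalogs, and Fisher-exact pathway enrichment with bipartite
network reconstruction. A synthetic-data module generates every input
with planted ground truth, so each stage can be validated against known
answers.

This vignette documents the models, the parameters that matter, the
numerical choices, and the design decisions taken where the analysis was
genuinely under-determined.

# Coordinates and promoter windows

All coordinates are 0-based half-open internally; BED input is consumed
natively. The transcription start site (TSS) is position 0 of
promoter-relative coordinates, upstream offsets are negative, and the TSS
base itself counts as the first downstream base, so an
up/down window of (u, d) has length exactly u + d. Two presets recur:
(−1000, +200) for motif over-representation and (−3000, +500) for E-box
positional analysis.

Minus-strand windows are reverse-complemented at extraction so every
promoter reads 5′→3′ on its gene's strand; a scanner never needs to know
the gene's genomic strand. The strand-symmetry property (extracting a
minus-strand promoter equals extracting the plus-strand promoter of the
reverse-complemented chromosome at the mirrored coordinate) is enforced
by a test. Promoters are retrieved from a local FASTA + BED6 pair rather
than from an annotation service; this is a deliberate substitution that
makes runs self-contained and reproducible.

N bases are preserved in extraction; scanners are responsible for
skipping windows that contain them.

# Motif scanning

## The posterior-odds threshold

A window $w$ of motif width is a hit when

$$\log \frac{P(w \mid M)}{P(w \mid B)} \;>\; \log \frac{1 - p}{p},$$

where $M$ is the
position frequency matrix, $B$ an order-0 background, and $p$ the prior
probability that any scanned window is a site. This is the classical
scanner thresholding rule in which the hit condition is "posterior odds
of motif versus background exceed 1". The exact internal threshold
function of the historical scanner this mirrors is not published; the
posterior-odds rule is this package's committed interpretation, exposed
through a single interpretable knob (`prior`, default 0.1) and flagged
for sensitivity analysis rather than hidden.

Practical consequences, all under test:

* raising the prior lowers the threshold, and hit sets grow
  monotonically (supersets);
* a prior small enough that the threshold exceeds the maximum attainable
  log-odds yields zero hits on any sequence;
* a point-mass matrix reproduces the exact-consensus hit set.

## Background model and pseudocount

The background is order-0 (base frequencies), either given directly or
estimated from a user-supplied background promoter FASTA. Count matrices
are regularized with a pseudocount (default 0.01 per position)
distributed proportionally to the background frequencies:
$f_{jb} = (c_{jb} + \epsilon \beta_b) / (\sum_b c_{jb} + \epsilon)$.
Zero background frequencies are rejected because the log-odds is then
undefined.

## Strands, palindromes, N windows

Both strands are scanned by default, the minus strand by scoring the
reverse-complemented window against the same matrix. A
self-reverse-complementary window that passes on both strands (the
canonical E-box CACGTG is the prototypical case) is a single physical
site and is reported once; this makes both-strand and forward-only scans
identical for palindromic patterns, which a property test asserts.
Windows containing N are skipped silently but counted per promoter in
the `skipped` attribute. Overlapping and nested hits are all reported —
no greedy masking — because real promoter site lists include
overlapping variants of the same E-box core.

PWM scanning is verified exactly (offsets, strands and scores to 1e-12)
against a brute-force window-enumeration oracle written independently in
the test suite.

# Motif over-representation

For each matrix, `n` counts hit *instances* in the foreground (a
promoter with two sites contributes two), matching how published
feature-count tables are defined. The expected rate per promoter is
estimated on a background promoter set and rescaled per-bp when the
foreground window length differs. The test statistic is the exact
binomial upper tail $P(X \ge n)$ with $X \sim \mathrm{Binomial}(gW,
r/W)$ for $g$ promoters and $W$ scannable windows per promoter; a
Poisson tail with $\lambda = gr$ is the documented fallback beyond
$gW > 10^6$, where the two are numerically indistinguishable. The
binomial is exact at desk scale and is preferred over the Poisson as the
primary model.

The reported significance is $-\log_{10}(p \cdot m)$ where $m$ is the
number of matrices scanned in the run; positive values mean the
Bonferroni-corrected p is below 1. A multiplier equal to the matrix
count reproduces, within ±0.02, all five printed
(probability → significance) pairs of the published table this scoring
mirrors, with a single integer multiplier of 264; since that count is
not itself printed, the package treats the multiplier as run metadata
(always emitted), never as a constant.

Calibration: on null promoters the fraction of matrices reaching
p < 0.05 sits slightly *below* 0.05 because the binomial tail is
discrete; with expected counts of order 30 the attained level is ≈0.046.
The type-I suite asserts the 0.05 ± 0.02 band over 420 null replicates.

# E-box positional analysis

Canonical E-boxes are found by exact consensus match (`CACGTG`; IUPAC
patterns are supported generally). Offsets are the site's first base in
gene-strand orientation. Density estimates are emitted two ways, and the
choice is recorded in output metadata rather than silently made:

* a histogram with 50-bp bins, normalized to integrate to 1;
* an optional Gaussian kernel (Silverman's bandwidth) for plotting.

The per-promoter count distributions are compared between up- and
down-regulated groups with a Fisher exact test on the 2×2 table
(≥k E-boxes vs fewer) × (up vs down). The threshold k defaults to 2 —
the "promoters with two E-boxes" comparison — but both k and the table
construction are exposed as parameters because the original tabulation
behind such comparisons is typically not recoverable from a published
figure legend. The Fisher p is verified against exhaustive
hypergeometric enumeration for all tables with margins ≤ 12.

# Differential expression

## The filter cascade and its composition

A gene is called responsive when it passes, in order:

1. |linear fold change| ≥ 1.2 **and** raw two-sided t-test p ≤ 0.01
   (the screen);
2. Benjamini–Hochberg q ≤ 0.05, computed **within the screened set**.

The composition order is a real decision, not bookkeeping. At triplicate
sample sizes (df = 4) a BH adjustment across all ~10⁴ genes of an array
demands raw p-values around 10⁻⁴–10⁻⁵ before any gene reaches q ≤ 0.05,
which no moderate fold change can deliver with three replicates —
composing the gates that way yields empty gene lists at realistic effect
sizes. Screening first and adjusting among survivors follows the stated
order of the workflow this package mirrors (exclusion first, corrected
test second) and keeps each printed threshold meaningful. The q column
is NA for genes that fail the screen.

The t-test is Student's with pooled variance (the classical two-sample
default for triplicate arrays); Welch's form is available by flag.
Zero-variance genes with zero mean difference get p = 1; zero-variance
genes with a nonzero difference get p = 0 rather than NaN. Fold changes
are displayed in the signed-reciprocal convention (ratios below 1 as
negative reciprocals) so |FC| ≥ 1 always.

A one-way F-test screen across ≥2 experimental groups with BH adjustment
is provided (`ftest_screen`) for the multi-group "any difference"
filtering that precedes clustering displays; the statistic behind
published multi-group feature counts of this kind is usually unnamed, so
this is offered as a stand-in and not claimed as a replication.

## What recovery the cascade can deliver

With the generator's default study conditions — 10,000 genes, 5% shifted
by ±1 log2 unit, per-observation noise SD 0.25, three replicates — the
noncentral-t power of the raw screen at α = 0.01, df = 4 and
noncentrality $1 / (0.25\sqrt{2/3}) = 4.90$ is 0.63. The cascade's
sensitivity for planted genes is therefore ≈0.63, and the screened-set
BH step does not control the overall FDR of the *composition* (screening
biases the surviving nulls toward large observed effects), which lands
near 0.15–0.2 in simulation. These are properties of the published
filter settings at triplicate scale, not implementation artifacts; the
acceptance suite reports them as measured rather than adjusting the
generator to flatter numbers.

## Cross-comparison

Two cell lines' responsive sets decompose into exclusive-to-A,
exclusive-to-B and shared; shared splits disjointly into co-up, co-down
and opposite. The partition identity |shared| = |co-up| + |co-down| +
|opposite| is asserted on every computed object. `median_center` centers
expression ratios per gene across analyses before display-oriented
comparisons.

# Target-catalog overlap

The catalog is a set of pairwise-disjoint clusters inside a declared
universe. The expectation for a responsive set of size $t$ against a
scope of size $K$ is the hypergeometric mean $e = tK/N$; the test is the
1-df goodness-of-fit chi-square on the (target, non-target) split of the
responsive set, with no continuity correction:

$$\chi^2 = \frac{(o-e)^2}{e} + \frac{(o-e)^2}{t-e}.$$

Two design points deserve emphasis:

* **The universe is a required, logged input.** Published overlap
  analyses rarely state the universe behind their expected counts, and
  it is generally unrecoverable; making it implicit would hide the
  single number that most influences the result.
* **The goodness-of-fit framing** is the only one consistent with
  reporting (observed, expected, total) triples. It is exactly valid
  when targets are a fixed classification of the universe and the
  responsive set is a simple random draw; because the draw is without
  replacement, the observed count's variance carries a finite-population
  factor $(N-t)/(N-1)$ the chi-square ignores, so the test is mildly
  conservative (attained level ≈0.04 at $t/N \approx 0.1$). The null
  calibration test asserts the 0.05 ± 0.03 band over 200 replicates.

Direction splits of each overlap (how many overlap genes were up- vs
down-regulated) are reported descriptively with a binomial sign-test p,
not a chi-square, because the statistic behind published up/down split
claims is unstated.

Probe-level inputs are collapsed to unique genes before intersection
(`dedup_to_genes`) so multi-probe genes are counted once; unmapped
probes are dropped and counted, never fatal.

# Pathways and the bipartite network

Pathway enrichment is the one-sided Fisher exact test on (in-pathway ×
significant) over a declared universe. Raw and BH-adjusted p-values are
emitted side by side, because published "corrected" pathway p-values
rarely state their correction. A pathway's direction label is the
majority sign of its significant members, "mixed" on ties.

The network places pathways (with ≥1 significant member) and significant
genes as the two node classes, edges being membership. The hub score of
a gene is its degree; *critical genes* are those connected to at least
k (default 2) significant pathways, ranked by hub score with
alphabetical tie-breaks for determinism. This reconstruction rule is the
package's committed definition — the original network-reconstruction
procedure it mirrors is cited to external work in the source literature
and is not recoverable — so outputs are labelled a reconstruction, not a
replication. The no-significant-gene case degrades to an empty network
rather than an error, because it is a real outcome (a c-Myc-null line
can show over-represented pathways with no significant genes attached).

# The synthetic-data generators

Every generator is a pure function of (parameters, seed): the RNG state
is set locally and restored, so calls are byte-identical under a fixed
seed and never interact through session state.

* **Genome/TSS**: one chromosome of i.i.d. bases from the supplied base
  frequencies (order-0, matching the scanners' background model so the
  null is analytic); TSSs placed so every gene admits an unclipped
  −3000/+500 window.
* **Motif planting** overwrites bases rather than inserting, so
  coordinates never shift; offsets are drawn uniformly or from a
  TSS-peaked Gaussian (default peak −50 bp, spread 30 bp, emulating the
  observed concentration of E-boxes within ~100 bp upstream of the TSS);
  placements that would cross the window boundary are resampled with a
  bounded retry budget and then fail loudly.
* **Expression**: per-gene baselines plus i.i.d. Gaussian noise on the
  log2 scale; a fixed fraction of genes is shifted by ±lfc in the
  treated condition. Defaults (3 replicates, 5% DE, lfc 1, noise SD
  0.25) are the study conditions the pipeline mirrors.
* **Target catalogs**: clusters drawn without replacement in cluster
  order (reproducible disjointness) with responsive genes weighted by
  the enrichment factor; the default cluster sizes (1712, 1643, 616,
  178, 30) mirror the published temporal-cluster catalog.
* **Pathways**: sizes uniform over a range (default 10–100, the size
  scale of curated pathway databases as mapped to an array); enriched
  pathways oversample the significant set, and an optional planted hub
  gene joins every enriched pathway.
* **Motif libraries**: random sharp position frequency matrices. The
  sharpness default is deliberately high (per-position Gamma(0.1)
  weights at depth 50) so decoy hit rates are of order one per kilobase,
  like curated transcription-factor matrices; soft matrices with tens of
  hits per promoter would put the binomial test in a large-count regime
  where tiny relative errors in the estimated background rate dominate.

What the generators deliberately do **not** emulate: probe-level
intensities, normalization artifacts, batch effects, correlated genes,
GC or repeat structure, and isoform-resolved TSS choice. Passing tests
on this synthetic data therefore validate the statistical machinery and
its calibration under the stated models — they do not certify
performance on real microarray data, where variance moderation and
annotation quality dominate.

# Problem sizes and numerical choices

The test and acceptance workloads were sized to be decisive yet quick:
oracle equivalence on 200 random 1.2-kb promoters; 420 null replicates
for motif-test calibration; 200 null catalogs at a 20,000-gene universe;
400 null pathways at a 4,000-gene universe; DE recovery at 10,000 genes.
Probability-vector sums are validated to 1e-9; oracle agreement is
asserted to 1e-12 on scores and 1e-10 on exact-test p-values;
probabilities that underflow to zero are capped at a significance score
of 300 (the double-precision decade limit) with a warning. Ties in
critical-gene ranking break alphabetically; all tables sort on stable
keys so serialized outputs are deterministic.

# Known limitations

* The posterior-odds threshold is an interpretation of an incompletely
  documented scanner; other thresholding rules would shift absolute hit
  counts (though not the calibration machinery around them).
* The binomial over-representation test treats the estimated background
  rate as known; with very permissive matrices (high hit rates) the
  extra estimation variance makes it anti-conservative. Use
  information-rich matrices or larger background sets.
* BH within the screened set does not control the FDR of the full
  cascade (see above); the cascade is faithful to its source, not
  optimal. A variance-moderated test would dominate it at triplicate
  scale.
* Cluster-level overlap p-values from the goodness-of-fit framing need
  not match published per-cluster significance claims, whose test
  construction is unknown and deliberately not imitated.
* One TSS per gene is assumed; transcript-isoform TSS selection is out
  of scope.
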