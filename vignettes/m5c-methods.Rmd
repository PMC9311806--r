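---
title: "Methods: calling and comparing RNA m5C sites from bisulfite sequencing"
author: "m5cpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and comparing RNA m5C sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5cpipe)
```

## The measurement model

Bisulfite treatment deaminates unmethylated cytosines to uracil, so after
reverse transcription and sequencing they read as T, while 5-methylcytosine
(m5C) resists conversion and still reads as C. A site's methylation level is
therefore estimated by the fraction of reads in which its cytosine stayed
unconverted,

\[ \hat m = M / C, \]

where \(C\) is the clean read coverage of the cytosine and \(M\) the number
of unconverted observations. Two failure modes mimic methylation and drive
the package's filter design:

* **incomplete conversion** of a whole molecule (chemistry failure), which
  leaves many cytosines of one read unconverted, and
* **structure-protected cytosines** inside stably base-paired RNA, where
  the single-strand-specific chemistry cannot act.

The true conversion rate \(r\) of the experiment is calibrated from an in
vitro transcribed, fully unmethylated spike-in mRNA added at 0.5% before
treatment: every unconverted spike-in cytosine is a conversion failure, so
\(\hat r\) is a simple binomial proportion with a Clopper–Pearson interval
(`estimate_conversion_rate()`). The estimate deliberately excludes spike-in
reads that fail the 3C rule below. Globally failed molecules are removed
from *all* evidence as noise, so the calibration should describe the failure
rate the calling null model actually faces; averaging them in would drag
\(\hat r\) far below the chemistry's per-cytosine rate (with the simulator's
defaults, to about 98.9%) while contributing nothing to the filtered
pileups. At the default rate the exclusion almost never triggers on a
genuine read (upper-tail probability around 1e-9), so the estimator remains
an unbiased proportion.

## The filter cascade

Candidate sites pass through five filters, in order, per library
(`three_c_filter()`, `apply_site_filters()`,
`remove_structural_sites()`):

1. **3C filter** — reads with more than 3 unconverted cytosines are
   discarded as incompletely converted; exactly 3 is still clean.
2. **Standard filter** — clean coverage \(C \ge 20\), level
   \(m \ge 0.1\), methylated depth \(M \ge 6\) (all inclusive).
3. **Signal/noise filter** — \(\mathrm{S/N} = C_{clean}/C_{total}\) must be
   *strictly* greater than 0.9; a site at exactly 0.9 fails.
4. **FDR filter** — the one-sided binomial p-value of observing \(\ge M\)
   unconverted draws at failure rate \(1-\hat r\), BH-adjusted over the
   sites that survive the standard filter, must be *strictly* below 0.05.
5. **Structure filter** — sites inside predicted conversion-resistant
   regions are removed.

A site is **high-confidence** only when it passes all filters independently
in both biological replicates (`merge_replicates()`); its merged level pools
counts, \((M_1+M_2)/(C_1+C_2)\).

Numerical notes: with \(M = 0\) the binomial tail is exactly 1; with
\(\hat r = 1\) and \(M \ge 1\) the p-value underflows to zero and is floored
at the smallest representable double with a `p_underflow` flag. The BH
universe is per library and per filter stage by design: adjusting over the
standard-filter survivors mirrors the stated filter order, and the choice
matters because it fixes the denominator of the adjustment. Two threshold
strictness conventions are intentionally different — site-level FDR is
strict (`< 0.05`) while differential-methylation FDR is inclusive
(`<= 0.05`) — preserving the distinct inequalities stated for the two
stages rather than harmonizing them.

## The structure filter

The default predictor is a conservative pairing heuristic, not free-energy
minimization: a Nussinov-style maximum-pairing recursion (Watson–Crick plus
G:U) constrained to pair spans of at most 150 nt, helices of at least 6
stacked pairs, and hairpin loops of at least 3 nt. Each maximal helix
defines a candidate interval from its 5' arm to its 3' arm; intervals whose
paired-base fraction reaches 0.8 are reported and merged. The helix-length
constraint is what makes the heuristic usable: unconstrained maximum
pairing marks most of any RNA as paired, whereas requiring 6 uninterrupted
stacked pairs keeps the spurious footprint on random sequence at a few
percent of bases while detecting planted perfect stems essentially always.
The constants (span 150, helix 6, paired fraction 0.8, loop 3) are package
constants, chosen once; only the span corresponds to a published parameter
of the thermodynamic folder the hook wraps.

When fidelity to a thermodynamic model is wanted, `method = "rnafold"`
shells out to an external `RNAfold` executable (passing span, temperature
70 and MEA gamma 0.1), parses the dot-bracket output and applies the same
region-extraction rule. Temperature has no meaning in the internal
heuristic and is passed through to the hook only.

## Differential methylation

For two conditions, a site is eligible when every replicate of both
conditions covers it with at least 10 clean reads and it is high-confidence
in at least one condition. Replicate counts are pooled per condition into
one 2x2 table (methylated/unmethylated by condition) — pooling, rather than
averaging, keeps the test exact and matches the convention of the odds-ratio
formulation used in this field; per-replicate coverage still gates
eligibility. The two-sided Fisher exact p follows the minimum-likelihood
convention (sum of hypergeometric probabilities not exceeding the observed
table's, with the standard 1 + 1e-7 tie tolerance); it is computed directly
from the hypergeometric density so thousands of sites vectorize cheaply,
and the test suite pins it against both `stats::fisher.test()` and an
exhaustive table-enumeration oracle for every margin up to 30. The odds
ratio is the sample OR \((M_A U_B)/(U_A M_B)\) with a Haldane 0.5 added to
every cell only when a cell is zero — the p-value stays exact. Sites with
BH-adjusted p at or below 0.05 are DMS, hypermethylated when
\(\Delta m = m_B - m_A > 0\) with the later condition as B.

## Differential expression and response classes

The package's internal DE test is a documented substitute for a full
negative-binomial analysis, because the downstream contribution lies in the
thresholds and response-gene classification, not the count model: counts
are normalized with median-of-ratios size factors, log2-transformed with a
0.5 pseudocount, and tested with an empirical-Bayes moderated t-test with a
mean-variance trend (limma) on the normalized log counts. The reported fold
change is the ratio of normalized condition means (pseudocount 0.5 keeps it
finite). With only two replicates per condition an unmoderated gene-wise
t-test has two degrees of freedom and essentially no power; variance
moderation across genes is the standard remedy. Results from an external
DE tool can be substituted via `import_de_results()`.

A DEG requires adjusted p at or below 0.05 **and** linear fold change
strictly above 2 (down-regulation symmetric, below 1/2); a fold change of
exactly 2 is not a DEG. Across the 0, 2, 6 h depolarization time course,
**early** response genes are up at 2 h and down again between 2 and 6 h;
**late** genes are up at 6 h in both the 0v6 and 2v6 comparisons. The two
sets are provably disjoint (a gene cannot be both up and down in 2v6), and
the implementation asserts it.

## Integration analytics

* **Metagene profile** — mRNA sites map into 45 ordered bins, 5/22/18 for
  5'UTR/CDS/3'UTR, mirroring the transcriptome-average segment-length
  ratio; a site at relative position \(f \in [0,1)\) of segment \(s\) falls
  in bin \(\mathrm{offset}(s) + \lfloor f \cdot \mathrm{bins}(s) \rfloor +
  1\). Percentages are over binned sites and sum to 100; the smoothed track
  is a window-3 moving average truncated at the edges (the smallest
  symmetric window, since none is prescribed).
* **Sequence context** — counts of A/C/G/U at offsets -5..+5 around each
  site; the center column is all C by construction and edge truncations are
  reported as gaps.
* **Clustering** — temporal profiles (expression or methylation levels)
  are Z-scored per row and clustered by k-means with 10 restarts under a
  fixed seed; labels are relabeled by descending cluster size for
  determinism. k-means on Z-scores is the simplest method consistent with
  the heatmap-style cluster structure this analysis targets; k is fixed at
  4 for expression and 5 for methylation profiles. Constant rows cannot be
  Z-scored and are rejected (the pipeline drops them with a log line).
* **Methylation–expression correlation** — each DMS contributes one pair
  (its gene's log2 fold change, its level difference \(\Delta m\)); Pearson
  correlation with a two-sided test. \(\Delta m\) — not the log OR — is the
  methylation-change axis, matching how level differences are usually
  displayed. When a gene carries several DMS, each site contributes a pair
  re-using the gene's single fold change. Sign categories: positive (hyper
  with up, hypo with down), negative (hyper with down, hypo with up),
  neutral (gene not a DEG); the three categories partition the pairs.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the emulated experiment: 3 time points x 2
replicates; mean segment lengths 100/440/360 nt (the 5:22:18 ratio);
uniform mean coverage 50; conversion rate 0.9995; 2% of reads from a failed
conversion process (per-cytosine unconversion 0.5 — chosen so such reads
almost surely violate the 3C rule, which is the filter they exist to
exercise; the true fraction in real libraries is not known and this default
is a free parameter, not an inference); a 0.5% unmethylated spike-in;
planted site levels Beta(2, 7), whose median of about 0.20 matches the
reported median methylation level; five temporal archetypes for
differential sites (up-then-down, up-and-stay, down-then-up, monotone up,
monotone down) with a planted level change of 0.3; four expression
archetypes (down, early, down-then-up, late); negative-binomial counts
(dispersion 0.05, log-normal baselines around 500); and a planted coupling
of -0.4 between methylation change and log2 expression change at
DMS-carrying genes. Hairpin regions (perfect 25-bp stems, 4-nt loops,
conversion probability multiplied by 0.1) create the false-positive class
the structure filter must remove; planted true sites are kept out of
hairpins so truth labels stay unambiguous. Genes carrying a differential
site receive the coupled expression shifts instead of an archetype, keeping
the two plantings from confounding each other. Each stage draws from its
own RNG stream derived from the master seed, so regenerating one library
leaves the transcriptome unchanged.

Deliberately not modeled: sequencing errors and base qualities, PCR
duplicates, alignment ambiguity (reads are born aligned in transcript
space), fragment-length and positional coverage biases beyond the natural
ramp at transcript ends, expression-dependent coverage, and genome-space
(spliced) coordinates. Passing tests on this generator therefore
demonstrate the statistical machinery — calibration, filtering, testing,
integration — not robustness to alignment artifacts or coverage bias in
real libraries.

## Validation problem sizes

The test suite validates the pipeline's statistical properties at sizes
chosen for quick, repeated desk runs: conversion-rate recovery from about
1.1e5 spike-in cytosines; Fisher equivalence against enumeration for all
2x2 tables with row margins up to 30 (about 2.45e5 tables); planted-site
recovery with 200 sites at level 0.3 and depth 50 among about 9,700 null
cytosines, 10 seeds (sensitivity here is scored on sites planted where
coverage reaches its nominal depth — the ramp within a read length of the
transcript ends carries systematically fewer reads, which is a property of
coverage, not of the caller); label-permuted type-I control over 10 seeds
for both the methylation and the expression test (2,000 null genes);
structure-filter efficacy over 10 seeds; and coupling recovery with about
200 called DMS genes over 10 seeds for both the planted and the null
coupling. The same drivers (`*_experiment()` functions) back the
acceptance script.

## Known limitations

* The internal fold is a pairing heuristic; thermodynamically weak but
  perfectly complementary repeats are flagged while stable non-canonical
  structures are missed. The external hook restores fidelity when a folding
  binary is available.
* Pooling replicates for the Fisher test ignores between-replicate
  overdispersion of methylation levels; a beta-binomial model is out of
  scope.
* The moderated log-count DE test is calibrated but less powerful than a
  dedicated NB framework at very low counts; the importer exists for that
  reason.
* With two replicates the replicate-intersection rule is a hard AND; it
  does not generalize to "present in k of n" designs.
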