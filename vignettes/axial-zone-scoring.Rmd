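---
title: "Scoring axial zone specificity from multi-zone RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring axial zone specificity from multi-zone RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Regional bulk RNA-seq cuts an animal along its anterior–posterior (A–P)
axis into a few ordered tissue zones — in the motivating design, a planarian
flatworm amputated into six fragments, each sequenced as a single pooled
library — and asks, per transcript: *is expression restricted to a
contiguous region of the axis, and to which zones?* The canonical positive
controls are HOX genes, whose staggered axial domains and posterior
expression gradients this kind of data should recover.

`axiszone` implements that analysis as a reusable, tested pipeline:

1. **Filter**: drop transcripts below a CPM cutoff in *every* zone.
2. **Normalize**: TMM factors, effective library sizes, normalized CPM.
3. **Test**: for each zone, a one-vs-rest negative-binomial conditional
   exact test of the zone against the pooled remaining zones.
4. **Code**: zones that are significant (BH q ≤ α) with positive log fold
   change form a composite membership code, highest expression first —
   `"2.1"` means specific to zones 1 and 2 with higher expression in zone 2.

```{r}
library(axiszone)
sim <- simulate_zone_counts(simulation_config(n_transcripts = 1500, seed = 1))
res <- run_pipeline(sim$table, run_config(seed = 1))
res
```

# Model and assumptions

## Counts and normalization

Counts \(K_{gz}\) for transcript \(g\) in zone \(z\) are modelled as
negative binomial with mean \(\mu_{gz} = p_{gz} L_z\) (relative abundance
times library size) and variance \(\mu + \phi\mu^2\); \(\phi = 0\) is
Poisson. Because each zone contributes different proportions of tissue
types, raw library sizes misstate the sequencing-effort difference between
zones; TMM corrects this with one factor \(f_z\) per zone:

- effective library size \(E_z = L_z f_z\),
- normalized CPM \(= 10^6 K_{gz} / E_z\).

`tmm_factors()` implements the trimmed mean of M-values from scratch:
reference zone by 75th-percentile CPM closest to the across-zone mean;
pairwise M (log2 ratio of library-size-scaled proportions) and A (mean log2
abundance) over transcripts positive in both zones; two-sided trims of 30%
on M and 5% on A; inverse delta-method-variance weighted mean of the
surviving M values; factors rescaled to geometric mean 1. The unit suite
checks it against an independently coded step-by-step evaluation (explicit
loops) to 1e-9 on random matrices, and against `edgeR::calcNormFactors` as
an external reference.

A consequence of the inverse-variance weights worth knowing: the factors
are only *approximately* invariant to a pure depth change. Doubling one
zone's counts halves that zone's pairwise weights but not the reference's,
so every factor shifts by roughly 0.1–0.4% (the reference implementation
shifts identically). Membership codes are stable under such a change;
normalized CPM moves at the per-mille level, not at machine precision.

## The low-expression filter

A transcript is removed only when its CPM (computed with raw library sizes,
factors of 1) is below the cutoff in **all** zones. The other reading —
require the cutoff everywhere — would delete exactly the single-zone
transcripts the analysis exists to find. The default cutoff of 0.5 CPM
follows the motivating study; `cutoff_diagnostic()` supports choosing it by
reporting, per candidate cutoff, the maximum pairwise Kolmogorov–Smirnov
statistic between zone log-CPM distributions after filtering (plus the
quartiles, distance matrix and MDS coordinates behind the usual QC plots).
The cutoff choice itself stays a manual decision: the KS report is a
diagnostic, not an optimizer.

## The one-vs-rest exact test

Specificity of transcript \(g\) to zone \(z\) is tested by comparing zone
\(z\) (one library) against the five other zones pooled as \(Z-1\)
libraries — not as one summed library, so the null correctly reflects the
average over the other zones. The conditional exact test requires equal
library sizes, so counts are first rescaled to the geometric mean of the
effective sizes and rounded half-to-even (`equalize_libraries()`).

Under the null of equal relative abundance \(m\), group sums of \(n\) iid
NB\((m,\phi)\) libraries are NB\((nm, \phi/n)\). Conditional on the total
\(s\), the p-value sums the probabilities of all outcomes no more likely
than the observed one (the two-sided "small-p" rule, chosen over doubling
the smaller tail so that the enumeration oracle and the implementation use
the same definition). \(s = 0\) gives p = 1. The per-zone q-values are
Benjamini–Hochberg within each zone's family of transcripts.

**Dispersion.** The zoned design pools triplicate samples into one library
per zone, so \(\phi\) cannot be estimated from the data. It is an explicit
configuration parameter, default 0.1 — a deliberately conservative value
for pooled bulk RNA-seq — with `dispersion_mode = "poisson"` for \(\phi =
0\). Raising \(\phi\) *usually* increases p-values (noise inflation is
conservative) but not always: grid monitoring finds left-tail cells
(observed count far below the null mean) where extra dispersion reshapes
the small-p rejection set and the p-value dips slightly. The test suite
monitors this rather than asserting it.

## Membership codes

A zone is selected when q ≤ α and logFC > 0, where logFC is
\(\log_2\left((\mathrm{CPM}_z + c)/(\overline{\mathrm{CPM}}_{z' \ne z} +
c)\right)\) with prior pseudo-CPM \(c = 0.5\) keeping it finite. Selected
zones are ordered by normalized CPM descending — both of the scheme's
worked examples ("2.1", "1.2") are explained by expression, so expression,
not test score, drives the order — with ties broken by smaller p-value and
then by the more anterior zone (a documented convention; the original
scheme does not state one). `"none"` encodes no axial restriction.
`summarize_categories()` then bins transcripts by code, and
`order_for_heatmap()` produces the primary-zone-grouped, row-scaled matrix
behind the standard heatmap.

# The synthetic generator

`simulate_zone_counts()` emulates the measured structure of a zoned
experiment so every stage can be validated against planted truth:

- **6 zones, one pooled library each** (no replicates), library sizes
  \(2\times10^6 \pm 20\%\) uniform jitter;
- **log-normal baseline** relative abundance (meanlog 1, sdlog 1.5 —
  a realistic several-orders-of-magnitude spread);
- **archetypes**: flat 55%, single-zone 8× enrichment 8%, adjacent dual
  zones (stronger 2× the weaker) 6%, posterior and anterior geometric
  gradients (step 2 per zone, matching the posterior HOX gradients such
  data should show) 3% each, below-filter 25%. The proportions mirror the
  motivating study's scale, where roughly 30% of detected transcripts
  passed the filter and about a fifth of the kept ones were axially
  restricted;
- **NB noise** with \(\phi = 0.05\); \(\phi = 0\) gives Poisson draws.

Each transcript's *expected* code is derived from its planted profile: the
zones whose planted abundance exceeds the mean of the remaining zones,
ordered by abundance (flat and below-filter transcripts are `"none"`).
Below-filter transcripts are planted at a CPM drawn from (0.05, 0.30) with
a final rescale guaranteeing they sit under the cutoff in every zone.
`score_recovery()` reports per-archetype exact-code sensitivity, primary
zone agreement, and the false-restriction rate on flat transcripts.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: transcript-length and positional bias, batch effects,
correlated transcript programs (counts are independent across transcripts
given the library size), partially overlapping anatomical structures, and
any mismatch between annotation and transcriptome. Recovery rates on
synthetic data are upper bounds for real tissue.

# Numerical choices

- **Poisson cutover**: for \(\phi \le 10^{-8}\) the conditional law is
  evaluated as the exact binomial; NB densities with size \(1/\phi >
  10^8\) lose ~1e-8 of accuracy, which would defeat the Poisson-limit
  checks at 1e-10.
- **Large totals**: conditional enumeration is exact up to \(s = 10^4\);
  beyond that a continuity-corrected normal approximation to the
  conditional distribution is used and flagged in the `"approximate"`
  attribute (and column). Near the switch it is accurate to about 0.03
  absolute — adequate because such totals are far from any decision
  boundary in practice.
- **Ties in the small-p rule** use a \(1 + 10^{-10}\) relative tolerance so
  float noise cannot split exactly tied outcomes.
- **Equalization rounding** is half-to-even (banker's rounding), keeping
  column sums within 0.5 per transcript of their exact rescaled values.
- **Degenerate inputs**: all-zero zones are rejected at table validation; a
  zone sharing no positive transcript with the TMM reference gets factor 1
  with a warning; a filter cutoff that removes every transcript is an
  error, not an empty result.

# Problem sizes in the test suite

The packaged checks run at desk scale, chosen to keep the full suite under
a minute while leaving Monte-Carlo margins comfortable: oracle equivalence
on 100 random 10×3 matrices (TMM) and 200 random totals ≤ 200 (exact
test); null calibration on 5,000 flat transcripts; recovery on 500 planted
single-zone effects among 5,000 flat; fuzzing over 50 random simulator
configurations of 40–120 transcripts. The headline numbers of a full-scale
zoned study (tens of thousands of transcripts from >50M reads per zone) are
not reproduced here — they require the original raw data and alignment,
which are out of scope.

# Known limitations

- Dispersion is assumed, not estimated; conclusions about marginal
  significance move with it. Report it alongside results.
- The exact test treats zones as independent libraries; residual
  correlation from the amputation design is not modelled.
- TMM assumes most transcripts are not differentially expressed between
  zones; a dataset dominated by axial structure would bias the factors.
- Membership codes are per-zone calls; they do not enforce contiguity along
  the axis, so a noisy transcript can in principle receive a
  non-contiguous code.
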