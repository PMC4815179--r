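# axiszone

Zone-specificity scoring for anterior–posterior RNA-seq.

Regional bulk RNA-seq designs cut an animal along its anterior–posterior
axis into a few ordered tissue zones (classically a planarian flatworm
amputated into six fragments, each sequenced as one pooled library) and
ask, per transcript, whether expression is restricted to part of the axis
and to which zones. HOX genes, with their staggered axial domains and
posterior gradients, are the textbook positive controls. `axiszone` turns
that analysis into a tested, reusable R pipeline, for anyone with a
transcripts × zones count matrix and ordered zone labels.

## Method

For counts $K_{gz}$ with library sizes $L_z$:

1. **Filter** — drop transcripts with CPM < cutoff (default 0.5) in
   *every* zone; keeping any transcript that clears the cutoff somewhere
   protects exactly the zone-restricted transcripts of interest.
2. **Normalize** — trimmed-mean-of-M-values (TMM) factors $f_z$, computed
   from scratch (reference by 75th-percentile CPM; trimmed, inverse
   delta-method-variance-weighted mean of pairwise M-values; geometric
   mean 1). Then effective library size $E_z = L_z f_z$ and normalized
   CPM $= 10^6 K_{gz}/E_z$.
3. **Test** — per transcript and zone, a one-vs-rest negative-binomial
   conditional exact test: zone $z$ (one library) versus the pooled other
   zones ($Z-1$ libraries) on library-equalized counts, two-sided
   "small-p" rule, NB dispersion $\phi$ as an explicit parameter
   (variance $\mu + \phi\mu^2$; default 0.1, Poisson mode available), BH
   q-values within each zone.
4. **Code** — zones with q ≤ α and logFC > 0 form a composite membership
   code ordered by expression: `"2.1"` = specific to zones 1 and 2, higher
   in zone 2; `"1.2"` = same zones, higher in zone 1; `"none"` = no axial
   restriction. Codes are binned into categories and ordered for heatmaps.

A negative-binomial simulator (`simulate_zone_counts()`) generates zoned
matrices with planted archetypes — flat, single-zone, adjacent dual-zone,
anterior/posterior geometric gradients, below-filter — so every stage is
validated against known truth (`score_recovery()`).

## Worked example

```r
library(axiszone)
sim <- simulate_zone_counts(simulation_config(n_transcripts = 1500, seed = 1))
res <- run_pipeline(sim$table, run_config(seed = 1))
res
#> zone pipeline run: 1500 detected -> 1378 kept -> 302 axially restricted
#> 302 of 1378 transcripts axially restricted in 12 categories ( 6 multi-zone )
#> none    1    6    5    2    4    3  6.5  3.2  4.5  5.6  2.3  5.4
#> 1076   75   62   43   38   37   32    7    2    2    2    1    1
```

1,500 simulated transcripts are read in; 1,378 clear the 0.5-CPM filter;
302 receive a non-`"none"` membership code across 12 categories. Single
zones dominate the categories; multi-zone codes such as `"6.5"` (zones 6
and 5, higher in 6) come from the planted posterior gradients.

```r
assigned <- setNames(rep("none", 1500), sim$table$transcript_ids)
assigned[res$codes$transcript_id] <- res$codes$code
score_recovery(assigned, sim$truth)
#> recovery over 1500 transcripts
#>           archetype   n sensitivity primary_zone_agreement
#>        below_filter 375  0.99200000              0.9920000
#>       dual_adjacent  90  0.04444444              0.9555556
#>                flat 825  1.00000000              1.0000000
#>   gradient_anterior  45  0.00000000              1.0000000
#>  gradient_posterior  45  0.15555556              0.9777778
#>         single_zone 120  1.00000000              1.0000000
#> false-restriction rate (flat): 0
```

Planted single-zone effects (8-fold) are recovered exactly; flat
transcripts are never falsely restricted at this size. Composite codes are
conservative: for dual-adjacent and gradient transcripts the *primary* zone
is almost always right, but the weaker second zone often misses the
significance bar, so exact-code sensitivity is low at these effect sizes —
the expected behaviour of a q ≤ 0.05 call on a 2-fold secondary signal.

A command-line wrapper ships in `inst/exec/axiszone`
(`simulate | normalize | test | membership | run`), e.g.:

```sh
axiszone simulate --out counts.tsv --truth truth.tsv --seed 4
axiszone run --counts counts.tsv --out-dir results/ --seed 4 --verbose
```

writing `results.tsv` (per-zone CPM and q-values plus code per transcript),
`factors.tsv`, `categories.tsv`, `qc.tsv` and `manifest.json`.

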