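# focalnet

Social network analysis for focal-follow observation data on group-living
animals, built for one recurring question in behavioural research on
primates: **are individuals with a different early-life history (here:
wild-born, orphaned, sanctuary-rehabilitated chimpanzees) socially
distinguishable from their mother-reared, sanctuary-born group mates?**

The package provides the complete analysis chain as composable,
tibble-in/tibble-out functions:

1. **Data handling** — read and validate the three observation tables
   (focal follows, dyadic behaviour events, demographics), apply the
   per-day one-zero (1/0) sampling reduction, and compute Cohen's kappa
   for inter-observer reliability.
2. **Association indices** — per-dyad sampling counts and the
   *twice-weight* association index

   ```
   AI = x / (x + 2*y_AB + y_A + y_B)
   ```

   where, counting sampling days, `x` = both identified and associated,
   `y_AB` = both identified but not associated, and `y_A`, `y_B` = only
   one of the two identified. Half-weight and simple-ratio variants are
   available for sensitivity analysis.
3. **Network metrics** — the five standard per-individual weighted
   metrics: strength (`s_i = sum_j a_ij`), eigenvector centrality
   (leading eigenvector, unit norm), reach (`(A s)_i`, two-step
   strength), Holme-style weighted clustering, and affinity
   (`reach_i / s_i`).
4. **Inference** — node-label permutation tests (origin shuffled across
   individuals, network held fixed; Monte-Carlo with add-one correction
   or exact enumeration), Bonferroni-Holm correction, likelihood-ratio
   tests, and leave-one-subject-out stability diagnostics.
5. **Models** — Poisson party-size regression with observation-effort
   and demographic offsets and focal-level random intercepts
   (`lme4`), an early- vs later-orphaned contrast, and a two-part
   hurdle model (binomial-logit occurrence + Gamma-log magnitude) for
   the zero-inflated dyadic association indices.
6. **Synthetic data** — a generator that emulates a four-group, 78-animal
   sanctuary study (~3,200 follows over 200 days) with known ground
   truth, used for type-I calibration, power, and parameter-recovery
   studies.

## Worked example

```r
library(focalnet)

sim <- synth_generate(synth_scenario("paper_like"))  # known ground truth
obs <- sim$data

# daily 1/0 records and a per-group association matrix
daily <- aggregate_daily(obs, "proximity")
demo  <- obs$demographics
ids   <- demo$id[demo$group_id == "G1"]
A     <- build_assoc_matrix(daily[daily$group_id == "G1", ], ids)
print(A)
#> <assoc_matrix> 20 individuals, behaviour = proximity, index = twice-weight
#>   190 of 190 dyads non-missing; mean AI (non-missing) = 0.02573

node_metrics(A)
#> # A tibble: 20 x 6
#>   id     strength eigenvector reach clustering affinity
#>   <chr>     <dbl>       <dbl> <dbl>      <dbl>    <dbl>
#> 1 G1_I01    0.185      0.0595 0.103     0.0807    0.558
#> 2 G1_I02    0.465      0.115  0.265     0.0345    0.570
#> # ...

# the whole chain in one call
report <- run_pipeline(synth_scenario("paper_like"), n_perm = 999, seed = 1)
print(report)
#> == Origin-signature analysis report ==
#> Headline: no origin signature detected
#>
#> -- Party size --
#>   sanctuary-born: 5.89 +/- 2.64 (n = 1485 follows)
#>   wild-born: 5.81 +/- 2.60 (n = 1715 follows)
#>   origin LRT: chi2 = 1.042, p = 0.307; estimate = -0.089 +/- 0.087
#>
#> -- proximity --
#>   connected dyads: SS 65.97% (95/144), WS 62.17% (235/378), WW 61.00% (122/200)
#>   hurdle LRT (dyad_origin): binomial p = 0.673, gamma p = 0.645, joint p = 0.796
#>   strength     diff = -0.0002  p = 0.998  p(Holm) = 1.000
#> ...
```

The headline line answers the study question directly; the party-size
block reports group means (+/- SD), the likelihood-ratio test for the
origin term and its estimate on the log scale; each behaviour block
reports the percentage of connected dyads per dyad type (WW/WS/SS, with
numerator and denominator), the hurdle-model LRTs, and the five
permutation-tested network metrics with raw and Holm-corrected p-values.
In this example the generator injected a small true party-size effect
(-0.105 on the log scale); the fitted estimate (-0.089 +/- 0.087) covers
it, and — as in the real study system this emulates — the effect is too
small to reach significance at this sample size.

Result objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()`/`plot_*()` companions (`plot_party_size()`,
`plot_metric_distributions()`).

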