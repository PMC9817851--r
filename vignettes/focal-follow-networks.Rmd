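---
title: "Association networks and origin effects from focal-follow data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association networks and origin effects from focal-follow data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalnet)
```

## The scientific problem

Group-living primates with adverse early-life histories — in the
motivating system, wild-born chimpanzees orphaned by the pet and
bush-meat trades and later rehabilitated in sanctuary groups — may or
may not remain socially distinguishable from their mother-reared group
mates years later. The observable evidence is focal-follow data: timed
video follows of one individual at a time, recording how large a party
the focal moves in, who sits within arm's reach (proximity), and who
grooms with whom. `focalnet` turns such data into three complementary
analyses:

* a **party-size model** (is an individual's typical subgroup smaller if
  it was orphaned?),
* **dyadic association models** (is a dyad containing orphans less
  likely to associate at all, and less intensely when it does?), and
* **individual network metrics with permutation tests** (is an orphan
  less embedded in the group's weighted association network?).

A consistent *absence* of differences across all three levels is itself
the scientifically interesting outcome in the motivating system, which
is why the package pairs every test with calibration machinery: a
synthetic-data generator with known ground truth, so that "no effect
found" can be backed by demonstrated type-I control and power.

## From video to one-zero records

The sampling unit is the *day*. Per day and behaviour, a dyad is scored
1 if it had at least one event, else 0 (`aggregate_daily()`); repeated
same-day events are deliberately collapsed to blunt serial dependence
within a day. An individual counts as *identified* on a day if it was
captured on video at all — as a focal or inside any focal's party
(follow plus end-of-follow scan). Days with no follows for a group
produce no record: association denominators only count days on which at
least one dyad member was actually observable. Grooming identification
uses the same presence-on-video definition as proximity; being
identified does not require grooming anyone.

Two boundary rules are worth stating explicitly:

* A dyad never co-sampled (denominator zero) has a **missing** index,
  not zero — zero would assert observed non-association.
* An individual identified on zero days carries no sampling information,
  so its whole matrix row is masked missing, even though a literal
  reading of the index formula would return 0 against any co-sampled
  partner.

Follows shorter than 300 s (half the nominal 600 s follow) are excluded
on input, mirroring the usual field inclusion rule; the threshold is a
configuration option because it belongs to the collection protocol, not
the analysis.

## The twice-weight association index

For a dyad (A, B), count days: `x` associated, `y_AB` both identified
but not associated, `y_A`/`y_B` only one identified. The twice-weight
index

\[
\mathrm{AI} = \frac{x}{x + 2 y_{AB} + y_A + y_B}
\]

down-weights joint-identification-without-association twice. It is the
appropriate choice when associated individuals are *more* likely to be
observed than lone ones — exactly the situation in party-based video
sampling, where one follow documents a whole subgroup. Because its
denominator dominates those of the half-weight and simple-ratio
variants, twice-weight is always the most conservative of the three
(`assoc_index()` exposes all of them; the ordering is property-tested).
Groups are treated as closed networks: cross-group dyads are never
formed.

## Network metrics

Five per-individual weighted metrics are computed from the association
matrix (`node_metrics()`), following the conventions long established in
the SOCPROG lineage of association analysis:

| metric | definition | reading |
|---|---|---|
| strength | \(s_i = \sum_j a_{ij}\) | overall association mass |
| eigenvector centrality | leading eigenvector of \(A\), unit norm | connectedness weighted by partners' connectedness |
| reach | \(r_i = \sum_j a_{ij} s_j = (A^2)_{i\cdot}\mathbf{1}\) | two-step connectedness |
| clustering | \((A^3)_{ii} \,/\, (a_{\max} \sum_{j \ne k} a_{ij} a_{ik})\) | closure of the weighted neighbourhood |
| affinity | \(r_i / s_i\) | mean strength of one's associates |

Verbal one-line glosses of these metrics in the applied literature are
sometimes imprecise — "reach" in particular is occasionally glossed as a
shortest-path quantity. We implement the standard weighted two-step
definition above and treat verbal glosses as descriptions, not
definitions; the identity `affinity * strength = reach` is asserted in
the tests, and each metric is checked against explicit-summation
oracles.

Missing matrix entries enter metric computation as 0 ("no observed
association"), distinct from their representation in the matrix. On a
disconnected network the leading eigenvector concentrates on the
dominant component (zeros elsewhere); the package warns when this
happens. An edgeless network has no defined centrality:
`ai_eigenvector()` errors, and `node_metrics()` degrades to `NA` with a
warning so one sparse behaviour network cannot abort a whole pipeline.

## Permutation inference

`node_permutation_test()` shuffles the origin label across individuals
while holding the network — and therefore every metric value — fixed,
preserving label counts by construction. The test statistic is the
difference in label-class means (wild minus sanctuary); a median
difference is available, but the mean is the default because metric
distributions here are unimodal and the mean difference is what the
downstream family correction assumes exchangeable. The test is
two-tailed on the absolute statistic, which also makes it invariant to
swapping the label names.

Monte-Carlo p-values use the add-one convention,
\(p = (1 + \#\{|t^\ast| \ge |t|\})/(B + 1)\), so p can never be zero and
the test is exact-conservative at any B. For small networks
(`exhaustive = TRUE`) all \(\binom{n}{k}\) assignments are enumerated
and the exact proportion is returned. Ties are compared with an absolute
tolerance of 1e-12 so that floating-point noise cannot break the
mirror-assignment tie that every two-class mean difference has.

Labels are shuffled across all individuals by default ("keeping the
ratio constant" globally); within-group stratification is available
(`stratify_by`) for designs where group composition differs enough that
global exchangeability is doubtful. The Holm family is the full set of
metric tests in an analysis (5 per behaviour, 10 when both behaviours
are analysed), applied in one step across behaviours — the layout in
which such results are conventionally reported.

## The party-size model

Party size (the focal's subgroup *including itself*) is bounded below by
1, so the package models the **associate count** (party size minus one)
with a Poisson log link by default; the Poisson-on-size variant is
available (`response = "size"`) for comparability with analyses that
model the full count. Fixed effects are origin, z-scored rank and age,
and sex. Offsets:

* log in-view time relative to the nominal 600 s follow (observation
  effort);
* log group size and log family units per group (demographic context).
  The phrase "population size and number of family units with population
  as offset terms" admits two readings — two separate log offsets, or
  the log ratio of the two; the package defaults to two separate offsets
  and exposes the ratio reading (`demographic_offsets = "ratio"`), and
  records the choice in the fit object.

Repeated follows of one focal are not independent. The package uses
focal-level (optionally plus group-level) random intercepts via
`lme4::glmer` rather than a full random-slope structure: the target
quantity is the likelihood-ratio test of one fixed effect, focal-level
intercepts capture the dominant dependence, and every fit object carries
a note that the random-effect structure is simplified.

Because all fixed covariates are focal-level constants, the per-follow
Poisson likelihood factorises through per-focal totals: conditional on
the focal's random intercept, the summed count with a log-sum-exp effort
offset is sufficient, and the allocation across follows contributes only
a parameter-free multinomial constant. The default fit therefore
aggregates to one row per focal — identical coefficients and LRT
statistics (verified numerically in the tests against the follow-level
fit) at a fraction of the cost. `aggregate = FALSE` forces the
follow-level representation.

The early- vs later-orphaned contrast restricts to wild-born subjects
and splits at arrival age 3 years — arrival age proxies the age at
maternal loss — with *age exactly 3 assigned to the later stratum*
(the split is "< 3" vs ">= 3"). Empty strata are an error, not a silent
degenerate fit.

## The hurdle model for dyadic indices

Association indices are zero for many dyads and continuous positive for
the rest, so a single family fits poorly. The two-part model separates
*whether* a dyad is connected (binomial, logit link, all dyads with a
defined index) from *how strongly* (Gamma, log link, connected dyads
only), the parts sharing dyad-level covariates: origin composition
(SS/WS/WW), sex composition (FF/MF/MM), age composition
(subadult/adult at a configurable 12-year cutoff — the subadult/adult
boundary is not standardised, and 12 is a conventional choice for
chimpanzees), same-matriline kinship, and a log group-size offset. The
index is modelled on its own scale (it is strictly positive in the
Gamma part); no transformation is applied.

The Gamma shape is profiled by maximum likelihood
(`MASS::gamma.shape`), which makes the two-part log-likelihood a true
joint maximum — for a log-link Gamma GLM the coefficient estimates do
not depend on the shape, so profiling after the GLM fit is exact. That
in turn guarantees the nesting inequality for the per-part LRTs. The
dyad-origin effect is tested per part and jointly (summed chi-square,
summed df). Dyadic records are not independent — each individual sits in
many dyads — so `hurdle_origin_permutation()` additionally offers a
node-level permutation p-value for the joint statistic: origin is
shuffled at the individual level, dyad composition rebuilt, and the
model refit.

Model stability is probed by `loo_stability()`: refit with each subject
excluded and flag subjects whose exclusion moves the coefficient of
interest by more than one full-data standard error (configurable).

## The synthetic-data generator

`synth_generate()` emulates the motivating study design: 4 closed groups
totalling 78 individuals (42 wild-born, 36 sanctuary-born), 200
observation days with 4 follows per group per day (~3,200 follows, the
scale of a two-year field effort), in-view times of 300–600 s averaging
about 480 s, and wild-born arrival ages averaging 3.2 years. The
generative model:

1. Individual gregariousness \(g_i\) is log-normal (log-SD 0.3, a
   moderate level of stable individual variation); the party-size origin
   effect shifts its log-mean for wild-born individuals. A
   sanctuary-born individual's expected party at full in-view time is
   7.36 including itself.
2. Dyadic daily association probability is
   \(w_{ij} = \mathrm{logit}^{-1}(\beta_0 + \tilde g_i + \tilde g_j +
   \text{matriline boost} + \text{origin shift} + \varepsilon_{ij})\)
   with centred log-gregariousness \(\tilde g\), a kinship boost of 1
   logit, an origin shift proportional to the number of wild-born
   members, and dyad noise \(\varepsilon_{ij}\) with SD 2. The wide dyad
   spread is what makes many dyads effectively never associate, so the
   zero-inflation that motivates the hurdle model *emerges* rather than
   being bolted on. With the default base of -4 logits this yields mean
   non-zero proximity indices around 0.03–0.05 and proximity connection
   rates around 55–70% — chimpanzee-like values.
3. Each day every individual is available with probability 0.6; focals
   are drawn from the available set, party sizes are Poisson
   (proportional to \(g\) and in-view time) with members drawn
   preferentially by affinity, and the day's identified set is exactly
   the union of everyone on video — so identification arises from the
   sampling process, as in the field, rather than being drawn
   independently.
4. Identified dyads associate (one-zero) with probability \(w_{ij}\)
   for proximity; grooming scales that probability down by 0.25 and is
   restricted to individuals older than 6 years.

Ground truth (every \(g_i\), every \(w_{ij}\), all injected effects) is
returned alongside the data. Three frozen scenarios cover the
calibration spectrum: `null` (all origin effects zero), `paper_like`
(party effect -0.105 on the log scale with mild dyadic shifts — the
magnitude regime where the question is genuinely hard), and
`strong_effect` (party -0.5, dyadic shifts -2 logits). The strong
scenario was power-calibrated once so that every pipeline stage detects
it reliably; notably, the level-sensitive metrics (strength,
eigenvector, reach) carry that detection, while clustering and affinity
are ratio-like quantities that largely cancel a uniform affinity shift
and remain near-null — a structural observation about the metrics, not
a deficiency of the test.

What the generator does **not** emulate: spatial movement and true
fission–fusion kinetics, observer bias beyond random availability,
seasonal or diurnal structure, behaviour-specific reciprocity, or any
welfare-related behaviours. Passing calibration on synthetic data
therefore demonstrates that the *statistical machinery* is sound under
the assumed data-generating structure, not that any particular real
population follows that structure.

## Numerical and design choices

* Tie handling in permutation tests: absolute tolerance 1e-12.
* Eigenvector orientation: sign chosen so the component sum is
  positive; values within 1e-8 below zero are clamped to 0.
* Exact permutation p is the proportion of *all* label assignments at
  least as extreme as the observed one (the observed assignment counts
  itself); the Monte-Carlo estimator uses the add-one convention.
* LRTs allow the degenerate zero-degrees-of-freedom comparison of
  identical models (chi-square 0, p 1) but reject a reduced model with
  a higher likelihood, which indicates broken nesting.
* Cohen's kappa returns exactly 1 in the degenerate all-one-category
  case where expected agreement is 1.
* Reported percentages always carry numerator and denominator; a bare
  percentage of dyads connected is otherwise unauditable.
* Test-suite problem sizes: oracle equivalence runs on 50 random daily
  histories (<= 10 individuals, <= 30 days) and 100 random matrices
  (n <= 12); type-I calibration uses 600 pipeline replicates at the full
  default study size with 199 permutations per test (the add-one
  estimator then rejects at exactly the nominal 5% under
  exchangeability); parameter recovery uses 200 replicates; power uses
  50. Calibration runs the *stratified* permutation variant, because the
  generator — like the study design it emulates — fixes the wild-born
  count within each group; shuffling across groups draws from a label
  law with more variance than the generating one and is measurably
  conservative (never anticonservative), which is worth knowing when the
  unstratified default is applied to real data. These sizes are the package's chosen operating points for its own
  validation and are stated here so they can be scaled in either
  direction.

## Known limitations

* The random-effect structure is deliberately simpler than a fully
  crossed random-slope specification; with strong focal-by-time
  interactions the party-size LRT could be mildly anticonservative.
* The asymptotic hurdle LRT ignores dyadic non-independence; the
  node-permutation variant is the honest (but slower) alternative.
* Eigenvector centrality on disconnected networks is reported from the
  dominant component only.
* The generator's identification process couples gregariousness and
  detectability (gregarious individuals appear in more parties), which
  is realistic but means per-individual sampling effort is not uniform;
  analyses that assume uniform effort should use the association
  denominators, which account for it.
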