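---
title: "Methods: from focal samples to sex-structured social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from focal samples to sex-structured social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalnet)
```

`focalnet` analyses focal-animal sampling data from stable primate groups:
what each individual does with its time, how it grooms, who it associates
with, and whether those association patterns are structured by sex. This
vignette explains the models and conventions behind each stage, the
parameters that matter, and the choices made where the methodology was
genuinely open.

## Observation model

A dataset is five tables. The *roster* lists individuals with sex, age
category and group. Each *session* is one focal follow under a fixed
protocol: behavioral state recorded instantaneously every
`behavior_interval_s` seconds, and proximity recorded every
`proximity_interval_s` seconds either instantaneously (partners within the
radius at the sampling instant) or by one-zero sampling (partners within
the radius at any point of the interval). The two protocols supported are
the typical enclosure design (3-min instantaneous sampling within 3 m for
both streams) and the typical field design (1-min instantaneous behavior,
5-min one-zero proximity within 10 m). Grooming is recorded by
all-occurrence sampling in seconds, each bout tagged with a three-digit
clique code and a grooming-handclasp flag.

Timestamps are seconds from session start, zero-based and aligned to the
sampling interval, so that `count x interval` is a well-defined time
estimate. Focals can be out of view: missing sampling points are simply
absent, and all denominators count recorded points only. This is the one
defensible reading when the records do not distinguish "out of view" from
"not sampled", but it does assume visibility is not correlated with
behavior.

## Activity budgets

A budget is the vector of category proportions over an individual's
recorded sampling points; foraging is additionally split into collecting,
extractive and hunting subtypes, each expressed against all points so the
three sum to the foraging proportion exactly. Budgets from disjoint sample
sets merge as count-weighted averages, and are invariant to sample order —
both properties are tested. Budgets are computed unstratified by time of
day; balancing across day periods is a design-time concern of the sampling
scheme, not of the estimator.

## Grooming cliques and the mutual-grooming ratio

The clique code concatenates (1) whether the focal is in mutual grooming,
(2) whether the focal is grooming anyone, and (3) how many individuals are
grooming the focal (the mutual partner counts among them). A code's
participant count is therefore `1 + digit3 + 1[one-directional outgoing
grooming]`. Codes with leading digit 1 are mutual; everything else is
one-directional.

The mutual-grooming ratio is mutual seconds over total grooming seconds.
Bout seconds are wall-clock seconds counted once, whatever the clique's
size or direction; a bout split into contiguous sub-bouts leaves every
ratio unchanged (tested). Two exclusion rules mirror standard practice:
individuals with less than `min_total_s` of recorded grooming (default
300 s — a round value; any cutoff above the sparsest retained individual
behaves identically) and individuals in excluded age categories (default
juveniles, whose grooming is developmentally atypical) are flagged out of
group-level comparisons. An individual with zero grooming seconds has an
undefined ratio, reported as `NA`, never as 0.

## Proximity index, Q3 filter, centrality

The dyadic proximity index is the simple ratio
`PI(A,B) = (T_A(B) + T_B(A)) / (T_A + T_B)`: both one-sided views of the
pair pooled over both focals' observation time. It is symmetric, bounded
in [0, 1], and — because both numerator and denominator are counts times
the same interval — invariant to the interval length whenever both focals
share a protocol. Indices from different protocols measure different
things (3 m instantaneous vs 10 m one-zero), so the pipeline refuses to
pool or compare them across groups; sex-combination contrasts are always
within-group.

A stable group observed long enough yields a complete raw network, so the
analysis keeps only dyads with `PI >= Q3`, the third quartile of all
`N(N-1)/2` dyadic values *including zeros* (managed never-co-present pairs
are genuine zeros of the association structure; excluding them would
shift the threshold by an arbitrary amount — a flag provides the
nonzero-only variant). The quartile is the linearly interpolated order
statistic at position `0.75 * (n - 1)` (0-based), making the threshold
bit-reproducible; ties at the threshold are retained (inclusive rule), so
slightly more than 25% of dyads can survive.

Eigenvector centrality is computed on the weighted filtered network by
default (edge weights are the retained PIs; a binary variant is available
for sensitivity). Scores are the principal eigenvector, nonnegative,
normalised to unit Euclidean norm over the *full* node set so that
isolates score exactly 0 and scores are comparable across individuals
within a group. The default solver is power iteration on `A + cI` with
`c` the maximum row sum: the shift leaves eigenvectors untouched but makes
the dominant eigenvalue simple and positive, which matters because
bipartite-like filtered networks have symmetric spectra that stall plain
power iteration. Convergence is declared at step-change below `1e-12`;
the dense symmetric eigendecomposition is exposed as `method = "eigen"`
and the two agree to better than `1e-8` on hundreds of random graphs in
the test suite (with base `eigen()` and igraph as independent oracles).
On a disconnected filtered network the score vector concentrates on the
component with the largest dominant eigenvalue; nodes elsewhere get 0,
which is the standard convention and matches how an isolated individual
should read in a group-level core/periphery summary.

## Statistical battery

*Mann–Whitney U* (between-group comparisons of per-individual budgets and
ratios) uses midranks, reports the min-U convention (`U + U' = n1*n2`),
and computes the two-sided p by exhaustive enumeration of group
assignments when `n1 + n2 <= 12` (exact under ties) and by the
tie-corrected normal approximation (no continuity correction) otherwise.

*Kruskal–Wallis* (dyadic PI across the three sex combinations) delegates
H, df and the chi-squared p to `stats::kruskal.test` and, when the
omnibus is significant at `alpha`, runs Dunn rank comparisons
(difference of mean ranks over its tie-corrected standard error) with
Holm adjustment via `stats::p.adjust`; pairwise Mann–Whitney with Holm is
available as an alternative. The dyadic values are not independent (each
individual contributes to 15 dyads), a caveat inherent to comparing
dyad-level indices with rank tests; the test is used descriptively, with
`k - 1 = 2` degrees of freedom over the 120 dyads of a 16-individual
group.

*Welch's t* is computed directly with `n - 1` variances and a fixed
female-minus-male convention, so male-dominated centrality yields a
negative t.

*The sex-label randomization test* permutes sex labels over the fixed
centralities, preserving group sizes, and recomputes Welch's t each time —
the appropriate null when the question is whether the *labels* explain
the scores, and the natural reading of resampling "of each sex" given
that reported directional p-values near 1 imply a null centred at zero
rather than at the observed t. A bootstrap mode (resampling scores within
sex with replacement) is provided for sensitivity; its null is centred at
the observed t and its p-values answer a different question. The p is the
plain resample proportion by default (the `(b+1)/(b+1)`-style add-one
estimator is a flag); degenerate resampled t of the form 0/0, possible
only with heavily tied scores, count as 0. With `exhaustive = TRUE` all
label assignments are enumerated, which the tests use to verify the
sampled p converges to the exact one.

## The synthetic colony generator

The generator exists so the pipeline can be tested and calibrated without
observational records. It emulates: i.i.d. categorical behavior sampling
per focal (budgets depend only on the marginal probabilities, so temporal
autocorrelation is deliberately not modelled); symmetric per-interval
pair association with probabilities depending only on the dyad's sex
combination, observed from the focal's side, with structural-zero pairs
for individuals managers never co-release; and grooming bouts as a
per-focal Poisson process (`groom_rate` bouts per focal-hour) with
lognormal durations, a Bernoulli mutual flag, an extra-groomer
distribution over 0–3 additional groomers, and a per-mutual-bout
handclasp probability.

Two presets encode the study designs the package targets. The wild-like
preset: 8 males + 8 females, 13 two-hour follows per focal (~1,560 min
each), 1-min behavior sampling, 5-min one-zero proximity within 10 m,
association probabilities MM = 0.17, FF = 0.09, MF = 0.085, collecting /
extractive / hunting at 18.2% / 2.8% / 0.3% of time, traveling 15.4%, a
low mutual-grooming probability (0.067) and handclasps on every mutual
bout. The captive-like preset: 5 males + 11 females (one juvenile male),
two five-hour follows per focal (~600 min each), 3-min instantaneous
sampling within 3 m for both streams, association probability 0.12 for
every sex combination, three structural-zero pairs, collecting /
extractive at 11.4% / 7.4% with no hunting, traveling 12.0%, a high
mutual-grooming probability (0.268) and no handclasps. Where a quantity
has no published value (the captive association level, the grooming rate
of 1.2 bouts per focal-hour, the lognormal bout duration with mean 300 s
and sd 200 s, and the resting/grooming/others split of the remaining
budget) the defaults are one-time choices at field-realistic magnitudes,
documented here and not revisited.

What the generator does *not* emulate: temporal autocorrelation of
behavior, party fission–fusion and travel (association is i.i.d. across
intervals), dominance or kinship structure beyond sex, seasonal effects,
observer error, and per-focal heterogeneity within a sex. Consequently,
passing parameter-recovery and calibration tests demonstrates the
*estimators and tests* behave correctly under the designed sampling
schemes — not that real chimpanzee data meet those assumptions. One
visible consequence: with tightly estimated PIs the Q3 filter separates
the sexes more cleanly than noisy field data would, so the wild-like
preset produces more extreme centrality contrasts than a real group.
Similarly, handclasp universality across focals is emergent (a focal with
no mutual bout shows none), not forced.

`simulate_proximity_tally()` is the generator's fast path: because each
partner is present at each sampling point independently, a pair's
focal-side near-count is exactly Binomial(points, p), so tally-level
replicates can be drawn directly without materialising record streams.
The record-level and tally-level routes are checked against each other in
the tests. The type-I calibration study (2,000 replicate null colonies,
B = 500 resamples each — scaled from the analysis default of 10,000 to
keep a replication study tractable) uses this path and finds the
two-sided rejection rate at `alpha = 0.05` within 0.04–0.06.

Every simulation is driven by one master seed fanned out into fixed
per-stage substreams, so a stage re-run in isolation reproduces its slice
of the pipeline and full runs are byte-identical.

## Numerical and edge-case conventions

- Quartile thresholds use linear interpolation (type-7 order statistics).
- An all-zero PI matrix filters to an empty edge set with a warning;
  centrality on an edgeless network is an error, not a zero vector.
- A proximity index for a pair where neither member was observed is an
  error; one-sided observation is fine (the unobserved side contributes
  zero time).
- Budget computation on a focal with no samples is an explicit error,
  never a zero-filled row; group-level budget tables keep unsampled
  individuals as flagged rows.
- Clique codes reject impossible configurations (mutual without the focal
  grooming, `000`, more than 9 groomers).
- Validation of a whole dataset returns a sorted violation report that is
  invariant to input row order.

## Problem sizes

The test suite exercises: 500 random connected weighted graphs of up to
12 nodes against the dense eigen-solver; exhaustive enumeration oracles up
to 6+6 (Mann–Whitney) and 16-choose-8 sampled / 8-choose-4 exhaustive
(randomization test); full-preset colonies (16 focals, ~25,000 behavior
samples in the wild design) for parameter recovery; and 2,000 tally-level
null replicates for calibration. The acceptance script simulates both
presets once at the given seed with B = 10,000 resamples.

## Known limitations

Dyadic rank tests ignore the non-independence of dyads sharing an
individual; the randomization test conditions on the observed network
rather than re-estimating it per permutation (node-label, not
edge-permutation, null); cross-protocol index comparison is refused
rather than calibrated; and the generator's independence assumptions make
it a tool for validating estimators, not a behavioral model of
chimpanzees.
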