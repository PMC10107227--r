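---
title: "Inferring co-foraging decisions from scan-sampling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring co-foraging decisions from scan-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coforage)
```

## The problem

Mixed-species aggregations of parrots form every morning on riverbank clay
licks: individuals of a dozen species arrive, forage in delimited zones of the
cliff, and leave, with group composition turning over on the scale of
minutes. Observers census the wall every 5 minutes, recording how many
individuals of each species occupy each zone. Two questions drive this
package:

1. **Are these true mixed-species groups?** That is, do species associate
   with (or avoid) particular other species beyond what shared preferences
   for zones and times of morning would produce?
2. **What information do the joining decisions use?** When a bird joins an
   occupied zone, is it discriminating partners at the species level, or on
   coarser perceptual categories — size, colour, shape?

`coforage` implements the full inference chain from raw scan tables to
answers for both questions, together with a generative simulator so that
every stage can be validated by parameter and schema recovery on data with
known ground truth.

## Data model and filtering

The input is a long-format scan table: one row per
`(date, time, zone, species)` with a positive count. The reader
(`read_scan_table()`) never silently drops data: rows with unparseable
dates, times or counts, and duplicated keys, go to a rejects report.
`filter_scans()` then applies the study conditions: the 12 focal species,
October–December, scan times strictly before 09:00 (the boundary is
exclusive), and the 11 standard zones. `partition_by_day_parity()` splits
the result into a main partition (even days of the month) and a validation
partition (odd days), a pre-registration-style split that keeps exploratory
and confirmatory analyses on disjoint data.

Day parity is interpreted as day-of-month parity — the simplest reading
consistent with dates being the unit of the split. Times are stored to
minute resolution; the 5-minute grid is enforced only where it matters
(run segmentation), so off-grid scans still contribute to co-presence
analyses.

The 12 species and their attributes (mass, clade, plumage colour classes,
size class) ship with the package (`species_attributes()`). Only the
smallest (DH, 108 g) and largest (RG, 1250 g) masses are fixed by the study
description; the other ten defaults are handbook-style means chosen to give
the strictly increasing order DH < WB < WE < OC < BH < RB < CF < YC < ME <
SC < BY < RG that the categorization table implies. All masses can be
overridden, and the validator insists on a total ordering because the
relative size schemas need "immediately adjacent in size" to be well
defined.

## Co-presence

The unit of observation is the **zone-scan**: a `(date, time, zone)` triple
with at least one focal individual present. `presence_table()` reduces the
counts to 0/1 presence per species; `copresence_counts()` counts, for each
pair, the zone-scans where both were present. `mixing_summary()` reports the
per-species medians (species present, focal group size, total individuals,
Shannon entropy of the within-scan count distribution, natural log, via
`vegan::diversity`) and the proportion of monospecific scans. Medians use
the lower middle order statistic for even sample sizes by default
(`median_type = "standard"` restores the usual convention) so that reported
values are always attainable data values.

Raw co-presence counts confound attraction with shared zone/time
preferences. The controlled analysis regresses, for each focal species, its
presence per zone-scan on the presence of the 11 other species (additive
effects), with crossed random intercepts for zone, time of morning and date
absorbing the spatial and temporal preferences.

## Joining

Co-presence is an equilibrium quantity; joining is the decision itself.
Within **runs** — maximal chains of scans of one `(date, zone)` spaced
exactly 5 minutes apart (`segment_runs()`; chains shorter than 2 scans are
unusable) — the focal's response at scan *t* is

* `y[t] = 1` iff the focal was absent at *t−1* and present at *t*,

and each candidate partner's predictor is

* `x[t] = 1` iff the partner was present at both *t−1* and *t*.

The first scan of every run carries `y = x = 0`, which reproduces the
canonical encodings `y = (0,0,1,0)`, `x = (0,1,1,0)` for a 4-scan run in
which the focal arrives at the third scan while the partner sits through the
first three. Timepoints where the focal was already present (and so cannot
join) are retained with `y = 0`, exactly as in those reference encodings;
this dilutes the at-risk set slightly but keeps the design faithful to the
published construction (`drop_present = TRUE` restricts the panel to at-risk
rows for users who prefer statistical purity). Rows are pooled across runs,
zones and dates into one panel per focal, with zone, time and date as
random-intercept labels; time-of-morning levels are the exact scan times by
default, with an optional coarser binning (`tod_bin_minutes`) for sparse
data.

## Edge inference

`fit_binomial_glmm()` fits the logit-link Bernoulli model by maximizing the
Laplace-approximated marginal likelihood (`lme4::glmer`; the `bobyqa`
optimizer, which reaches the same optimum as the default on these sparse
binary designs at a fraction of the cost). Setting
`constrain_zero_variance = TRUE` fixes all three variance components at
zero, in which case the marginal likelihood is exactly the ordinary
Bernoulli likelihood and the fit reduces to plain logistic regression — the
package's testable zero-variance limit. Random factors with a single
observed level are dropped from the formula (they are inestimable), and
constant predictor columns are removed and recorded.

For each of the 132 ordered (focal, predictor) pairs, `infer_edge_network()`
compares the full model against the reduced model omitting that predictor by
likelihood-ratio test, adjusts the 132 p-values jointly with
Benjamini–Hochberg, and keeps edges with adjusted values below `alpha`
(default 0.05 — the conventional level; the procedure's level is exposed as
an argument). Edges are signed by the coefficient: positive = affiliative,
negative = avoidant. Non-converged or separated fits yield NA p-values, are
excluded from the adjustment family, and are visible in the output. The
co-presence and joining families are corrected separately, since each is
its own 132-test family.

Model-comparison conventions: the parameter count `k` underlying AIC and the
likelihood-ratio degrees of freedom includes the estimated variance
components (three, in the standard design), matching the mixed-model AIC
convention of the fitting tools. Deviations below zero beyond numerical
tolerance trigger a refit warning; tiny negative deviances are clamped to
zero, and comparing a model with itself gives p = 1 by convention.

## Networks

Community detection uses Newman's leading-eigenvector modularity method
(`igraph::cluster_leading_eigen`) on three community-matrix variants
(`build_community_matrix()`): raw co-presence counts (diagonal zeroed),
binary affiliative adjacency (an edge in either direction makes the pair
adjacent), and the signed joining matrix (+1 affiliative, −1 avoidant).
Signed matrices are reduced to their positive part before detection —
communities are detected among the affiliative edges only, the same
convention the co-presence analysis uses. A graph with no edges returns
all-singleton memberships. `centrality_scores()` reports degree (in+out
significant affiliative edges) and betweenness (shortest paths through the
node; directed by default, with a switch, since the underlying edge list is
directed).

## Categorization schemas

Nine schemas map the 12 species onto categories: `species` (12), `clade`
(5), `large_macaw` (2), `back_colour` (3), `head_colour` (5), `face_colour`
(5), `size` (3), and the focal-relative `larger` (2) and `similar` (2,
the mass-rank neighbours of the focal). `encode_schema_predictors()`
replaces the 11 species predictors by one column per category — the
elementwise OR of the member species' indicators, with the focal excluded
from its own category and empty categories omitted. The `species` schema is
the identity encoding, so its AIC equals the raw 11-predictor model's AIC —
an internal consistency check the tests enforce.

`compete_schemas()` fits all nine encodings on an identical row set and
compares them by AIC. Although the coarser schemas are not all mutually
nested, AIC with Akaike weights is the appropriate comparison for such a
candidate set, and the weights give the probability each model is best given
the candidates. The best model is flagged *strongly differentiated* when the
runner-up's ΔAIC exceeds 2, and the runner-up is always reported. Within the
best model, each category coefficient is classified preferred / avoided /
neutral by its Wald z-test at 0.05 (no further correction — these are
descriptive classifications within an already-selected model; a
likelihood-ratio variant per category can be substituted by refitting).
`usage_complexity()` counts the significantly used categories, and
`category_preference_map()` projects the category classifications back onto
the 11 species, including whether the focal's own category is preferred
(undefined when the focal is its category's sole member, or under the
`larger` schema, which assigns the focal no category).

Two cross-cutting checks close the analysis:
`mass_difference_edge_test()` asks, one-tailed Mann–Whitney, whether
avoidant edges connect species with larger mass differences than affiliative
edges (the normal approximation is used without continuity correction, so a
fully symmetric configuration gives p = 0.5 exactly; exact enumeration is
used where sample sizes permit), and
`complexity_centrality_regression()` regresses per-species usage complexity
on degree and on betweenness centrality by ordinary least squares.

## The simulator

`simulate_scans()` generates scan tables from the same model family the
inference assumes. Per `(date, zone)`, ticking through the 5-minute grid:
species present at the previous tick remain with probability `stay_prob`
(decided first, so "who stayed" is known at decision time); each absent
species then joins with probability

logistic( β₀ + Σ_c β_c · occ_c + u_zone + u_time + u_date ),

where `occ_c` indicates that some *other* species of category *c* (under the
focal's generating schema) was present at the previous tick **and** remained
through the current one. That is exactly the adjacent-pair predictor rule
the inference uses, which is what makes clean recovery testing possible.
Random intercepts are drawn once per level and shared across species; group
sizes are 1 + Poisson(mean − 1), keeping counts positive. The same seed
yields a bit-identical table.

Defaults are fixed once as the simulated study conditions: 60 days starting
1 October, the 11 standard zones, the 05:00–08:55 grid, baseline arrival
log-odds `qlogis(0.03)` per tick, stay probability 0.8 (implying mean run
lengths of about 5 scans, in line with the persistence the field data
suggest), random-intercept SDs (0.5, 0.25, 0.25) for zone/time/date, mean
group size 3, and a joining rule in which every species is attracted
(+1.5 log-odds) to occupied groups of its own size class — the similarity
preference that dominates the empirical findings. `ground_truth()` derives
the expected recovery answers (schema, coefficient signs, preferred and
avoided species sets) deterministically from a configuration.

What the simulator does **not** emulate: movement between zones within a
tick, departures beyond geometric persistence, predator-driven flushes,
diurnal and seasonal non-stationarity, and observer error. Passing recovery
tests therefore demonstrates that the inference chain is correct for data
generated under its own assumptions — not that those assumptions hold in
any particular field dataset.

## Identifiability in schema recovery

A recovery test asks whether the generating schema wins the AIC competition.
That is only a fair question when the generating encoding is identifiable:
for some focal species, the single informative category of the generating
schema is exactly reproduced by a schema with fewer categories, and AIC then
(correctly) prefers the cheaper equivalent model. Under the default
size-class rule this happens for BH, whose size-class "small" colleagues
coincide with the species below it in mass (the `larger` schema's "smaller"
category), and for the three large macaws, whose "large" class coincides
with the `large_macaw` "yes" category. The recovery tests therefore rotate
focals over the eight species for which the size schema is identifiable;
the equivalence itself is a property of the category system, not a failure
of the inference.

## Problem sizes and numerical choices

The package's own validation uses simulations scaled to keep each stage
informative: schema recovery at 60 days × 3 zones (about 7,000 zone-scans,
the scale at which the nine-model competition separates cleanly over 20
seeds), network inference and null-calibration at 25 days × 2 zones, and
model-level calibration at n = 2000 rows with 500 replicates for the null
distribution of the likelihood-ratio p-value. Tie-breaking and sign
conventions in community detection follow igraph's deterministic ARPACK
implementation, so partitions are reproducible. Degenerate inputs are
handled explicitly: constant responses flag a panel as degenerate (its 11
tests are excluded from the FDR family), empty graphs return singleton
communities, empty edge-sign groups make the mass-difference test NA while
still reporting group means, and zero-variance regressors make the
complexity regression NA with a message.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_days = 60, zones = c("1A", "2C", "3B"),
                  generating_schema = "size", seed = 1)
scans <- simulate_scans(cfg)
main <- partition_by_day_parity(filter_scans(scans))$main
p <- presence_table(main)

mixing_summary(p)[1:3, ]
cr <- compete_schemas(p, "DH")
cr$best                 # "size"
usage_complexity(cr)    # number of significantly used categories
```

## Known limitations

* Individuals are unidentifiable in scan data, so all inferences are at the
  species level; no individual association indices are computed.
* The joining model conditions on the partner spanning the adjacent pair; a
  partner that arrives and leaves within one inter-scan interval is
  invisible.
* The nine schemas are a hypothesis set, not an exhaustive search; a
  best-fit schema is the best of the candidates, nothing more.
* AIC comparison assumes all nine fits share one row set; the implementation
  guarantees this by construction, but user-supplied panels with differing
  rows are rejected rather than reconciled.
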