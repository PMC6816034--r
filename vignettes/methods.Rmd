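---
title: "Methods: subnetwork entropy, removal nulls, and hub-target counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subnetwork entropy, removal nulls, and hub-target counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(netentropy)
```

## The model

The pipeline treats one patient's tumor as a perturbation of that same
patient's normal tissue, read out through network complexity.

**Up-regulation calling.** For genes shared between the paired samples we
form the differential expression `d_g = tumor_g − control_g` on the
normalized (RSEM upper-quartile) scale. The bulk of these values is
approximately Gaussian noise around zero; truly up-regulated genes form an
upper tail. We bin the values into an equal-width frequency histogram,
transform the relative frequencies with `y' = log10(y + 1)` — which
compresses the sharp central peak so the least-squares fit is not dominated
by the modal bins — and fit the three-parameter Gaussian
`A·exp(−(x−μ)²/(2σ²))` to `(bin centers, y')`. The one-tail threshold is
`μ + σ·z(1−α)` on the differential-expression axis: a gene strictly above
it has fitted-bulk upper-tail mass at most α. This reads "one-tail p ≤ α
under the fitted bulk" as a gene-level cut, which is the only
interpretation that yields a per-gene decision rule. Down-regulation is
deliberately not called: the therapeutic question concerns proteins whose
inhibition could selectively hit the tumor.

**Assumptions.** The bulk is unimodal and roughly symmetric; the planted
tail is a minority (the calibration breaks down if most genes move); tumor
and control index the same gene universe; expression values are consumed
as given (no re-normalization, no replicate-based variance model).

**Subnetwork and entropy.** Called genes map to protein accessions through
a one-to-one symbol map; the subnetwork keeps every interactome edge with
both endpoints in the called set. Proteins without a partner inside the set
are excluded — subnetworks are built from interaction records, and a k = 0
class would make `log2 p(0)` ill-posed in the entropy. With `p(k)` the
fraction of subnetwork nodes of degree `k` (degrees counted inside the
subnetwork, not the whole interactome),

    H = − Σ_k p(k) log2 p(k)   (bits).

H is computed over observed degrees only, so no `0·log 0` term arises. It
is invariant to relabeling and to exact duplication of the network
(proportions only), bounded by `log2(number of degree classes)`, and 0 for
regular graphs. We note the tension between calling entropy "extensive"
and using a proportion-based formula; the formula is implemented literally,
with no normalization by network size.

**Removal null.** Hub relevance is tested per patient: remove the top-5
degree hubs, record H; build the empirical null from 1,000 replicates of
removing 5 uniformly chosen nodes; report the one-sided add-one p-value
`p = (1 + #{H_null ≤ H_hub}) / (1 + reps)`. The add-one estimator is
standard permutation-test practice and keeps p strictly positive;
one-sidedness encodes the hypothesis that hub removal *lowers* entropy
more than random removal. Node removal cascades: nodes isolated by a
deletion are dropped, consistently with subnetwork construction.

**Survival linkage.** Per cancer type, the Kaplan–Meier product-limit
curve is estimated from event flags (1 = death) and days of follow-up
(`survival::survfit`); the five-year rate is `100·S(1825)` by
right-continuous step lookup (5 years = 1825 days, configurable). Cohort
mean entropy is regressed on the five-year rate by ordinary least squares;
Pearson r, the two-sided slope t-test, and the 95% t-interval are
reported. Kruskal–Wallis (with tie correction) tests entropy-level equality
across cancer types, followed by two-sided Mann–Whitney rank-sum tests for
every pair, Holm-corrected by default.

**Target counting.** Evaluating the fitted line at X = 100 gives the
entropy associated with full five-year survival. Per patient, the top-20
hub ranking is frozen at baseline (the ranking is *not* recomputed after
each removal — the prescription names a fixed drug-target combination, not
an adaptive sequence), hubs are removed cumulatively for n = 1..20, and
the prescribed count is the smallest n with H ≤ goal; 0 if the baseline is
already at or below the goal (a real subpopulation, reported rather than
errored); "unreached" if 20 removals do not suffice (reported explicitly,
never extrapolated). An emptied subnetwork has H = 0 by convention, with
an emptied flag.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.05 | one-tail mass | conventional significance for the up-regulation cut |
| `n_bins` | 100 | bins | smooth bulk for ~10^3–10^4 genes; the calling is insensitive to moderate changes |
| `null_reps` | 1000 | replicates | resolves p down to 1/1001 |
| `null_remove` | 5 | nodes | matches the hub-removal comparison (top-5) |
| `max_targets` | 20 | hubs | the top-20 cap of the prescription |
| `five_years_days` | 1825 | days | 5 × 365 |
| `correction` | holm | — | default of standard pairwise-comparison utilities; `"none"` for heat-map output |
| `min_cohort_size` | 30 | patients | cohorts below it are flagged, still processed |
| `goal_mode` | all-cohort | — | the entropy goal comes from the cross-cohort line; a within-tissue interval regression is additionally run for eligible cohorts |

## Numerical choices

* **Gaussian fit**: Levenberg–Marquardt (`minpack.lm::nlsLM`), initialized
  at μ₀ = modal bin center, σ₀ = half the interquartile range of the raw
  differentials (floored at one bin width), A₀ = max transformed
  frequency; `ftol = ptol = 1e-8`, up to 10,000 function evaluations. On
  non-convergence (or a non-positive fitted σ or A) the threshold falls
  back to the empirical `1 − α` quantile of the raw differentials and the
  fit is flagged `converged = FALSE`, so one pathological patient cannot
  abort a cohort run. Fewer than 4 non-empty bins is a hard error.
* **Degenerate inputs**: a patient with tumor identical to control (no
  distinct differential values) is flagged `no_upregulated`; a called set
  inducing no edge is flagged `empty_subnetwork`; both keep the cohort run
  alive.
* **Membership is strict** (`> threshold`), so a gene exactly at the cut is
  not called.
* **Hub ties** break lexicographically by accession — the ranking must be
  deterministic for reproducible prescriptions.
* **Survival-rate intervals** are `[81, 100]`, `[61, 81)`, `[41, 61)`,
  `[21, 41)`, `(0, 21)`: a rate of exactly 81% belongs to the top interval
  and 80.5% to the second. Intervals need ≥ 3 patients to enter
  interval-level averaging.
* **Randomness**: one master seed; each patient's null replicates use a
  stream derived from (seed, patient id) via a fixed string hash, so
  per-patient results are independent of cohort ordering and the whole run
  is bit-reproducible.
* **Fast null path**: per-replicate entropies are computed from the
  baseline adjacency (a survivor's degree drops by its number of removed
  neighbours; newly isolated survivors are dropped) without rebuilding the
  graph; the test suite asserts replicate-by-replicate agreement with the
  explicit graph-deletion path.

## Design decisions on genuinely open points

* **Pairwise test**: the phrase "signed-rank" presumes paired samples, but
  cancer-type cohorts contain different patients in different numbers, so
  the cross-cohort pairwise test is the unpaired two-sided Mann–Whitney
  rank-sum; a paired signed-rank mode exists (`paired = TRUE`) but is not
  the default.
* **Null comparison removes the patient's own top-5 induced-degree hubs**,
  not any externally validated hub list — the only patient-specific
  reading.
* **Entropy goal** defaults to the all-cohort regression; the
  within-tissue interval machinery is run for every cohort with at least
  three patients in each populated survival interval and reported
  alongside.
* **Mapping collisions** (one symbol, two accessions) keep the first
  occurrence and warn; unmapped called genes are dropped with a count.
* **MITAB filtering** keeps rows where both interactors carry `uniprotkb:`
  accessions and both taxa are `taxid:9606`; self-interactions are
  dropped, duplicate pairs collapse to one undirected edge, and every
  skipped row is counted in the log.

## The synthetic generator

`synthetic_spec()` defaults describe the desk-scale study used throughout
the tests and the acceptance script: 9 cohorts × 30 paired patients over
2,000 genes mapped one-to-one onto a 2,000-protein interactome.

* **Interactome**: preferential attachment in the classic construction
  (start from m isolated seed nodes; each new node attaches to m = 2
  distinct existing nodes with probability proportional to degree), giving
  a connected simple graph with exactly `m(n−m)` edges and a right-skewed
  degree distribution — the scale-free shape on which targeted attack
  beats random failure.
* **Expression**: log-normal control baselines; tumor = control + N(0, σ)
  bulk noise (σ = 1) plus a +5σ shift on a planted 5% of genes, sampled
  per patient with probability proportional to interactome degree (raised
  to a per-cohort exponent spread over 0.25–1.75), so planted subnetworks
  contain hubs and cohorts genuinely differ in composition and mean
  entropy. Uniform planting is available. Negative expression values are
  clamped at 0 (the expression scale is non-negative); with the default
  log-normal baseline this affects a negligible fraction of entries.
* **Survival**: exponential event times calibrated so the true `S(1825)`
  equals a linear link in cohort mean entropy, clamped to (1, 99)%; the
  default link (slope −48, intercept 143 on the percent scale) maps the
  measured entropy scale of default-size synthetic subnetworks (about 1 to
  2.3 bits) onto five-year survival spanning roughly 35–95%, the spread of
  real multi-cancer panels. Records are censored independently with
  probability 0.3 (a typical overall-survival censoring load), replacing
  the event time by a uniform draw in (0, T). `write_synthetic_dataset()`
  links survival to the cohort mean entropies *measured by the caller on
  the generated cohort*, so the emitted study has survival genuinely
  decreasing with subnetwork entropy rather than by construction fiat.
* **Formats**: the generator writes the exact formats the readers consume
  (expression TSV, sample sheet, mapping TSV, PSI-MITAB with interactor
  and taxon columns populated, clinical TSV), so synthetic runs exercise
  the real parsers.

**What it does not emulate**: read-level RSEM quantification, tumor
heterogeneity mixtures, cancer-stem-cell contamination of controls,
correlated gene expression, molecular subtypes, and non-exponential
hazards. Passing tests therefore demonstrate that the *method* behaves as
specified under its own assumptions — calibration, planted recovery, hub
dominance, regression recovery — not that real tumors satisfy those
assumptions.

## A note on where hub dominance lives

Hub removal lowers entropy below the random-removal null on *induced
up-regulated subnetworks*, which are rich in degree-1 nodes: deleting a
hub pushes its low-degree neighbours into (and out through) the dominant
k = 1 class, concentrating the distribution. On a raw preferential-
attachment graph with minimum degree 2 the same operation *raises*
entropy — it flattens the dominant k = 2 class into a newly created k = 1
class. The hub-dominance checks in this package therefore operate on
subnetworks induced from seeded scale-free interactomes through the full
up-regulation caller, the objects the method actually analyzes.

## Problem sizes

The test suite and the acceptance script run at: exhaustive entropy
verification on all 32,767 labeled graphs with up to 6 nodes plus 100
seeded scale-free graphs; calibration on 10 seeds × 9,190 genes; one
9,190-gene planted-recovery patient; 20 seeded hub-dominance subnetworks
with 1,000-replicate nulls; 50 regression-recovery seeds; and one full
default-scale cohort study (270 patients, 1,000-replicate nulls each).
These sizes were chosen so the whole battery completes comfortably on a
single core while keeping every rate estimate stable.

## Known limitations

* The entropy goal inherits the uncertainty of a regression over few
  cohort means; with fewer than 3 cohorts no goal is produced.
* Static-network analysis: no regulatory dynamics, no attractor modeling,
  no drug-interaction or pharmacokinetic layer — the prescription counts
  hubs, it does not design a therapy.
* The per-patient survival lookup assigns each patient their cohort
  KM-curve value at their own follow-up time, which ties within-tissue
  analysis to cohort-level curves.
* Subnetwork induction treats the interactome as error-free and binary;
  edge confidence scores are ignored.
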