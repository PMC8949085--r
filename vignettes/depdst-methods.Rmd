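---
title: "Methods: dependency-aware credibility and evidence fusion for ADR signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dependency-aware credibility and evidence fusion for ADR signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depdst)
```

## The model

A candidate adverse drug reaction (ADR) record links a patient, their
disease, one of their drugs, and an observed symptom. The core difficulty is
confounding by indication: the disease that motivated the prescription may
itself cause the symptom. `depdst` addresses this by measuring, per record,
four kinds of statistical dependence and folding them into a single
credibility score that conditions downstream evidence.

### Dempster–Shafer evidence

Evidence lives on a frame of discernment $\Theta$ (here usually
$\{\mathrm{ADR}, \mathrm{DISEASE}, \mathrm{OTHER}\}$). A mass function
$m : 2^\Theta \to [0,1]$ satisfies $m(\emptyset) = 0$ and
$\sum_A m(A) = 1$; belief is $\mathrm{Bel}(A) = \sum_{X \subseteq A} m(X)$.
Two independent sources combine by the orthogonal sum
$$ (m_1 \oplus m_2)(A) = \frac{1}{1-K} \sum_{B \cap C = A} m_1(B)\, m_2(C),
   \qquad K = \sum_{B \cap C = \emptyset} m_1(B)\, m_2(C), $$
where $K$ is the conflict. Subsets are keyed canonically (members in frame
order), so focal-set equality is exact; combination is commutative and,
because the rule is associative up to floating point, n-ary fusion is a left
fold over pairwise calls — the fold order is an implementation convenience,
not a modelling claim. Masses are validated to $10^{-9}$ on the unit sum,
total conflict is declared at $K \ge 1 - 10^{-12}$, and post-combination
masses below $10^{-15}$ are dropped and the rest renormalized to keep focal
sets sparse. These tolerances reflect products of normalized doubles; they
are far below any scientifically meaningful mass.

### The four credibility components

**Causal arc strength.** A discrete Bayesian network over patient-level
disease, drug-exposure and symptom indicators is explored by a Metropolis
walk on DAG space scored with the BDeu marginal likelihood (equivalent
sample size 10, at most 3 parents per node — drug/disease/symptom networks
are sparse, and the cap bounds CPT size). The proposal is the classic
symmetric toggle/reverse move: with probability 0.75 a uniformly chosen
ordered pair has its edge added or deleted, otherwise a uniformly chosen
edge is reversed; proposals creating cycles or exceeding the parent cap are
rejected outright. A symmetric proposal needs no Hastings correction and
avoids enumerating the legal-move set (an $O(p^2)$ cycle-check sweep) at
every iteration, and acceptance uses score *differences* only, so the chain
is invariant to adding constants to the score. The strength of an arc is the
fraction of post-burn-in sampled structures containing it. Because
Markov-equivalent DAGs often cannot be distinguished by score, orientations
of a pair are pooled by default in the pipeline (`undirected_strength =
TRUE`); the directed table remains available. A record's
`dep_causal_strength` is the strength of its drug–symptom arc. The
disease–symptom strength is available from the same table for analysts who
want it as an explicit penalty; the pipeline feeds only the drug–symptom
value to the index, leaving the disease side to the correlation component.

**Correlation.** Per (disease, symptom) pair, the patient-level 2×2 table
(disease yes/no × symptom yes/no) is tested with Pearson's chi-square (no
continuity correction) and the record receives $1 - p$. Note the reading:
$1-p$ is *large* when the disease is strongly associated with the symptom.
Whether that should raise or lower ADR credibility is genuinely ambiguous —
both readings are defensible — so the direction is a flag
(`correlation_direction = "one_minus_p"` or `"p"`), with `one_minus_p` the
default. In practice the PCA step resolves the orientation: the loading on
this component takes whatever sign maximizes explained covariance with the
other components, and the random forest downstream is indifferent to
monotone recodings.

**Effect size.** With $n$ concurrently administered drugs the component is
$1/n$: an isolated exposure is maximally believable, and each additional
drug that could explain the symptom dilutes attribution. Concurrency is
defined by the patient's prescription list over the observation window; the
temporality basis uses a 30-day exposure lag (below).

**Temporal trend.** Lab-marker series (creatinine, glucose, urea,
platelets) are fit per patient and marker by OLS of value on days since the
first observation, with the two-sided t-test of $H_0: \beta_1 = 0$
(equivalently the 1-df regression F-test) at $\alpha = 0.05$. A series needs
at least 3 observations (one residual degree of freedom); shorter series
yield no temporal support rather than an error. A significant trend whose
window midpoint falls inside a drug's exposure window extended by a 30-day
lag — drug effects on blood chemistry persist and are measured at monthly
cadence, so a strict end-of-exposure cut would miss real signal — enters the
temporality basis for every symptom the (marker, direction) pair maps to.
The map is an explicit CSV knowledge input (clinical experience, e.g.
decreasing platelets → bleeding), never inferred from the data. No
multiplicity correction is applied across the patient × marker tests: each
series feeds a per-record indicator, not a family-wise claim; a
Benjamini–Hochberg hook would be a one-line change but is deliberately off
by default and so documented here.

### The integrated index

With component matrix $V$ (records × 4), $S = \mathrm{cov}(V)$ and $e$ the
unit eigenvector of the largest eigenvalue,
$$ \mathrm{IC}(z) = e_1 V_1(z) + e_2 V_2(z) + e_3 V_3(z) + e_4 V_4(z), $$
min–max normalized to $[0,1]$ per batch. The covariance (not correlation)
matrix is the default because the components already live on comparable
[0, 1] scales and their variances are informative; `standardize = TRUE`
switches to correlation-scale PCA. The eigenvector sign is fixed by
$\sum_i e_i \ge 0$ (ties by the first non-zero coordinate positive), and an
eigenvalue tie beyond $10^{-9}$ breaks to the lexicographically larger
oriented eigenvector, making the index fully deterministic. The batch
(min, max) bounds persist with the loadings (`ci_to_json()`), and held-out
records reuse them, clipped to $[0,1]$.

The first quartile of the normalized index (type-7 linear-interpolation
quantile, the most common convention) bounds the low-credibility zone. The
cutoff is always recomputed from the batch at hand — on one data set it may
be 0.21, on another 0.05 — and records at or below it are flagged by
default, dropped only under `prune_low_ci = TRUE`.

### Evidence generation and fusion

A probability forest (500 trees, $\sqrt{p}$ features per split,
single-threaded and seed-deterministic) predicts the record's class. During
evaluation the class probabilities come from stratified 5-fold held-out
predictions, so generated masses are not optimistically sharp; at inference
the full model is used. Probabilities become a BPA by
$m(\{k\}) = \mathrm{CI} \cdot p_k$, $m(\Theta) = 1 - \mathrm{CI}$: the
index's complement is explicit ignorance, not redistributed probability.
The index enters both as this discount and as a forest feature; each role
can be disabled (drop the feature column, or pass `ci = 1`). Generated BPAs
use only singleton and whole-frame focal sets — the decision surface is
singleton beliefs — while the DST core supports arbitrary focal sets for
external sources. Leaflet knowledge contributes
$m(\{\mathrm{hypothesis}\}) = c$, $m(\Theta) = 1 - c$ for a documented
(drug, reaction) pair with source credibility $c$, vacuous otherwise, and
the two sources combine by Dempster's rule. The frame can be the cause
frame (ADR/DISEASE/OTHER, the default in `dep_dst()`) or a symptom frame;
`leaflet_mass()` takes the supported hypothesis explicitly so both framings
work.

## The synthetic generator

`world_params()` fixes the study conditions: 1000 patients, 5 diseases, 20
drugs, 10 symptoms over one year starting 2019-01-01; 10% of drug–symptom
pairs are true ADRs and 20% of disease–symptom pairs are confounded, with
per-pair emission probabilities drawn uniformly within ±0.15 of 0.4 (the
same magnitude for both mechanisms, so confounded records genuinely mimic
ADRs); polypharmacy is 1 + truncated Poisson with mean 3, capped at 6;
background noise emits a causeless symptom at 0.02 per patient–symptom;
half of the true ADR mechanisms also move a lab marker, with slope sized at
8 noise standard deviations over 360 days so a full-window exposure is
clearly detectable while short exposures remain ambiguous; labs sample
monthly with ±5-day jitter; the leaflet knowledge base covers 70% of true
ADRs with source credibility drawn in [0.6, 0.95], leaving covered and
uncovered ADRs for fusion tests. One disease per patient — comorbidity is
out of scope. Disease- and noise-caused symptoms are attributed to a random
concurrent drug, which is what makes the discrimination task non-trivial.
All generation is deterministic per seed (base R Mersenne–Twister), and
truth labels live in a separate file so the pipeline runs blind.

What the generator does *not* emulate: free-text clinical notes, dose and
route, comorbidity, inter-drug interaction effects beyond the count-based
effect size, irregular visit schedules, and measurement batch effects.
Passing recovery tests on this generator shows the machinery identifies the
modelled dependency structure; it does not certify performance on real
hospital data, whose headline metrics depend on private material.

## Benchmark protocol and problem sizes

`run_benchmark()` compares three nested feature sets per simulated cohort:
`base` (age, sex, disease, attributed drug, symptom, drug count, and one
binary exposure indicator per drug), `base_ci` (plus
correlation, effect size, temporal support, and their 3-component PCA
index), and `base_ci_bayes` (plus the arc strength and the full 4-component
index). Per seed, a fresh world is simulated, components are computed
blind, and a forest is evaluated by stratified 5-fold cross-validation;
metrics are accuracy and macro-averaged precision/recall (macro because the
cause classes are imbalanced and the minority classes are the interesting
ones; micro averaging is available). Improvements are reported relative to
`base`, and the final scenario is compared to `base` by a one-sided paired
t-test across seeds. The package's benchmark protocol uses 1000 patients
(roughly 2500 candidate records), 10 replicate seeds, 300 trees, and a
1500-iteration / 300 burn-in structure walk over the ~30-node indicator
network — sizes chosen so the full recovery experiment runs on a laptop
CPU in minutes while leaving the scenario ordering statistically resolvable.
`dep_dst()` defaults are larger (500 trees, 2000/500 MCMC) since it fits
once.

Degenerate inputs are handled explicitly: constant structure-learning
columns and all-constant component tables are errors naming the culprit;
a class with fewer than two records refuses stratification with a message;
a contingency table with a zero margin raises a degenerate-margin error
carrying the record id; total fusion conflict flags the record and the
batch continues.

## Known limitations

* Arc strength from single-edge-move MCMC mixes slowly on large networks;
  the patient-level indicator network here is small, but hundreds of nodes
  would need order-MCMC or bootstrap-based strengths.
* The chi-square component tests marginal, not conditional, dependence; a
  disease correlated with a drug's use (indication) contributes to both
  components.
* `1/n` effect size ignores dose, timing and pharmacological interaction
  structure.
* Per-batch min–max normalization makes the index relative to the batch;
  cross-batch comparisons must reuse persisted bounds.
* Dempster's rule assumes independent sources; forest evidence and leaflet
  knowledge are treated as independent, which is an approximation whenever
  the leaflet informed prescribing behaviour in the data.
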