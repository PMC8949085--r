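# depdst

Dependency-aware evidence fusion for adverse drug reaction (ADR) signal
discrimination in EHR-style data.

## The problem

When a patient on several drugs develops a symptom, three explanations
compete: a true adverse reaction to one of the drugs, the natural evolution
of the disease being treated (confounding by indication), or neither.
Classifiers trained on raw drug/symptom co-occurrence conflate these.
`depdst` scores every candidate ADR record with a **credibility index**
built from four dependency measurements, and uses that index to temper the
evidence a classifier produces before fusing it with external knowledge
under Dempster–Shafer theory (DST).

## The method

For each candidate record *z* (patient, disease, drug, symptom) the package
computes the component vector

> V(z) = (DepCausalStrength, DepCorrelation, DepEffectSize, DepTemporal)

* **DepCausalStrength** — posterior support for the drug→symptom arc: the
  fraction of Bayesian-network structures containing it across a
  BDeu-scored Metropolis walk over DAGs (`sample_structures_mcmc()`,
  `arc_strength()`).
* **DepCorrelation** — `1 − p` from the Pearson chi-square independence
  test on the record's disease × symptom contingency table
  (`dep_correlation()`).
* **DepEffectSize** — `1/n` for `n` concurrently administered drugs: an
  effect that many drugs could explain is less believable
  (`dep_effect_size()`).
* **DepTemporal** — 1 iff a statistically significant lab-marker trend
  (OLS slope test at α = 0.05) overlaps the drug's exposure window and a
  knowledge map links that (marker, direction) to the symptom
  (`fit_trend()`, `build_temporality_basis()`).

The components are integrated by the first principal component of their
covariance matrix,

> IC-PCA(z) = e₁·V₁(z) + e₂·V₂(z) + e₃·V₃(z) + e₄·V₄(z),

min–max normalized to [0, 1], with the first quartile marking the
low-credibility zone (`pca_integrate()`, `low_credibility_cutoff()`).

A random forest turns record features (plus the index) into class
probabilities; these become a basic probability assignment with
`m({k}) = CI·p_k` and `m(Θ) = 1 − CI`, so distrust is explicit ignorance,
and are fused with medicine-leaflet knowledge by Dempster's rule
(`bpa_from_probs()`, `leaflet_mass()`, `fuse()`).

A synthetic EHR generator (`simulate_ehr()`) provides worlds with known
ADR/confounding/noise structure and ground-truth labels, so every stage is
testable without private hospital data.

## Worked example

```r
library(depdst)

# Two experts disagree about a bleeding episode under an anti-inflammatory:
f <- dst_frame(c("ADR", "DIS", "OTH"))
john <- mass_function(f, c(ADR = 0.8, "*" = 0.2))
paul <- mass_function(f, c(DIS = 0.7, ADR = 0.2, "*" = 0.1))
dempster_combine(john, paul)
#> Dempster combination (conflict K = 0.56)
#> Mass function on {ADR, DIS, OTH}
#>   m({ADR}) = 0.63636
#>   m({DIS}) = 0.31818
#>   m({Theta}) = 0.045455
```

More than half the joint mass (K = 0.56) falls on contradictory
hypotheses; after renormalization the fused belief in an ADR is 0.636 —
substantial but far from either expert's certainty.

End to end on a synthetic cohort:

```r
sim <- simulate_ehr(world_params(n_patients = 200, seed = 5))
fit <- dep_dst(sim$candidates, sim$registry, sim$prescriptions, sim$labs,
               sim$marker_symptom_map,
               labels = sim$truth$label[match(sim$candidates$record_id,
                                              sim$truth$record_id)],
               leaflet_kb = sim$leaflet_kb, seed = 5,
               num_trees = 150, mcmc_iter = 600, mcmc_burn = 150)
fit
#> Dependency-aware DST evidence model
#>   442 candidate records, 139 patients in temporality basis
#>   Credibility-index loadings:
#> dep_causal_strength     dep_correlation     dep_effect_size        dep_temporal
#>              0.3497             -0.1796             -0.0928              0.9148
#>   Low-credibility cutoff (first quartile): 0.049
#>   Evidence forest: 150 trees over classes ADR, DISEASE, OTHER
head(predict(fit), 3)
#>   record_id   bel_ADR  bel_DISEASE   bel_OTHER   conflict flagged
#> 1   R000001 0.6549935 0.0038903683 0.041382403 0.00000000   FALSE
#> 2   R000002 0.7071711 0.0072543937 0.026098578 0.00000000   FALSE
#> 3   R000003 0.9650582 0.0003895019 0.004543076 0.04455407   FALSE
```

The loadings show temporal support and causal arc strength carrying the
index on this cohort; `bel_*` columns are fused singleton beliefs after
combining the credibility-conditioned forest BPA with the leaflet evidence.

The three-scenario benchmark (`run_benchmark()`) compares nested feature
sets — covariates only, plus the non-causal credibility components and
their index, plus the Bayesian arc strength — under stratified 5-fold CV
over multiple simulated cohorts, reporting accuracy, macro precision and
macro recall with relative improvements.

A thin CLI over the same functions ships in `inst/scripts/depdst.R`
(subcommands `simulate`, `ci`, `train`, `benchmark`, `fuse`, `report`).

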