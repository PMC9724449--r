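# modsig

Additive mutational-signature analysis explains a cancer sample's 96-channel
single-base-substitution (SBS) spectrum as a non-negative sum of signature
profiles, `X̃ᵏⱼ = Σᵢ aᵏᵢ μᶦⱼ` — the NMF paradigm behind COSMIC signature
refitting. That model can only *add* mutations. Real catalogues, however,
show systematic residual structure: whole base classes over- or
under-predicted in cancer-type-specific ways, consistent with processes
(e.g. sample-specific DNA repair propensities) that multiplicatively rescale
— and can *remove* — mutations.

`modsig` is an R package for analysts of somatic mutation catalogues that

* diagnoses that structure — additive (`X − X̃`) and multiplicative
  (`(X+1)/(X̃+1)`) residuals, complete-linkage correlation clustering at a
  0.75 correlation threshold, cancer-type entropy ranking of clusters, and a
  Poisson-resampled null control;
* extends the additive model with a **modulatory process**: a global profile
  `r ∈ [−1, 1]⁹⁶` and per-sample activities `cᵏ ≥ 0`, modelling

  ```
  Xᵏⱼ ~ Pois( (1 + cᵏ rⱼ) · X̃ᵏⱼ ),    1 + cᵏ rⱼ ≥ 0
  ```

  with Poisson maximum likelihood, analytic gradients, gauge fixing
  (`max|r| = 1`; only the product `c·r` is identified) and an alternating
  refitting loop with random restarts — `c = 0` recovers the additive model,
  so the models are nested and the log-likelihood *gain* measures the
  evidence for active modulation;
* simulates realistic benchmark catalogues (COSMIC-like peaked signature
  pools, log-normal exposures at whole-genome burdens, structured modulatory
  profiles over two base classes, Poisson counts) and scores recovery with
  cosine similarity, MSE, per-mutation gain, modulation impact
  `⟨1 + cᵏ rⱼ⟩ₖ` and BIC.

## Worked example

Simulate one modulated dataset at whole-genome burdens, fit both models, and
compare against the ground truth:

```r
library(modsig)
set.seed(42)
cfg <- simulationConfig(nSamples = 50, seed = 42)
sim <- simulateDataset(cfg)
sim$catalog
#> MutationCatalog: 50 sample(s) x 96 channels; 939,823 total mutations

fit <- alternatingFit(sim$catalog, sim$signatures, fitConfig(seed = 1))
fit
#> ModSigFit: 50 sample(s), 10 signature(s)
#>   logLik = 5020699.1424 (additive 4998969.1395, gain 21730.0029)
#>   converged: TRUE | restarts used: 0

cosineSimilarity(modProfile(fit), modProfile(sim$trueModulatory))
#> 0.996
mse(modActivities(fit), modActivities(sim$trueModulatory))
#> 0.0011
modelComparison(fit, sim$catalog)
#>    gain deltaBIC gainPerMutation nSamples nMutations
#> 1 21730 42222.46      0.02312138       50     939823
```

The fitted modulatory profile matches the injected one almost exactly
(cosine 0.996), its per-sample activities are recovered with MSE ≈ 0.001 on
the gauged `[0, 1]` scale, and the log-likelihood gain of ~2.2 × 10⁴ over
the additive refit dwarfs the BIC penalty for the 96 + 50 extra parameters
(ΔBIC ≈ +4.2 × 10⁴): the modulation is decisively supported. On unmodulated
data the same pipeline returns a per-mutation gain below 10⁻³.

Real catalogues and signature sets are read from COSMIC/PCAWG-style TSVs
with `readCatalog()` / `readSignatures()`; `inst/cli/modsig.R` exposes the
pipeline (`simulate`, `fit`, `residuals`, `cluster`, `evaluate`) to the
shell, e.g.

```sh
Rscript inst/cli/modsig.R fit --catalog catalog.tsv --signatures cosmic.tsv \
    --by-group types.tsv --seed 7 --out fit/
```

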