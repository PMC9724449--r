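---
title: "Modulatory mutational signatures: model, inference and simulation design"
author: "modsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulatory mutational signatures: model, inference and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modsig)
```

## The model

The additive mutational-signature model explains a sample's 96-channel
single-base-substitution (SBS) spectrum as a non-negative linear combination
of signature profiles:

$$\widetilde{X}^k_j = \sum_{i} a^k_i \, \mu^i_j,$$

where $\mu^i$ is the $i$-th signature (a probability distribution over the
96 trinucleotide-context channels) and $a^k_i \ge 0$ its activity in sample
$k$. Being purely additive, this model can only *add* mutations; it cannot
represent processes — DNA repair being the biological prototype — that
selectively *remove* mutations from some channels, nor sample-specific
rescaling of whole base classes. Both leave systematic residuals in real
catalogues.

`modsig` extends the model with one global, multiplicatively acting
modulatory process: a profile $r_j \in [-1, 1]$ over channels and a
non-negative activity $c^k$ per sample, entering as

$$X^k_j \sim \mathrm{Pois}\!\big( (1 + c^k r_j)\, \widetilde{X}^k_j \big),
\qquad 1 + c^k r_j \ge 0 .$$

Negative $r_j$ models removal (down-modulation), positive $r_j$
amplification; $c^k = 0$ switches the process off in a sample and recovers
the additive model exactly, so the two models are nested. Only the product
$c^k r_j$ is identified: rescaling $r \to r/\alpha$, $c \to \alpha c$ leaves
every Poisson rate unchanged. This *gauge* degeneracy is fixed by
normalising $\max_j |r_j| = 1$ (`gaugeFix()`), the analogue of normalising
each additive signature to unit sum. The log-likelihood (dropping the
$\log X!$ constant, which cancels from all model comparisons) is

$$\ell = \sum_{k,j} \Big[ -p^k_j \widetilde{X}^k_j
        + X^k_j \log\big(p^k_j \widetilde{X}^k_j\big) \Big],
\qquad p^k_j = 1 + c^k r_j,$$

with closed-form gradients in $a$, $r$ and $c$ (`gradActivities()`,
`gradModulatoryProfile()`, `gradModulatoryActivity()`), each verified in the
test suite against central finite differences to $10^{-6}$ relative error.

## Inference

`alternatingFit()` performs block coordinate ascent:

1. refit the additive activities $a$ per sample (signatures held fixed,
   modulation fixed at its current value — initially off);
2. fit $(r, c)$ jointly with the additive part fixed;
3. alternate, three rounds by default, stopping early when an alternation
   improves the log-likelihood by less than `minGainImprovement`
   ($10^{-4}$).

Each block is maximised with a bound-constrained quasi-Newton method
(L-BFGS-B) fed the analytic gradients, under $a \ge 0$, $c \ge 0$ and
$r \in [-1, 1]$; a failed convergence triggers random restarts (up to 100)
with uniform reinitialisation. Because every half-step maximises its own
block starting from the current iterate, the recorded log-likelihood trace
is non-decreasing up to optimizer tolerance, and the final extended fit can
never fall below the plain additive refit — if an (extremely rare) failed
optimisation would leave it lower, the additive solution with the modulation
switched off is returned instead, preserving the nesting property
`gain >= 0`.

Initialisation matters and is deliberately informed: $r$ starts from the
centred mean multiplicative residual of the current additive fit (gauged),
reflecting the empirical observation that the inferred modulatory profile
closely tracks the mean multiplicative residual; $c$ starts at $0.5$; the
activities start from a non-negative least-squares fit of the
pseudo-counted catalogue. Channels that carry essentially no additive
intensity are uninformative about $r_j$; under this initialisation they stay
near zero instead of wandering to arbitrary values, which measurably
improves profile recovery on the benchmark compared to fully random
starts.

Numerical choices:

* Poisson rates are clamped at $\varepsilon = 10^{-9}$ inside the
  optimizer's objective so the log stays finite at the feasibility boundary
  $p = 0$ (which is only reachable across cells with $X = 0$); the exact
  likelihood (`logLikelihood()`) instead treats a zero rate under a positive
  count as an explicit error.
* The gauge is re-applied between optimizer rounds (up to 5 rounds, stopping
  once the gauge is already the identity), keeping $r$ on its natural scale
  while the box constraint $r \in [-1,1]$ is active.
* After each round $c$ is projected back onto the feasible set
  ($c \le (1 - 10^{-9}) / (-\min_j r_j)$ when $\min_j r_j < 0$): the clamp
  lets the optimizer drift marginally infeasible only where it is
  likelihood-neutral.
* `fitActivities()` treats samples independently (the likelihood separates),
  so results do not depend on sample order.

Model choice between additive and extended fits uses the BIC
(`modelComparison()`): the extension costs 96 profile parameters plus one
activity per sample, so $\Delta\mathrm{BIC} = 2\,\mathrm{gain} - (96 +
N_S)\log(96\,N_S)$; the report also carries the gain per mutation, the
scale-free quantity used to rank groups.

### What "no modulation" looks like

On purely additive data the extended model still absorbs counting noise:
the expected maximum-likelihood gain is about half the added degrees of
freedom, $(96 + N_S)/2$, and after gauging the most overfit channel's
impact deviates from 1 by roughly the mean fitted $c$. The honest
diagnostics for an inactive process are therefore a *per-mutation* gain
near zero (the suite asserts $< 10^{-3}$) and a typical (mean across
channels) impact near 1 — not a pointwise 1% band, which no
maximum-likelihood fit of this size satisfies.

## Residual diagnostics

`computeResiduals()` evaluates the additive residual $X - \widetilde{X}$
and the multiplicative residual $(X + 1)/(\widetilde{X} + 1)$; the
pseudo-count of 1 is applied only where a division or log would otherwise
hit zero, never to the likelihood, where zero counts are valid
observations. Samples are clustered by Pearson correlation of their
96-channel residual profiles (Spearman available as an option), with
complete linkage on the distance $1 - \rho$ and a flat cut at a correlation
threshold of 0.75 (distance 0.25). Clustering uses unclipped correlations;
clipping to $[0, 1]$ is a display concern for heat maps only. Cluster
quality by cancer type is summarised with the label entropy $S = -\sum_i
p_i \log p_i$ (natural log by default, base exposed), reported for clusters
of at least 10 samples and sorted ascending, so type-specific (low-entropy)
clusters rank first. `poissonResampleControl()` provides the matching null:
counts redrawn as Poisson with the observed counts as rates show essentially
no residual correlation structure (the suite asserts that fewer than 1% of
off-diagonal entries exceed $|\rho| > 0.5$ on a 200-sample control).

## The simulator and what it does (not) emulate

`simulateDataset()` mirrors the benchmark protocol: a pool of 10
signatures; 4 active per sample, chosen uniformly without replacement;
activities drawn log-normally ($\mathrm{sdlog} = 1.5$); a structured
modulatory profile that up-modulates every channel of one SBS base class
with $U(0,1)$ magnitudes and down-modulates a second, plus $N(0, 0.05)$
noise on all 96 channels (read as standard deviation 0.05, the
conventional notation; configurable); $c \sim U(0, 1)$; joint gauging of
$(r, c)$ with redraw of any $c$ violating feasibility (truncation only
after 100 failed redraws); Poisson counts from the modulated rates.

Two simulator parameters deserve justification:

* **Burden.** The location of the activity distribution is anchored so the
  expected per-sample burden, $4\,e^{\mu_{\log} + 1.5^2/2}$, matches the
  PCAWG average of ${\sim}17{,}400$ SBS per whole genome (48.3M mutations
  over 2,780 samples), the corpus this simulator stands in for; a
  whole-genome catalogue with only a handful of mutations per sample would
  be neither biologically plausible nor informative about a 96-parameter
  profile. This fixes $\mu_{\log} = \log(17366/4) - 1.125 \approx 7.25$.
* **Signature shape.** Synthetic pools are symmetric-Dirichlet draws with
  concentration 0.25, giving the sparse, peaked profiles characteristic of
  COSMIC signatures (a few dominant channels over a long tail) without
  requiring the COSMIC file; `signatureSource = "file"` reproduces the
  draw-from-COSMIC protocol exactly when a signature TSV is supplied.

What the simulator does **not** emulate: correlated signature co-occurrence
across samples, over-dispersion beyond Poisson, multiple simultaneous
modulatory processes, sequencing artefacts, or tumour heterogeneity — so a
passing benchmark demonstrates correct inference under the stated
generative model, not performance guarantees on real catalogues.

## Benchmark scales

The acceptance-scale benchmark (`runBenchmark()` at its defaults) uses 50
independent datasets of 100 samples each — the study conditions — and
completes in well under a minute on one CPU; each dataset derives its own
seed from the configuration seed, so per-dataset results are independent of
execution order and the whole run is a pure function of the seed. Unit
tests use smaller instances (tens of samples, 2–5 signatures) chosen so
that finite-difference oracles remain numerically clean.

## Known limitations

* One modulatory process per dataset/group: fitting several interacting
  processes jointly is out of scope, as is de novo extraction of the
  additive signatures themselves.
* The profile $r$ is unidentifiable on channels with no additive intensity;
  the residual-based initialisation leaves such channels near 0 rather than
  flagging them. Inspect `additiveReconstruction()` column sums when in
  doubt.
* Reported log-likelihoods omit $\log X!$ and are comparable only within a
  dataset; gains and BIC differences are unaffected.
* `c` has no upper bound beyond feasibility; its scale is set by the data
  and the gauge.
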