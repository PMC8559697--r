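---
title: "Modelling sparse mutation catalogs with a mixture of multinomial mixtures"
author: "mixmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sparse mutation catalogs with a mixture of multinomial mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixmm)
```

## The problem

Targeted gene-panel sequencing yields somatic mutation catalogs in which a
typical tumour contributes fewer than ten single-base substitutions.  Classic
signature analysis — NMF-style de-novo extraction, or per-sample refitting
against known signatures — estimates one exposure vector per sample and
therefore needs each sample to populate a meaningful fraction of the 96 SBS
categories.  At panel sparsity most categories are empty and the number of
per-sample parameters exceeds the number of observations.

mixmm addresses this by clustering samples and estimating exposures *per
cluster*.  Samples belong to one of $L$ latent clusters; cluster $\ell$ has a
relative exposure vector $\pi^\ell$ over $K$ signatures $e_1, \dots, e_K$
shared by all clusters; each mutation of a sample in cluster $\ell$ is drawn
by first picking a signature $i \sim \pi^\ell$ and then a category
$j \sim e_i$.  Marginally, a sample's counts $V$ follow a multinomial over
the cluster's category mixture, and the data likelihood is

$$\Pr[V \mid w, \pi, e] \;=\; \prod_{n=1}^N \sum_{\ell=1}^L w_\ell
  \prod_{j=1}^{M} \Big( \sum_{i=1}^K \pi^\ell_i e_i(j) \Big)^{V^n_j},$$

with cluster priors $w$.  Mutations pooled across a cluster's samples are
what make the exposures estimable: the model has
$(L-1) + L(K-1) + K(M-1)$ parameters regardless of the number of samples.

## Training

`mix_fit()` maximises the likelihood by EM.  The E-step computes cluster
responsibilities $f^{n,\ell}$ and, per signature, the expected number of
emissions of each category pooled over samples and clusters; the M-step
renormalises these into new $w$, $\pi$, $e$.  Each iteration costs
$O(\text{nnz} \cdot L)$ where nnz is the number of non-zero (sample,
category) cells — panel catalogs are extremely sparse, so the compiled core
works on the catalog's triplet representation.  One EM step is also exposed
in pure R (`mix_em_step()`) and the test suite verifies that the two paths
agree to machine precision.

Choices the user can control, with their defaults:

* **Restarts** (`n_restarts = 10`): EM converges to a local maximum, so
  training restarts from independent Dirichlet(1) draws of all parameter
  blocks; the restart with the highest final log-likelihood wins.  Restart
  $r$ seeds the generator with `seed + r - 1`, making fits bit-reproducible.
* **Iteration cap** (`max_iterations = 1000`) per restart.
* **Convergence** (`tol = 1e-6`, `tol_rel = 1e-10`): stop when the absolute
  log-likelihood improvement falls below `tol` or the relative improvement
  below `tol_rel`.  The cap and the restart count follow the training
  protocol of the underlying method; the tolerances are this package's
  choice, as is the initialisation distribution (uninformative, the standard
  for mixture EM).
* **Refitting** (`signatures =`): fixing the signature matrix skips the
  $e$ update; only $w$ and $\pi$ are learned, and the BIC uses the reduced
  parameter count $(L-1) + L(K-1)$ — fixed signatures are inputs, not
  estimated parameters.

Numerical guards: per-category mixture probabilities are floored at 1e-300
before logs, so underflow never produces spurious $-\infty$; a genuinely
structural zero (probability exactly 0 with a positive count) still yields
$-\infty$ or an error naming the offending category/sample, because it
indicates inconsistent inputs rather than underflow.  A cluster or signature
whose pooled expectation is exactly zero in an M-step keeps its previous
parameters and triggers a warning instead of a 0/0.  Zero-mutation samples
contribute likelihood 1 and take the prior $w$ as their responsibility; they
are retained.  Posterior ties in hard assignments break to the lowest
cluster index.

## Model selection

`mix_select()` fits every $(L, K)$ on a grid and scores
$\mathrm{BIC} = \text{size}\cdot\log n - 2\log\Pr[V]$, where $n$ is the
total number of mutations — the iid units of the likelihood.  Ties break
towards smaller $K$, then smaller $L$.  `stats::BIC()` on a fitted model
agrees with `bic_score()` because `logLik()` carries the parameter count and
`nobs()` returns the mutation total.

## Exposure inference

Given a trained model, per-sample exposures come in two schemes
(`infer_exposures()`): **hard** — the exposure row of the
maximum-posterior cluster; **soft** — the responsibility-weighted average
$\sum_\ell f^{n,\ell}\pi^\ell$.  Soft is the default for exposures and hard
for cluster assignments.  Both are relative (rows sum to 1);
`scale = "counts"` multiplies by the sample's mutation total.  The two
schemes coincide whenever the posterior is (near) certain — which is also
why their reconstruction errors are nearly identical on well-separated
synthetic data (below).

## The synthetic-data generator

`simulate_catalog()` draws catalogs from the generative process itself, so
round-trip experiments have exact ground truth.  Study conditions are set by
two defaults:

* **Mutation budgets** (`default_budget_pool()`): per-sample totals are
  resampled uniformly with replacement from a fixed pool distributed as
  $1 + \mathrm{NegBin}(\text{size}=1.5, \mu=6)$ — long-tailed with mean
  about 7, emulating a pan-cancer panel cohort at roughly 7 mutations per
  sample.  A Poisson alternative (`budget_mean =`) supports sweeps over the
  average mutation count.
* **The base model** (`default_base_model()`): the subsetting procedure of
  `build_ground_truth()` — draw $L_{sub}$ clusters without replacement by
  $w$, renormalise; draw $K_{sub}$ signatures without replacement by the
  marginal usage $p_k = \sum_\ell w_\ell \pi^\ell_k$; restrict and
  renormalise the exposures — needs a realistic base.  The reference for
  such a base is a model *selected by BIC* on a large cohort, which imposes
  two structural properties that our synthetic stand-in must reproduce:
  (i) *self-consistency*: a BIC grid on a 5,000-sample catalog generated
  from the base recovers its own dimensions $(L=10, K=6)$ — each signature
  carries enough likelihood at panel sparsity to justify its own BIC cost,
  which requires the marginal usage of the six signatures to be balanced;
  (ii) *distinguishable clusters under subsetting*: no two cluster exposure
  rows may become effectively identical after restriction to a 4-signature
  subset, since a selected model would not retain duplicate clusters.
  The construction therefore draws sparse Dirichlet(0.05) signatures,
  builds exposure rows from sorted Gamma$(t_l,2,1,0.3,0.3,0.3)$ shares
  (two to three dominant signatures over a varied background; dominance
  strength $t_l$ varies across clusters), assigns shares to signatures
  preferring low accumulated usage, and rejects any assignment whose
  projection under *any* 4-signature subset comes within cosine 0.98 of an
  existing cluster.  The realised base has marginal usages in
  $[0.15, 0.21]$ and a worst-case projected cluster cosine of 0.979.
  Everything is deterministic (fixed internal seed) and cached.

What the generator does *not* emulate: trinucleotide-context composition
differences between genome, exome and panel territories; sequencing error;
inter-sample contamination; and real signatures' correlated co-occurrence
patterns.  Passing round-trip tests therefore demonstrates correctness of
the estimator under its own model assumptions, not performance on real
cohorts.

Two downsampling utilities sparsify rich catalogs for refitting
experiments: `poisson_downsample()` keeps $\min(n_i, T_i)$ mutations per
sample with $n_i \sim \mathrm{Pois}(d)$, sampled without replacement from
the sample's mutation multiset (truncation at $T_i$ is forced by sampling
without replacement; the reference procedure leaves the $n_i > T_i$ case
unstated); `region_downsample()` keeps per-mutation records falling inside
the intervals of a BED panel (0-based half-open intervals against 1-based
positions: kept iff $\text{start} < \text{pos} \le \text{end}$).

## Evaluation utilities

* `nnls_exposures()` — the standard rich-data refitting baseline
  (Lawson-Hanson non-negative least squares, via pracma).
* `reconstruction_error()` — $\mathrm{RE} = |\tilde V - E_d S|_1$ per
  sample, where $\tilde V$ is the row-normalised full catalog and $E_d$
  the relative exposures inferred on sparse data; the mean over evaluable
  samples is reported, zero-mutation samples are skipped.
* `exposure_reconstruction_error()` — $\mathrm{ERE} = |\tilde E - E_d|_1$
  against row-normalised NNLS exposures computed on the full data;
  zero-reference rows are skipped with a warning.
* `match_signatures()` — cosine matching, either best-match (repeats
  allowed, for reporting against a reference catalogue) or one-to-one
  (Hungarian assignment maximising total cosine, for recovery scoring);
  ties break to the lowest reference index.
* `adjusted_mutual_information()` — chance-corrected partition agreement
  under the permutation model, normalised by $\max(H_a, H_b)$ (the
  normalisation variant is this package's choice).

`refit_benchmark()` assembles these into the downsampling experiment: train
a refit model on the Poisson-downsampled half of a rich catalog, infer
soft, hard and NNLS exposures for the held-out half from their sparse
counts, and score RE/ERE against the held-out full data.

## Problem sizes used by the test suite and acceptance script

The shipped checks use 2,000-sample catalogs for the single-setting
parameter-recovery test and 5,000-sample catalogs (the cohort size the
generator emulates) for recovery scoring and the five BIC settings, with 10
restarts — model selection at these margins genuinely needs both the full
catalog size and the full restart policy: at 2,000 samples the BIC penalty
per signature (about 910) can exceed the weakest signature's likelihood
contribution, and with 5 restarts the larger-$L$ cells occasionally land in
poor optima, inverting adjacent BIC comparisons.  The refit-ordering
experiment aggregates 30 replicate seeds because the soft-hard difference
is an order of magnitude smaller than its per-replicate noise (the schemes
coincide at posterior certainty); NNLS trails both by a wide margin in
every replicate.

## Known limitations

* The number of clusters should exceed the number of signatures for the
  exposures to be meaningfully shared; with $L \le K$ the model can devote
  one near-pure signature per cluster.
* De-novo fits are identifiable only up to jointly permuting signatures
  (and clusters); comparisons against a reference must match first —
  `match_signatures()` exists for exactly this.
* BIC consistency relies on the total mutation count; on very sparse
  cohorts (a few thousand mutations) expect conservative selection of both
  $L$ and $K$.
* A drawn ground truth whose weakest signature falls below roughly 10% of
  marginal usage may be unrecoverable by BIC at these catalog sizes — the
  same failure mode the underlying method reports on its own synthetic
  experiment.

## A minimal session

```{r example, eval = FALSE}
base <- default_base_model()
truth <- build_ground_truth(base, L_sub = 5, K_sub = 4, seed = 1)
sim <- simulate_catalog(truth, n_samples = 2000, seed = 2)

fit <- mix_fit(sim$catalog, L = 5, K = 4, n_restarts = 10, seed = 3)
summary(fit)

match_signatures(fit$params$e, truth$e, mode = "one_to_one")
exposures <- infer_exposures(sim$catalog, fit$params, scheme = "soft")
clusters <- assign_clusters(sim$catalog, fit$params)
adjusted_mutual_information(clusters, sim$truth$cluster_assignments)
```
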