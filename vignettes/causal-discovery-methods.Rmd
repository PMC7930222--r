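---
title: "Time-lagged causal discovery and causal-effect analysis with causalts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lagged causal discovery and causal-effect analysis with causalts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalts)
```

## The problem

Effective connectivity asks a directed question of multivariate recordings
such as ROI-averaged BOLD time series: which component drives which, at what
delay, and how strongly? Plain lagged correlation cannot answer it — strong
autocorrelation and common drivers produce dependence between components
that exchange no information. `causalts` implements a two-stage
conditional-independence search over lag-specific links, a linear
causal-effect and mediation layer on top of the discovered graph, an
information-theoretic transfer-entropy decomposition, and a ground-truth
synthetic generator that makes the whole chain testable end to end without
any external data.

## Model and assumptions

The observed series is treated as a realization of a stationary
multivariate discrete-time stochastic process $X_t = (X^1_t, \dots,
X^N_t)$. Its causal structure is a time-series graph with one node per
(component, time) pair and a lag-specific directed link
$X^i_{t-\tau} \to X^j_t$ (with lag $\tau \ge 1$) exactly when
$X^i_{t-\tau}$ is *not* independent of $X^j_t$ given the rest of the
process's past with $X^i_{t-\tau}$ removed. Links with $i = j$ are
autolinks (autodependencies); links with $i \ne j$ are cross-links
(couplings).

Interpretation of the recovered graph as causal rests on the usual
assumptions: causal sufficiency (no unobserved common drivers), the causal
Markov condition, faithfulness, causal stationarity over the analysis
window, and the absence of contemporaneous (lag-0) effects. The last
assumption is structural in this package: no operation can ever emit a
lag-0 link. It is an assumption about sampling resolution, not physics —
dependencies faster than one sampling step cannot be oriented and are
deliberately out of scope.

## The two-stage search

**Stage 1 — parent pre-selection** (`pc1_parent_selection()`). For each
target, all $N \tau_{\max}$ lagged candidates are screened
unconditionally, then repeatedly re-tested conditioned on the $q$
strongest remaining co-parents for $q = 1, 2, \dots$ (one condition set
per cardinality). A candidate is dropped as soon as its test exceeds
`pc_alpha`. This is the polynomial variant of the PC search: at most
$N^3\tau_{\max}^2$ tests, against exponentially many for subset-exhaustive
PC. `pc_alpha` is a regularization knob, not a calibrated level; it
defaults to `alpha` because the second stage, not the first, controls
error rates. During the iteration a candidate's ranking statistic is the
weakest (smallest absolute) statistic observed for it so far — the
conservative choice, so that barely-surviving candidates are conditioned
on last.

**Stage 2 — momentary conditional independence** (`mci_link_test()`).
Every ordered pair $(i, j)$ and lag $\tau$ is tested:
$X^i_{t-\tau} \perp X^j_t$ given the target's selected parents (minus the
tested link) *and* the source's own parents shifted back by $\tau$.
Conditioning on both parent sets is what neutralizes
autocorrelation-inflated false positives. All $N^2\tau_{\max}$ results are
retained with statistics and p-values; the graph keeps links with
$p \le \alpha$.

Two different alignment windows are used, and deliberately so. Stage 1
conditions only on lags up to $\tau_{\max}$, so its common window is
$T - \tau_{\max}$. Stage 2's shifted source parents reach back up to
$2\tau_{\max}$, so a single common window of $T - \tau_{\max}$ is
impossible there; instead every MCI test shares the window
$T - 2\tau_{\max}$, which keeps the effective sample size identical across
all MCI tests (the property that matters for comparing p-values across
links). With the default $\tau_{\max} = 15$ and $T = 280$ this gives
$n_\mathrm{eff} = 250$.

## Conditional-independence tests

Two tests are provided behind one interface, because the right choice
depends on the data:

* `parcorr_test()` — linear partial correlation. Both variables are
  residualized on the conditioning set; the residual correlation is
  referred to a two-sided Student-$t$ null with $n - |Z| - 2$ degrees of
  freedom. Fast, analytic, and appropriate when dependencies are
  approximately linear. This is the default and the setting used
  throughout the packaged end-to-end runs.
* `cmi_knn()` / `cmi_knn_test()` — conditional mutual information
  estimated with the k-nearest-neighbour entropy-estimator construction,
  with a permutation null. Model-free, so it can in principle detect
  nonlinear dependence (the generator's optional `link_transform` exists
  to exercise exactly this), at a substantial computational and variance
  cost.

Estimator conventions that matter for reproducing its numbers: neighbour
distances use the maximum norm in the joint space; subspace counts use
*strict* inequality (distance $< \epsilon_i$) excluding the point itself;
the digamma terms use the standard count-plus-one convention, under which
the conditional form degrades exactly to the classical k-NN mutual
information estimator when the conditioning set is empty. Exact duplicate
values (which would give zero distances) are broken by a deterministic,
seeded jitter of relative scale $10^{-10}$. Estimates are not clipped at
zero: under independence the estimator is slightly negative about half
the time, and the permutation test uses the null distribution, not the
sign. The permutation scheme is a simple random permutation of the `x`
samples; the p-value $(1 + \#\{\hat I_\pi \ge \hat I\})/(B+1)$ has
resolution $1/(B+1)$, so $B \ge 19$ is required for anything useful and
$B = 200$ is the default. A restricted (conditioning-preserving) local
permutation scheme would be an improvement; it is acknowledged and not
implemented.

With `k = 10`, $n = 1000$ samples of a bivariate Gaussian with
$\rho = 0.6$, the estimate concentrates near the closed form
$-\tfrac12\ln(1-\rho^2) = 0.2231$ nats; the acceptance script recomputes
this calibration at every run.

## Causal effects, mediation, aggregates

On the discovered graph, `fit_path_coefficients()` runs one joint
least-squares regression per target on all of its discovered parents over
the common window, giving the lag-specific path-coefficient matrices
$\Phi(\tau)$ (entries exactly zero off the graph; the joint fit, not
pairwise fits, is what gives the entries path-coefficient semantics). On
standardized series — the default — all coefficients are effects per
standard deviation; this also makes effects comparable across components,
which the aggregate measures below assume. Whether to standardize is a
genuine choice: raw-scale coefficients estimate the generating
coefficients of a known system (the package's recovery tests do exactly
that), standardized ones are the comparable ones. The pipeline
standardizes by default and exposes the toggle.

Accumulated effects follow the impulse-response recursion
$$\Psi(0) = I,\qquad \Psi(\tau) = \sum_{s=1}^{\tau} \Phi(s)\,\Psi(\tau-s),$$
so $\Psi_{ji}(\tau)$ — the causal effect $CE_{i \to j}(\tau)$ — sums the
coefficient products of *all* directed paths from $i$ to $j$ whose lags
total $\tau$, direct and indirect. This recursion is verified in the test
suite against a scalar time-domain propagation of a noiseless unit
impulse on 100 random stable models (agreement to $10^{-10}$); the
equivalence of the two routes is the package's core numerical invariant.
Negative effects are meaningful (a suppressive influence) and preserved
end to end; aggregate measures take absolute values explicitly.

The mediated causal effect through a component $k$
(`mediated_causal_effect()`) blocks every link *into* $k$ — row $k$ of
every $\Phi(\tau)$ set to zero — recomputes the recursion, and takes the
difference: $MCE^{(k)}_{i \to j}(\tau) = \Psi_{ji}(\tau) -
\Psi^{(k)}_{ji}(\tau)$. Blocking the inputs of $k$ severs every path
through $k$ while leaving all other paths untouched, so for a pair whose
paths all pass through $k$ the mediated effect is the whole effect, and
for a pair with no path through $k$ it is exactly zero.

Per-node aggregates (`aggregate_measures()`) start from
$CE^{\max}_{i\to j} = \max_{0<\tau\le\tau_{\max}} |CE_{i \to j}(\tau)|$:

* **ACE** (aggregated causal effect) of $i$: mean of $CE^{\max}_{i\to j}$
  over targets $j \ne i$ — how strongly the node drives the network;
* **ACS** (aggregated causal susceptibility) of $j$: mean over sources
  $i \ne j$ — how strongly it is driven;
* **AMCE** of $k$: mean of $\max_\tau |MCE^{(k)}_{i\to j}(\tau)|$ over the
  ordered pairs $(i,j)$, $i \ne j$, both $\ne k$, that have at least one
  causal path through $k$ reachable within the horizon ($\min$ in-lag
  plus $\min$ out-lag $\le \tau_{\max}$). Pair membership is decided by
  boolean path reachability on the support of $\Phi$ (absolute values, so
  coefficient cancellations cannot hide a path), not by whether the
  numerical MCE happens to be nonzero. A node mediating no pair has
  AMCE 0 by convention.

`mediation_graph()` unrolls the graph over time offsets $0..\tau$ and
keeps exactly the nodes and links on at least one connecting path,
annotating intermediate nodes with their MCE — the time-resolved picture
of *how* an effect at a long lag is carried by shorter links.

## Decomposed transfer entropy

Transfer entropy from $i$ to $j$ — information in the source's past about
the target beyond the target's own past — involves conditioning on an
unboundedly large history. `decomposed_transfer_entropy()` uses the
discovered graph to reduce it to a sum of per-lag CMI terms
$\sum_{\tau=1}^{\tau^*} I(X^i_{t-\tau}; X^j_t \mid S)$, each conditioned
on the finite, graph-derived set $S$ (the target's parents minus the
tested link, plus the source's shifted parents). Irrelevant components
never enter $S$, so adding bystander series leaves the estimate unchanged
up to estimator noise — a property the test suite checks by paired runs.
Condition sets larger than `max_conds` (default 10) are refused rather
than silently estimated: k-NN CMI in high-dimensional condition spaces at
a few hundred samples is not trustworthy.

## The synthetic generator

`make_var_model()` / `simulate_process()` define the study conditions the
package is validated under: a stationary linear stochastic process with
sparse lag-specific links, i.i.d. Gaussian innovations (the noise law is
a modelling choice; nothing downstream depends on Gaussianity except the
analytic null of the partial-correlation test), and a stability gate —
the companion-form spectral radius must be below 1, checked by eigenvalue
computation at construction, with the radius reported in the error when a
model is rejected. Burn-in defaults to ten model orders and is discarded.
Coefficients are interpreted per standard deviation of the driving
component; innovations default to unit variance so that generated and
fitted coefficients live on comparable scales.

The packaged 14-region fixture (`example_motor_model()`) sketches a
visual-to-motor cascade over the labelled ROI set — right V2 driving
visual and premotor areas, premotor to motor cortex, a deliberate
long-lag (15-sample) direct link, a thalamic node that receives from
premotor cortex and sends a weak *negative* link back to visual cortex,
plus cerebellar and frontal inputs — with lag-1 autolinks (0.35)
everywhere and cross-coefficients 0.25–0.30. The intended regime is
$T = 280$ samples at a 2.8 s interval. `apply_hrf_downsample()` offers a
deliberately simple stand-in for hemodynamic blurring (causal convolution
with a short nonnegative kernel, then integer decimation); it makes no
claim to physiological realism, and no realistic BOLD forward model is
attempted. Consequently, passing tests demonstrate correctness of the
*algorithms* under a known stationary linear ground truth — they do not
demonstrate that real BOLD recordings satisfy the assumptions (no
unobserved drivers, stationarity, no sub-sample dependence), and results
on real data inherit those caveats.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tau_max` | 15 samples | largest lag searched; choose where `lagged_dependence()` has decayed (`suggest_tau_max()`, threshold 0.2 on absolute correlation) |
| `alpha` | 0.01 | MCI link threshold; a model-selection regularizer, reported raw (optional FDR correction is out of scope here) |
| `pc_alpha` | = `alpha` | stage-1 screening threshold |
| `k` | 10 | CMI neighbours; bias grows with k, variance shrinks |
| `n_permutations` | 200 | permutation-null size; p-resolution 1/(B+1) |
| `sampling_interval` | 2.8 s | metadata carried through; decimation factors must be integer |
| `standardize` | TRUE | per-SD effect scale |

Degenerate inputs fail loudly by design: missing or non-numeric values,
zero-variance components, length mismatches, collinear parent designs and
unstable generator models are all errors, never silent fixes — temporal
noise and imputation artifacts are precisely what a causal analysis is
most sensitive to.

## Problem sizes and determinism

The validation suite runs at desk scale, chosen to estimate each property
with useful precision: 100 random models ($N \le 5$) for the recursion
oracle, 50 replicates of $n = 1000$ for CMI calibration, 50 replicates of
five independent AR(1) series ($n = 500$) for false-positive control
(5000 cross-link tests total), 20 replicates of a five-node network
($n = 1000$) for recovery and coefficient bias, and one full 14-region,
$T = 280$ end-to-end run. Every stochastic step flows from explicit
seeds; identical configuration, inputs and seed reproduce every exported
file byte for byte.

## Known limitations

* Causal effects are linear by definition here; the CMI machinery detects
  nonlinear *links*, but effect sizes on such links are not meaningful.
* No latent-variable search, no contemporaneous-link orientation, no
  group-level aggregation across subjects (a genuinely unsettled
  methodological question, left out rather than done badly).
* The permutation null ignores conditioning structure (global, not local,
  permutations).
* At $n_\mathrm{eff}$ of a few hundred and $\alpha = 0.01$, a 14-node
  search still performs thousands of tests; scattered false cross-links
  at roughly the nominal rate are expected and visible in the fixture
  runs.
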