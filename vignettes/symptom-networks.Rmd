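---
title: "Ising symptom networks, bridge symptoms, and simulated interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ising symptom networks, bridge symptoms, and simulated interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingbridge)
library(dplyr)
```

## The scientific question

When two questionnaire instruments measure two clusters of symptoms in the
same people — here labelled MW (a 5-item cluster) and PSVU (a 13-item
cluster) — the network view treats each symptom as a node and asks which
symptoms *bridge* the clusters: through which nodes does activation in one
cluster reach the other, and what would intervening on each symptom do to
overall severity? This package implements that pipeline for binary symptom
data: Ising network estimation, bridge centrality against the fixed
instrument partition, and computational intervention simulation.

## The model and its state convention

The joint distribution over symptom states $x \in \{0,1\}^p$ is

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} \omega_{ij} x_i x_j\Big).$$

Two conventions matter and are easy to get wrong:

* **States are $\{0,1\}$, not $\{-1,+1\}$.** The same $(\tau, \omega)$ mean
  different distributions under the two codings; the $\{0,1\}$ coding is the
  one under which nodewise logistic regression recovers the parameters
  directly, and it is what "active/inactive" means throughout this package.
* **Edges are conditional log-odds associations.** A weight $\omega_{ij}$
  is the change in the log-odds of symptom $i$ being active when $j$ is
  active, holding all other symptoms fixed. Applied papers sometimes call
  these "partial correlations"; we keep the log-odds scale and do not
  rescale.

Binarization follows the presence rule for 1–5 Likert items: the lowest
response is "not present" (0), everything above is "present" (1). The cut
point is configurable (`present_min`), but out-of-range responses are an
error, never clamped, and incomplete rows are removed at load time with a
reported count (listwise deletion; no imputation).

## Estimation: eLasso with EBIC

Each item is regressed on all remaining items with an L1 penalty along a
descending grid of 100 log-spaced $\lambda$ values down to
$10^{-3}\lambda_{\max}$ (glmnet's grid; $\lambda_{\max}$ is the smallest
penalty with an all-zero solution). Per node the penalty is selected by the
extended BIC,

$$\mathrm{EBIC}(\lambda) = -2\ell + k\log n + 2\gamma k \log(p-1),$$

with $\gamma = 0.25$ by default (the common eLasso choice; $\gamma = 0$ is
the ordinary BIC) and ties broken toward the sparser model. The two
directed coefficients per pair are averaged; the AND rule (default) keeps
an edge only when both are nonzero, the OR rule when either is, so the AND
network is always a subgraph of the OR network. Thresholds are the selected
penalized intercepts, reported without debiasing — so both weights and
thresholds inherit lasso shrinkage toward zero, which is visible in the
worked example (a planted weight of 0.8 is estimated near 0.5–0.65 at
$n = 2000$). Constant items abort with a named error rather than being
dropped silently, so descriptive tables stay aligned with the input.

## The distribution machinery

For $p \le 20$ items the package enumerates all $2^p$ states, which gives
the exact distribution (probabilities sum to 1 within $10^{-10}$ by
construction of the log-sum-exp normalization), exact i.i.d. sampling, and
sampling-free expectations (`expected_sum_score()`). Past the cap a
single-site Gibbs sampler (C++ via Rcpp) with full conditional
$P(x_j = 1 \mid x_{-j}) = \mathrm{logistic}(\tau_j + \sum_k \omega_{jk} x_k)$,
fixed ascending scan, burn-in 1000 and thinning 1 by default takes over.
Both paths are seeded through R's RNG; the test suite requires their
empirical distributions to agree within total-variation distance 0.02 at
50,000 draws on 6-item networks, where enumeration provides the oracle.

Every simulation scenario draws its own child seed from a master seed
(`derive_seeds()`), so scenarios are mutually independent but a whole run
is reproducible bit for bit.

## Bridge centrality

With the partition fixed by instrument (never detected from the data), the
four bridge indices are: bridge strength
$\sum_{j \notin c(i)} |\omega_{ij}|$; bridge expected influence, the same
sum signed (so strength $\ge$ |bridge EI|, with equality exactly when all
cross-community edges share a sign); bridge betweenness, the number of
shortest paths between cross-community node pairs passing through the node;
and bridge closeness, the inverse mean shortest-path distance to the other
community. Distances use the standard psychometric convention, edge length
$= 1/|\omega|$, with zero-weight pairs non-adjacent; when several
equal-length shortest paths tie (within a relative tolerance of $10^{-9}$)
the betweenness count is split fractionally among them, each unordered pair
counted once; a node with any unreachable out-community member gets
closeness 0. One-step expected influence $\sum_j \omega_{ij}$ is reported
alongside, and every index also in z-standardized form (a constant column
standardizes to zero rather than NaN). The implementation computes
distances with igraph and path counts by predecessor accumulation; the test
suite checks all indices exactly against a brute-force simple-path
enumeration oracle on 50 random networks.

Stability uses the case-dropping bootstrap: drop a proportion $q$ of
persons, re-estimate the entire network on the subsample (the expensive but
faithful choice), recompute the index, and correlate (Spearman) with the
full-sample index. The CS coefficient is the largest $q$ such that at every
proportion up to $q$ at least 95% of successful replicates correlate
$\ge 0.7$; the "every proportion up to $q$" clause means an isolated pass
beyond a failing proportion does not count. Replicates with failed
estimation or undefined correlations are recorded, counted and excluded.
Defaults are a 0.05–0.75 grid in steps of 0.05 with $B = 500$ replicates;
the bundled acceptance run uses a coarser grid with $B = 50$ to stay
desk-scale. On the default synthetic network the CS of the bridge indices
is volatile across seeds: with only three true bridge edges, bridge EI is
zero for 13 of 18 nodes, and tie-heavy rank correlations sit near the 0.7
rule boundary. That is a property of the sparse planted truth, not of the
estimator; empirical symptom networks typically have many more
cross-community edges.

## Intervention simulation

An intervention on symptom $t$ shifts its threshold by
$\pm m \cdot \mathrm{sd}(\tau)$ ($m = 2$ by default): down for an
*alleviating* intervention, up for an *aggravating* one, all other
parameters untouched. The SD referent is the sample SD of the whole
threshold vector; because the perturbation itself changes that SD, chained
perturbations accept an explicit `sd_reference` (and with the base SD held
fixed, aggravate-then-alleviate is an exact inverse). $n_{\mathrm{sim}} =
5000$ observations are drawn per scenario, sum scores computed, and each
scenario compared to one shared baseline simulation by a two-sided Welch
t-test, with BH-FDR correction across candidates within each direction and
ranking by absolute mean difference. If both arms are constant the t
statistic is undefined and reported as NA with $p = 1$. Both the CI of the
mean difference (the reported `conf_low`/`conf_high`) and the baseline and
perturbed means are returned, so either re-centring can be plotted.

The outcome sum score defaults to **all** items — the "overall state of the
network" reading, which is also what makes the intervened symptom's own
activation change count. A subset outcome (e.g. only the PSVU items when
intervening on MW items, to isolate cross-community spill-over) is equally
supported; note that subset effects are roughly an order of magnitude
smaller (the dominant bridge intervention in the default synthetic network
moves the 13-item outcome sum by about 0.1 symptoms versus 0.4–0.5 for the
full sum), so they need far more than 5000 draws to resolve reliably.

On *attractive* networks (all $\omega \ge 0$) the direction of every effect
is provable without sampling: alleviating any node strictly lowers and
aggravating strictly raises the exact expected sum score. The test suite
checks this node by node via enumeration, which also pins down the expected
sign and rough magnitude before any Monte-Carlo comparison is trusted.

## The synthetic ground truth

The generator emulates the study design the pipeline targets: 18 items in
communities of 5 (MW-like) and 13 (PSVU-like); within-community pairs get
an edge independently with probability 0.3 and weight Uniform(0.3, 0.9);
exactly three cross-community bridges are planted — a dominant one at 0.8
(the MW5–PSVU8 analog) and two minor ones at 0.4 and 0.35; thresholds are
Uniform(−2, 0), negative-leaning so endorsements stay in a realistic band;
the default sample size is 1989. The within-community density of 0.3 is
the one generator parameter no design source fixes; it was chosen as a
realistic sparse-ish symptom network that keeps mean degree near 4 and
endorsement rates away from the boundaries. All weights are positive, so
the exact monotonicity property above holds and the network is unimodal
enough for both samplers.

The Likert expansion is a deliberate *right inverse* of binarization:
absent symptoms become response 1, present symptoms draw a severity from
{2,…,5} (uniform by default). Severity is synthetic noise by design —
the pipeline discards it again — so `binarize(expand(b)) = b` exactly, and
no attempt is made to match any particular study's Likert means or SDs.

What passing on this generator does and does not show: recovery and
target-identification results demonstrate internal validity of the whole
chain (generate → binarize → estimate → centrality → intervene) under a
correctly specified model with independent observations. Real
questionnaire data bring ordinal information loss, local dependence,
unmodelled covariates, and cluster structure that the generator does not
emulate, so field performance claims need their own validation.

## Numerical choices and limitations

* Enumeration cap 20 items ($2^{20} \approx 10^6$ states); the 18-item
  design fits exact sampling.
* Problem sizes in the tests and the acceptance run: recovery and
  target-recovery experiments use 20 data seeds at $n = 2000$ and 5000
  draws per scenario; sampler-fidelity checks use 10 six-item networks at
  50,000 draws; the oracle comparison uses 50 networks of up to 10 nodes.
* At $n = 2000$ the union-support correlation between true and estimated
  weights plateaus around 0.85: with true weights confined to
  [0.3, 0.9] the between-edge spread (SD ≈ 0.17) is not much larger than
  the per-edge estimation noise plus node-wise shrinkage heterogeneity.
  It rises to ≈ 0.99 at $n = 20000$, confirming consistency rather than an
  estimator defect.
* Network files serialize reals as `%.17g` strings inside JSON so that
  save → load is bit-exact; plain JSON number formatting is not.
* Not in scope: Gaussian/mixed graphical models for ordinal data,
  edge-weight (rather than threshold) perturbations, sequential or
  combined interventions, community detection, and edge-difference
  bootstrap tests.
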