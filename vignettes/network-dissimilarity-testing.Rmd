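---
title: "Dissimilarity-based hypothesis tests for labelled networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissimilarity-based hypothesis tests for labelled networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdiss)
```

## The problem

Biological networks — co-expression, partial-correlation, regulatory —
are estimated from noisy samples, and the natural scientific questions
about them are comparative: does the network estimated from patient data
differ from a gold-standard pathway (one-sample), or do two conditions
induce different networks (two-sample)? Networks rarely admit concise
parametric summaries, so `netdiss` treats the network itself as the
observation and bases inference on a dissimilarity statistic combined
with resampling.

Both networks must be *aligned*: defined over the same labelled node set
(genes, proteins, metabolites), with rows and columns in a common order.
`align_networks()` performs the ordering and refuses label sets that do
not match; unlabeled graph matching is out of scope.

## The statistic

For an observed weight matrix $W^O$ and target $W^T$ over $n$ common
nodes (zero means "no edge", loops are excluded), the base dissimilarity
at node $i$ is

$$d_i = \sum_{j \ne i} \left| I(w^O_{ij} \ne 0) - I(w^T_{ij} \ne 0) \right|
      + \left| w^O_{ij} - w^T_{ij} \right|,$$

an L1 difference of edge indicators plus an L1 difference of weights.
Because interactions in a network are meaningful only jointly with their
neighbourhood, the statistic optionally adds, for each first neighbour
$j$ of $i$, the same quantity evaluated at $j$ with the centre excluded,

$$d^{*}_{ij} = \sum_{k \ne i,j} \left| I(w^O_{jk} \ne 0) - I(w^T_{jk} \ne 0) \right|
      + \left| w^O_{jk} - w^T_{jk} \right|,$$

weighted by $c_{ij}$, giving

$$D = \sum_i \Big( d_i + \sum_{j \in \Gamma(i)} c_{ij}\, d^{*}_{ij} \Big).$$

Every edge is counted from both endpoints; the double counting is
deliberate and consistent, and avoids single-count partitioning schemes.
Nodes of high degree consequently contribute more, in the spirit of a
"large degrees of freedom" comparison. For binary graphs with
$c_{ij} = 0$, $D$ collapses to four times the Hamming distance between
edge sets (each differing dyad counted at both endpoints and in both
components), which the test suite verifies against an exhaustive
symmetric-difference oracle on all graph pairs up to order 4.

### Tunable pieces, defaults, and why

* **Components** (`edge`, `weight` in `dissim_config()`): both on by
  default. For (partial) correlation networks, where the existence of an
  edge is itself defined by a thresholded weight, the edge indicator is
  redundant and the analyses here use the weight component only
  (`edge = FALSE`).
* **Neighbour rule** (`neighbour`): `"none"` by default.
  `"constant"` uses a researcher-chosen $c \ge 0$ for every neighbour
  and is the natural choice for unweighted graphs. `"weighted"` uses the
  signed rule $c_{ij} = w^O_{ij}\, I(w^T_{ij} \ne 0)$ — the observed
  weight, gated by edge presence in the target — which is motivated by
  conditional-dependence weighting: the state of an adjacent edge should
  influence a node's comparison in proportion (and direction) of its
  association. Because correlation-type weights can be negative, a
  magnitude variant `"weighted_abs"` ($c_{ij} = |w^O_{ij}|\,I(\cdot)$)
  is provided; it keeps $D$ monotone in edge discordance at the price of
  discarding the sign information. We kept the signed rule as the
  default weighted mode: in the two-sample studies below it decorrelates
  the neighbour-inclusive statistic from the neighbour-free one (the
  behaviour a practitioner should expect when the two settings are
  reported side by side) with power comparable to the magnitude variant
  in our studies.
* **Neighbour set**: $j$ ranges over the union
  $\Gamma_O(i) \cup \Gamma_T(i)$. Under the weighted rules non-shared
  edges receive zero weight automatically, so the union is the only
  choice that also gives the constant-$c$ case a well-defined domain.
  Only first neighbours are supported; `dissim_config(radius = ...)`
  rejects anything beyond path length 2. The statistic extends
  conceptually to larger radii, but each extra step multiplies the
  estimation noise folded into $D$ and we have not studied it.
* **Orientation**: under the weighted rules $D$ is *not* symmetric in
  $(O, T)$. The first argument is always the observed network; in
  two-sample tests group 1 plays that role, and permutation replicates
  preserve the orientation. No silent symmetrization is performed.
* **Zero tolerance** (`zero_tol`, default 0): the indicator is
  $|w| > \texttt{zero\_tol}$, so networks produced by floating-point
  thresholding behave deterministically.

### Node decomposition

$D$ is a sum of per-node contributions, so the portion attributable to
a node or subgraph is well defined (`node_decomposition()`); contributions
sum to $D$ to within $10^{-9}$ by construction and test. This supports
post-hoc localization of a significant global difference. Note that
under the signed weighted rule individual contributions can be negative.

## Inference

The tests follow the classical resampling recipe: state the hypotheses,
compute $D$, generate its null distribution by resampling, reject for
large $D$ (one-sided — a larger $D$ means a larger departure from the
target or between groups).

* **One-sample, null model known** (`one_sample_test_model()`): B
  networks are drawn from the null generative model and each is compared
  to the *same fixed target realization*; the observed $D$ is referred
  to that distribution. Drawing the target once per experiment, rather
  than re-drawing it per resample, matches the "compare an estimate to a
  gold standard" framing and gives the one-sided test its power: if the
  observed model is denser than the null, $D$ against any fixed target
  rises in expectation.
* **One-sample, null represented by historical data**
  (`one_sample_test_bootstrap()`): null replicates are bootstrap
  resamples (rows with replacement) of an a-priori sample, re-estimated
  into networks. This is a pragmatic substitute for an explicit null
  model; it attains its nominal size only when the a-priori sample is
  much larger than the observed one (a factor of about 10 at $n = 200$
  in our studies) and is reported, not certified, at other settings.
* **Two-sample** (`two_sample_permutation_test()`): under the null of
  network equality the pooled sampling units are exchangeable, so each
  replicate randomly partitions the pooled rows into the original group
  sizes (every row used exactly once — a partition, not a bootstrap) and
  recomputes $D$. Monte-Carlo permutations are used throughout; full
  enumeration is pointless at the sample sizes where network estimation
  is feasible.

P-values use the add-one convention $p = (1 + \#\{D_b \ge D_{obs}\}) /
(B + 1)$: $p$ is never zero and ties count as extreme, which is
conservative for the discrete null distributions binary graphs produce.
The studies below use $B = 1000$ resamples; the type-I behaviour of the
one-sample binary test is visibly conservative (rejection rates at
$\alpha = 0.05$ typically between 0 and 0.03) precisely because of tie
handling in a lattice-valued statistic, an effect the user should expect
with unweighted graphs.

Estimation failures inside resampling loops (a catchable condition class
raised by the estimators) trigger a redraw of that replicate, up to 100
times, with the redraw count recorded on the result.

## Network models and the synthetic study populations

The package ships the generators used to characterize the test. They
define the reference study conditions and are not tuning knobs.

* **Erdős–Rényi** `sample_er(n, p)`: order 25 and $p_0 = 0.20$ in the
  reference study; the alternative uses $p = 0.25$; constant neighbour
  weight $c \in \{0, e^{-2}\}$; 100 experiments of $B = 1000$ resamples.
* **Block-diagonal correlation populations**
  `sample_block_correlation()`: 6 diagonal blocks of 5 variables
  (dimension 30), every within-block entry at least 0.2 in magnitude,
  exact zeros elsewhere. Each block is drawn by giving the 5 variables a
  path-shaped conditional-dependence structure with partial correlations
  of magnitude 0.5–0.65 and random signs, then rejecting draws that are
  not positive definite or violate the 0.2 marginal floor. Two
  considerations fix this choice. First, a magnitude floor on all
  marginal correlations says nothing about conditional structure:
  blocks built from single-factor structures satisfy it while their
  partial correlations stay below $1/3$, so a partial-correlation
  network at cutoff 0.5 would be empty and every test degenerate.
  Second, with block partial correlations straddling the 0.5 cutoff, the
  estimated networks retain connected chains inside blocks with
  realistic estimation noise — edges near the selection boundary come
  and go across resamples, which is exactly the regime a practitioner
  faces. Five-variable path blocks cannot carry interior partial
  correlations much above 0.58 (a positive-definiteness constraint), so
  the 0.5–0.65 magnitude window spans most of the feasible strong-
  dependence range rather than being a free parameter.
* **Multivariate normal sampling** `sample_mvn()`: rows i.i.d.
  $N(0, \Omega)$; both groups use $n_1 = n_2 = 200$ in the reference
  two-sample study.
* **Correlation networks** `correlation_network(X, rho)`: Pearson
  correlations thresholded at $\rho = 0.2$, the same threshold that
  defines the generating population.
* **Shrinkage partial-correlation (GGM) networks** `ggm_network()`:
  the empirical correlation matrix is linearly shrunk toward the
  identity with the analytic intensity
  $\lambda^* = \sum_{i<j}\widehat{\mathrm{Var}}(r_{ij}) / \sum_{i<j} r_{ij}^2$
  (clipped to $[0,1]$, overridable for testing), converted to partial
  correlations $\pi_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$
  from the inverse, and thresholded at $|\pi| \ge 0.5$. The cutoff is a
  literal magnitude threshold on the shrunken partial correlation; some
  GGM software attaches posterior-probability semantics to a parameter
  of the same value, and that interpretation (which would yield denser
  networks at 0.5) is deliberately not implemented. A singular
  correlation matrix can be inverted with a flagged pseudo-inverse;
  non-finite estimates raise a catchable estimation error so simulation
  drivers can redraw.
* **Alternative hypothesis** `perturb_blocks()`: at least 10% of the
  blocks (minimum one; exactly one at the 6-block default) are redrawn
  wholesale from the block sampler. The effect size is therefore the
  natural variability between independent block draws, not a controlled
  shift.

### What the generators do and do not emulate

The populations mimic sparse modular dependence with strong within-module
association — the qualitative structure of pathway-level co-expression —
under exact multivariate normality, independent sampling units, equal
group sizes and homogeneous blocks. Real expression data adds heavy
tails, batch structure, unequal library quality and correlated sampling,
none of which is represented. Passing the simulation studies therefore
certifies the inferential machinery (size under exchangeability, power
against block rewiring), not robustness to real-data pathologies; for
real data the permutation test's validity rests on the exchangeability
of sampling units under the null, which the user must judge.

## Reference simulation studies

`run_er_experiment()`, `run_onesample_corr_experiment()` and
`run_twosample_ggm_experiment()` repeat the corresponding test over
independently regenerated populations (100 experiments of $B = 1000$
resamples at the reference settings) and return the per-experiment
p-values with rejection rates at $\alpha \in \{0.01, 0.05, 0.10\}$.
The two-sample driver evaluates the neighbour-inclusive
($c_{ij} = \hat\pi^O_{ij}$ gated on the target) and neighbour-free
settings on identical data and identical permutation streams, so the two
p-values of an experiment are directly comparable; the Erdős–Rényi
driver consumes the same random stream for any constant $c$, so runs at
matched seeds are likewise paired.

At these settings, on this package, the one-sample binary study rejects
a true null well below the nominal 5% (the conservatism discussed
above), rejects the $p = 0.25$ alternative in roughly a third of
experiments without neighbour information, and noticeably more often
with $c = e^{-2}$; the two-sample GGM study holds its size under the
null and rejects the one-redrawn-block alternative in roughly a quarter
to two-fifths of experiments. `scripts/acceptance.R` recomputes all of
these numbers from scratch; the vignette intentionally states no figure
that script does not produce.

Runtime is dominated by re-estimating GGM networks inside permutation
loops (about 200 thousand estimations for a full two-sample study —
a few minutes on one core). The test suite runs the two-sample power
study at 50 experiments and 500 permutations, which halves both axes of
the Monte-Carlo error budget and keeps the suite fast; the acceptance
script always runs the full reference scale.

## Numerical and degenerate-input policy

* Symmetry of input matrices is enforced at construction with tolerance
  $10^{-10}$ and the stored matrix is exactly symmetrized; diagonals are
  zeroed (no loops).
* The indicator tolerance is exact zero by default; thresholded
  estimators produce exact zeros, so no epsilon is needed there.
* Identical observed and target networks give $D = 0$ and $p = 1$
  exactly, for every configuration.
* Block rejection sampling aborts with the acceptance rate in the error
  message after 10,000 failed draws rather than looping forever.
* Zero-variance columns are rejected by every estimator with the column
  named; missing values are rejected at I/O time with the cell named.
* Ties in the permutation null count against rejection (add-one,
  $\ge$ comparison), the conservative direction.

## Known limitations

* Directed and bipartite networks are not implemented; the statistic's
  definition extends to them but nothing here is tested for that case.
* Neighbourhood radius is fixed at first neighbours.
* The bootstrap one-sample test's size depends strongly on the a-priori
  sample size; treat p-values from small a-priori samples as indicative
  only.
* The signed weighted neighbour rule sacrifices the guarantee that
  flipping a concordant edge cannot decrease $D$ (that guarantee holds
  for the constant rule and is property-tested there).
* Large dense networks make permutation testing expensive since every
  replicate re-estimates two networks; the implementation is vectorized
  but single-threaded.
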