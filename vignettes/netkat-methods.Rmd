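---
title: "Pathway-integrated kernel association testing: model, regularization, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-integrated kernel association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkat)
```

## The problem

High-throughput molecular profiling (metabolomics, proteomics,
transcriptomics) measures hundreds of features whose biological
relationships are partially documented in pathway databases.  Testing each
pathway as a *set* of features against a phenotype is more powerful and more
interpretable than feature-by-feature testing, and kernel machine regression
is the standard set-testing framework.  But pathway graphs assembled from
databases are incomplete: many measured features sit in sparse or fully
disconnected pathway fragments, and treating the members as exchangeable
throws away the connectivity that is known.

`netkat` tests each pathway with a variance-component kernel score test in
which the topology of the pathway graph is injected into the kernel through
a *regularized normalized Laplacian*.  The package also implements the
pathway-free and plain-Laplacian variants of the same test, two standard
competitors, and a full Monte Carlo framework for studying how the test
behaves when the pathway information handed to it is wrong or incomplete.

## The model

For $n$ samples let $Y$ be a continuous phenotype, $X$ an $n \times q$
covariate matrix (with intercept), and $Z$ an $n \times p$ feature matrix
whose columns align with the $p$ nodes of a pathway graph $G$.  The
semiparametric model is

$$Y = X\beta + h(Z \tilde L_R) + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2 I),$$

where $h$ lives in the reproducing-kernel space of a positive semidefinite
kernel.  Treating $h$ as a random effect with covariance proportional to the
kernel matrix $K$, the null hypothesis of no pathway effect is a
variance-component test whose score statistic

$$Q = \frac{(Y - X\hat\beta)^\top K (Y - X\hat\beta)}{\hat\sigma^2}$$

needs only the covariates-only least-squares fit ([`fit_null()`]) — the
kernel effect is never estimated.

### Small-sample p-values

Plugging $\hat\sigma^2$ into $Q$ is unstable at moderate $n$.  The package
instead conditions the variance estimate out through the scale-free ratio
$s = r^\top K r / r^\top r$, where $r$ are the null residuals.  Writing
$P_0$ for the residual projection and $\lambda_1,\dots,\lambda_m$
($m = n-q$) for the residual-space eigenvalues of $P_0 K P_0$, the exact
finite-sample null gives

$$\Pr(s^{*} \ge s_{\mathrm{obs}})
  = \Pr\Big(\sum_{i=1}^{m} (\lambda_i - s_{\mathrm{obs}})\,\xi_i > 0\Big),
  \qquad \xi_i \overset{iid}{\sim} \chi^2_1 .$$

This mixed-sign weighted chi-square tail is evaluated by numerical
inversion of the characteristic function (the Gil–Pelaez/Davies integral,
`weighted_chisq_tail()`).  The test suite validates this form against a
$2 \times 10^5$-draw parametric bootstrap of the ratio statistic on several
fixed small-$n$ instances; the bootstrap oracle, not any asymptotic
argument, is the arbiter of the reconstruction.

Numerical details that matter:

* equal nonzero weights reduce exactly to a scaled chi-square and are
  special-cased (the inversion integral converges slowly there);
* the integral is accepted when the quadrature's absolute-error estimate is
  below $10^{-4}$ and the probability lies in $[0,1]$; otherwise a
  Liu-type moment-matching approximation is used and the result flagged
  with `davies_converged = FALSE`;
* eigenvalues of $P_0 K P_0$ below $10^{-8}\lambda_{\max}$ are truncated to
  zero and all $m$ are retained — zero eigenvalues still carry the
  $-s_{\mathrm{obs}}$ weight;
* a kernel proportional to the identity on the residual space has all
  centered weights zero; it carries no contrast, and the test returns
  $p = 1$ with a warning rather than a spurious number;
* an outcome fit exactly by the covariates ($\hat\sigma^2 < 10^{-12}$) is a
  degenerate input and raises an error.

## Graph regularization

For an undirected, unweighted pathway graph with adjacency $A$ and degree
matrix $D$, the normalized Laplacian is
$\tilde L = I - D^{-1/2} A D^{-1/2}$, symmetric positive semidefinite with
spectrum in $[0, 2]$; the multiplicity of eigenvalue $0$ equals the number
of connected components.  The package follows the convention that a
degree-zero node contributes a zero row and column (not a $1$ on the
diagonal).  This choice is load-bearing: each isolated node then adds a zero
eigenvalue, and the regularizer below acts as the identity on it, so an
entirely edgeless pathway makes the pathway-integrated test *exactly* equal
to the pathway-free test — a property the test suite asserts to $10^{-10}$.

The regularizer is the linear filter

$$\tilde L_R = (I + \tau \tilde L)^{-1},$$

whose eigenvalues $1/(1+\tau\lambda_i)$ decay monotonically in $\lambda_i$:
high-frequency (noisy) graph components are shrunk toward zero while smooth,
low-frequency structure — the part assumed to carry biological signal — is
kept near weight 1.  $\tau \ge 0$ controls the amount of smoothing
(dimensionless; $\tau = 0$ disables the topology; the package default is
$\tau = 1$ everywhere, matching the calibration used throughout the
simulation study).  The inverse is computed by a symmetric Cholesky solve
and re-symmetrized by averaging with its transpose.  A diffusion-type filter
$e^{-\tau \tilde L / 2}$ would serve the same purpose but is deliberately
out of scope.

Features enter the kernel as the projected matrix $Z \tilde L_R$: each
feature is replaced by a proximity-weighted blend of its pathway
neighbours ("guilt by association"), and disconnected features are left
untouched.

## Kernel and bandwidth

Only the Gaussian kernel
$K_{ij} = \exp\{-\lVert z_i - z_j\rVert^2/\rho\}$ is used for calibrated
inference (linear and polynomial kernels are available behind the same
interface).  The bandwidth follows the median heuristic, and the package
exposes the two conventions in circulation:

* `median_dist` (default): $\rho$ = median pairwise Euclidean *distance*;
* `median_sqdist`: $\rho$ = median pairwise *squared* distance.

The distinction is not cosmetic.  With `median_dist` the exponent at the
median pair is $-d_{\mathrm{med}}$, so for raw high-dimensional features
(where $d_{\mathrm{med}} \approx \sqrt{2p}$) the kernel is extremely local
and the pathway-free test loses power, while for the Laplacian-projected
features (much smaller $d_{\mathrm{med}}$) the kernel stays informative.
With `median_sqdist` the exponent at the median pair is $-1$ regardless of
scale.  The bandwidth is always computed on the matrix that actually enters
the kernel — the projected features for the topology-aware modes — since
that is the object whose geometry the kernel measures.  Type I error is
nominal under both conventions; power, and any power comparison *between*
modes, depends on the convention, which is why it is a documented argument
rather than a hidden constant.

## Competitor tests

* `pc_f_test()` — F-test of all principal components of the column-centered
  $Z$ added to the null model.  Because the PCs span the full column space,
  the p-value is invariant to any invertible linear transform of $Z$; in
  particular it cannot see the Laplacian projection at all (asserted to
  $10^{-10}$ in the tests).
* `univariate_simes()` — covariate-adjusted per-feature regressions
  combined by Simes' rule $\min_i\{p\,p_{(i)}/i\}$.  Per-feature tests are
  adjusted for $X$ because the simulated outcome depends on the covariates;
  unadjusted tests would be misspecified.

## The simulation framework

`run_scenario()` implements a five-step generative pipeline per replicate:

1. **Graph.** A Barabási–Albert preferential-attachment graph with one edge
   per new node ($m=1$), i.e. a scale-free tree with $p-1$ edges.  At
   $p = 15, 30, 45$ this gives edge densities $0.133, 0.069, 0.044$,
   matching the sparsity of curated metabolic pathways.
2. **Precision matrix.** Edges become unit entries; each row's off-diagonal
   block is scaled by $1/(1.5 \times \text{row sum})$; the matrix is
   symmetrized by averaging and given a unit diagonal.  Each row is
   diagonally dominant before averaging, but averaging can break dominance
   at hubs whose neighbours are leaves, so when the smallest eigenvalue
   falls below $0.01$ the whole off-diagonal block is shrunk uniformly to
   floor it at $0.01$.  The shrinkage preserves the zero pattern (about 3%
   of 15-node trees need it) and the positive-definiteness invariant is
   asserted over the sampled graph distribution.
3. **Features.** $Z \sim MVN(0, \Omega^{-1})$, $n = 160$ by default, so
   conditional independence matches the non-edges exactly.
4. **Outcome.** $Y_i = 0.26 + 0.5X_{1i} + 0.25X_{2i} + \sum_j \beta_j Z_{ij}
   + \varepsilon_i$ with $X_1 \sim \text{Bernoulli}(0.5)$,
   $X_2 \sim U(0,1)$, $\varepsilon \sim N(0, 1.3688^2)$ (residual scale
   calibrated to observed metabolomics data; the binary/uniform covariate
   shapes are symmetric defaults).  $\beta_j = 0$ for type I error,
   $\beta_j = 0.1$ for the reference alternative.
5. **Corruption, then testing.** The graph handed to the test — never the
   data — is degraded by a *knowledge* scenario (5% or 15% of absent edges
   added to the generating graph while the test sees the sparse one;
   or weakly connected nodes dropped along with their feature columns)
   crossed with a *structure* scenario (each edge rewired with probability
   0.1/0.4/0.7; an edge-disjoint replacement tree; or no graph at all).

Design choices worth recording:

* **Node dropping.**  "Weakly connected" means degree at or below the
  linear-interpolation 25th percentile of the degree sequence, excluding
  nodes of maximal degree; each such node is dropped with probability 0.25.
  A strict "below the percentile" rule would be vacuous on scale-free
  trees, where the percentile equals the leaf degree and nothing lies
  strictly under it; the tie-inclusive rule targets the leaves while
  leaving regular graphs (no node more connected than another) untouched.
* **Rewiring.**  A selected edge $\{u,v\}$ becomes $\{u,w\}$ with $w$
  uniform over nodes forming neither a current edge nor an edge of the
  original graph; edge count is preserved and at probability 1 the result
  shares no edge with the input.  Rewiring a tree edge almost always
  disconnects a subtree, so partially rewired graphs are substantially more
  fragmented than the edge-disjoint replacement tree; since Laplacian
  pooling over a connected graph is itself a large share of the power when
  every feature carries signal, heavily rewired graphs can test *worse*
  than a fully wrong but nearly connected one.  The simulation machinery
  reports this honestly rather than forcing a monotone ordering.
* **Replication.**  1000 replicates per scenario cell (500 per grid point
  in the power sweep), with per-replicate seeds drawn once from the master
  seed so cells are reproducible and order-independent.  These sizes put
  every Monte Carlo standard error near $0.007$ on a rejection rate of
  0.05 and keep a full scenario cell around 20 seconds on one CPU.
* **Signal-to-noise ratio.**  `signal_to_noise()` uses
  $\beta^\top \Omega^{-1} \beta$ over
  $\mathrm{Var}(0.5X_1 + 0.25X_2 + \varepsilon)
  = 0.0625 + 0.0625/12 + \sigma^2$; a $\sigma^2$-only denominator is
  available as a switch.  `power_snr_sweep()` sweeps a global multiplier on
  $\beta = 0.1$, shares the graph and features across the grid within a
  replicate, and `snr_at_power()` linearly interpolates the first crossing
  of a target power.

### What the generator does and does not emulate

The generator reproduces the *dependence* structure of pathway data —
features correlated through a sparse conditional-independence graph, a
dense linear signal, realistic pathway sparsity — under Gaussian
assumptions throughout.  It does not emulate heavy-tailed or skewed
abundance distributions, missingness/imputation artefacts, batch or
run-day effects, measurement error in the outcome, or nonlinear
feature–phenotype relationships.  Passing tests therefore demonstrate
calibration and relative power under corrupted *pathway knowledge*, not
robustness to distributional violations in real data: on real abundances
the package expects upstream log-transformation, normalization and
imputation to have been done.

## Known limitations

* Continuous outcomes only; the logistic branch of the kernel machine model
  is intentionally not implemented and raises a clear error path upstream
  (binary phenotypes would need a different null model and score variance).
* Calibration work covers the Gaussian kernel; the linear and polynomial
  kernels are provided but not studied.
* Graphs are undirected and unweighted; reaction stoichiometry or edge
  confidence weights are ignored.
* Raw p-values are reported per pathway (with optional Benjamini–Hochberg
  adjustment); the test is a global null per pathway, so a rejection means
  *some* member covaries with the phenotype.

## A worked run

```{r example}
sim <- demo_pathway_data(n = 60, p = 8, beta_effect = 0.15, seed = 42)
fit <- kat_test(sim$features, sim$covariates, "y", sim$pathways,
                mode = "pairkat", tau = 1)
tidy(fit)
glance(fit)
```

A small null scenario (sizes chosen to keep the vignette light):

```{r scenario}
sim0 <- run_scenario(sim_config(p = 10, n = 60, reps = 20, seed = 7),
                     methods = c("pairkat", "none"))
tidy(sim0)[, 1:4]
```

The full-scale study conditions ($n = 160$, $p \in \{15, 30, 45\}$, 1000
replicates, $\tau = 1$, $\alpha = 0.05$) are exercised by the acceptance
script (`scripts/acceptance.R`) and the acceptance test file, which
recompute every headline rejection rate and both 80%-power SNR crossings
from scratch.
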