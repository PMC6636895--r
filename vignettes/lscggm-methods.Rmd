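---
title: "Latent sparse conditional Gaussian graphical models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent sparse conditional Gaussian graphical models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lscggm)
```

## The model

We observe `n` i.i.d. samples of a zero-mean random vector split into an
input block `Y_Z` (m variables, e.g. genotypes) and an output block `Y_X`
(p variables, e.g. metabolite levels). The working assumption is a Gaussian
conditional random field over the outputs *and* a set of `h` unobserved
variables `Y_H`: conditional on `Y_Z`, the vector `(Y_X, Y_H)` is
multivariate normal with a mean linear in `Y_Z` and a joint conditional
precision matrix partitioned into blocks `M_X` (p x p), `M_XH` (p x h) and
`M_H` (h x h). Nothing is assumed about the distribution of the inputs
themselves.

Marginalizing the unobserved block by partitioned inversion gives

    Y_X | Y_Z  ~  N( -(S_X - L_X)^{-1} (S_ZX - L_ZX)' Y_Z ,  (S_X - L_X)^{-1} )

with `S_X = M_X`, `L_X = M_XH M_H^{-1} M_XH'`, `S_ZX` the direct input
effects and `L_ZX` the input effects routed through the latent block. The
scientifically interesting object is `S_X`: its off-diagonal zeros are
exactly the conditional independencies among the outputs given everything
else, including the latent variables. The data, however, only identify the
differences `S_X - L_X` and `S_ZX - L_ZX`; the decomposition into a sparse
direct part and a low-rank latent part is recovered by penalization:

    minimize  -loglik(S - L) + lambda * ( gamma * ||S||_1 + (1 - gamma) * ||L||_* )
    subject to  S_X - L_X > 0 (positive definite),  L_X >= 0 (PSD),

where `S = rbind(S_X, S_ZX)` and `L = rbind(L_X, L_ZX)` are the stacked
(p+m) x p views. The log-likelihood depends on the data only through the
1/n-scaled second-moment matrices (`suff_stats()`), and the whole problem
is jointly convex. This identification through sparsity-versus-rank
incoherence is the same mechanism as in low-rank plus sparse precision
decompositions; the conditional formulation additionally regresses out the
inputs, which both removes their confounding influence on the output graph
and avoids placing any distributional assumption on them.

`log_likelihood()`, `crf_gradient()`, `conditional_distribution()` and
`objective_value()` expose these pieces directly; all are unit-tested
against independent oracles (per-sample Gaussian densities, central finite
differences, partitioned-inverse marginalization, full SVDs).

### Penalty conventions

Two parameterizations of the combined penalty circulate; this package uses
the bounded one, `lambda * (gamma ||S||_1 + (1 - gamma) ||L||_*)` with
`gamma` in (0, 1), everywhere. `penalty_to_unbounded()` converts to the
`lambda2 * (gamma2 ||S||_1 + ||L||_*)` form. The l1 norm covers *all*
entries of `S`, diagonal of `S_X` included, following the objective as
printed; `penalize_diagonal = FALSE` exempts the diagonal for users who
prefer the graphical-lasso convention. Data are assumed zero-mean and are
not centered by default (the simulator generates zero-mean data); pass
`center = TRUE` / `standardize = TRUE` for real data, or use
`quantile_normalize()` per column.

## Solvers

### ADMM

`fit_admm()` minimizes the objective by a two-block ADMM on the consensus
constraint `R = S - L`:

1. **Likelihood block.** `R` solves `min -loglik(R) + (rho/2)||R - A||^2`.
   The conditional likelihood couples `R_X` and `R_ZX` through `R_X^{-1}`,
   so there is no single closed form; the update alternates two
   eigendecomposition-based exact half-steps — a Sylvester-diagonalized
   solve in `R_ZX` (using the eigenbases of `Sigma_Z` and `R_X`) and a
   log-det prox in `R_X` with the Schur-type term
   `R_X^{-1} R_ZX' Sigma_Z R_ZX R_X^{-1}` frozen at the previous inner
   iterate — until the subproblem gradient stabilizes (at most
   `inner_sweeps` passes). With `m = 0` one step is exact.
2. **Penalty block.** `(S, L)` jointly solve the prox of
   `gamma l1 + (1-gamma) nuclear + PSD-cone` around `R + U`; the quadratic
   couples the two matrices, so block-coordinate passes alternate
   soft-thresholding of `S` with the constrained nuclear prox of `L` until
   the pair stabilizes. Keeping this subproblem a *joint* minimization is
   what makes the scheme a genuine two-block ADMM; updating `S` and `L`
   once each per outer iteration (a three-block scheme) was observed to
   diverge on some instances during development, consistent with the known
   counterexamples for multi-block ADMM.
3. Scaled dual update with residual balancing of `rho` (factor 2 whenever
   primal and dual residuals differ by 10x, frozen after iteration 200).

The constrained nuclear prox — the one subproblem with no closed form —
minimizes `0.5||L - M||^2 + t ||L||_*` subject to a symmetric PSD top
block. `prox_stacked_nuclear_psd()` solves it with Dykstra's algorithm
alternating singular-value shrinkage with the cone projection, including
the correction terms that make the limit the exact constrained proximal
point rather than a mere alternating projection. In practice it converges
in a handful of iterations (typically under 10 at the default tolerances;
the solver logs the counts). Subproblem accuracy follows the outer
progress: the inner tolerance tracks two orders of magnitude below the
current relative primal residual, floored at 1e-10, so early iterations
are cheap and the final iterations are solved essentially exactly.

Defaults: `rho = 1`, relative primal/dual tolerances `1e-5`, `max_iter =
1000`, strict-feasibility floor `1e-8` applied in the likelihood block
(the log-det barrier keeps iterates in the interior; the floor only guards
the returned `S_X - L_X`). Initialization is `S_X = I`, everything else 0,
unless warm-started from a neighboring penalty configuration — paths are
fitted warm along decreasing `lambda`.

### The SDP form and the bundled oracle

The same problem admits an exact semidefinite reformulation in which every
nonsmooth term becomes linear: a PSD-constrained block
`K = [[W, S_ZX - L_ZX], [., S_X - L_X]]` whose free corner `W` tightens to
the Schur complement and reproduces the likelihood's quartic term; an
elementwise dominator `F >= |S|` for the l1 norm; and the epigraph pair
`(H1, H2)` with `[[H1, L], [L', H2]]` PSD for the nuclear norm, whose
optimal value satisfies `0.5 (tr H1 + tr H2) = ||L||_*` (at `L = diag(3,
1)` this evaluates to 4, which pins the 1/2 scaling). `build_sdp()` emits
the problem description and `sdp_to_json()` serializes it so any conic
solver can be attached. The log-det term applies to the precision block
`S_X - L_X` of `K`; this is forced by the requirement that the
reformulation be equivalent to the original objective (a reading with
`logdet(S_X)` alone would change the optimum), and the equivalence is
verified numerically in the tests.

`solve_sdp()`'s bundled back-end does not bundle an interior-point code;
it solves the equivalent composite problem by FISTA with backtracking and
adaptive restart, run to a tight tolerance, and then reconstructs the full
SDP variable assignment. It shares no code with the ADMM path — its
constrained nuclear prox is an independent Douglas-Rachford iteration in
pure R — so agreement between the two solvers (objective gap below 1e-4,
max entrywise gap of the identified sum `S - L` below 1e-3 on random small
instances) is a genuine dual-route correctness check; both routes are also
compared against closed forms (the conditional MLE at `lambda = 0`, the
inverse covariance for the joint methods).

## Baselines

`fit_method()` exposes four estimators through one interface. `lscggm` is
the full machinery. `scggm` freezes `L = 0` (sparse conditional model; its
l1 weight is `lambda * gamma` so that small-`gamma` full fits reproduce it
exactly — fits at `gamma <= 0.05` have rank-0 latent components and match
the sparse-only solution). `lrps` applies the `m = 0` machinery to the
joint (m+p) second-moment matrix — low-rank plus sparse decomposition of
the joint precision — and extracts the conditional blocks as submatrices;
`glasso` is `lrps` with the low-rank part frozen. The joint methods
implicitly treat the inputs as Gaussian, which the simulator deliberately
violates (t-distributed inputs); this is one of the mechanisms the
benchmark probes.

## The simulator

`sim_design()` / `sim_model()` / `sim_dataset()` generate the benchmark
family. Two integers describe each design at `p = m = 2^k`:

* the output graph is always a chain over `p` variables with every fifth
  link removed (off-diagonal support `{(i, i-1): i mod 5 != 0}`; 25 edges
  at `p = 32`);
* `d_H` sets the latent structure: `2^d_H` confounders, each loading on
  exactly `p / 2^d_H` outputs, each output tied to exactly one confounder,
  so `rank(L_X) = 2^d_H` exactly (4 latent variables at `d_H = 2`, 8 at
  `d_H = 3`); at `d_H = k` the pairing is one-to-one and there is
  effectively no confounding;
* `d_Z` sets the input design: the input-effect matrix has rank `2^d_Z`
  and exactly `p / 2^d_Z` nonzeros in every row and column (8 outputs per
  input at `d_Z = 2`, 4 at `d_Z = 3`), realized as disjoint rank-one
  blocks over random partitions of inputs and outputs; `d_Z = k` is a
  signed scaled permutation.

Inputs are drawn i.i.d. from a t-distribution with 4 degrees of freedom
(heavy-tailed, variance 2); outputs follow the implied Gaussian
conditional law. The benchmark grid (`sim_grid()`) enumerates `(d_Z, d_H)`
in `{2,...,5}^2` at `k = 5`, `n = 3000` — 16 designs, 20 replicates each,
320 datasets — with per-dataset seeds derived from one base seed by a
counter scheme, so any single dataset regenerates in isolation.

Free quantities the design description leaves open were fixed once as
follows and are configurable through `effect_config` arguments: nonzero
effect magnitudes are drawn uniformly from ±[0.2, 0.4] (detectable but not
trivial against unit-scale noise); the latent precision `M_H` is diagonal
with entries jittered in [1, 1.2] (diagonal so that the `d_H = k` design
is exactly confounding-free); diagonals of the joint conditional precision
are set to the row absolute sums plus 0.5, which guarantees strict
diagonal dominance and hence positive definiteness of every generated
model. Input columns are left on their raw t(4) scale. What the simulator
does *not* emulate: discrete (0/1/2) genotype coding, missing data,
mean structure, or non-Gaussian outputs — passing benchmarks here shows
correct recovery under the stated model, not robustness to those
real-data features.

## Evaluation

Support recovery of `S_X` is scored on the `p(p-1)/2` undirected
off-diagonal pairs of the output block only. An estimated edge is an
off-diagonal entry whose symmetrized magnitude exceeds 1e-6 (a
solver-tolerance-scaled threshold; configurable). Precision of an empty
estimate is defined as 1 so curves start at recall 0. `pr_auc()`
integrates the monotonized upper precision envelope by trapezoid, treating
precision as 0 beyond the largest achieved recall; `fixed_recall_precision()`
reads the envelope at recalls {0.1, ..., 1} by right-continuous
interpolation; `pr_vus()` integrates AUC over the `gamma` grid
(trapezoid, normalized by the grid range) to summarize sensitivity to both
tuning parameters. `consistency_check()` reports exact sign-pattern
agreement, rank agreement and the error norms `||S_hat - S*||_inf`,
`||L_hat - L*||_2`. `identifiability_bounds()` computes two documented
*proxies* for the rank-sparsity incoherence quantities: the maximum
row/column support cardinality of the stacked sparse truth, and twice the
largest coordinate leverage of the low-rank column space (2/sqrt(p) for
one uniformly-loading latent variable, 2 for a diagonal latent part).
The exact variational quantities require constants that are not available
in closed form; the proxies preserve the orderings the theory cares about.

## Stability selection

`stability_select()` implements complementary-pairs stability selection:
`B` pairs of disjoint half-samples (default `B = 50`, subsample size
`floor(n/2)`), the penalty path refitted on each of the `2B` halves, and
an edge counted once per half if it appears anywhere along the lambda path
("pointwise" max-over-path selection; a per-lambda mode is available).
The inclusion threshold `tau` is calibrated from the expected-false-
discovery bound `E(V) <= q^2 / ((2 tau - 1) p_cand)` with `q` the average
selected-set size, choosing the smallest `tau` meeting the budget
(default `E(V) <= 1`); if even `tau = 1` cannot meet it the selection is
empty, with a warning. The sharper r-concave refinement of this bound is
deliberately not the default — the classical form is what the error-control
guarantee is stated for. `jaccard_index()` and `gamma_similarity()`
quantify agreement of selections across the `gamma` grid and locate the
stable region (longest contiguous block with pairwise similarity at or
above 0.9). `B` and the subsample scheme are package choices, not dictated
by the method's description.

## Numerical choices and degenerate inputs

* Symmetry is enforced (tolerance 1e-10) on construction; feasibility
  means `S_X - L_X` PD and `L_X` eigenvalues above -1e-10.
* Singular `Sigma_Z` (collinear inputs) is handled: the Sylvester step
  only needs nonnegative eigenvalues. Singular `Sigma_X` is handled by the
  log-det barrier keeping iterates PD.
* Ties among singular values are benign: tests compare function values and
  identified quantities, never factor matrices.
* `lambda_max` is found by log-scale bisection on the smallest penalty
  with an empty off-diagonal support; default grids are log-spaced over
  `[lambda_max/100, lambda_max]` with 25 points.
* Matrix text I/O prints 17 significant digits and parses with the
  correctly-rounded base-R reader, so round trips are bit-exact.

## Problem sizes used in the test suite

The suite exercises the prescribed study conditions directly: solver
cross-checks on instances with `p, m <= 4`; the recovery experiment at
`p = m = 16`, `n = 20000`, 5 seeds; the benchmark comparison on the
`(d_Z = 2, d_H = 2)` design at `p = 32`, `n = 1500` with 6 replicates
and 5 gamma values; stability-selection error control at `p = 8`,
`n = 400`, `B = 25`, 20 runs. The compiled solver core keeps these within
interactive runtimes.

## Known limitations

* The solvers target desk-scale problems (full eigen/SVD per iteration;
  no randomized or partial factorizations), appropriate up to a few
  hundred variables.
* No missing data, no discrete-output likelihoods, no mean-parameter
  estimation.
* The bundled oracle is first-order; extremely tight tolerances (beyond
  ~1e-9 relative) are better served by attaching an interior-point conic
  solver through the `backend` hook of `solve_sdp()`.
* Stability selection refits the path `2B` times; at large `p` this is the
  dominant cost and `B` should be chosen with that in mind.
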