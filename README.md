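# lscggm

Structure learning for Gaussian conditional random fields in the presence of
unobserved confounders.

## The problem

Given `n` samples of an input block `Y_Z` (m variables — genotypes, batch
covariates, experimental conditions) and an output block `Y_X` (p variables —
metabolite levels, expression traits), one often wants the conditional
independence graph *among the outputs*, holding both the inputs and any
unmeasured common causes fixed. Conditioning on the inputs alone is not
enough: marginalizing latent variables adds a low-rank perturbation to the
conditional precision matrix, and a sparse-only estimate of it is biased
toward spurious edges.

The model assumes `(Y_X, Y_H) | Y_Z` is multivariate normal with mean linear
in `Y_Z` (nothing is assumed about the input distribution). Marginalizing the
latent block `Y_H` gives

    Y_X | Y_Z ~ N( -(S_X - L_X)^{-1} (S_ZX - L_ZX)' Y_Z , (S_X - L_X)^{-1} )

where `S_X` is the sparse conditional precision over the outputs (the graph
of interest), `L_X` is positive semidefinite with rank equal to the number of
latent variables, and `S_ZX`, `L_ZX` carry direct and latent-routed input
effects. The package estimates all four blocks by penalized maximum
likelihood,

    min  -loglik(S - L) + lambda * ( gamma * ||S||_1 + (1 - gamma) * ||L||_* )
    s.t. S_X - L_X positive definite,  L_X PSD,

a jointly convex program whose l1 term recovers the sparse direct structure
and whose nuclear-norm term absorbs the latent effects into a low-rank
component.

## What is in the package

* `fit_admm()` — compiled multi-block ADMM solver with an inexact proximal
  step for the PSD-constrained stacked nuclear norm
  (`prox_stacked_nuclear_psd()`), warm starts, and convergence diagnostics
  (`kkt_report()`).
* `build_sdp()` / `solve_sdp()` — the exact semidefinite reformulation of the
  objective, a plain-JSON problem export for external conic solvers, and a
  bundled high-accuracy first-order back-end used as a correctness oracle.
* `fit_method()` / `regularization_path()` — one front-end for the four
  estimators compared throughout: the full conditional model (`lscggm`), the
  sparse conditional model (`scggm`), low-rank plus sparse decomposition of
  the joint precision (`lrps`), and the graphical lasso (`glasso`).
* `sim_design()` / `sim_model()` / `sim_dataset()` / `sim_grid()` — a
  structured simulator: chain output graphs (one link in five removed),
  block latent designs indexed by `d_H`, block input designs indexed by
  `d_Z`, heavy-tailed t(4) inputs.
* `pr_curve()` / `pr_auc()` / `pr_vus()` / `consistency_check()` — support
  recovery scoring (precision/recall, area under the curve, volume under the
  (lambda, gamma) surface, sign and rank agreement).
* `stability_select()` / `jaccard_index()` / `gamma_similarity()` —
  complementary-pairs stability selection with expected-false-discovery
  control, and selection-similarity analysis across the `gamma` grid.
* Broom-style `tidy()` / `glance()` methods, `autoplot()` for paths and
  stability results, a thin command-line interface at `inst/cli/lscggm.R`
  (subcommands `simulate`, `fit`, `path`, `stability`).

## Worked example

```r
library(lscggm)

# simulate a benchmark design: p = m = 16, 4 confounders (d_H = 2),
# each input acting on 4 outputs (d_Z = 2)
design <- sim_design(k = 4, d_Z = 2, d_H = 2, n = 2000, seed = 42)
truth  <- sim_model(design)
data   <- sim_dataset(truth)

fit <- fit_method(data, "lscggm", lambda = 0.08, gamma = 0.6)
glance(fit)
#> # A tibble: 1 x 10
#>   lambda gamma objective n_edges rank_L iterations converged     n     p     m
#>    <dbl> <dbl>     <dbl>   <int>  <int>      <int> <lgl>     <int> <int> <int>
#> 1   0.08   0.6      15.2      12     16         38 TRUE       2000    16    16

head(tidy(fit), 3)
#> # A tibble: 3 x 4
#>   block     i     j   value
#>   <chr> <int> <int>   <dbl>
#> 1 S_X       1     2 -0.252
#> 2 S_X       2     3 -0.0840
#> 3 S_X       3     4 -0.107

consistency_check(fit, truth)
#> # A tibble: 1 x 7
#>   sign_agreement sx_sign_f1 rank_match rank_L_hat lx_psd err_S_inf err_L_2
#>   <lgl>               <dbl> <lgl>           <int> <lgl>      <dbl>   <dbl>
#> 1 FALSE                   1 FALSE              16 TRUE       0.373    1.20
```

At this single penalty setting every true output edge is recovered and no
false edge enters (`sx_sign_f1 = 1`): the 12 reported edges are exactly the
chain links of the design. The full sign pattern over all four blocks is not
reproduced exactly (`sign_agreement = FALSE`) and the numerically full rank
of the shrunken low-rank block at this moderate `lambda` is expected —
rank recovery needs the penalty path, not one point. Sweeping the surface:

```r
path <- regularization_path(data, "lscggm", gammas = c(0.3, 0.6, 0.9),
                            n_lambda = 8)
pr <- pr_curve(path, truth)
vapply(split(pr, pr$gamma), pr_auc, numeric(1))
#>  0.3  0.6  0.9
#> 1.00 1.00 0.75
pr_vus(pr)
#> [1] 0.937
```

The area under the precision/recall curve is 1 for a wide range of `gamma` —
the latent component is being absorbed — and degrades only when almost all
weight moves onto the l1 term (`gamma = 0.9`), where the method approaches a
sparse-only conditional fit.

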