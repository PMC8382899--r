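---
title: "Species-tree estimation for a triplet under the multispecies coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-tree estimation for a triplet under the multispecies coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaltrio)
```

## The model

`coaltrio` studies the smallest species-tree problem that still has all the
structure of the general one: three species $A$, $B$, $C$, one sequence from
each per locus, evolving under the Jukes–Cantor substitution model with a
molecular clock, with genealogies generated by the multispecies coalescent
(MSC). The three rooted species trees are $S_1 = ((A,B),C)$,
$S_2 = ((B,C),A)$, $S_3 = ((C,A),B)$. Under $S_1$ the model has four
parameters, all in expected substitutions per site: the divergence ages
$\tau_0$ (root) and $\tau_1$ (ingroup split), and the population-size
parameters $\theta_0$ (root population $ABC$) and $\theta_1$ (ancestral
population $AB$), where $\theta = 4N\mu$.

At each locus the gene tree may disagree with the species tree through
incomplete lineage sorting. The two ingroup lineages fail to coalesce in
population $AB$ with probability
$\varphi = e^{-2(\tau_0-\tau_1)/\theta_1}$, in which case all three lineages
enter the root population and the three gene-tree topologies are equally
likely. Hence $P(G_1) = 1 - \tfrac23\varphi$ and
$P(G_2) = P(G_3) = \tfrac13\varphi$ (`gene_tree_topology_probs()`). The
joint density of the gene-tree class and its node ages $(t_1, t_0)$ is the
product of exponential coalescent waiting-time densities on the class's
support (`msc_density()`); the four classes ($G_{1a}$: coalescence inside
$AB$; $G_{1b}, G_2, G_3$: all lineages reach the root) have masses
$(1-\varphi, \varphi/3, \varphi/3, \varphi/3)$.

Under JC with a clock, an alignment column for the triplet collapses into
five site-pattern classes, ordered throughout the package as
(`xxx`, `xxy`, `yxx`, `xyx`, `xyz`). Given a gene tree the pattern
probabilities are polynomial in $u = e^{-8t_0/3}$ and $v = e^{-4t_1/3}$
(`pattern_probs()`); averaging them over the MSC gives the closed-form
marginal probabilities $\bar p$ (`marginal_pattern_probs()`), which drop to
a three-parameter family when $\theta_0 = \theta_1$
(`marginal_pattern_probs_equal_theta()`).

All ages and $\theta$s are in substitutions per site; the only conversion
helper provided is `internal_branch_coalescent_units()`
($2(\tau_0-\tau_1)/\theta_1$). Infinite times are accepted as sentinels
meaning $u = v = 0$ (random sequences).

## The four estimators

* **Two-step** (`two_step()`): the ML gene tree per locus is the topology
  whose supporting informative pattern count is largest (`ml_gene_tree()`);
  the modal topology across loci is the species-tree estimate. Tied loci are
  split evenly by default (policies `"even"`, `"drop"`, `"random"`).
* **Concatenation** and **independent-sites ML (isml)**
  (`concat_isml_topology()`): both choose the species tree by the argmax of
  the informative pattern counts pooled across loci; for the triplet they
  are the same topology rule. `concat_fit_times()` additionally returns the
  JC-clock node-age MLEs from the pooled counts — deliberately misspecified
  (one gene tree for all sites), to quantify the bias of concatenation-based
  dating. `isml_estimate_params()` inverts the equal-$\theta$ marginal model
  for $(\tau_0, \tau_1, \theta)$ via a closed-form quadratic; with
  $\theta_0 \ne \theta_1$ truth the estimates are finite but inconsistent,
  although the topology call remains consistent.
* **Full ML** (`ml_msc_fit()`, `ml_msc_species_tree()`): maximizes the exact
  MSC likelihood, with the coalescent times integrated out numerically (see
  below), separately under each species tree; the highest maximized
  log-likelihood wins, with ties declared within $10^{-6}$ log-units.
* **Infinite-sites ML** (`species_tree_from_true_gene_trees()`): with exact
  gene trees the likelihood has a singularity and the winner is decided by
  the smallest pairwise coalescent time; the error is exactly
  $\varphi^m \cdot 2/3$ (`ml_error_infinite_n()`).

## Numerical integration of the likelihood

The per-locus likelihood is a mixture over the four gene-tree classes of
two-dimensional integrals of multinomial kernels against exponential
densities. The package evaluates them with fixed Gaussian quadrature built
from two ingredients:

1. **Mutation-scale Jacobi rules** for every half-infinite axis. Substituting
   $\xi = e^{-a s}$ (with $a = 4/3$ or $8/3$, the rates at which $v$ and $u$
   decay) turns $\int_0^\infty r e^{-rs} g(e^{-as})\,ds$ into
   $\tfrac{r}{a}\int_0^1 \xi^{r/a-1} g(\xi)\,d\xi$ — a *polynomial*
   integrand (the pattern probabilities are polynomial in $\xi$) against a
   Jacobi weight. Gauss rules for that weight (Golub–Welsch on the Jacobi
   recurrence) are therefore **exact** whenever the per-axis count exponents
   are below $2K - 1$, and remain well adapted at large counts because the
   nodes follow the density mass.
2. **Composite Gauss–Legendre** for the one truncated axis (the $G_{1a}$
   ingroup age on $(\tau_1, \tau_0)$), in the probability coordinate
   $y = e^{-2(t_1-\tau_1)/\theta_1} \in (\varphi, 1)$ with panels graded
   geometrically toward $0$, which keeps the mildly singular factor
   $y^{2\theta_1/3}$ resolved for any $\varphi$.

With the default `quad_nodes = 32` the scheme agrees with adaptive nested
integration to better than $10^{-8}$ relative error across single-site,
moderate, and 1000-site loci (this is asserted in the test suite). The one
regime where accuracy degrades is super-saturated data more divergent than
random sequences (e.g. pattern counts $(4,13,12,11,50)$), where the
integrand mass escapes to $t \to \infty$; there the relative error is about
$2\times10^{-4}$ at $K = 32$. Such data have vanishing probability under the
model at realistic lengths, and no default behavior is keyed to them.

Optimization is bounded quasi-Newton (L-BFGS-B) on
$(\log\tau_1, \log(\tau_0-\tau_1), \log\theta_0, \log\theta_1)$ — this
parameterization, rather than $\log \tau_0$ itself, enforces
$0 < \tau_1 < \tau_0$ by construction. Default three starts: a heuristic
start from the pooled frequencies through the isml inversion, and dispersed
$\times 3$ / $\div 3$ variants. Convergence is declared at $10^{-8}$
log-likelihood units; parameters are bounded below at $10^{-8}$ and
estimates on the bound are flagged `boundary`. Standard errors, when
requested, come from the numerically differentiated observed information
mapped to the natural scale.

## The simulator

`sim_gene_trees()` / `sim_dataset()` implement the exact generative process:
an exponential waiting time $s_1$ with mean $\theta_1/2$; if
$\tau_1 + s_1 < \tau_0$ the class is $G_{1a}$ with $t_1 = \tau_1 + s_1$ and
$t_0 = \tau_0 + s_0$ ($s_0$ exponential, mean $\theta_0/2$); otherwise one
of $G_{1b}, G_2, G_3$ uniformly, with $t_1 = \tau_0 + s_1'$ ($s_1'$ mean
$\theta_0/6$) and $t_0 = t_1 + s_0$. Site-pattern counts are multinomial
given the class-permuted pattern probabilities, drawn through a vectorized
binomial cascade.

Reproducibility: each dataset is generated from a user seed on L'Ecuyer-CMRG
substreams assigned to fixed-size blocks of loci; the generator always
produces whole blocks and truncates, so enlarging $m$ extends a dataset
without reshuffling the loci already drawn. The infinite-sites regime
(`n = Inf`) stores each locus's exact pattern-probability vector instead of
counts.

What the generator emulates — and does not: free recombination among loci,
no recombination within a locus, a strict clock, JC substitution, equal
locus lengths, no rate variation, no indels or missing data. Tests passing
on these simulations validate the mathematics and the implementation under
the model's own assumptions; they say nothing about robustness to model
violations in real data.

`realize_alignment()` expands counts into three labelled sequences
(`a`, `b`, `c`), assigning bases uniformly among the assignments consistent
with each pattern; writers/readers cover FASTA, sequential PHYLIP, and a
TSV-plus-JSON-sidecar dataset format.

## Error theory

For any estimator that picks the species tree by the largest of three
per-locus-averaged statistics with means $(\mu_1, \mu_2, \mu_2)$ and
exchangeable covariance, the error
$\zeta = P(\bar z_1 < \max(\bar z_2, \bar z_3))$ is approximated by
`zeta_normal()`:
$$\zeta \approx \Phi\!\left(\frac{-\Delta\mu\sqrt m + \sqrt{(\sigma_2^2-\sigma_{23})/\pi}}
 {\sqrt{\sigma_1^2 - 2\sigma_{12} + \sigma_2^2 - (\sigma_2^2-\sigma_{23})/\pi}}\right),$$
with the multinomial specialization `zeta_multinomial()` and the bound pair
$\Phi(-h)(1 + \tfrac2\pi\arctan a) \le \zeta < 2\Phi(-h)$ (`zeta_bounds()`).
The printed rendering of this formula family is ambiguous in places; the
adopted convention is pinned jointly by three independent reference cells
(0.644 at $n=1$, 0.264 at $n=1000$, 0.113 at $n=\infty$, all at
$m = 1000$) — any sign or denominator variant fails at least one of them.

Method-specific predictors: two-step uses
$\zeta(m, g_1(n), g_2(n))$ with the estimated-gene-tree probabilities from
`gene_tree_recovery()` (exact at $n = 1$ and $n = \infty$, Monte Carlo
between); isml/concatenation uses `zeta_normal()` with
$\Delta\mu = \bar p_1 - \bar p_2$ and the mixed covariance
$\Sigma(n) = \tfrac1n\Sigma(1) + \tfrac{n-1}{n}\Sigma(\infty)$
(`sigma_one_site()`, `sigma_infinite()`, `sigma_mixed()`), where
$\Sigma(\infty)$ — the coalescent fluctuation of the per-locus pattern
probabilities — is estimated by Monte Carlo (default $10^6$ gene trees, with
reported standard errors). A no-correlation variant
(`correlations = FALSE`) reproduces the less accurate $\zeta_{N0}$ row of
the reference grid. For full ML at finite $n$, `kl_predict_ml_error()`
estimates pseudotrue parameters for the misspecified trees on a simulated
reference sample and plugs the Kullback–Leibler divergence and the
log-likelihood covariance into the same normal approximation; it is
research-grade, as its inputs are themselves Monte Carlo estimates.

A discontinuity-corrected variant of the multinomial form is included as
`zeta_zly()` but kept behind an `experimental` flag: the published rendering
of that expression is garbled and no parse we tried reproduces its reference
values, so it is never used as a default predictor and nothing downstream
depends on it.

## Experiments and diagnostics

`run_error_experiment()` scores $R$ replicate datasets per method, with
dataset-level ties credited evenly (a $k$-way tie including the true tree
counts $(k-1)/k$ of an error). The infinite-sites regime is implemented per
method: two-step scores true topologies, isml/concatenation averages exact
per-locus pattern probabilities, ML applies the smallest-coalescent-time
rule. At $n = 1$ every method reduces exactly to the pooled-pattern argmax,
whose tallies are multinomial with the marginal probabilities — so
single-site experiments are drawn directly at that level. For small $m$ at
$n = 1$ the exact error is available by complete enumeration
(`exact_error_n1()`) and anchors the simulation machinery.

`probit_linearity()` checks the theory's signature prediction that
$\Phi^{-1}(e)$ falls linearly in $\sqrt m$. Two empirical notes, both
visible in the tests: the fit should sweep the full $m$ range of the error
curve (narrow sweeps are noise-dominated); and at $n = 1$ under the
challenging parameter set the exact error curve retains a little genuine
curvature at small $m$ (where the normal approximation is weakest), capping
$R^2$ near $0.9987$ no matter how many replicates are used — the
$R^2 \ge 0.999$ regime is the moderate-to-large-$m$, larger-signal sweep
such as two-step at $n = \infty$.

`table1_report()` rebuilds the analytic grid (recovery probabilities, zeta
predictions, bound quantities, optional simulated errors) over
$n \in \{1, 2, 10, 100, 1000, \infty\}$, deterministically for a given seed.

## Default problem sizes

The study conditions follow the reference analysis: the challenging species
tree $(\tau_0, \tau_1, \theta_0, \theta_1) = (0.02, 0.019, 0.01, 0.05)$ for
the error work, and $(0.02, 0.01, 0.02, 0.01)$ with $m = 10^4$, $n = 250$
for the concatenation-bias experiment. Monte Carlo sizes used by the test
suite and the acceptance script are our own choices, set so that the checks
are decisive at 3–4 standard-error tolerances: $10^6$ gene trees for class
masses, $10^5$–$2\times10^5$ loci for recovery probabilities and marginal
frequencies, $R = 10^4$ replicate datasets for the simulated error cells,
$4\times10^5$ gene trees for $\Sigma(\infty)$, reduced $m = 1000$ (with
observed-information standard errors) for the full-ML parameter-recovery
check, and $R$ in the tens for the expensive finite-$n$ full-ML error
simulations. Reference-scale runs ($R = 10^6$–$10^8$) are available through
the same functions by raising the `R` arguments.

## Known limitations

* Three taxa, one sequence each, JC, strict clock — by design; none of the
  machinery generalizes to more taxa as written.
* The finite-$n$ full-ML error experiment refits three trees per replicate
  and is orders of magnitude slower than the summary methods.
* `zeta_zly()` is a documented open question, not a usable predictor.
* Quadrature accuracy degrades (to $\sim 10^{-4}$ relative) on
  super-saturated data beyond the random-sequence limit.
* The isml parameter estimator requires admissible moments (it fails with an
  informative error near saturation), and is inconsistent when
  $\theta_0 \ne \theta_1$, as documented.
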