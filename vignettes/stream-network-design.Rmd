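---
title: "Optimal and adaptive monitoring design on stream networks: models, criteria and algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal and adaptive monitoring design on stream networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamdesign)
```

## The problem

Freshwater monitoring programmes must decide where to place a limited number
of sampling sites on a stream network. `streamdesign` treats this as a
model-based design problem: a geostatistical linear model describes the
spatial process of interest (temperature, dissolved oxygen, an index of
ecosystem health), and candidate site configurations — *designs* — are ranked
by how much information they are expected to deliver for a stated goal:
estimating the model's parameters, predicting at unsampled locations, or
simply covering the network evenly.

Stream networks break the assumptions of ordinary two-dimensional
geostatistics. Flow is directional, sites interact along the branching
network rather than through straight-line space, and the influence of an
upstream tributary on a downstream reach depends on how much of the flow it
contributes. The package therefore works with the stream-specific model
family described next, and every distance it uses is hydrologic — measured
along the network.

## The geostatistical model

For observations $y$ at $n$ sites with design matrix $X$,

$$y \sim \mathcal N(X\beta,\ \Sigma(\theta)),$$

where the covariance is a sum of up to three components,

$$\Sigma_{ij} = \sigma^2_{tu}\, W_{ij}\, e^{-3 H_{ij}/\alpha_{tu}}
             + \sigma^2_{td}\, e^{-3 H_{ij}/\alpha_{td}}
             + \sigma^2_{0}\, 1\{i = j\}.$$

* **Tail-up** ($\sigma^2_{tu}, \alpha_{tu}$): a moving-average construction
  whose kernel points upstream. It produces correlation only between
  *flow-connected* pairs (one site lies on the other's path to the outlet),
  attenuated at confluences by the weights
  $W_{ij} = \sqrt{\mathrm{afv}_{up}/\mathrm{afv}_{down}} \in (0, 1]$, built
  from an additive function value (afv) per edge — Shreve magnitude by
  default, watershed area if the user supplies one. Monotonicity of the afv
  downstream guarantees $W \le 1$.
* **Tail-down** ($\sigma^2_{td}, \alpha_{td}$): correlation between *all*
  pairs, a function of the total hydrologic separation $H_{ij}$ only, which
  for flow-unconnected pairs is the sum of the two distances to the nearest
  common downstream junction.
* **Nugget** ($\sigma^2_0$): measurement error and micro-scale variation.

Ranges use the *effective-range* convention $e^{-3h/\alpha}$, so $\alpha$ is
the distance at which correlation falls to about 0.05. The factor 3 is a
convention, not a property of the data; `range_convention = "natural"`
switches to $e^{-h/\alpha}$, and fitted ranges differ between the two by
exactly that factor. Both conventions appear in the literature, which is why
the switch is explicit rather than silent.

Parameters $\theta$ are estimated by maximising the Gaussian likelihood (ML)
or restricted likelihood (REML) over $\log\theta$, with analytic gradients,
box bounds $[-20, 20]$ on the log scale, three jittered starts and relative
tolerance $10^{-8}$. Initial values are unglamorous but reproducible: sills
split the sample variance, ranges start at the median nonzero distance, the
nugget at 10% of the sample variance. Log-scale standard errors come from
the inverse observed information of the profile objective; the inverse is
computed through an eigenvalue-floored decomposition so that directions with
no curvature (the range of a component whose sill collapsed to zero) yield
very large rather than undefined uncertainties.

## Design criteria

Every criterion is oriented so that **larger is better** and the optimiser
always maximises. The estimation criteria are log-determinants of
information matrices: `D` uses $\log\det(X_d'\Sigma_d^{-1}X_d)$ (fixed
effects), `CP` uses $\log\det I(\theta; d)$ with
$I_{jk} = \tfrac12\mathrm{tr}(Q\Sigma_j Q\Sigma_k)$ the expected Fisher
information of the covariance parameters, and `CPD` is their sum. One
orientation note: a convention in which the covariance-parameter criterion
is printed as $\log\det I^{-1}$ and *maximised* would reward uninformative
designs; this package uses $\log\det I$ so that all information criteria
point the same way, and documents the flip rather than inheriting the
ambiguity. The prediction criterion `K` is the inverse of the summed
universal-kriging variances over a user-supplied prediction set. Empirical
variants (`ED`, `EK`) simulate data at the design under each prior draw,
re-estimate $\theta$ by (RE)ML, and evaluate the criterion at the estimate —
they price in estimation error, at substantial computational cost.
Sequential variants (`seqCP`, `seqD`, `seqED`) add a summary statistic $O_t$
carrying the information already held by existing sites: the Fisher
information of those sites for `seqCP` (information scale), their GLS
fixed-effect covariance for `seqD`/`seqED` (covariance scale), rebuilt per
prior draw. Space-filling scores (`maximin`, Morris–Mitchell $-\phi_p$ with
$\phi_p = [\sum_w J_w D_w^{-p}]^{1/p}$) ignore the model entirely. The
Morris–Mitchell criterion is implemented with inverse distance weighting, the
form under which large $p$ provably approaches the maximin ranking; a printed
variant that weights distances directly rather than inversely conflicts with
that limiting behaviour and is not used.

Because $\theta$ is unknown at design time, criteria are averaged over
independent log-normal priors on the covariance parameters by Monte-Carlo
integration — the pseudo-Bayesian expected utility
$U(d) = \tfrac1M\sum_m u(d, \theta^{(m)})$. The draw matrix is generated
once per optimisation run and shared across all candidate designs (common
random numbers), which makes greedy comparisons consistent and the whole
procedure deterministic given a seed. `sdlog = 0` priors collapse to
point-mass (locally optimal) design. Draws whose utility fails (a
non-convergent empirical fit, say) are dropped and counted; beyond 50%
failures the evaluation aborts rather than report a mean of survivors.

## Optimisation

The greedy coordinate-exchange algorithm starts from `K` random designs; in
each sweep it visits the free design points in order, evaluates all
$N - n$ exchanges with non-members, and accepts the best strictly improving
one (absolute tolerance $10^{-12}$, ties to the smallest candidate index, so
runs are deterministic). Sweeps repeat until one passes with no acceptance.
Each sweep costs exactly $n_{free}(N - n)$ expected-utility evaluations —
the package counts them and exposes the count, so the run-time model
`cost_model(K, L, T_sec, n, N, C)` = $K L T n (N-n) / (3600 C)$ hours is an
assertion about the implementation, not folklore. Greedy exchange is a
heuristic: it can stop at a local optimum, which is why `exhaustive_search()`
exists as a small-instance oracle and why restarts are cheap insurance.

Designs may not contain two sites at zero hydrologic distance (the
covariance of the pair differs only by the nugget, and space-filling scores
degenerate); the optimisers skip such exchanges, while distance structures
themselves permit co-located sites — repeated yearly measurements at a site
are exactly that.

Stepwise reduction (`drop_one_stepwise()`) removes one site at a time,
keeping priors and draws fixed — deliberately *not* adaptive, since no model
is refit. Exact ties among deletions, routine under space-filling scores,
fall to the more dispersed retained design and then to the smallest index.

## Adaptive design

`adaptive_loop()` implements myopic sequential design: at each step it fits
the model to all accumulated data, rebuilds the log-normal priors from the
fit ($\mu = \log\hat\theta$, $\sigma$ = log-scale standard errors, capped at
2 so that unidentified directions get a weakly informative prior rather than
an absurd one), draws a fresh shared draw matrix, builds $O_t$ from the
existing sites when a sequential criterion is used, and runs greedy exchange
for the new sites with existing sites held fixed. Data for the augmented
design then come from a user-supplied source (a simulated "true" process, a
field campaign) or are simulated from the fitted model. Myopic means each
step optimises only the next decision; backward induction over all future
steps is out of scope by design. The first design must already exist —
probability-based or optimal — because nothing can be fit to no data.

## Baseline designs

`standard_design()` provides the comparison schemes: simple random sampling;
a spatially balanced sampler that orders candidates by quadrant-recursive
hierarchical randomisation with an independent random quadrant permutation
in every cell, then takes prefixes of the reverse-hierarchical order (so
draws under one seed are nested — the "master sample" property); variants
anchoring the outlet or clustering triplets at confluences; and heuristic
headwater/tributary allocations. The one-line scheme descriptions in the
source literature leave the mechanics open; the concrete fill orders used
here (nearest candidate on each of the three edges at a confluence, quota
then remainder) are this package's renderings and are documented in the
function help. The balance property — not numerical agreement with any
survey package — is what is promised and tested. Cluster size for the
confluence-cluster variant defaults to 3, one site per incident edge, the
natural triplet motif; nothing in the sources pins this number.

## The synthetic-data generator

`synth_network()` grows a random full binary confluence tree: `n_headwaters`
headwater edges merge pairwise in random order, giving $2n_{hw}-1$ edges,
edge lengths drawn from a configurable law (default uniform), Shreve afv,
and a dendrogram-style planar embedding so spatially balanced schemes have
coordinates. `place_sites()` positions candidates at regular fractions
$i/(k+1)$ of each edge (never on a junction, avoiding ambiguous edge
membership), at random positions, or at explicit fractions.

What the generator emulates: dendritic topology, confluence weighting,
hydrologic distance, Gaussian responses from the model above, yearly
revisits as independent replicate fields. What it does not: braided
channels, intermittent streams, non-Gaussian responses, temporal
autocorrelation between years, covariate structure along the network, and
real GIS-derived afv (watershed area). Tests passing on synthetic networks
therefore validate the algorithms and the model arithmetic, not the model's
adequacy for any particular river.

### Study conditions used by the packaged experiments

The worked examples and tests use conditions chosen once, on the following
grounds:

* True covariance parameters $(\sigma^2_{tu}, \alpha_{tu}, \sigma^2_{td},
  \alpha_{td}, \sigma^2_0) = (1, 6, 1, 6, 0.5)$ on networks with edge
  lengths uniform on $(1, 3)$: equal tail sills, ranges a moderate fraction
  of the network span, and a nugget at 20% of the total variance — a
  regime in which no single component dominates.
* The parameter-recovery experiment uses a 25-headwater tree (49 edges)
  with three sites per edge at alternating fraction patterns
  $(0.03, 0.08, 0.97)$ and $(0.03, 0.5, 0.97)$, i.e. 147 sites arranged as
  confluence clusters — two sites close together at the downstream end of
  each edge, one near the upstream end, mid-segment sites on alternating
  edges. This mirrors how real monitoring networks are laid out, and for
  good reason: close flow-unconnected pairs across a junction are what
  separate the tail-up from the tail-down component, and close same-edge
  pairs are what identify the nugget. On sparse layouts (one site per
  edge) the components are close to unidentifiable at $n \approx 150$ —
  REML then legitimately drives the nugget to zero or inflates the
  tail-down sill; these are global optima of the restricted likelihood,
  not optimiser failures. Even under the clustered layout the tail
  decomposition is the weakest link, with median relative errors of the
  tail sills around 5–20% over 50 replicates.
* The site-reduction walkthrough (`demo_site_reduction()`) uses a
  7-headwater network with 39 candidates and halves it under `CPD` and `K`
  with 500 Monte-Carlo draws, priors centred at REML estimates with
  log-scale standard deviations $(0.35, 0.56, 0.63, 0.69, 0.68)$, and 20
  simple-random plus 20 spatially balanced baselines — the structure of a
  typical effort-reduction study, at a size a laptop handles in minutes.
* The adaptive walkthrough (`demo_adaptive_monitoring()`) runs, at desk
  scale, 62 candidates, 20 spatially balanced legacy sites observed for
  two years, then two adaptive steps of +5 sites under `K` with 50 draws,
  validated with 1000 draws; the full scale (897/200/+50/+50, 500 draws,
  5 restarts) matches the shape of a large multi-year programme but costs
  hours.
  Validation scores the full final design for every scheme (legacy sites
  are shared, so differences are attributable to the additions). Scoring
  the added sites alone is also reported, but it penalises exactly the
  complementarity the adaptive step optimises — additions deliberately
  avoid duplicating legacy coverage — and at desk scale that comparison is
  close to a coin flip.

## Numerical choices and degenerate inputs

* All covariance solves go through Cholesky factorisations; a factorisation
  failure surfaces as a rejected design (`-Inf`) inside utilities, as a
  dropped draw inside expected utilities, and as an error with the smallest
  eigenvalue reported inside the simulator.
* Singular information matrices yield `-Inf`, not exceptions: a design that
  cannot estimate the parameters is a bad design, not a broken program.
* Exhaustive search refuses instances beyond $10^5$ designs before doing
  any work.
* Networks must be single-outlet trees; cycles, multiple outlets, forked
  flow and non-positive lengths are each rejected with the offending edge
  or node named. Imported sites exactly on a junction are assigned to the
  downstream edge by the placement convention.
* All randomness flows through explicit integer seeds; repeated calls with
  the same seed are bitwise identical on one platform, and RNG state is
  restored after every seeded operation.

## Limitations

Only exponential tail-up/tail-down forms are implemented (no spherical,
linear-with-sill or Mariah kernels), responses are Gaussian, and the
Euclidean covariance component is off by default and not used by the
packaged experiments. REML here does not promise numerical parity with any
other stream-model implementation. Fully Bayesian design criteria
(posterior-based information gains) are out of scope: the framework is
pseudo-Bayesian — priors express design-time uncertainty, inference on the
collected data remains frequentist.
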