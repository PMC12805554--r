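---
title: "Methods: latent-factor spatial causal inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-factor spatial causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`spcausal` estimates the average treatment effect (ATE) of a binary or
graded areal treatment on a continuous areal outcome when two confounding
channels are plausible and neither is directly observed:

1. a **non-spatial latent construct** (in the motivating setting,
   neighborhood socio-economic status) that influenced both the treatment
   assignment and the present-day outcome, and is measured only with error
   by a handful of observed **proxy variables**; and
2. a **smooth spatial surface** shared by treatment and outcome (anything
   that varies slowly over a city and loads on both).

# The structural model

Cities are indexed by $i = 1, \dots, M$, regions within city $i$ by
$j = 1, \dots, N_i$. With outcome $Y_{ij}$, treatment
$A_{ij} \in \{0, 1\}$, proxies
$W_{ij} \in \mathbb{R}^p$, latent confounder
$U_{ij} \in \mathbb{R}^q$ and spatial process $Z_{ij}$:

$$
\begin{aligned}
Y_{ij} &= \alpha_y + \theta A_{ij} + \alpha_{yu}^\top U_{ij}
         + \alpha_{yz} Z_{ij} + \varepsilon_{y,ij}\\
A_{ij} &= \mathrm{I}\!\left(\alpha_a + \alpha_{au}^\top U_{ij}
         + \alpha_{az} Z_{ij} + \varepsilon_{a,ij} > 0\right)\\
W_{ij} &= \alpha_w + \alpha_{wu} U_{ij} + \varepsilon_{w,ij}
\end{aligned}
$$

with independent mean-zero errors of variances $\sigma^2_y$,
$\sigma^2_a$ and $\Sigma_w = \mathrm{diag}(\sigma^2_{w_1}, \dots,
\sigma^2_{w_p})$. Under latent ignorability, positivity, the structural
model, and a row-deletion (Anderson–Rubin) condition on the loading matrix
$\Lambda = \alpha_{wu}\Sigma_u^{1/2}$ — checked numerically by
`check_assumption5()` — the coefficient $\theta$ equals the ATE. The
intuition for the row-deletion condition is the classical factor-analysis
rule of thumb that each latent confounder must be correlated with at least
three proxies.

The spatial process is a per-city basis expansion
$Z_{ij} = \sum_{l=1}^{L_i} \lambda_{il} B_{ijl}$, with
$\lambda_{il} \sim \mathcal{D}_\lambda(0, \sigma^2_z)$ and $B_{ijl}$ a
spline basis function integrated over region $j$ (next section). The
number of basis functions is $L_i = \lfloor r N_i \rfloor$, where the
**spline ratio** $r$ is the single spatial-flexibility knob; it is chosen
by minimizing the WAIC of the outcome model over a candidate set
(default $\{0, 0.2, 0.4, 0.6, 0.8\}$).

# Areal spline bases

For each city we take the minimum bounding rectangle of its polygons, lay
a regular $100 \times 100$ grid of points over it, evaluate a 2D
tensor-product B-spline basis at those points, and average the values over
the grid points falling inside each region:
$B_{ijl} = \sum_k b_{il}(s_k)\mathbf{1}(s_k \in A_{ij}) /
\sum_k \mathbf{1}(s_k \in A_{ij})$.

Numerical choices (the construction itself, not the knot layout, is fixed
by the design):

* **Knot layout.** For a target count $L$ we use $m = \lceil \sqrt{L}
  \rceil$ basis functions per axis — per-axis spline order
  $\min(4, m)$ (constant, linear, quadratic, then cubic), equally spaced
  interior knots with full boundary multiplicity — and keep the first $L$
  of the $m^2$ tensor products in row-major order. The full tensor is a
  partition of unity; a truncated basis is not, which is harmless because
  each basis column carries a free coefficient. $L = 1$ degenerates to a
  constant column, which the city intercept absorbs.
* **Point-in-polygon.** For the simulator's axis-aligned unit cells we
  assign grid points to cells by index with closed-left/open-right edges
  (the city's outer max edge closed), so each point lands in exactly one
  cell. General polygons use even-odd ray casting (`mgcv::in.out`).
* **Empty regions.** A sliver region containing no grid point falls back
  to the basis value at a representative interior point, with a warning;
  only if that also fails is an error raised.
* **Stability.** Refining the grid from $100^2$ to $200^2$ moves basis
  entries by under 2% on the simulator's convex cells (tested).

# Posterior computation

All full conditionals are conjugate, so the sampler is a pure Gibbs sweep
(written in C++ via RcppArmadillo):

* probit data augmentation for each treatment equation (one-sided
  truncated normals; inversion near the mode, Robert's
  translated-exponential rejection in the far tail);
* a joint normal update of each regression block (outcome, treatment
  index, per-proxy measurement equation), with normal priors
  $N(0, 10^2)$ on all coefficients and intercepts;
* per-city multivariate-normal updates of the spline coefficients
  $\lambda_i$ (the $B_i^\top B_i$ Gram matrices are precomputed once);
* inverse-gamma IG(0.1, 0.1) updates for $\sigma^2_y$,
  $\sigma^2_{w_k}$, $\sigma^2_z$.

**Identification normalization.** $\theta$ is identified only up to
rotation of the factor space, so the sampler fixes $\Sigma_u = I_q$ and
$\sigma^2_a = 1$, and keeps the first row of each loading column positive
by jointly flipping the signs of $(\alpha_{wu,\cdot c}, \alpha_{yu,c},
\alpha_{au,c}, U_{\cdot c})$ — a relabeling that leaves the likelihood
and priors invariant and affects mixing only; $\theta$ itself is
rotation-invariant (tested by running the sampler from sign-flipped
starting loadings).

**Variants.** Two baselines share the skeleton: *outcome regression with
proxy* moves $W$ into the outcome equation as fixed covariates and drops
$U$ and the measurement equations; *no adjustment* drops $U$ and $W$
entirely. Both keep the spatial process and the probit treatment
equation, so WAIC ratio selection works identically across methods.

**Multilevel treatment.** Grades B, C, D enter the outcome as indicator
columns with effects relative to grade A, and each gets its own probit
equation. The three treatment equations share the city spline process but
carry their own spatial coefficients — a genuinely open design point; the
shared-process choice keeps the spatial confounder interpretation (one
surface per city) while letting each grade load on it differently. The
*generator* instead uses a single ordered-probit index with three
cutpoints, so simulated grades are mutually exclusive by construction.

**Random effects.** With `effect = "random"`, each city gets its own
$\theta_i \sim N(\bar\theta, \tau^2)$; $\bar\theta$ has a normal update
and $\tau$ a half-normal(0, 5) prior, updated by a random-walk Metropolis
step on $\log\tau$ (half-normal is not conditionally conjugate; the step
size 0.35 gives acceptance rates near 0.5 across the tested settings).

**Chain protocol.** Single chain, defaults 50,000 burn-in / 50,000
retained / thinning 10; every replicated experiment in the tests uses the
reduced desk-scale protocol 3,000 / 3,000 / 3, which the parameter
recovery and calibration checks showed to be sufficient for this model
size (≈ 500 regions, ≲ 400 basis coefficients). Convergence is monitored
by trace inspection and `split_rhat()` on the effect chain.

**WAIC.** $\mathrm{WAIC} = -2(\mathrm{lppd} - p_\mathrm{WAIC})$ from the
pointwise outcome log-likelihoods only; treatment and proxy equations are
deliberately excluded so model selection targets the outcome model. Ties
between candidate ratios break toward the smaller ratio (parsimony).

# What the simulator states, and what a green test establishes

The generator's defaults are a **stated world**, fixed once: 10 cities of
$7 \times 7$ unit-cell grids (490 regions), $q = 1$, $p = 3$,
$\theta^* = 1$, true spline ratio 0.4, loadings
$\alpha_{yu} = \alpha_{au} = \alpha_{yz} = \alpha_{az} = 1$,
$\alpha_{wu} = (1, 0.8, 0.6)^\top$, $\sigma^2_y = \sigma^2_{w_k} = 0.25$,
$\sigma^2_z = 1$. These are this package's own choices — the reference
study's exact preset values live in unpublished supplementary material —
selected so that (i) the naive estimator's confounding bias (≈ 1.1, i.e.
comparable to $\theta^*$) dwarfs the posterior SD (≈ 0.05), and (ii) the
row-deletion condition holds with margin. The six named presets perturb
exactly one aspect each (proxy strength ×2 or ×0.5, outcome noise ×4,
true ratio 0.6, confounder loadings ×1.5).

The generator emulates: factor-structured proxies, probit treatment
assignment, a smooth shared spatial confounder, optional heavy-tailed
($t$) latents, per-city effect heterogeneity, and ordered-probit grades.
It does **not** emulate irregular real-city polygon geometries, zero
inflation in proxies (handled at the data layer by the rank-based inverse
normal transform, not in the latent model), spatial interference between
regions, or exposure-model measurement error in the outcome. A green
calibration test therefore establishes correctness of the sampler and
selection machinery *under the stated structural model*, not robustness
to its violation — misspecification of the structural form is a known
failure mode.

# Proxy preprocessing

For application data the package provides the transforms used in the
motivating analysis: Box-Cox for positive skewed rates (with
$\lambda$ estimated by profile likelihood by default — the reference
analysis does not publish its $\lambda$ — and a documented offset of half
the smallest positive value for exact zeros), the rank-based inverse
normal transform with Blom offsets $(3/8, 1/4)$ and average ranks for
ties (so a zero-inflated point mass maps to one shared quantile), and
within-city mean centering of outcomes and proxies (idempotent; removes
city-level shifts so they cannot masquerade as treatment effects).
The Blom convention is a documented choice; the transform's rank
invariance makes the offset convention immaterial for monotone analyses.

# Numerical and degenerate-input policy

* Zero variances are legal in the *generator* (degenerate limits used by
  tests); the *fitter* requires positive variances.
* $r = 0$ drops the spatial term entirely (no basis, no
  $\lambda$, no $\sigma^2_z$ update).
* An all-treated (or all-control) design leaves $\theta$ separated from
  the intercept only by the prior; the fit proceeds (the posterior is
  proper) and the inflated posterior SD is the diagnostic.
* Non-finite outcome log-likelihood aborts the sampler with an error
  rather than returning silently broken draws.
* The row-partition search in `check_assumption5()` enumerates all
  $2^{p-1}$ splits per deleted row; with the package's intended
  $p \lesssim 10$ this is exact and instantaneous, and the singular-value
  tolerance (relative, default $10^{-8}$) is configurable.

# Known limitations

* The three multilevel probit equations are treated as independent given
  $(U, Z)$ at fit time although real grades are mutually exclusive; the
  ordered-probit generator deliberately stresses this approximation. Under
  confounding, the mismatch shows up as a shared positive offset on all
  grade effects while grade-to-grade contrasts remain accurate (the unit
  tests measure exactly this), so multilevel contrasts are the more
  trustworthy quantity.
* Factor-model identification with the minimal $p = 2q + 1$ proxies is
  weak when loadings are small; the weak-proxy preset exists to exercise
  exactly that regime and is expected to degrade coverage.
* WAIC selection is performed per method per replicate and the winning
  fit's interval is reported without a post-selection correction,
  matching the procedure it reimplements. WAIC's mild overfitting
  tendency means the selected ratio sits above the generating ratio on
  average, increasingly so the stronger the spatial signal relative to
  outcome noise; in the package's base world the calibration study
  measures this drift directly (and the estimator remains unbiased at any
  fixed ratio, so the drift costs little beyond a slightly wider spread).
* No CRS handling: polygon inputs must already be planar/projected.
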