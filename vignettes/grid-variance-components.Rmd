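---
title: "Mixed models on a variance-component grid: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed models on a variance-component grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridvc)
```

## The model

`gridvc` fits the Gaussian linear mixed model

$$
y = W\alpha + X\beta + \sum_{l=1}^{L} Z_l u_l + e,
\qquad u_l \sim N(0,\ \sigma^2 h_l^2 K_l),
\qquad e \sim N(0,\ \sigma^2 h_e^2 I),
$$

where $W$ holds covariates (always including an intercept), $X$ holds the
focal marker columns, the $K_l$ are known relationship matrices (additive,
epistatic, gene-by-environment, cage/line, ...) expanded to the observation
level by incidence matrices $Z_l$, and $\sigma^2$ is the *total* phenotypic
variance. The vector $h^2 = (h_1^2, \dots, h_L^2, h_e^2)$ of
variance-component *proportions* lives on a simplex: every entry is
non-negative and the entries sum to one. This reparameterization is the key
to the whole package: because the parameter space is bounded, a finite
rectangular grid of step $1/m$ can span *all* valid variance-component
values.

The latent vectors $u_l$ and $e$ are never materialized. Marginally,

$$
y \sim N\!\big(W\alpha + X\beta,\ \sigma^2 V\big), \qquad
V = \sum_l h_l^2 Z_l K_l Z_l^\top + h_e^2 I ,
$$

and at any fixed vertex $h^2$ with $h_e^2 > 0$, $V$ is positive definite, so
one Cholesky factorization $V = LL^\top$ whitens the model:
$y^* = L^{-1}y$ obeys an ordinary linear model with iid errors. Everything
downstream — GLS fits, ML and REML profile likelihoods, Wald F statistics,
conjugate Bayesian marginal likelihoods — is closed-form *given the vertex*.
The expensive object (the factorization, $O(n^3)$) depends only on the
vertex, never on the marker or trait being tested, so one rotation is reused
across all tests: a scan of $p$ markers over $g$ vertices costs
$O(g(n^3 + pn^2))$ instead of $O(pn^3)$ per-marker optimizations.

Profiled criteria used at each vertex (natural log everywhere):

* ML: $\;l_F(h^2) = \tfrac n2[\log\frac{n}{2\pi} - 1 - \log \mathrm{RSS}] - \log|L|$,
* REML: the same expression with $n$ replaced by $n - c - p$, plus
  $\tfrac12(\log|\tilde X^\top \tilde X| - \log|\tilde X^{*\top}\tilde X^*|)$,
  i.e. the restricted likelihood profiled at
  $\hat\sigma^2_{\mathrm{REML}} = \mathrm{RSS}/(n-c-p)$. This is invariant
  under full-rank reparameterizations of the design (tested).
* Wald: $F = \hat\theta^\top M^\top (M(\tilde X^\top V^{-1}\tilde X)^{-1}M^\top)^{-1} M\hat\theta
  \,/\, (q\,\hat\sigma^2_{\mathrm{REML}})$ on $(q,\ n-c-p)$ df. Note the
  $\hat\sigma^2$ in the denominator: without it the statistic is not
  F-distributed; the implementation is validated against the classical
  $t^2$ identity and by null-calibration simulation.
* Bayes: a conditional normal-inverse-gamma prior
  $(\theta, \sigma^2) \sim \mathrm{NIG}(0, \Psi, a_0, b_0)$ gives a
  closed-form marginal likelihood $p(y \mid h^2)$; posteriors over $h^2$ and
  Bayes factors are finite sums over the grid, assembled by log-sum-exp.

## Improper priors without infinities

Flat priors on shared covariates (and the scale-free limit $a_0 = b_0 = 0$
for $\sigma^2$) are represented as zero rows/columns of the prior
*precision*, and the corresponding (divergent) normalizing constants are
simply dropped. Two models that share the same improper components drop the
same constants, so Bayes factors are exact; this is the
$\tau \to \infty$ limit of the proper prior, keeping $a^* = a_0 + n/2$.
A practical consequence (tested): rescaling the trait leaves every Bayes
factor unchanged, so results do not depend on measurement units. Improper
priors on components *not* shared by the compared models are refused.

## The grid, pegging, and the three accelerated searches

A complete grid of step $1/m$ over $L$ proportions has
$\binom{m+L-1}{L}$ vertices (220 for $L=3$, $m=10$), enumerated in
deterministic lexicographic order; argmax ties break to the first vertex.
Vertices with $h_e^2 = 0$ are excluded so every $V$ is positive definite.
The grid is pegged either at the origin or at the null-model REML estimate
$\hat h_0^2$, which itself is found by a self-contained coarse-to-fine grid
refinement (full grid at $m=10$, then balls at doubled resolutions to
$m=40$) — no external optimizer.

Three heuristics avoid evaluating every vertex, relying on two assumptions:
most markers explain less variance than one grid step, and the likelihood /
posterior surface is unimodal.

1. **REML ball search** (per-marker tests). Score all markers at
   $\hat h_0^2$; expand a ball of radius $1/m$ (all $\pm 1/m$ coordinate
   combinations, $3^L$ including the center, clipped to the simplex); retire
   any marker whose score did not improve; repeat around the current best
   vertices, deduplicating globally, until no active test improves. Because
   the search starts at $\hat h_0^2$, no marker can ever score below the
   two-step (fixed-null-variance) analysis.
2. **Adaptive posterior refinement** (variance-component posteriors). After
   a full grid at $m_1$, find the smallest vertex set $H$ holding 99% of
   the posterior. While $|H| < 10$, double the resolution and evaluate
   fine-lattice neighbors of $H$ until $H$ stops growing, then double
   again (capped at `max_resolution`). Restricted to uniform grid priors —
   with a non-uniform prior the refinement logic is invalid and the function
   refuses.
3. **Bayes-factor ring search**. Evaluate marginal likelihoods in concentric
   Chebyshev rings around $\hat h_0^2$; a marker stops once a new ring adds
   less than 0.01% of its evaluated posterior mass. The ring at which this
   fires tracks the posterior spread (2–4 rings in our simulations).

All three evaluate subsets of the full grid and never fabricate scores;
driven to their degenerate limits (`exhaustive = TRUE`, `ring_stop = 0`,
`h_threshold = 1`) each reproduces the full-grid result bit-for-bit, which
the acceptance suite asserts. Likelihood surfaces are not always unimodal;
`search_settings(diagnostic_fraction = ...)` re-runs a full grid on a random
subset of tests and reports disagreements.

## Kinship constructions

* Additive: VanRaden's first method,
  $K_A = (G - 2f)(G - 2f)^\top / (2\sum_j f_j(1-f_j))$ with observed allele
  frequencies $f$ — the de facto GRM standard and PSD by construction. The
  source never states a formula (it delegates to an external package), so
  this is a documented package choice. Missing dosages are mean-imputed per
  marker. Centered (intercept projected out) and trace-normalized to mean
  diagonal 1 by default.
* Pairwise-epistatic: $K_A \odot K_A$, re-normalized by default (the
  renormalization question is ambiguous for one of the source datasets;
  `normalize = FALSE` is available).
* Gene-by-environment: $D Z K Z^\top D$ with $D = \mathrm{diag}(\pm 1)$
  encoding the two environments; with $K = I$ and all signs $+1$ this is the
  iid line/cage covariance.
* Small negative eigenvalues within $10^{-8}\,\mathrm{tr}(K)/n$ are
  tolerated but never clipped; anything worse is an error, because silent
  clipping hides data bugs.

## What the synthetic data does and does not emulate

The generator draws family-structured genotypes (Balding–Nichols beta
differentiation between blocks, default $F_{st} = 0.3$, 10 blocks —
family-level structure comparable to heterogeneous-stock or accession
panels), then sums marker effects, correlated random draws
($\mathrm{chol}(K_l)$ with a recorded $10^{-8}$ jitter only if
factorization fails) and iid noise, weighting by *theoretical* variance
proportions so the total variance is 1. Defaults mirror the simulation
settings of the motivating study: G×E null calibration at proportions
0.4/0.4 with $n = 316$; power curves with a single causal marker explaining
0–0.15 of variance; the three-component weights 0.23/0.29/0.25 for
sample-size experiments; residual proportion defined as one minus everything
else. Every dataset is bit-reproducible from its recorded seed.

The generator does *not* produce linkage disequilibrium, realistic allele
frequency spectra, or pedigree structure. A green calibration test
establishes that the machinery is correct under the stated covariance
model, not that any real dataset satisfies that model.

## Numerical choices and degenerate inputs

* Triangular solves everywhere; explicit inverses only in test oracles.
* Vertex coordinates are snapped at $10^{-9}$ when deduplicating search
  vertices, and rotation tolerates coordinate dust down to $-10^{-10}$.
* Markers collinear with the covariates (or constant) yield NA-flagged rows
  with a reason, never an exception that aborts a scan; `RSS = 0` yields a
  flagged $-\infty$ log-likelihood.
* The LRT statistic is clamped at zero; an alternative below the null by
  more than $10^{-6}$ (possible with a coarse grid) records a warning flag.
* Genomic control is reporting-only: stored p-values are never silently
  corrected, $\lambda$ is always reported alongside.
* Credible sets are the smallest vertex set covering the requested mass;
  with a coarse grid their *boundaries* are unreliable even though means
  and joint densities are accurate — the docs repeat this caveat.
* Continuous priors are discretized either by nearest-vertex assignment of
  Monte-Carlo draws (default, seed recorded; out-of-simplex draws are
  renormalized and counted) or by a midpoint density rule; the two differ
  at simplex boundaries and no attempt is made to decide which is "right".

## Design decisions that were genuinely open

* The restricted-likelihood profile is assembled by substituting
  $\hat\sigma^2_{\mathrm{REML}} = \mathrm{RSS}/(n-c-p)$; validated against a
  dense joint-maximization oracle rather than derived from a reference.
* The null-model estimate $\hat h_0^2$ uses grid refinement instead of a
  generic optimizer: self-contained, deterministic, and consistent with the
  grid philosophy; accuracy is one part in 40 per coordinate by default.
* For G×E scans the repeated-accession (line) effect, when used, occupies
  its own grid dimension rather than being folded into the additive term.
* Marker dosages are used as-is (no standardization) so effect sizes stay
  on the dosage scale; a `standardize` flag exists.
* Multiple testing is Bonferroni at a configurable genome-wide level
  (default threshold $2\times 10^{-7}$); no FDR machinery.
* Per-trait variance-component scans reuse rotations across traits exactly
  as marker scans reuse them across markers.

## Known limitations

* Grid cost grows combinatorially with $L$; beyond ~6–8 random effects a
  grid search is impractical (as is every general-purpose alternative).
* REML/posterior point estimates are only as precise as the grid step; this
  matters little for fixed-effect tests (the acceptance suite shows
  step-0.01 p-values match a continuous optimizer to 0.05 in $-\log_{10}p$)
  but caps the precision of variance-component estimates. At realistic
  sample sizes the REML sampling error (~0.1 per proportion at $n = 800$)
  dwarfs a 0.05 grid step anyway.
* Gaussian traits only; generalized mixed models re-weight observations
  iteratively and cannot be discretized this way. Correlated random effects
  are out of scope.
* The fast searches can lock onto local maxima when the surface is
  multimodal (rare, but real); the diagnostics flag quantifies this.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
G  <- simulate_structured_genotypes(n = 80, p = 500, blocks = 8, seed = 3)
K  <- additive_kinship(G)
y  <- simulate_phenotype(list(K), proportions = 0.4, seed = 4)$y
spec <- model_spec(y, random_effects = list(A = K))
tab <- run_association_scan(spec, G, scan_config("wald", "fast", m = 100))
head(tab[order(tab$p), c("marker", "beta", "F", "p", "h2_1", "h2_e")])
```

The same pipeline is exposed on the command line via `cli_main()`
(subcommands `simulate`, `kinship`, `scan`, `vc`).
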