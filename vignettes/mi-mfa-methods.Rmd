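---
title: "Methods: multiple imputation for multiple factor analysis with missing rows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple imputation for multiple factor analysis with missing rows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-omics integration studies measure several tables of quantitative
variables (transcripts, proteins, clinical markers, ...) on one set of
individuals. In practice some individuals are absent from some tables —
a sample failed QC, a patient skipped a visit — producing *missing rows*:
an individual's entire record in one table is gone while its records in the
other tables are intact. Most multi-table ordination methods require
complete data, and deleting every individual with any missing row can
discard a large share of an expensive experiment.

`mimfa` estimates the multiple factor analysis (MFA) configuration — the
coordinates of individuals on the leading components of a joint analysis —
despite missing rows, and attaches an explicit uncertainty region to every
individual. The aim is not to reconstruct the missing measurements
themselves but to place the affected individuals, with honest uncertainty,
in the consensus ordination.

## Multiple factor analysis

Given J tables $K_1, \dots, K_J$ over the same I individuals, each table is
centered (and by default scaled to unit variance, population convention,
divisor $I$), its first PCA eigenvalue $\lambda_1^j$ is computed, and every
variable of table $j$ is weighted by $1/\sqrt{\lambda_1^j}$. A global PCA
(SVD with uniform row weights $1/I$) of the column-wise concatenation gives
the configuration $F$ (scores). The weighting removes each table's own
leading variance so that no single table can dominate the first global
dimension; after weighting, every table's first eigenvalue is exactly 1.

Whether variables should be standardized within tables is a genuine choice:
it is exposed as `preprocess_spec(scale_unit_variance = )` and defaults to
`TRUE`, the behaviour of the standard MFA implementations for quantitative
groups. Centering is not optional. Eigenvalues are reported on the
covariance scale (singular value squared over $I$). A deterministic sign
convention (the loading of largest absolute value is made positive,
earliest column on ties) makes results platform-stable.

## The MI-MFA procedure

1. **Multiple hot-deck imputation.** Donor pools are formed per
   (table, stratum): the donors for a missing row are the observed
   individuals of the same stratum in the same table; recipients of one
   stratum share one pool. Each completion draws, for every recipient
   independently, one donor with replacement and copies its row verbatim.
   $M$ pairwise-distinct completions are kept (distinctness is enforced at
   the level of assignment maps, by rejection with a cap of $100M$ draws;
   duplicates are simply redrawn). Because imputed rows are copies of
   observed rows, completions are always realistic, and no distributional
   model is needed — which is what makes the approach workable for tables
   with thousands of variables.
2. **MFA per completion**, giving configurations $F_1, \dots, F_M$.
3. **STATIS combination.** Averaging configurations directly is unsafe
   (components can be reflected, rotated or dilated between completions),
   so the cross-product matrices $W_m = F_m F_m^T$ are combined instead.
   The RV-coefficient matrix
   $R_{jk} = \mathrm{trace}(W_j^T W_k) / \sqrt{\mathrm{trace}(W_j^T W_j)\,\mathrm{trace}(W_k^T W_k)}$
   is built; its leading eigenvector (nonnegative by Perron–Frobenius,
   sign-fixed to a positive sum, normalized to sum 1) supplies weights
   $\alpha_m$; and the compromise $W_c = \sum_m \alpha_m W_m$ is
   eigendecomposed. Compromise scores are eigenvectors scaled by the square
   roots of eigenvalues (principal coordinates). Outlying configurations
   receive weights near zero, which gives the combination its robustness.

Configurations enter STATIS at full rank: $W_m$ is then exactly the Gram
matrix of the weighted, preprocessed data of completion $m$, and the
compromise does not depend on the requested dimensionality $d$ — $d$ only
selects how many compromise dimensions are reported, so the $d$-dimensional
solution is nested inside the $(d+1)$-dimensional one. The default
$d = 2$ matches standard two-dimensional configuration comparisons.

**Trajectories.** Each configuration is projected onto the compromise axes
as $W_m U_c \Lambda_c^{-1/2}$ (the classical supplementary projection),
giving $M$ points per individual; the $\alpha$-weighted average of the
trajectories reproduces the compromise exactly.

## How many imputations?

The number of distinct completions is
$M_{total} = \prod_{\text{recipients}} |\text{pool}|$, the product over
recipients of their donor-pool sizes — each recipient draws independently,
so assignment maps multiply. (Counts above $2^{53}$ are returned as
doubles, hence rounded.) If $M_{total} \le 50$, all completions are used.
Otherwise `choose_num_imputations()` grows nested collections of
completions across levels $M_0 < M_1 < \cdots$, computes the compromise at
each level, and tracks the RV coefficient between compromises at
consecutive levels over $N$ replicate collections. Nesting is obtained for
free: sub-seeds are derived per draw attempt from the master seed, so the
first $m$ completions never depend on how many are requested. Convergence
is declared when successive mean RVs differ by less than `tol`; the default
`tol = 0.01` targets two-decimal stability, matching the precision at
which RV coefficients are usually read. The criterion itself is a
documented choice, not an estimate.

## Uncertainty regions

For each individual, the $M$ trajectory points in the first two compromise
dimensions are summarized by

* a **95% confidence ellipse**: normal-theory, $\{x : (x-\mu)^T
  \Sigma^{-1} (x-\mu) \le q\}$ with $\mu$ the point mean, $\Sigma$ the
  sample covariance and $q$ the 0.95 quantile of $\chi^2_2$; area
  $\pi q \sqrt{\det \Sigma}$. (Peeling-based ellipses would be an
  alternative; the normal-theory construction is the standard ordination
  practice and is what we document and test.)
* a **convex hull** of the $M$ points, with shoelace area.

Every individual gets a region — imputing one row perturbs the whole
configuration — but areas concentrate on the imputed individuals, and they
grow with the missingness rate. The regions are visual uncertainty guides;
no formal coverage claim about the unknown true configuration is made.
With $M < 3$ the ellipse is skipped (covariance undefined or singular) and
the hull is still reported; singular covariances yield area 0 with a
warning.

## Baselines and evaluation

* **MVI-MFA**: missing rows replaced by per-variable observed means, then
  MFA. Simple, and systematically distorts the configuration at higher
  missingness (mean-imputed individuals collapse toward the origin).
* **RI-MFA**: regularized iterative low-rank imputation. Missing cells are
  initialized with column means; then the weighted merged table is
  repeatedly fit by a rank-`ncp` SVD whose retained singular values are
  shrunk by the mean squared magnitude of the discarded ones
  ($d_k' = (d_k^2 - \bar\sigma^2)/d_k$), and missing cells are replaced by
  the reconstruction until the relative change falls below `tol` (default
  `1e-6`, cap 200 iterations). Preprocessing statistics and table weights
  are fixed at the initial fill, which makes `ncp = 0` reduce exactly to
  MVI-MFA and keeps the unregularized iteration monotone in the observed
  residual; the shrinkage itself can cause sub-`1e-4` relative
  fluctuations of that objective, which is why the monotonicity test
  carries that slack. Choosing `ncp` is known to be hard; when a reference
  configuration is available the benchmark selects it by maximizing the RV
  to that reference (`ncp_rule = "best"`). The rule is exposed — including
  a `"worst"` variant — because descriptions of this selection in the
  literature are ambiguous about the direction of optimization; maximizing
  similarity is the only reading consistent with RV being a similarity,
  and is our default.
* **Comparison protocol**: a complete dataset provides the true MFA
  configuration; rows are removed per scenario; each method's
  configuration is Procrustes-aligned (translation, rotation/reflection,
  isotropic scaling — via `vegan::procrustes`) to the truth and scored by
  the RV coefficient of centered score cross-products, which is invariant
  to exactly those similarity transforms (the alignment matters only for
  the per-individual divergence arrows, not for RV — an identity the test
  suite checks). Per-individual divergences (distances between aligned and
  true coordinates) are exported for arrow plots.

## The synthetic data generator

Real multi-omics benchmarks cannot ship with the package, so study designs
are emulated. `generate_multitable()` gives every stratum its own latent
factor with sparse Gaussian loadings on `prop_informative` (default 0.5)
of each table's variables; a measurement is `effect_size` times the
stratum's loading plus `N(0, noise_sd^2)` noise. Defaults
`effect_size = 2`, `noise_sd = 1` produce clearly separated strata with
realistic within-stratum scatter. High-dimensional random signatures are
nearly orthogonal, so stratum recoverability holds by construction — an
earlier design embedding all strata in a shared two-dimensional latent
space was rejected precisely because two strata could coincide there
regardless of effect size.

Two presets mirror the classical designs: `liver_synthetic()` (64
individuals, 8 balanced strata of 8, a 300-variable expression-like table
plus a 10-variable clinical-like table — the wide table deliberately scaled
down from thousands of transcripts; MFA results depend on the variable
space only through covariance structure, so width beyond a few hundred
variables adds runtime, not information) and `nci60_synthetic()` (60
individuals, 9 unequal strata of sizes 8, 6, 7, 6, 9, 8, 6, 2, 8, two
tables of 150 and 40 variables).

What the generator does **not** emulate: real correlation structure among
variables, heavy tails, batch effects, or informative (MAR/MNAR)
missingness — rows are always removed completely at random, as in the
evaluation protocol it supports. Passing tests therefore demonstrate the
mechanics and the comparative ordering of the methods under MCAR, not
performance on any particular real dataset.

Missing-row scenarios are expressed per (stratum, table). Removals within
a stratum are **disjoint** by default — an individual loses at most one
table — which is the reading under which the per-stratum case counts
$C(n, t_1)\,C(n-t_1, t_2)\cdots$ hold (all seven standard two-table values
56, 168, 168, 280, 420, 560, 280 for $n = 8$ are reproduced by this
formula, and the test suite checks them against exhaustive enumeration).
An individual is never left unobserved in every table; such a pattern is
redrawn (and rejected at load time by the data model, since it could not
act as a hot-deck recipient anywhere).

## Numerical choices and degenerate inputs

* Rank deficiency: requested dimensions beyond the numerical rank
  (tolerance `max(dim) * eps * d1`) are zero-padded with a warning, so
  downstream shapes stay stable.
* Zero-variance variables cannot be unit-scaled and raise an error naming
  the column.
* A complete dataset has exactly one completion: `run_mi_mfa()` forces
  `M = 1` with a message and the compromise equals the plain MFA
  configuration.
* All randomness flows from one master seed through deterministic
  sub-seeds (kept below $2^{31}$), so results are bit-reproducible and
  collections are nested across `M`.
* Configuration files are written at `%.17g` precision and round-trip
  doubles exactly.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
the liver-shaped design (64 individuals, 310 variables) with 20 replicates
per missingness scenario and $M = 30$ imputations; stability levels
$\{10, 20, 30\}$ with $N = 5$ replicates; and the NCI-60-shaped design
with $M = 50$ imputations at 10% and 30% missing rows. These sizes were
chosen to exercise every code path at the designs' true shapes while
keeping a full run in the minutes range on a single core.

## Known limitations

* Hot-deck pools require at least one observed donor per (table, stratum)
  with recipients; very small strata (e.g. a 2-member stratum losing a
  row) leave pools of size 1 and limit $M_{total}$.
* Only row-level missingness of quantitative variables is handled — no
  cell-level imputation, no categorical tables.
* The method assumes ignorable (MCAR/MAR) missingness; nothing here models
  informative missingness.
* Choice of the reported dimensionality $d$ is left to the user.
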