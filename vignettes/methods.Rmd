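---
title: "Methods: Dirichlet likelihood-ratio testing for compositional change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Dirichlet likelihood-ratio testing for compositional change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistics: the model
and its assumptions, the parameters that matter, the numerical choices,
and — importantly — what the goodness-of-fit check does and does not
establish.

## The model

A sample from a multitype population with $K$ classes is reduced to its
composition $x = (x_1, \dots, x_K)$, $\sum_k x_k = 1$, $x_k > 0$. We
model compositions as draws from a Dirichlet distribution with density

$$f(x;\alpha) = \frac{1}{B(\alpha)} \prod_{k=1}^K x_k^{\alpha_k - 1},
\qquad B(\alpha) = \frac{\prod_k \Gamma(\alpha_k)}{\Gamma(\alpha_0)},
\qquad \alpha_0 = \sum_k \alpha_k,$$

with mean $\mathbb{E}[X_k] = \alpha_k/\alpha_0$ and variance
$\alpha_k(\alpha_0-\alpha_k)/(\alpha_0^2(\alpha_0+1))$: $\alpha_0$ is a
concentration — scaling $\alpha$ leaves the mean composition unchanged
and shrinks the spread. Working with compositions rather than counts
makes the test applicable to qPCR arrays as well as sequencing data, and
gives every sample equal weight regardless of sequencing depth. The
price is the Dirichlet's assumptions: no free intra-class correlation
parameter (unlike the Dirichlet-multinomial) and strictly positive
support.

With $m$ environments and $n_i$ samples in environment $i$, the
hypotheses are nested: under $H_0$ one parametrisation governs
everything; under $H_1$ each environment has its own $\alpha_i$. The
statistic is $D = -2\log(L_0/L_1)$ from the maximized likelihoods, and
under $H_0$ it is asymptotically $\chi^2$ with $(m-1)K$ degrees of
freedom — the number of extra parameters under $H_1$.

## Chi-squared versus randomization

The $\chi^2$ reference needs the total sample count $n = \sum_i n_i$ to
dominate the dimensionality $mK$. When it does not, the $\chi^2$ tail is
anti-conservative — sometimes spectacularly so, and the package's
acceptance suite reproduces this (on null data with $n = 12$, $mK = 15$,
the $\chi^2$ test rejects several times more often than the nominal 5%,
while the randomization test stays calibrated). The randomization
reference permutes the environment labels across samples (preserving
group sizes), recomputes $D$ each time, and reports the exceedance
proportion. Choices made here:

* Ties count as exceedances ($D_{rand} \ge D_{obs}$) — conservative, and
  ties have probability zero in exact arithmetic.
* The observed labeling is *not* included as a trial; with full
  enumeration (available for small designs via `exhaustive = TRUE`) the
  observed assignment is one of the enumerated labelings, so the exact
  p-value is never below $1/\binom{n}{n_1 \cdots n_m}$.
* Zero exceedances are reported as the bound `p < 1/n_trials`, with the
  raw count stored.
* `recommend_method()` advises randomization when $n < 2\,mK$ (boundary
  inclusive for $\chi^2$). The factor 2 is a safety margin on the
  asymptotic requirement; the advisory never overrides an explicit
  method choice.
* Permutations on which a group's Dirichlet fit fails (degenerate
  resampled groups, possible at very small $n_i$) are redrawn and
  counted; a run aborts if failures exceed ten times the trial budget.

## Class inclusion rules

A single zero anywhere zeroes the whole likelihood, so before testing,
a class is kept only if it is strictly positive in every sample
(*ever-present*) and reaches `min_proportion` in at least one sample
(both criteria evaluated on the pooled, normalized table across all
environments). Everything else is summed into an aggregate class
(default label `"LRT other"`); if the aggregate is empty or still
carries a zero it is deleted and each row renormalized. Degrees of
freedom downstream always use the post-filter $K$, which is how
aggregation buys power: pooling $K'$ rare classes removes
$(m-1)(K'-1)$ parameters from the alternative.

Defaults: `min_proportion = 0` (no threshold); 0.01 is the conventional
field choice for compositional metagenomics and is what the examples
use. The escape hatch `zero_replacement` (≈1e-16) substitutes zeros and
renormalizes instead of filtering; it places enormous log-density mass
at the simplex boundary, so its use triggers a persistent warning that
results should be quoted with extreme caution. When both zero
replacement and ever-present filtering are requested, zero replacement
wins — retaining zero-bearing classes is its entire purpose. Whether
the original field tools renormalize after replacement is unclear; we
renormalize so the data stay on the simplex. Fewer than three surviving
classes is an error: the Dirichlet model used here is for $K > 2$.

## Estimation

The one-group MLE uses the classic fixed-point sweep
$\alpha_k \leftarrow \psi^{-1}(\psi(\alpha_0) + \overline{\log x_k})$,
with $\psi^{-1}$ computed by five Newton steps from the standard
piecewise initializer ($e^y + 0.5$ for $y \ge -2.22$, else
$-1/(y+\gamma)$), giving ~14-digit inversion accuracy. Initialization
is method of moments from the first class's mean and variance
($\alpha^0 = \bar m \cdot (\bar m_1(1-\bar m_1)/\bar v_1 - 1)$), falling
back to the all-ones vector when that variance is zero or the implied
concentration non-positive. Convergence is declared when the largest
relative parameter change drops below `tol = 1e-10`.

Numerical choices worth recording:

* `max_iter` defaults to 10000 sweeps. The iteration converges only
  linearly, and fits to two or three samples can legitimately need a
  few thousand sweeps at this tolerance; each sweep is a handful of
  digamma evaluations (compiled, see below), so the cap is cheap.
* The likelihood is unbounded when all samples coincide (a point mass);
  $\alpha_0$ then grows without limit. Two guards exist: an immediate
  error for exactly identical rows (where growth is only ~$K/2$ per
  sweep and a cap would take forever to trip) and a divergence cap
  $\alpha_0 > 10^8$ for near-identical data.
* All likelihood work is in log space via `lgamma`; no density product
  is ever formed, and $\chi^2$ tails are computed with
  `lower.tail = FALSE` so p-values down to ~1e-300 are representable.
* Nesting guarantees $\log L_1 \ge \log L_0$; the computed $D$ is
  clamped to zero only within $-10^{-9}$, and anything more negative is
  treated as a fit failure rather than silently truncated.
* The sweep itself is compiled (Rcpp): the test suite's calibration
  study runs ~200,000 fits, which is impractical at R call overhead.

## Goodness of fit, and an exact degeneracy worth knowing about

The check simulates $N$ replicate datasets with the observed geometry
($K$, $m$, $n_i$) from a stated parametrisation $\hat\alpha$, computes
the log-likelihood $T_0$ of $\hat\alpha$ on the observed data and $T_j$
on each simulated dataset (no per-simulation refit), and reports
$p = \#\{T_j < T_0\}/N$: if the model fits poorly the observed data are
unusually unlikely under it and $T_0$ lands in the lower tail.

Where $\hat\alpha$ comes from matters more than it first appears. The
Dirichlet is an exponential family with sufficient statistics
$\sum_j \log x_{jk}$, and the MLE matches their expectations exactly.
Consequently, **if $\hat\alpha$ is the MLE refit on the very data being
tested, $T_0$ equals the mean of the $T_j$ distribution identically** —
for well-fitting and grossly misfitting data alike — and the p-value
degenerates into a readout of the skewness of the $T_j$ distribution,
clustering near 0.5. (The same moment-matching argument applies in the
large-pilot limit to any parametrisation estimated from the same
data-generating process: mean-level discrepancies are invisible by
construction; only distributional-shape mismatch can register, and in
our experiments a strongly bimodal contamination moved the one-sided
rejection rate only to ~0.3–0.5.) The test suite asserts this identity
directly. Two practical consequences:

* `gof_test()`'s default (`model = "alt"`, refit per environment)
  reproduces the established field behaviour, and its p-values should
  be read accordingly: values near 0.5 mean "nothing detectably wrong
  in distribution shape", not a calibrated tail probability.
* For a calibrated check, supply the parametrisation independently of
  the tested data via `params` — e.g. fitted to pilot data, with the
  new data tested against it. Under the null (data truly drawn from
  the stated $\hat\alpha$) the p-value is then exactly uniform by
  exchangeability, and contamination of new data relative to a clean
  pilot model is detected with high power. The acceptance suite runs
  both protocols: uniformity within a Kolmogorov 99% band over 100
  replications, and >80% detection of a 50/50 mixture of
  well-separated Dirichlets against a clean-pilot model.

The strict inequality $T_j < T_0$ follows the counting definition;
$T_j = T_0$ has probability zero. `model = "null"` (single pooled fit)
is available by flag.

## Power analysis

For experimental design, assume $H_1$ with the per-environment MLEs
$\tilde\alpha$ of pilot data as the truth, simulate $n$ compositions per
environment, run the LRT, and count rejections at the chosen
significance (default 0.05) over `n_sims` simulated experiments
(default 500). The inner p-value method defaults to $\chi^2$ — a full
randomization inside every simulation is quadratic-cost and available
behind a flag with a reduced trial count. Simulations are seeded per
simulation index, shared across group sizes, so power curves use common
random numbers and are monotone in $n$ up to Monte-Carlo noise. Fits
that fail inside simulations are redrawn and counted; more than 10%
failures aborts the estimate (group sizes of 2–3 at the requested
tolerance can genuinely be too small to fit reliably). The whole
procedure is computationally expensive; expect minutes, not seconds,
at production settings.

Note the null-case subtlety: with identical $\tilde\alpha$ across
groups, estimated "power" equals the size of the *inner* test, so with
the $\chi^2$ inner method it only approximates the nominal significance
when the simulated $n$ is large relative to $mK$ — the acceptance suite
checks the null case at $n = 40$ per group for exactly this reason.

## The synthetic generator: what a green test establishes

`scenario()`/`generate_table()` produce tables from stated Dirichlet
worlds: known $\alpha_i$ per environment, optional 50/50 two-component
contamination (for misfit studies), and optional spliced rare classes
with stated maxima and zero positions (for filter tests). Generation is
deterministic given the scenario seed, down to the CSV bytes.
`survey_geometries()` reproduces the *shapes* of real resistome/
microbiome designs (8 treatments × 3 replicates × 8 ARG classes; a
3-season × 4-animal pilot; a 354-sample two-site survey) with synthetic
placeholder $\alpha$ values — they are geometry fixtures only.

What the generator does **not** emulate: intra-class correlation (the
data are exactly Dirichlet unless contaminated), sequencing/assignment
noise, detection-limit zeros in otherwise abundant classes, and
compositional structure induced by normalizing counts. A green
calibration or recovery test therefore establishes correctness of the
statistical machinery under its own model, not robustness to violations
of it — that is precisely what `gof_test()` is for on real data.

## Known limitations

* One environmental factor at a time; no multi-factor designs and no
  PERMANOVA-style distance decomposition.
* No Dirichlet-multinomial extension (abundance information and
  overdispersion are discarded with the counts).
* Randomization p-values have granularity $1/\texttt{n\_trials}$; the
  observed-labeling exclusion can shift p by about that much relative
  to implementations that include it.
* The goodness-of-fit degeneracy described above: with same-data
  refitting the check cannot, even in principle, flag mean-level model
  error.
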