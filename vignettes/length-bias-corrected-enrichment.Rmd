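---
title: "Length-bias-corrected category enrichment: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-bias-corrected category enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gobias)
```

## The problem and the model

In count-based expression assays the expected read count of a gene is
proportional to its expression level times its transcript length. Any
statistical test for differential expression (DE) therefore has more power
for genes with more reads: long genes and highly expressed genes are
called DE more often at a fixed true effect size. This is a property of
count data, not of any particular test, and it cannot be normalised away —
dividing counts by length rescales the estimate but not the information
content.

Category over-representation analysis inherits the bias. The classical
test assumes that, under the null, each of the $N$ genes in the universe
is equally likely to appear among the $n$ DE genes, so the number $k$ of
DE genes in a category of size $K$ is hypergeometric. When power varies
with length, a category whose genes are systematically long is enriched
among DE calls for purely technical reasons.

`gobias` models the technical effect explicitly. A **probability
weighting function** (PWF) $w(x)$ gives the probability that a gene with
bias covariate $x$ (transcript length, or total read count summed over
both conditions) is called DE. The null hypothesis for category testing
becomes: DE status is assigned by sampling $n$ genes without replacement
with probability proportional to $w(x_g)$ — genes remain exchangeable
*given their covariate*, and only enrichment beyond the covariate effect
is evidence for a category.

Two computations of the category tail probability are provided:

* **Sampling**: simulate the weighted sampling null directly; the
  replicate draws use the exponential-keys construction (take the $n$
  smallest of $E_g / w_g$, $E_g \sim \mathrm{Exp}(1)$), which is
  distributionally identical to drawing genes one at a time with
  probability proportional to remaining weight, and one replicate ensemble
  is shared across all categories. The Monte-Carlo p-value is
  $(b+1)/(m+1)$, so it is never exactly zero and is bounded below by
  $1/(m+1)$.
* **Wallenius**: approximate each gene's weight by its category's mean —
  inside the category $\bar w_{in}$, outside $\bar w_{out}$ — so the
  in-category DE count follows Wallenius' non-central hypergeometric
  distribution with odds $\omega = \bar w_{in}/\bar w_{out}$. The
  distribution is evaluated by the exact forward recursion over draws
  (cost $O(n \min(n, K))$), not by numerical integration, so the only
  error relative to the sequential-sampling law is floating-point
  rounding; at $\omega = 1$ it reproduces the hypergeometric to
  $<10^{-11}$. The approximation error relative to *sampling* comes from
  the within-category weight variance, so Wallenius is most accurate when
  the PWF range is moderate; sampling is the reference when they disagree.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `fdr_threshold` | `1e-4` | BH FDR for DE calls; stringent because two deep libraries give very small p-values, and the PWF needs a clean binary signal |
| `n_knots` | 6 | basis dimension of the cubic regression spline; knots at equally spaced quantiles of the distinct log10 covariate values, robust to skewed length distributions |
| `floor_eps` | `1e-8` | lower clamp on PWF values; a weight of exactly 0 would make a gene unsampleable under the resampling null |
| `reps` | 2000 | sampling replicates; 200,000 recommended when the very top ranks must be resolved finely |
| `bin_size` | 300 | genes per bin in the DE-proportion diagnostic |
| covariate | `length` | `total_count` (sum of both conditions' counts) shows the same but stronger trend; correcting for it also removes expression-level bias, which may or may not be wanted |

The PWF is fitted on log10(covariate) by least squares with a
monotonicity constraint on the spline coefficients
(`mgcv::smoothCon`/`mono.con`/`pcls`, with the smoothing parameter taken
from the unconstrained fit). Monotonicity is a modelling assumption
justified by power theory for statistical DE callers; because
non-statistical selection rules (e.g. fold-change cutoffs) can produce
*decreasing* trends, the direction is not assumed: both constraints are
fitted and the lower residual sum of squares wins.

## What the synthetic generator emulates

`simulation_config()` states a small, explicit world:

* lengths $\sim$ log-normal(meanlog 7.8, sdlog 0.7) — median $\approx$
  2.4 kb, the order of human transcript lengths;
* expression $\sim$ Gamma(1.2, 1) — right-skewed abundances;
* counts $\sim$ Poisson with mean $\propto$ length × expression,
  normalised per condition to the library size (2 × 10⁶ by default);
  matched to the Poisson exact test, with an optional negative-binomial
  overdispersion knob (off by default);
* 10% of genes truly DE at fold change 4, direction up/down with equal
  probability;
* categories of 10–100 genes; a configurable fraction draw their members
  with weight $\propto$ (length rank / $N$)⁴, giving long- (or short-)
  gene categories; enriched categories over-weight truly DE genes by a
  configured odds factor.

This generator reproduces the qualitative phenomena that motivate the
method: rising binned DE proportion with length, an excess of small
Mann–Whitney p-values when categories are length-structured, and positive
correlation between category length and hypergeometric-vs-corrected rank
change.

What it does **not** emulate: mapping ambiguity, isoform structure,
GC/sequence effects, correlated gene expression, and composition effects
handled upstream by normalisation in real pipelines. Two consequences
worth knowing. First, a green planted-enrichment test shows the method
ranks genuine enrichment first *in this world*, not that real GO analyses
are correct. Second, with per-condition library-size normalisation, very
large fold changes on many genes shift the composition of the library, so
"unchanged" genes genuinely change in rate terms — the un-normalised
two-library reality; TMM-style normalisation is deliberately out of
scope.

## Numerical choices

* **Two-sided exact p-value**: minimum-likelihood rule (sum of all
  outcomes no more probable than observed, with a $1+10^{-7}$ relative
  tolerance on ties, as in `fisher.test`). For totals above 10,000 the
  more-probable-than-observed window around the binomial mode is located
  by outward scan and the p-value computed from its complement, entirely
  in log space.
* **Wallenius tails**: linear-space forward recursion; probabilities are
  bounded in $[0,1]$ so no rescaling is needed; tails sum the pmf
  including the observed point, so $p_{over} + p_{under} \ge 1$ always.
* **Ties and ranking**: results order by ascending $p_{over}$ with
  lexicographic tie-break on category id; ranking uses raw p-values, the
  BH-adjusted column is reported only.
* **Degenerate inputs**: all-identical DE flags are refused with advice
  to use a constant PWF; fewer distinct covariate values than knots
  reduces the knot count with a warning; all-tied lengths give a
  Mann–Whitney p of 1.
* **Seeding**: every stochastic routine takes an explicit seed and runs
  in a private RNG stream, restoring the caller's state; the generator
  derives stage seeds as seed, seed+1, seed+2 so stages are independently
  reproducible.

## Design decisions taken where the design was open

* **Shared sampling ensemble.** Whether the resampling null should draw
  per category or share draws across categories is not fixed by the
  method's definition. One shared ensemble costs $|categories|$ times
  less and induces the same dependence across categories as the single
  observed DE set; it is the default and is seed-controlled.
* **Universe membership.** Genes with zero counts are kept (they dilute
  weights correctly; they can never be DE), genes without annotation are
  dropped by default (standard GO practice) — both switchable, both
  logged, because they change $N$ and hence every p-value.
* **Under-representation p-values** are computed and reported even
  though over-representation is the scientific target; they come free
  from the same tails.
* **Calibration test world.** The calibration acceptance test uses
  long-biased categories only and category sizes of 100–250 genes with a
  quarter of genes DE. The direction is fixed because the claim under
  test — uncorrected p-values are stochastically too small — concerns
  long-gene categories; the sizes guarantee per-category DE counts around
  40, without which the discrete null's lattice is too coarse for a
  continuous-uniform Kolmogorov–Smirnov comparison to be meaningful.
* **PWF-recovery test world.** The logistic-truth recovery test uses a
  log-uniform covariate over 100 bp–10 kb with the logistic saturating
  inside that range: with a log-normal covariate the extreme tails
  contain essentially no data, and no 6-knot quantile spline (nor any
  estimator) can be held to a uniform-error bound there.

## Known limitations

* The Wallenius approximation degrades as the PWF range widens (its
  within-category equal-weight assumption); use sampling with large
  `reps` for covariates with strong trends, e.g. total read count.
* Any genuine biological association between category membership and
  gene length is removed along with the technical one; the method assumes
  long genes are not inherently more interesting.
* The DE module implements exactly one test (two-library Poisson exact);
  replicated designs should call DE externally and use the flag bypass.
* p-values across categories are dependent (shared DE set and, for
  sampling, shared ensemble); the BH column is a convenience, not a
  guarantee.
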