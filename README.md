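# gobias

Gene category over-representation analysis for count-based expression data
(bulk or single-cell RNA-seq and related tag-counting assays), correcting
for the **selection bias** by which genes with more reads — longer genes
and more highly expressed genes — have more statistical power to be called
differentially expressed (DE).

## Who this is for

Anyone running a GO-term / pathway / gene-set over-representation test on a
DE gene list derived from read counts. The standard test assumes every gene
is equally likely to be DE under the null, so the in-category DE count
follows a hypergeometric distribution (Fisher's exact test). Count data
violate that assumption: power grows with read count, so categories full of
long or highly expressed genes look enriched even with no biology behind
it. `gobias` replaces the biased null with one that knows each gene's
propensity to be called DE.

## The method

Three steps, each usable on its own:

1. **Call DE genes.** A Poisson exact test between two libraries:
   conditional on the total `s = y1 + y2`, `y1 ~ Binomial(s, M1/(M1+M2))`
   under equal rates; two-sided p-value by the minimum-likelihood rule,
   then Benjamini–Hochberg FDR (default threshold `1e-4`). Any external DE
   caller can be substituted via binary flags.
2. **Fit the probability weighting function (PWF).** A monotone cubic
   regression spline (6 knots, constrained least squares via `mgcv::pcls`)
   of the binary DE indicator on log10 of a bias covariate — transcript
   length or total read count — giving each gene's probability `w_g` of
   being called DE. Direction (increasing/decreasing) is chosen by residual
   fit.
3. **Test each category against the weighted null.** Either
   * *sampling*: repeatedly draw `n_DE` genes without replacement with
     probability proportional to remaining `w_g`, count in-category hits,
     and take the add-one Monte-Carlo tail; or
   * *wallenius*: approximate the same null analytically with the
     Wallenius non-central hypergeometric distribution using the
     mean-weight odds `ω = mean(w in category) / mean(w outside)`; at
     `ω = 1` it reduces exactly to the hypergeometric.

   For a category with `K` of `N` genes and `k` of `n` DE genes,
   `p_over = P(X ≥ k)` under the chosen null.

## Worked example

Simulate a 5,000-gene experiment with length-biased categories and one
genuinely enriched category (`cat0042`, enrichment odds 6), then analyse
it:

```r
library(gobias)
cfg <- simulation_config(n_genes = 5000, n_categories = 100,
                         length_bias_strength = 0.4,
                         enriched_categories = c(cat0042 = 6), seed = 101)
sim <- simulate_dataset(cfg)
tab <- call_de(sim$table, fdr_threshold = 1e-4)
pwf <- fit_pwf(tab$length_bp, tab$de_flag)
tab$pwf_weight <- evaluate_pwf(pwf, tab$length_bp)
res <- test_categories(tab, sim$map, method = "wallenius")
head(res, 5)
```

Output (abridged):

```
DE genes: 522 of 5000
pwf: monotone increasing cubic spline in log10(length), 6 knots
  fitted on 5000 genes (522 DE), log10-covariate range [2.38, 4.46]
  category_id n_category n_de_in_category  odds   p_over fdr_over rank
1     cat0042         53               19 0.986 5.35e-07 5.35e-05    1
2     cat0020         87               15 0.984 3.03e-02 9.83e-01    2
3     cat0034         81               14 1.010 4.17e-02 9.83e-01    3
```

The planted category ranks first with `p_over = 5.4e-07`; its `odds` near
1 says its genes are length-typical, so its signal survives the bias
correction. Every other category's corrected p-value is consistent with
the null (`fdr_over ≈ 1`). The per-category length-bias diagnostic
(`category_length_bias_test`, a two-sided Mann–Whitney U of in-category vs
out-of-category lengths) flags 34 of the 100 categories as
length-structured (p < 0.01) in this simulation — exactly the situation in
which the uncorrected hypergeometric test cannot be trusted.

## Command line

An executable script is installed at `inst/cli/gobias`:

```sh
gobias simulate --n-genes 5000 --length-bias 0.4 --seed 1 --out-prefix sim
gobias run --counts sim_counts.tsv --lengths sim_lengths.tsv \
           --categories sim_categories.tsv --method wallenius --outdir out
gobias diagnose --lengths sim_lengths.tsv --categories sim_categories.tsv
```

Subcommands: `simulate`, `de`, `pwf`, `enrich`, `diagnose`, `compare`,
`run`. All output TSVs carry a `#` comment header recording tool version,
seed, method and parameters.

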