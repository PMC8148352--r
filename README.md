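# tdfe — tensor-decomposition-based unsupervised feature extraction for mitotic bookmarks

`tdfe` finds genomic regions whose histone-modification pattern across the
cell cycle looks like a *mitotic bookmark*: the activity mark H3K27ac drops
in prometaphase and returns in anaphase/telophase (transcription
reactivation), while H3K4me1 and H3K4me3 stay constant through all phases
and above the Input control (the persistent mark that "remembers" where
transcription should resume). It is aimed at analysts with multi-condition
ChIP-seq coverage — two cell lines, several marks, three cell-cycle
phases, replicates — where per-region testing across so many small groups
is hopeless.

## Method

Coverage is summed over fixed 25,000-bp genome tiles and arranged as a
five-mode tensor `x[i, j, k, m, s]` (region x cell line x mark x phase x
replicate), each condition slice normalized to `sum_i x = 0`,
`sum_i x^2 = N`. Higher-order SVD decomposes it as

    x[ijkms] = sum G(l1, l2, l3, l4, l5) u[l1,j] u[l2,k] u[l3,m] u[l4,s] u[l5,i]

with orthonormal factor matrices per mode and core tensor `G`. The fit
selects the condition components with the biologically required shapes —
constant across cell lines (`l1`) and replicates (`l4`), a reactivation
profile over phases (`l3`), mark components distinct from Input (`l2`) —
then scores region components by `S(l5) = sum_{l2} |G(l1, l2, l3, l4, l5)|^alpha`
and takes the maximizer. Each region gets a chi-squared P-value for
`(u[l5,i] / sigma)^2` under a Gaussian null (1 df), Benjamini–Hochberg
corrected; adjusted `P < 0.01` selects the bookmark candidates. Six Welch
t-tests then verify the reactivation/bookmark pattern inside the selected
set, and annotation helpers map regions to gene symbols and integrate
peak-call sets. See the methods vignette
(`vignettes/bookmark-extraction.Rmd`) for assumptions and tuning.

## Worked example

```r
library(tdfe)

sim <- simulate_tensor(sim_config(seed = 1))   # 2000 regions, 100 planted
fit <- tdfe(sim$tensor)
fit
#> Tensor-decomposition-based unsupervised feature extraction
#>
#> Call: tdfe(x = sim$tensor)
#> Components: cell line l1 = 1, marks l2 = {1,2,3,4}, phase l3 = 2, replicate l4 = 1, region l5 = 1
#> Regions: 2000 total, 87 selected at adjusted P < 0.01

x <- normalize_tensor(sim$tensor)
reactivation_tests(x, fit$selection$selected)
#> Reactivation/bookmark t-tests over 87 selected regions (Welch)
#>
#>  test alternative         p                                description
#>     1     greater 9.87e-198 H3K27ac reactivation (int & ana/tel > pro)
#>     2   two.sided  9.02e-01     H3K4me1 bookmark (int & ana/tel = pro)
#>     3   two.sided  9.17e-01     H3K4me3 bookmark (int & ana/tel = pro)
#>     4   two.sided  1.82e-01     Input as control (int & ana/tel = pro)
#>     5     greater 1.35e-241                            H3K4me1 > Input
#>     6     greater 1.80e-201                            H3K4me3 > Input
```

All 87 selected regions are planted ones (precision 1.00, recall 0.87).
The fit found the constant cell-line and replicate components (`l1 = l4 =
1`), the reactivation-shaped phase component (`l3 = 2`), kept all four mark
components (none is Input-like on this synthetic background), and the
t-tests show exactly the bookmark signature: reactivation and
above-background methylation highly significant, no phase difference for
the methylation marks or Input.

From files instead of memory:

```r
out <- simulate_coverage(sim_config(seed = 1), "simdata")   # 48 bedGraphs + manifest
res <- run_pipeline(out$manifest, out$chrom_sizes, out_dir = "results_run")
```

or from a shell, via the thin CLI installed with the package:

```sh
Rscript $(Rscript -e 'cat(find.package("tdfe"))')/exec/tdfe simulate --out simdata --seed 1
Rscript $(Rscript -e 'cat(find.package("tdfe"))')/exec/tdfe run \
  --manifest simdata/manifest.tsv --chrom-sizes simdata/genome.chrom.sizes --out results_run
```

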