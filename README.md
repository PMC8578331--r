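# speccorr

Off-target specificity correction for CRISPR-Cas9 essentiality screens.

In pooled viability screens, guide RNAs that cut the genome at unintended
sites are depleted by DNA-damage toxicity regardless of which gene they
target, which inflates gene-essentiality calls. speccorr removes that
confounder instead of discarding the guides. It models each guide's measured
depletion as

    D_i = G_i + O_i

— the sum of the gene-knockout effect `G_i` and an off-target effect `O_i` —
and estimates `O_i` per screen from five sequence-derived covariates: the
guide's CFD-aggregated specificity score `s` and its counts of genomic
target sites at Hamming distance 0–3 (`H0`–`H3`). The estimator is a
multivariate adaptive regression spline (intercept, hinge functions
`max(0, ±(x − t))`, and hinge products), grown by a greedy forward pass and
pruned back to the minimum-GCV sub-model, with a 90/10 train/test split per
screen. Corrected depletion values are

    D_i − Ô(x_i) + Ô(x_ref),   x_ref = (s=1, H0=1, H1=H2=H3=0),

so perfectly specific guides are untouched.

The package contains the full chain: an exact trie-backed enumerator of all
NGG target sites within Hamming distance 3 (with an independent brute-force
oracle used by the tests), CFD-style specificity scoring with injectable
penalty tables, screen preprocessing (30-read plasmid filter, median-ratio
normalization, replicate-mean log2 fold changes), the spline engine, a
Bayes-factor essentiality benchmark (precision–recall, recall at 5% FDR,
matched-hit false positives, distortion), and a synthetic-screen generator
with planted ground truth so everything is verifiable offline. The shipped
CFD tables are labelled synthetic stand-ins; inject the published constants
via `cfd_penalty_table()` for real libraries.

## Worked example

A fully synthetic screen: 40 genes × 4 guides on a 60 kb genome with planted
repeat families, essential-gene effects of −2, and off-target toxicity
`O = −0.5 (1/s − 1)`:

```r
library(speccorr)

sim  <- simulate_crispr_screen(seed = 5, n_genes = 40, guides_per_gene = 4,
                               genome_length = 6e4)
prep <- prepare_screen(sim$counts)
prof <- sim$profiles[match(prep$guide_id, sim$profiles$guide_id), ]
corr <- correct_screen(prof, prep$logfc_mean, seed = 5)
print(corr$model)
#> Adaptive regression spline: 2 basis functions (GCV 1.141, train RMSE 1.042, test RMSE 1.025)
#>   -0.15235 * (intercept)
#>   -23.166 * h(0.294204 - specificity)
#>   covariates used: specificity
```

The model found what was planted: depletion grows steeply once the
specificity score drops below ~0.29, and the other covariates add nothing.
Promiscuous guides are pulled back toward their gene effect while specific
guides are untouched:

```r
head(corr$results[corr$results$H0 > 1, c("guide_id", "gene", "specificity",
                                         "H0", "logfc_observed", "logfc_corrected")], 2)
#>   guide_id     gene specificity H0 logfc_observed logfc_corrected
#> 5   g00005 gene0002   0.2127334  4     -2.8011384      -0.9137471
#> 6   g00006 gene0002   0.1821494  4     -3.8915723      -1.2956574
```

Both guides target the non-essential `gene0002`; uncorrected they looked
like a strong knockout effect. Benchmarking against the generator's gold
standard shows the gene-level consequence:

```r
benchmark_screen(corr$results$logfc_observed, corr$results$logfc_corrected,
                 prof$gene, sim$gold, seed = 5)
#> Benchmark report (FDR 0.05):
#>   observed   recall 0.750 (BF threshold 12.70), AUC 0.978
#>   corrected  recall 1.000 (BF threshold 13.34), AUC 1.000
#>   distortion mean 0.2795, median 0.0000; separation delta +0.2115
```

Recall of gold-standard essential genes at 5% FDR rises from 0.75 to 1.00
after correction; the median guide is untouched (median distortion 0). The
binned specificity–depletion correlation drops from 0.77 to 0.29
(`specificity_depletion_cor()`).

A command-line wrapper with `index`, `annotate`, `correct`, `simulate` and
`evaluate` subcommands is provided in `inst/scripts/csc.R`; an optional
RMSE gate (`--rmse-gate`, `rmse_threshold =`) suppresses correction for
screens whose model generalizes poorly while still emitting the
specificity annotations.

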