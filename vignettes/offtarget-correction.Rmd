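---
title: "Modeling and removing off-target depletion in CRISPR essentiality screens"
author: "speccorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and removing off-target depletion in CRISPR essentiality screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccorr)
```

## The problem

In a pooled CRISPR-Cas9 viability screen, each guide RNA (gRNA) directs Cas9
to a 19- or 20-nt protospacer adjacent to an NGG PAM. Cells carrying guides
that disrupt essential genes drop out of the population, so the log2 fold
change (logFC) of a guide's abundance between the initial plasmid pool and
the post-screen samples reads out gene fitness. Cas9, however, also cleaves
*off-target* sites that differ from the guide by a few substitutions. Each
cut is a double-strand break, and the resulting DNA-damage toxicity depletes
promiscuous guides regardless of the gene they were designed against. In
gene-level analyses this manifests as inflated essentiality calls — false
positives concentrated on genes that happen to be targeted by unspecific
guides.

speccorr takes the decomposition

$$D_i = G_i + O_i$$

as its working model: the measured depletion $D_i$ of guide $i$ is the sum of
the knockout effect $G_i$ of its target gene and an off-target effect $O_i$
that depends only on the guide's match profile against the genome. The
package estimates $\hat O_i$ from sequence-derived covariates and returns
$D_i - \hat O_i(x_i) + \hat O_i(x_{\mathrm{ref}})$, leaving $G_i$ in place.

## Off-target enumeration

`build_target_index()` records every genomic k-mer that sits immediately 5'
of a PAM match, on both strands, keyed on the protospacer sequence
(reverse-strand sites are stored as the reverse complement of the genomic
window, i.e. always 5'→3' on the cutting strand). Queries traverse the
sorted key set as a prefix tree with a bounded-mismatch depth-first search,
so `hamming_neighbors()` returns *exactly* the sites within Hamming distance
3 of a guide — no seed heuristics, no alignment scores. Substitutions only:
bulged (insertion/deletion) alignments rarely preserve Cas9 activity and are
deliberately out of scope.

Choices that matter:

* **PAM set** defaults to NGG, the SpCas9 motif; it is configurable
  (`pam_patterns`) for relaxed-PAM analyses, but non-canonical PAMs are not
  enumerated by default.
* **Ambiguity**: windows containing non-ACGT characters are skipped
  entirely, matching the exact-match semantics of the index. There is no
  IUPAC expansion.
* **Alternative contigs** can be excluded by a configurable name pattern
  (default `"_alt"`). Alt haplotypes duplicate primary sequence and would
  otherwise inflate every neighbor count.
* **Coordinates** are 0-based half-open with the protospacer start reported
  on the + strand, so BED export round-trips without arithmetic.

`brute_force_site_scan()` re-implements the same contract as a per-guide
sliding-window scan that shares no code or state with the index. It exists
to make exhaustiveness *testable*: the suite asserts set-equality between
both paths on dozens of random genomes, including a 2 Mb one.

## Specificity scoring

Each enumerated site is scored with a CFD-style penalty product: the
probability that Cas9 cuts a mismatched site is modeled as the product over
mismatched positions of a position- and identity-specific penalty, times a
PAM penalty. A guide's specificity score aggregates its entire neighborhood:

$$s = \frac{1}{\sum_{\text{sites}} \mathrm{CFD}},$$

so a guide whose only site is its intended target scores exactly 1, a guide
with two perfect targets scores 0.5, and the score decays toward 0 as
off-target cutting mass accumulates. This reciprocal-sum aggregation is the
unique simple form consistent with those endpoints; we adopt it as a
compatibility assumption and document it prominently because the upstream
literature defines the aggregation in a separate reference.

Guides with no perfect genomic target have no defined score; they are
flagged (`no_perfect_target` / `not_in_index`) and propagated as missing —
never as 0, which would fake maximal promiscuity.

The packaged penalty tables
(`inst/extdata/cfd_*_penalties_synthetic.tsv`) are **synthetic stand-ins**:
deterministic values with the qualitative structure of empirical CFD
constants (penalties fall from ~0.94 PAM-distal to ~0.02 PAM-proximal;
transitions are better tolerated than transversions; NGG PAMs score 1). All
functions accept user-supplied tables through `cfd_penalty_table()`; for
production analyses of real libraries the published constants should be
injected. Every test in the package injects controlled tables, so no result
depends on the shipped values. 19-nt guides are scored by anchoring to the
PAM-proximal 19 positions of the 20-position table; the score is known to be
weakly informative for 19-mer designs, which is precisely why the model
below is free to ignore it.

## Preprocessing

`prepare_screen()` follows the standard pipeline in a fixed order: (1) drop
guides with fewer than 30 plasmid reads (strict `<`); (2) joint median-ratio
normalization of plasmid and all replicates — size factor = median over
guides of count / geometric-mean across samples, rescaled to geometric mean
1 so the operation is idempotent; (3) per-replicate
`log2((post + 1)/(plasmid + 1))` with the arithmetic replicate mean as the
guide's depletion value. The pseudocount of 1 read-equivalent (applied after
normalization) is our choice where the upstream procedure is silent; it is
recorded in the output attributes. Normalizing plasmid and replicates
jointly (one size-factor fit) rather than pairwise is likewise an assumption
we flag. z-scores (population-SD convention) are emitted for plotting only;
the model always regresses raw mean logFC.

Median-ratio normalization assumes most guides are unchanged. In screens
where a large fraction of the library is depleted the pseudo-reference
shifts and all logFCs move by a common constant; this affects absolute
Bayes-factor values but not guide ranking, and the correction is invariant
to it (a constant is absorbed by the model intercept).

## The off-target model

The five covariates are $x = (s, H_0, H_1, H_2, H_3)$: the specificity score
and the neighbor counts at Hamming distance 0–3. Per screen, mean logFC is
regressed on $x$ with a multivariate adaptive regression spline implemented
from scratch in this package:

$$\hat O(x) = \sum_{j=1}^{J} C_j B_j(x),$$

where each basis function $B_j$ is 1 (intercept), a hinge
$\max(0, \pm(x_v - t))$, or a product of hinges in distinct covariates.

* **Forward pass**: starting from the intercept, each step adds the mirrored
  hinge pair (parent basis × new hinge) with the largest OLS
  residual-sum-of-squares reduction, refitting all coefficients after every
  addition; it stops at `max_terms` (default 21) or when the relative MSE
  improvement falls below `1e-4`.
* **Backward pass**: terms are deleted one at a time (least RSS increase
  first, mirrored-pair members independently), and the sub-model minimizing
  generalized cross-validation is returned:
  $\mathrm{GCV} = (RSS/n) / (1 - C(m)/n)^2$ with effective parameters
  $C(m) = m + d\,(m-1)/2$, $d = 3$ when interactions are allowed and $d = 2$
  for additive fits (the standard convention; the upstream method names GCV
  but not $d$).
* **Knot candidates** are the unique observed covariate values,
  quantile-thinned to at most `max_knots = 61` per covariate. The neighbor
  counts are small integers, so they are never thinned; the specificity
  score is continuous with thousands of unique values at library scale, and
  an exhaustive candidate set would make the forward pass quadratic in the
  number of guides for no measurable gain in fit. `max_knots = Inf` restores
  the exhaustive search (the engine tests use it to verify exact hinge
  recovery).
* **Linear effects** are representable because a hinge at a covariate's
  minimum is linear over the data.
* **Degenerate candidates** (zero or collinear columns) are dropped and the
  search continues; an all-degenerate step stops the forward pass with a
  warning.
* `max_degree` defaults to 2: pairwise hinge products capture the
  interactions that matter for five covariates; higher orders mostly add
  pruning work.

Each screen gets a 90/10 train/test split (seeded, reproducible); the
holdout root-mean-squared error is reported in the model file and drives the
optional **RMSE gate**: if `rmse_threshold` is set and the holdout RMSE
exceeds it, depletion values are passed through uncorrected while the
specificity annotations are still emitted. The gate guards against applying
a badly-generalizing model.

## Anchored correction

The fitted $\hat O$ is subtracted relative to a reference covariate vector,
default $x_{\mathrm{ref}} = (s{=}1, H_0{=}1, H_1{=}H_2{=}H_3{=}0)$:

$$D^{\mathrm{corr}}_i = D_i - \hat O(x_i) + \hat O(x_{\mathrm{ref}}).$$

How the predicted effect should be re-leveled after subtraction is genuinely
open; anchoring at the fully-specific guide is the minimal-intervention
choice — perfectly specific guides are untouched by construction, guides
sharing covariates receive identical offsets, and within-class ordering is
preserved. The anchor is configurable. Guides ineligible for fitting (no
perfect target, missing score) pass through unchanged, flagged. Externally
corrected logFC tables (e.g. copy-number-corrected values) can be supplied
directly in place of the internal preprocessing.

## Benchmarking

`benchmark_screen()` scores gene essentiality with a Bayes-factor engine in
the spirit of BAGEL: per gene, the sum over its guides of the log2 ratio of
kernel-density likelihoods under the gold-standard essential versus
non-essential guide fold-change distributions (Gaussian kernel, Silverman
bandwidth, densities floored at 1e-12). Gold genes are scored with k-fold
cross-validation over genes (default 10 folds), so a gene's own guides never
inform the densities that score it. Exact numeric parity with the external
BAGEL implementation is not claimed — the engine exists so the benchmark is
self-contained.

From BF-ordered genes the package computes precision–recall curves over
gold-standard genes (FDR = 1 − precision), recall at 5% FDR (among
thresholds with precision ≥ 0.95, the one with maximal recall), trapezoidal
PR-AUC, false positives at a matched number of hits across pipelines
(deterministic tie-breaking: BF descending, then gene name), and distortion
metrics: mean and median |corrected − observed| per guide — our
interpretation of the published distortion metric, whose precise definition
lives in an external reference — plus the change in essential/non-essential
class separation.

## The synthetic-data generator

Because reproducing DepMap-scale analyses requires the human genome and
restricted-size data, validation runs entirely on synthetic screens whose
generative model mirrors the additive decomposition above:

* **Genome**: i.i.d. ACGT background (default 2 Mb) with planted repeat
  families — near-identical copies of an 80-bp unit carrying a guaranteed
  NGG site. Copy numbers cycle over {2, 3, 4, 6, 8} and each copy is
  independently mutated at rate 0.02/bp, so consensus guides have controlled
  $H_0$ and mutation-diverged copies populate $H_1$–$H_3$.
* **Library**: default 200 genes × 5 guides. A configurable fraction
  (default 0.3) of guide slots is drawn from repeat loci; 85% of those use
  multi-copy consensus sequences ($H_0 > 1$), the rest diverged singletons
  ($H_0 = 1$, $H_1 > 0$). Promiscuous slots cluster gene-wise (~80% of the
  guides of a promiscuity-prone gene subset), mirroring the observation in
  real libraries that multi-target guides concentrate on a minority of
  genes — which is exactly what makes off-targeting produce gene-level false
  positives.
* **Effects**: essential genes (fraction 0.3) draw
  $G \sim \mathcal N(-2, 0.3)$; others have $G = 0$. Off-target toxicity is
  $O = -\beta\,(1/s - 1)$ with $\beta = 0.5$, i.e. proportional to the
  guide's excess CFD cutting mass, and 0 for fully specific guides. A
  deliberately mis-specified variant ($O = -0.15\,H_2$) is available for
  robustness checks.
* **Counts**: negative binomial (dispersion 0.05) around
  depth × guide-abundance (log-normal, sd 0.3) × per-sample size factor
  (log-normal, sd 0.15), sequencing depth 500 reads/guide, 2 replicates.
  Size factors give median-ratio normalization real work; the abundance
  spread interacts with the 30-read plasmid filter by design.

Everything is a deterministic function of one seed, and the stored
ground-truth covariates are recomputable from the emitted genome (a test
asserts this round trip). What the generator does *not* emulate: real
human-genome composition and repeat taxonomy, guide-efficiency variation,
copy-number amplifications, and batch structure. Passing the synthetic
recovery tests therefore demonstrates that the estimator recovers the model
it assumes under realistic count noise — not that real screens satisfy that
model.

## Problem sizes and numerical choices in the test suite

The enumeration oracle is verified on 20 random genomes (19 × 100 kb plus
one 2 Mb) × 1,000 guides each, exact set equality at distances 0–3.
Correlation-removal and benchmark-direction studies use 20 seeds at the
default screen size (1,000 guides); planted-effect recovery regresses
$\hat O(x) - \hat O(x_{\mathrm{ref}})$ on the true $O$ at 10,000 guides ×
20 seeds. The specificity–depletion diagnostic groups guides into 0.05-wide
score bins (bin value = upper edge, bins with < 3 guides dropped) and
correlates bin value with bin mean logFC. One caveat worth stating plainly:
a Pearson correlation on binned means is scale-invariant, so once the
systematic signal is removed, its magnitude is governed by bin-mean sampling
noise (≈ $1/\sqrt{n_{\mathrm{bins}}}$) rather than by any property of the
correction — the residual correlation of a *perfect* correction fluctuates
just as widely. The per-seed after-correction correlation should therefore
be read as a sign diagnostic, while the seed-pooled version (reported by
`scripts/acceptance.R`) is the stable summary.

## Limitations

* The CFD constants shipped are synthetic stand-ins (see above); absolute
  specificity scores on real libraries require the published table.
* Hamming neighborhoods stop at distance 3 and exclude bulges, matching the
  enumeration the method is defined for.
* The Bayes-factor engine is a simplified re-implementation; use it for
  relative comparisons between pipelines, not as a drop-in for BAGEL
  scores.
* Correction quality is bounded by the covariates: toxicity that is not a
  function of $(s, H_0\ldots H_3)$ — chromatin context, cutting in
  amplified regions — is out of reach and should be handled upstream (e.g.
  supplying copy-number-corrected logFCs as the input).
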