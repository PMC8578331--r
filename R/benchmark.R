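#' Read a gene list (one gene per line)
#'
#' @param path Plain-text file, one gene symbol per line.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Bundle gold-standard essential and non-essential gene sets
#'
#' @param essential,nonessential Character vectors of gene names; must be
#'   disjoint and non-empty.
#' @return A `gold_standard` list.
#' @export
gold_standard <- function(essential, nonessential) {
  essential <- unique(as.character(essential))
  nonessential <- unique(as.character(nonessential))
  if (length(essential) == 0L || length(nonessential) == 0L)
    stop("both gold-standard sets must be non-empty")
  if (length(intersect(essential, nonessential)))
    stop("gold-standard sets must be disjoint")
  structure(list(essential = essential, nonessential = nonessential),
            class = "gold_standard")
}

# Gaussian KDE with Silverman's bandwidth, evaluated directly and floored.
.kde_eval <- function(train, at, floor = 1e-12) {
  bw <- stats::bw.nrd0(train)
  if (!is.finite(bw) || bw <= 0) bw <- max(sd(train), 1e-3) * 0.5
  dens <- vapply(at, function(x) mean(dnorm(x, mean = train, sd = bw)),
                 numeric(1))
  pmax(dens, floor)
}

#' Gene-level Bayes factors from guide fold changes
#'
#' For each gene, sums over its guides the log2 likelihood ratio of the
#' guide's fold change under kernel-density estimates of the gold-standard
#' essential versus non-essential guide distributions. Positive values are
#' essential-like. Gold genes are scored with cross-validation: the
#' densities scoring a gold gene are fit on folds excluding it, so a gene's
#' own guides never inform its score. Non-gold genes are scored against
#' densities fit on all gold guides.
#'
#' @param logfc Guide fold-change vector.
#' @param genes Gene of each guide.
#' @param gold A [gold_standard()].
#' @param folds Number of cross-validation folds over gold genes
#'   (default 10).
#' @param seed Seed for the fold assignment.
#' @param density_floor Densities are clamped at this floor to keep the
#'   log ratio finite outside the training support.
#' @return Named numeric vector of Bayes factors, sorted by gene name.
#' @export
bayes_factors <- function(logfc, genes, gold, folds = 10L, seed = 1L,
                          density_floor = 1e-12) {
  stopifnot(inherits(gold, "gold_standard"), length(logfc) == length(genes))
  genes <- as.character(genes)
  keep <- !is.na(logfc)
  logfc <- logfc[keep]
  genes <- genes[keep]
  ess <- intersect(gold$essential, genes)
  non <- intersect(gold$nonessential, genes)
  if (length(ess) == 0L || length(non) == 0L)
    stop("no overlap between screen genes and a gold-standard set")
  old <- .Random.seed_safe_get()
  on.exit(.Random.seed_safe_set(old))
  set.seed(as.integer(seed))
  folds <- max(2L, min(folds, length(ess), length(non)))
  fold_of <- c(setNames(sample(rep_len(seq_len(folds), length(ess))), sort(ess)),
               setNames(sample(rep_len(seq_len(folds), length(non))), sort(non)))

  is_ess_guide <- genes %in% ess
  is_non_guide <- genes %in% non
  all_genes <- sort(unique(genes))
  bf <- setNames(numeric(length(all_genes)), all_genes)
  for (g in all_genes) {
    gl <- logfc[genes == g]
    if (g %in% names(fold_of)) {
      f <- fold_of[[g]]
      train_mask <- !(genes %in% names(fold_of)[fold_of == f])
    } else {
      train_mask <- TRUE
    }
    p_ess <- .kde_eval(logfc[is_ess_guide & train_mask], gl, density_floor)
    p_non <- .kde_eval(logfc[is_non_guide & train_mask], gl, density_floor)
    bf[g] <- sum(log2(p_ess / p_non))
  }
  bf
}

#' Precision-recall curve over Bayes-factor thresholds
#'
#' Genes are ordered by decreasing Bayes factor (ties broken by gene name)
#' and at every threshold TP, FP and FN are computed over gold-standard
#' genes only: precision = TP / (TP + FP), recall = TP / (TP + FN) with FN
#' the gold essential genes not called.
#'
#' @param bf Named Bayes-factor vector ([bayes_factors()]).
#' @param gold A [gold_standard()].
#' @return Data frame: threshold (BF of the last called gene), precision,
#'   recall, in decreasing-threshold order.
#' @export
precision_recall <- function(bf, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  gold_genes <- names(bf)[names(bf) %in% c(gold$essential, gold$nonessential)]
  if (length(gold_genes) == 0L) stop("no gold-standard genes among scored genes")
  ord <- order(-bf, names(bf), method = "radix")
  bf_ord <- bf[ord]
  is_ess <- names(bf_ord) %in% gold$essential
  is_non <- names(bf_ord) %in% gold$nonessential
  n_ess <- sum(is_ess)
  if (n_ess == 0L) stop("no gold essential genes scored")
  tp <- cumsum(is_ess)
  fp <- cumsum(is_non)
  keep <- is_ess | is_non  # thresholds where a gold gene enters the call set
  data.frame(threshold = unname(bf_ord[keep]),
             precision = (tp / pmax(tp + fp, 1L))[keep],
             recall = (tp / n_ess)[keep])
}

#' Recall at a fixed false discovery rate
#'
#' FDR = 1 - precision. Among thresholds with precision at or above
#' `1 - fdr`, returns the one with maximal recall (the stated tie rule);
#' if none qualifies, recall 0 with an infinite threshold sentinel.
#'
#' @param pr_curve Curve from [precision_recall()].
#' @param fdr Target false discovery rate (default 0.05).
#' @return List with `recall` and `bf_threshold`.
#' @export
recall_at_fdr <- function(pr_curve, fdr = 0.05) {
  if (nrow(pr_curve) == 0L) stop("empty precision-recall curve")
  ok <- pr_curve$precision >= 1 - fdr
  if (!any(ok)) return(list(recall = 0, bf_threshold = Inf))
  i <- which(ok)[which.max(pr_curve$recall[ok])]
  list(recall = pr_curve$recall[i], bf_threshold = pr_curve$threshold[i])
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration over recall, with the curve extended to recall 0
#' at its first observed precision.
#'
#' @param pr_curve Curve from [precision_recall()].
#' @return AUC in \[0, 1\].
#' @export
auc_pr <- function(pr_curve) {
  if (nrow(pr_curve) < 2L) stop("need at least 2 curve points")
  r <- c(0, pr_curve$recall)
  p <- c(pr_curve$precision[1], pr_curve$precision)
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}

#' False positives at a matched number of hits
#'
#' For each pipeline's Bayes-factor vector, the threshold is set so that
#' exactly `n_hits` genes are called (ties broken by BF then gene name,
#' deterministically) and the gold non-essential genes among the hits are
#' counted.
#'
#' @param bf_by_pipeline Named list of named BF vectors over the same gene
#'   universe.
#' @param gold A [gold_standard()].
#' @param n_hits Number of hits to call per pipeline.
#' @return Named integer vector of false-positive counts.
#' @export
false_positives_at_matched_hits <- function(bf_by_pipeline, gold, n_hits) {
  stopifnot(inherits(gold, "gold_standard"), is.list(bf_by_pipeline))
  universe <- sort(names(bf_by_pipeline[[1]]))
  vapply(bf_by_pipeline, function(bf) {
    if (!identical(sort(names(bf)), universe))
      stop("pipelines must score the same gene universe")
    if (n_hits > length(bf)) stop("n_hits exceeds the number of scored genes")
    ord <- order(-bf, names(bf), method = "radix")
    hits <- names(bf)[ord][seq_len(n_hits)]
    sum(hits %in% gold$nonessential)
  }, integer(1))
}

#' Correction distortion and class-separation change
#'
#' Distortion is the absolute per-guide difference between corrected and
#' observed fold changes (mean and median reported). `separation_delta` is
#' the change, after minus before, in the mean fold-change distance between
#' guides of gold essential and gold non-essential genes — a correction
#' that preserves biology keeps it near zero.
#'
#' @param observed,corrected Aligned guide fold-change vectors.
#' @param genes Gene of each guide.
#' @param gold A [gold_standard()].
#' @return List: distortion_mean, distortion_median, separation_delta.
#' @export
distortion <- function(observed, corrected, genes, gold) {
  if (length(observed) != length(corrected) || length(observed) != length(genes))
    stop("observed, corrected and genes must be aligned")
  d <- abs(corrected - observed)
  sep <- function(x) {
    e <- mean(x[genes %in% gold$essential])
    n <- mean(x[genes %in% gold$nonessential])
    e - n
  }
  list(distortion_mean = mean(d), distortion_median = median(d),
       separation_delta = sep(corrected) - sep(observed))
}

#' Benchmark a corrected screen against gold-standard gene sets
#'
#' Computes Bayes factors, the precision-recall curve, recall at 5% FDR,
#' AUC, and distortion summaries for observed and corrected fold changes.
#'
#' @param observed,corrected Guide fold-change vectors aligned with
#'   `genes`.
#' @param genes Gene of each guide.
#' @param gold A [gold_standard()].
#' @param folds,seed Passed to [bayes_factors()].
#' @param fdr Target FDR (default 0.05).
#' @return A `benchmark_report` list: per-pipeline BF vectors, PR curves,
#'   recall at the FDR, AUC, and the distortion summary.
#' @export
benchmark_screen <- function(observed, corrected, genes, gold, folds = 10L,
                             seed = 1L, fdr = 0.05) {
  res <- lapply(list(observed = observed, corrected = corrected), function(fc) {
    bf <- bayes_factors(fc, genes, gold, folds = folds, seed = seed)
    pr <- precision_recall(bf, gold)
    rec <- recall_at_fdr(pr, fdr)
    list(bayes_factors = bf, pr_curve = pr, recall = rec$recall,
         bf_threshold = rec$bf_threshold, auc_pr = auc_pr(pr))
  })
  structure(list(pipelines = res,
                 distortion = distortion(observed, corrected, genes, gold),
                 fdr = fdr),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (FDR ", x$fdr, "):\n", sep = "")
  for (nm in names(x$pipelines)) {
    p <- x$pipelines[[nm]]
    cat(sprintf("  %-10s recall %.3f (BF threshold %.2f), AUC %.3f\n",
                nm, p$recall, p$bf_threshold, p$auc_pr))
  }
  d <- x$distortion
  cat(sprintf("  distortion mean %.4f, median %.4f; separation delta %+.4f\n",
              d$distortion_mean, d$distortion_median, d$separation_delta))
  invisible(x)
}
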