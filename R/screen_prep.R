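#' Remove guides with low initial plasmid representation
#'
#' Guides with fewer than `min_reads` reads in the plasmid (initial) sample
#' are removed before normalization: their fold changes are dominated by
#' sampling noise. The comparison is strict (`< min_reads`).
#'
#' @param counts Data frame with one row per guide and a plasmid count
#'   column.
#' @param min_reads Minimum plasmid reads to keep a guide (default 30).
#' @param plasmid_col Name of the plasmid count column.
#' @return Filtered data frame; the number of removed rows is attached as
#'   attribute `n_filtered` and reported via `message()`.
#' @export
filter_low_plasmid <- function(counts, min_reads = 30L, plasmid_col = "plasmid") {
  if (!plasmid_col %in% names(counts))
    stop("plasmid column '", plasmid_col, "' not found")
  keep <- counts[[plasmid_col]] >= min_reads
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_removed <- sum(!keep)
  message("filter_low_plasmid: removed ", n_removed, " of ", length(keep),
          " guides with ", plasmid_col, " < ", min_reads)
  if (nrow(out) == 0L) warning("all guides removed by the plasmid read filter")
  attr(out, "n_filtered") <- n_removed
  out
}

#' Median-ratio normalization of screen counts
#'
#' Per-sample size factor = median over guides of count / geometric mean of
#' that guide's counts across samples. Guides with a zero count in any
#' sample are excluded from the factor estimation (their geometric mean is
#' zero) but are still normalized. All samples (plasmid and replicates) are
#' normalized jointly with a single size-factor fit.
#'
#' @param counts Data frame with count columns `sample_cols`.
#' @param sample_cols Character vector of count columns to normalize
#'   (default: all numeric columns).
#' @return Data frame with the count columns replaced by normalized counts;
#'   the size factors are attached as attribute `size_factors`.
#' @export
median_ratio_normalize <- function(counts, sample_cols = NULL) {
  sample_cols <- sample_cols %||%
    names(counts)[vapply(counts, is.numeric, logical(1))]
  if (length(sample_cols) < 2L) stop("need at least 2 samples to normalize")
  m <- as.matrix(counts[sample_cols])
  if (any(m < 0)) stop("negative counts")
  zero_sample <- colSums(m) == 0
  if (any(zero_sample))
    stop("sample(s) with all-zero counts: ",
         paste(sample_cols[zero_sample], collapse = ", "))
  pos <- rowSums(m == 0) == 0L
  if (!any(pos)) stop("no guide has nonzero counts in every sample; cannot ",
                      "estimate size factors")
  log_gm <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2L, function(col) {
    median(exp(log(col) - log_gm))
  })
  # rescale to geometric mean 1: keeps ratios intact and makes the
  # normalization idempotent (renormalizing yields factors of exactly 1)
  sf <- sf / exp(mean(log(sf)))
  norm <- sweep(m, 2L, sf, "/")
  out <- counts
  out[sample_cols] <- as.data.frame(norm)
  attr(out, "size_factors") <- sf
  out
}

#' Per-replicate and mean log2 fold changes
#'
#' For each replicate, `log2((norm_post + pseudocount) / (norm_plasmid +
#' pseudocount))`; the arithmetic mean over replicates is the guide's final
#' depletion value.
#'
#' @param counts Normalized counts ([median_ratio_normalize()]).
#' @param plasmid_col Plasmid column name.
#' @param rep_cols Replicate column names (default: all numeric columns
#'   except the plasmid).
#' @param pseudocount Added to both numerator and denominator after
#'   normalization (default 1 read-equivalent).
#' @return Input with added `logfc_<rep>` columns and `logfc_mean`.
#' @export
log2_fold_changes <- function(counts, plasmid_col = "plasmid", rep_cols = NULL,
                              pseudocount = 1) {
  rep_cols <- rep_cols %||% setdiff(
    names(counts)[vapply(counts, is.numeric, logical(1))], plasmid_col)
  rep_cols <- setdiff(rep_cols, plasmid_col)
  if (length(rep_cols) == 0L) stop("no replicate columns")
  if (!plasmid_col %in% names(counts)) stop("plasmid column not found")
  lfc <- vapply(rep_cols, function(rc) {
    log2((counts[[rc]] + pseudocount) / (counts[[plasmid_col]] + pseudocount))
  }, numeric(nrow(counts)))
  lfc <- matrix(lfc, nrow = nrow(counts),
                dimnames = list(NULL, paste0("logfc_", rep_cols)))
  out <- cbind(counts, as.data.frame(lfc))
  out$logfc_mean <- rowMeans(lfc)
  out
}

#' z-scores of mean log2 fold changes (diagnostic)
#'
#' Centered and scaled with the population standard deviation across the
#' screen. Presentation-layer only; the correction model always regresses
#' the raw mean log fold changes.
#'
#' @param prepped Data frame with a `logfc_mean` column.
#' @return Input with an added `zscore` column.
#' @export
zscore_logfc <- function(prepped) {
  x <- prepped$logfc_mean
  if (length(x) < 2L) stop("need at least 2 guides for z-scores")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero standard deviation of log fold changes")
  prepped$zscore <- (x - mean(x)) / s
  prepped
}

#' Raw counts to guide-level depletion values
#'
#' Full preprocessing pipeline: plasmid read filter (strict `< min_reads`),
#' joint median-ratio normalization, per-replicate log2 fold changes with
#' replicate mean, and diagnostic z-scores — in that order.
#'
#' @inheritParams filter_low_plasmid
#' @inheritParams log2_fold_changes
#' @return Data frame with normalized counts, `logfc_*` columns,
#'   `logfc_mean` and `zscore`; attributes `size_factors`, `n_filtered`
#'   and `pseudocount` record the run.
#' @export
prepare_screen <- function(counts, min_reads = 30L, pseudocount = 1,
                           plasmid_col = "plasmid", rep_cols = NULL) {
  filt <- filter_low_plasmid(counts, min_reads, plasmid_col)
  rep_cols <- rep_cols %||% setdiff(
    names(filt)[vapply(filt, is.numeric, logical(1))], plasmid_col)
  norm <- median_ratio_normalize(filt, c(plasmid_col, rep_cols))
  out <- log2_fold_changes(norm, plasmid_col, rep_cols, pseudocount)
  out <- zscore_logfc(out)
  attr(out, "size_factors") <- attr(norm, "size_factors")
  attr(out, "n_filtered") <- attr(filt, "n_filtered")
  attr(out, "pseudocount") <- pseudocount
  out
}
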