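#' Run the full correction pipeline on one screen
#'
#' Index (or reuse an index), annotate the library, preprocess the counts
#' (or accept a precomputed fold-change table, e.g. copy-number-corrected
#' values), fit the per-screen off-target model and emit corrected
#' depletion values. Output files are written with fixed column names and
#' order; two runs with identical inputs, config and seed are
#' byte-identical.
#'
#' @param index A [build_target_index()] result (or path to a serialized
#'   index).
#' @param library Guide library data frame (guide_id, sequence, gene) or
#'   TSV path.
#' @param counts Screen count table (guide_id, gene, plasmid, rep...) or
#'   TSV path. Ignored when `logfc` is supplied.
#' @param logfc Optional precomputed per-guide fold changes: data frame
#'   with columns guide_id and logfc (or TSV path).
#' @param rmse_threshold Optional holdout-RMSE gate.
#' @param seed Seed for the model's train/test split.
#' @param out_dir Optional output directory; writes `corrected.tsv`,
#'   `annotation.tsv` and `model_report.json`.
#' @param cfd_table CFD penalty table.
#' @param min_reads,pseudocount Preprocessing parameters
#'   ([prepare_screen()]).
#' @param ... Passed to [mars_fit()].
#' @return List: results (corrected table), model, rmse_gate_triggered,
#'   profiles, prepped (preprocessed counts, when computed).
#' @export
run_correction_pipeline <- function(index, library, counts = NULL,
                                    logfc = NULL, rmse_threshold = NULL,
                                    seed = 1L, out_dir = NULL,
                                    cfd_table = cfd_penalty_table(),
                                    min_reads = 30L, pseudocount = 1, ...) {
  if (is.character(index)) index <- read_target_index(index)
  if (is.character(library)) library <- read.delim(library, stringsAsFactors = FALSE)
  profiles <- annotate_library(index, library, table = cfd_table)
  prepped <- NULL
  if (is.null(logfc)) {
    if (is.null(counts)) stop("either counts or logfc must be supplied")
    if (is.character(counts)) counts <- read.delim(counts, stringsAsFactors = FALSE)
    prepped <- prepare_screen(counts, min_reads = min_reads,
                              pseudocount = pseudocount)
    logfc <- prepped[c("guide_id", "logfc_mean")]
    names(logfc)[2] <- "logfc"
  } else if (is.character(logfc)) {
    logfc <- read.delim(logfc, stringsAsFactors = FALSE)
    names(logfc)[2] <- "logfc"
  }
  # align: guides that survived preprocessing, in annotation order
  m <- match(logfc$guide_id, profiles$guide_id)
  if (anyNA(m)) stop("fold-change table contains guides absent from the library")
  prof <- profiles[m, , drop = FALSE]
  corr <- correct_screen(prof, logfc$logfc, rmse_threshold = rmse_threshold,
                         seed = seed, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(profiles, file.path(out_dir, "annotation.tsv"))
    write.table(corr$results, file.path(out_dir, "corrected.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_model_report(corr$model, file.path(out_dir, "model_report.json"))
  }
  c(corr, list(profiles = profiles, prepped = prepped))
}
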