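#' Build the covariate matrix for the off-target model
#'
#' Columns, in fixed order: `specificity`, `H0`, `H1`, `H2`, `H3`. Guides
#' with an undefined specificity score or no perfect target are not
#' eligible for model fitting (they are retained downstream as
#' pass-through rows).
#'
#' @param profiles Annotation table from [annotate_library()].
#' @return List with `X` (numeric matrix, one row per guide, `NA` rows for
#'   ineligible guides) and `eligible` (logical vector).
#' @export
build_covariates <- function(profiles) {
  need <- c("specificity", "H0", "H1", "H2", "H3")
  if (!all(need %in% names(profiles)))
    stop("profiles must contain columns: ", paste(need, collapse = ", "))
  X <- as.matrix(profiles[need])
  storage.mode(X) <- "double"
  eligible <- !is.na(profiles$specificity) & profiles$H0 > 0
  if (!any(eligible)) stop("no guides eligible for model fitting ",
                           "(all lack a perfect target)")
  list(X = X, eligible = eligible)
}

#' Reference covariate vector of a perfectly specific guide
#'
#' `s = 1, H0 = 1, H1 = H2 = H3 = 0`: the anchoring point of the
#' correction, so perfectly specific guides are left unchanged.
#'
#' @return Named numeric vector.
#' @export
reference_covariates <- function() {
  c(specificity = 1, H0 = 1, H1 = 0, H2 = 0, H3 = 0)
}

#' Fit the off-target depletion model for one screen
#'
#' Regresses guide mean log2 fold changes on the five specificity
#' covariates with an adaptive regression spline ([mars_fit()]): 90/10
#' train/test split, forward hinge construction, GCV-pruned backward pass.
#'
#' @param logfc Guide depletion values (mean log2 fold changes), aligned
#'   with `covariates$X` rows.
#' @param covariates Result of [build_covariates()].
#' @param seed Seed for the train/test split.
#' @param ... Passed to [mars_fit()] (`max_terms`, `max_degree`, ...).
#' @return A `mars_model`.
#' @export
fit_offtarget_model <- function(logfc, covariates, seed = 1L, ...) {
  el <- covariates$eligible
  if (sum(el) < 20L) stop("need at least 20 fit-eligible guides")
  if (length(logfc) != nrow(covariates$X))
    stop("logfc and covariate matrix are misaligned")
  mars_fit(covariates$X[el, , drop = FALSE], logfc[el], seed = seed, ...)
}

#' Subtract the predicted off-target effect from observed depletion
#'
#' `corrected_i = observed_i - O(x_i) + O(x_ref)` for every fit-eligible
#' guide, where `O` is the fitted spline and `x_ref` a fully specific
#' reference guide ([reference_covariates()] by default), so guides with
#' reference covariates are unchanged. Flagged (ineligible) guides pass
#' through uncorrected.
#'
#' @param logfc Observed depletion values.
#' @param covariates Result of [build_covariates()].
#' @param model Fitted `mars_model`.
#' @param x_ref Reference covariate vector (default
#'   [reference_covariates()]).
#' @param apply_correction If `FALSE` (e.g. the RMSE gate fired), predicted
#'   effects are still reported but corrected values equal observed.
#' @return Data frame: observed, offtarget_pred (relative to the
#'   reference), corrected, correction_applied.
#' @export
correct_depletion <- function(logfc, covariates, model,
                              x_ref = reference_covariates(),
                              apply_correction = TRUE) {
  stopifnot(inherits(model, "mars_model"))
  X <- covariates$X
  el <- covariates$eligible
  if (length(logfc) != nrow(X)) stop("logfc and covariates are misaligned")
  if (length(x_ref) != ncol(X)) stop("x_ref must have ", ncol(X), " covariates")
  pred <- rep(NA_real_, length(logfc))
  ref <- drop(predict(model, matrix(x_ref, nrow = 1,
                                    dimnames = list(NULL, colnames(X)))))
  pred[el] <- predict(model, X[el, , drop = FALSE]) - ref
  corrected <- logfc
  applied <- el & apply_correction
  corrected[applied] <- logfc[applied] - pred[applied]
  data.frame(observed = logfc, offtarget_pred = pred, corrected = corrected,
             correction_applied = applied)
}

#' Holdout-RMSE quality gate
#'
#' If a threshold is set and the model's holdout RMSE exceeds it, no
#' correction is performed (specificity annotations are still emitted).
#'
#' @param model Fitted `mars_model`.
#' @param threshold Numeric RMSE threshold, or `NULL` to always correct.
#' @return `TRUE` if the gate fires (correction suppressed).
#' @export
rmse_gate <- function(model, threshold = NULL) {
  if (is.null(threshold)) return(FALSE)
  if (threshold < 0) stop("RMSE threshold must be non-negative")
  isTRUE(model$rmse_test > threshold)
}

#' Baseline comparison filter: keep uniquely targeting guides only
#'
#' The simple alternative to model-based correction: retain guides with
#' exactly one perfect target site (H0 == 1), discarding multi-target
#' guides.
#'
#' @param profiles Annotation table from [annotate_library()].
#' @return Subset of `profiles` with `H0 == 1`.
#' @export
filter_h0_baseline <- function(profiles) {
  out <- profiles[profiles$H0 == 1L, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no guides with a single perfect target site")
  out
}

#' Correct a screen's depletion values for off-target effects
#'
#' The core correction: builds the covariate matrix from the annotation,
#' fits the per-screen off-target spline on fit-eligible guides, applies
#' the holdout-RMSE gate if requested, and subtracts the predicted
#' off-target effect anchored at the fully specific reference guide.
#'
#' @param profiles Annotation table from [annotate_library()], one row per
#'   guide.
#' @param logfc Observed depletion values aligned with `profiles` (e.g.
#'   `logfc_mean` from [prepare_screen()], or an externally corrected
#'   fold-change table such as copy-number-corrected values).
#' @param rmse_threshold Optional holdout-RMSE gate ([rmse_gate()]).
#' @param seed Seed for the model's train/test split.
#' @param x_ref Reference covariate vector.
#' @param ... Passed to [mars_fit()].
#' @return List with `results` (guide_id, gene, covariates, observed,
#'   offtarget_pred, corrected, correction_applied, flags), `model` (the
#'   fitted `mars_model`) and `rmse_gate_triggered`.
#' @export
correct_screen <- function(profiles, logfc, rmse_threshold = NULL, seed = 1L,
                           x_ref = reference_covariates(), ...) {
  cov <- build_covariates(profiles)
  model <- fit_offtarget_model(logfc, cov, seed = seed, ...)
  gate <- rmse_gate(model, rmse_threshold)
  corr <- correct_depletion(logfc, cov, model, x_ref,
                            apply_correction = !gate)
  results <- data.frame(
    guide_id = profiles$guide_id, gene = profiles$gene,
    specificity = profiles$specificity,
    H0 = profiles$H0, H1 = profiles$H1, H2 = profiles$H2, H3 = profiles$H3,
    logfc_observed = corr$observed,
    offtarget_pred = corr$offtarget_pred,
    logfc_corrected = corr$corrected,
    correction_applied = corr$correction_applied,
    flags = profiles$flags,
    stringsAsFactors = FALSE
  )
  list(results = results, model = model, rmse_gate_triggered = gate)
}

#' Pearson correlation between binned specificity and mean depletion
#'
#' Diagnostic mirroring the standard specificity-vs-depletion summary:
#' guides are grouped into fixed-width specificity bins (bin value = upper
#' edge), sparsely populated bins are dropped, and the correlation between
#' bin specificity and bin mean log fold change is returned. A strong
#' positive correlation means less specific guides are more depleted; a
#' successful correction removes it.
#'
#' @param specificity Guide specificity scores.
#' @param logfc Guide depletion values.
#' @param bin_width Specificity bin width (default 0.05).
#' @param min_guides Minimum guides per bin (default 3).
#' @return List with `r`, `n_bins`, and the per-bin summary table.
#' @export
specificity_depletion_cor <- function(specificity, logfc, bin_width = 0.05,
                                      min_guides = 3L) {
  keep <- !is.na(specificity) & !is.na(logfc)
  s <- specificity[keep]
  d <- logfc[keep]
  breaks <- seq(0, 1, by = bin_width)
  bin <- cut(s, breaks = breaks, include.lowest = TRUE, right = TRUE)
  upper <- breaks[-1]
  mean_lfc <- tapply(d, bin, mean)
  n <- tapply(d, bin, length)
  tab <- data.frame(specificity = upper, n = as.integer(ifelse(is.na(n), 0L, n)),
                    mean_logfc = as.numeric(mean_lfc))
  tab <- tab[tab$n >= min_guides, , drop = FALSE]
  if (nrow(tab) < 3L)
    return(list(r = NA_real_, n_bins = nrow(tab), bins = tab))
  list(r = cor(tab$specificity, tab$mean_logfc), n_bins = nrow(tab), bins = tab)
}
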