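#' @section Adaptive regression splines:
#' The off-target model is a multivariate adaptive regression spline: a
#' weighted sum of basis functions that are either the constant 1 (the
#' intercept), a hinge `max(0, +/-(x_v - t))` in one covariate, or a product
#' of hinges in distinct covariates. The forward pass grows the basis set by
#' greedily adding mirrored hinge pairs; the backward pass prunes terms and
#' selects the sub-model with minimum generalized cross-validation (GCV).
#' @name mars
#' @keywords internal
NULL

.mars_knots <- function(X, max_knots) {
  lapply(seq_len(ncol(X)), function(v) {
    u <- sort(unique(X[, v]))
    if (!is.finite(max_knots) || length(u) <= max_knots) return(u)
    sort(unique(quantile(X[, v], probs = seq(0, 1, length.out = max_knots),
                         names = FALSE, type = 7)))
  })
}

# Evaluate the basis matrix for a list of factor data frames (var, knot, dir)
.mars_design <- function(bases, X) {
  n <- nrow(X)
  B <- matrix(1, nrow = n, ncol = length(bases))
  for (j in seq_along(bases)) {
    f <- bases[[j]]
    if (nrow(f) == 0L) next
    col <- rep(1, n)
    for (i in seq_len(nrow(f))) {
      col <- col * pmax(0, f$dir[i] * (X[, f$var[i]] - f$knot[i]))
    }
    B[, j] <- col
  }
  B
}

.mars_ols <- function(B, y) {
  fit <- lm.fit(B, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  rss <- sum(fit$residuals^2)
  list(coefficients = unname(coefs), rss = rss)
}

.new_mars_model <- function(bases, coefficients, X, y, penalty, varnames) {
  B <- .mars_design(bases, X)
  resid <- y - drop(B %*% coefficients)
  rss <- sum(resid^2)
  m <- length(bases)
  used <- sort(unique(unlist(lapply(bases, function(f) f$var))))
  structure(list(bases = bases, coefficients = coefficients,
                 varnames = varnames, penalty = penalty,
                 n_train = length(y), rss = rss,
                 gcv = mars_gcv(rss, length(y), m, penalty),
                 rmse_train = sqrt(rss / length(y)),
                 rmse_test = NA_real_,
                 selected_covariates = varnames[used]),
            class = "mars_model")
}

#' Generalized cross-validation score
#'
#' `GCV = (rss / n) / (1 - C(m)/n)^2` with effective parameter count
#' `C(m) = m + penalty * (m - 1) / 2`, where `m` is the number of basis
#' functions including the intercept.
#'
#' @param rss Residual sum of squares.
#' @param n Number of training observations.
#' @param m_terms Number of basis functions (intercept included).
#' @param penalty Effective-parameter cost per knot (3 when interaction
#'   terms are allowed, 2 for additive models).
#' @return GCV value.
#' @export
mars_gcv <- function(rss, n, m_terms, penalty = 3) {
  C <- m_terms + penalty * (m_terms - 1) / 2
  if (C >= n) stop("model has as many effective parameters (", C,
                   ") as observations (", n, ")")
  (rss / n) / (1 - C / n)^2
}

#' Forward pass: greedy hinge-basis construction
#'
#' Starts from the intercept and at each step adds the mirrored hinge pair
#' (parent basis x new hinge at a candidate knot) that minimizes the
#' residual sum of squares, refitting all coefficients by OLS after every
#' addition. Stops at `max_terms` basis functions or when the relative MSE
#' improvement falls below `thresh`. Knot candidates are the unique observed
#' values of each covariate, quantile-thinned above `max_knots` (set
#' `max_knots = Inf` for an exhaustive candidate set). A hinge at a
#' variable's minimum is a linear term in that variable, so purely linear
#' effects are representable.
#'
#' @param X Numeric covariate matrix (no missing values).
#' @param y Numeric response.
#' @param max_terms Maximum number of basis functions including the
#'   intercept (default 21).
#' @param max_degree Maximum number of hinge factors per basis (default 2).
#' @param thresh Forward stopping tolerance on relative MSE improvement.
#' @param max_knots Knot candidate cap per covariate (default 61).
#' @param penalty GCV penalty; default 3 if `max_degree > 1`, else 2.
#' @return A `mars_model`.
#' @export
mars_forward <- function(X, y, max_terms = 21L, max_degree = 2L,
                         thresh = 1e-4, max_knots = 61L, penalty = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(y)) stop("missing values in covariates or response")
  if (nrow(X) < 10L) stop("need at least 10 observations")
  if (max_terms < 1L) stop("max_terms must be >= 1")
  penalty <- penalty %||% if (max_degree > 1L) 3 else 2
  varnames <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  knots <- .mars_knots(X, max_knots)
  fw <- cpp_mars_forward(X, as.numeric(y), as.integer(max_terms),
                         as.integer(max_degree), thresh, knots)
  if (isTRUE(fw$degenerate_stop) && length(fw$bases) == 1L)
    warning("all candidate terms degenerate; returning intercept-only model")
  bases <- lapply(fw$bases, function(f) as.data.frame(f))
  B <- .mars_design(bases, X)
  fit <- .mars_ols(B, y)
  .new_mars_model(bases, fit$coefficients, X, y, penalty, varnames)
}

#' Backward pass: GCV-guided pruning
#'
#' Iteratively deletes the non-intercept term whose removal least increases
#' the residual sum of squares, recording the GCV of every visited
#' sub-model, and returns the sub-model with minimum GCV (the forward model
#' itself competes). Members of a mirrored hinge pair are pruned
#' independently.
#'
#' @param model A `mars_model` from [mars_forward()].
#' @param X,y Training data the model was built on.
#' @return The minimum-GCV `mars_model`; the GCV path is attached as
#'   attribute `gcv_path`.
#' @export
mars_prune <- function(model, X, y) {
  stopifnot(inherits(model, "mars_model"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  B <- .mars_design(model$bases, X)
  current <- seq_along(model$bases)
  fit <- .mars_ols(B, y)
  best <- list(keep = current, rss = fit$rss,
               gcv = mars_gcv(fit$rss, n, length(current), model$penalty))
  gcv_path <- best$gcv
  while (length(current) > 1L) {
    rss_cand <- vapply(current[-1], function(drop_j) {
      keep <- setdiff(current, drop_j)
      .mars_ols(B[, keep, drop = FALSE], y)$rss
    }, numeric(1))
    j <- current[-1][which.min(rss_cand)]
    current <- setdiff(current, j)
    rss <- min(rss_cand)
    gcv <- mars_gcv(rss, n, length(current), model$penalty)
    gcv_path <- c(gcv_path, gcv)
    if (gcv < best$gcv) best <- list(keep = current, rss = rss, gcv = gcv)
  }
  keep <- best$keep
  fit <- .mars_ols(B[, keep, drop = FALSE], y)
  out <- .new_mars_model(model$bases[keep], fit$coefficients, X, y,
                         model$penalty, model$varnames)
  attr(out, "gcv_path") <- gcv_path
  out
}

#' Fit an adaptive regression spline with a held-out test split
#'
#' Randomly assigns `train_frac` of the observations to training (seeded,
#' fully reproducible), runs the forward and backward passes on the
#' training set, and reports the root mean squared prediction error on the
#' holdout.
#'
#' @inheritParams mars_forward
#' @param train_frac Fraction of observations used for training
#'   (default 0.9).
#' @param seed Integer seed for the split.
#' @return A `mars_model` with `rmse_test` filled in.
#' @export
mars_fit <- function(X, y, train_frac = 0.9, seed = 1L, max_terms = 21L,
                     max_degree = 2L, thresh = 1e-4, max_knots = 61L,
                     penalty = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 20L) stop("need at least 20 observations for a train/test split")
  n_train <- floor(train_frac * n)
  if (n_train < 10L || n_train >= n)
    stop("degenerate train/test split (train_frac = ", train_frac, ", n = ", n, ")")
  old <- .Random.seed_safe_get()
  on.exit(.Random.seed_safe_set(old))
  set.seed(as.integer(seed))
  train <- sort(sample.int(n, n_train))
  test <- setdiff(seq_len(n), train)
  model <- mars_forward(X[train, , drop = FALSE], y[train], max_terms,
                        max_degree, thresh, max_knots, penalty)
  model <- mars_prune(model, X[train, , drop = FALSE], y[train])
  pred <- predict(model, X[test, , drop = FALSE])
  model$rmse_test <- sqrt(mean((y[test] - pred)^2))
  model
}

.Random.seed_safe_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_safe_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Predict from a fitted spline model
#'
#' @param object A `mars_model`.
#' @param newdata Matrix or data frame with the covariates the model was
#'   fit on (matched by name when available).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$varnames %in% colnames(X))) {
    X <- X[, object$varnames, drop = FALSE]
  } else if (ncol(X) < max(c(1L, unlist(lapply(object$bases, function(f) f$var))))) {
    stop("newdata is missing covariates the model was fit on")
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in newdata")
  drop(.mars_design(object$bases, X) %*% object$coefficients)
}

#' @export
print.mars_model <- function(x, ...) {
  cat("Adaptive regression spline:", length(x$bases), "basis functions",
      sprintf("(GCV %.4g, train RMSE %.4g%s)\n", x$gcv, x$rmse_train,
              if (is.na(x$rmse_test)) "" else sprintf(", test RMSE %.4g", x$rmse_test)))
  for (j in seq_along(x$bases)) {
    f <- x$bases[[j]]
    lab <- if (nrow(f) == 0L) "(intercept)" else
      paste(ifelse(f$dir > 0,
                   sprintf("h(%s - %.6g)", x$varnames[f$var], f$knot),
                   sprintf("h(%.6g - %s)", f$knot, x$varnames[f$var])),
            collapse = " * ")
    cat(sprintf("  %+.5g * %s\n", x$coefficients[j], lab))
  }
  cat("  covariates used:", paste(x$selected_covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Write a model report (human-readable and machine-parsable)
#'
#' JSON serialization of the basis functions, coefficients, GCV and
#' train/test RMSE; [read_model_report()] round-trips to an identical
#' predictor.
#'
#' @param model A `mars_model`.
#' @param path Output path (`.json`).
#' @export
write_model_report <- function(model, path) {
  stopifnot(inherits(model, "mars_model"))
  obj <- list(
    format = "speccorr_mars_model_v1",
    varnames = model$varnames,
    penalty = model$penalty,
    n_train = model$n_train,
    rss = model$rss,
    gcv = model$gcv,
    rmse_train = model$rmse_train,
    rmse_test = model$rmse_test,
    selected_covariates = model$selected_covariates,
    coefficients = model$coefficients,
    bases = lapply(model$bases, function(f)
      list(var = f$var, knot = f$knot, dir = f$dir))
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' Read a model report written by [write_model_report()]
#'
#' @param path Report path.
#' @return A `mars_model`.
#' @export
read_model_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "speccorr_mars_model_v1"))
    stop("'", path, "' is not a speccorr model report")
  bases <- lapply(obj$bases, function(f)
    data.frame(var = as.integer(unlist(f$var) %||% integer(0)),
               knot = as.numeric(unlist(f$knot) %||% numeric(0)),
               dir = as.integer(unlist(f$dir) %||% integer(0))))
  structure(list(bases = bases, coefficients = as.numeric(obj$coefficients),
                 varnames = obj$varnames, penalty = obj$penalty,
                 n_train = obj$n_train, rss = obj$rss, gcv = obj$gcv,
                 rmse_train = obj$rmse_train,
                 rmse_test = if (is.null(obj$rmse_test)) NA_real_ else obj$rmse_test,
                 selected_covariates = obj$selected_covariates),
            class = "mars_model")
}
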