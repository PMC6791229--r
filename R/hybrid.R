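#' Build the hybrid feature dataset from grey fits
#'
#' The two-stage hybrid scheme uses the grey models' restored fitted values
#' (training years) and forecasts (testing years) as the feature matrix, with
#' the actual counts as labels. One row per year; the feature columns are the
#' chosen grey models in the canonical order of [grey_models()]. Because
#' every grey model preserves the first observation, the first training row's
#' features all equal its label.
#'
#' Testing labels travel with the dataset for evaluation only; no second-stage
#' regressor sees them during training.
#'
#' @param fits a `grey_fit_list` trained on `split$train`.
#' @param split a `dataset_split` from [split_series()].
#' @param subset character vector of grey model identifiers to use as feature
#'   columns (default: all available fits).
#' @return An object of class `hybrid_dataset`: a list with `years`,
#'   `features` (numeric matrix), `labels` and `group`
#'   (`"training"`/`"testing"` per row).
#' @examples
#' sp <- split_series(china_occupational())
#' hd <- build_features(fit_all_grey(sp$train), sp)
#' head(cbind(hd$features, label = hd$labels))
#' @export
build_features <- function(fits, split, subset = names(fits)) {
  stopifnot(inherits(fits, "grey_fit_list"), inherits(split, "dataset_split"))
  if (length(subset) == 0L)
    stop("'subset' must name at least one grey model", call. = FALSE)
  missing_fit <- setdiff(subset, names(fits))
  if (length(missing_fit))
    stop(sprintf("no fit available for: %s", paste(missing_fit, collapse = ", ")),
         call. = FALSE)
  subset <- intersect(grey_models(), subset)   # canonical column order
  years <- c(split$train$years, split$test$years)
  h <- length(split$test)
  feats <- vapply(subset, function(m) {
    f <- fits[[m]]
    if (!identical(f$years, split$train$years))
      stop(sprintf("%s fit does not match the training years of 'split'", m),
           call. = FALSE)
    c(f$fitted, unname(forecast(f, h)))
  }, numeric(length(years)))
  structure(list(years = years,
                 features = matrix(feats, ncol = length(subset),
                                   dimnames = list(years, subset)),
                 labels = c(split$train$values, split$test$values),
                 group = rep(c("training", "testing"),
                             c(length(split$train), h))),
            class = "hybrid_dataset")
}

#' @export
print.hybrid_dataset <- function(x, ...) {
  cat(sprintf("Hybrid dataset: %d training + %d testing years, features: %s\n",
              sum(x$group == "training"), sum(x$group == "testing"),
              paste(colnames(x$features), collapse = ", ")))
  invisible(x)
}

#' Second-stage regressor specification
#'
#' Describes one second-stage regressor family together with its
#' hyperparameters and seed. Defaults reproduce the reference configuration
#' of each family:
#'
#' * `knn` — `k = 2`, `weighting = "inverse"` (inverse-distance); the query
#'   point is included among its own candidate neighbours, so the
#'   inverse-distance variant interpolates the training data exactly.
#' * `svr` — epsilon support vector regression ([e1071::svm()]);
#'   `kernel` one of linear/polynomial/radial/sigmoid, `cost = 1`,
#'   `epsilon = 0.1`, `degree = 3`, `coef0 = 0`, `gamma = 1/p` (p features).
#' * `rf` — random forest ([randomForest::randomForest()]) with `mtry = 1`,
#'   `ntree = 30`.
#' * `gbm` — gradient boosting ([xgboost::xgboost()]) with `nrounds = 100`,
#'   `eta = 0.1`, `gamma = 0.5`, `max_depth = 3`, `subsample = 0.5`,
#'   `colsample_bytree = 1`, `min_child_weight = 1`.
#' * `ann` — single-hidden-layer network ([nnet::nnet()]) with `size = 5`,
#'   `decay = 1e-8`, `maxit = 10000`, convergence tolerance `1e-8`, logistic
#'   output on min-max scaled inputs and labels, and `restarts` random
#'   restarts of which the one with the lowest training RMSE is kept.
#'
#' @param family one of `"knn"`, `"svr"`, `"rf"`, `"gbm"`, `"ann"`.
#' @param ... family-specific hyperparameters overriding the defaults above.
#' @param seed integer seed used by the stochastic families (rf, gbm, ann);
#'   the default is a fixed documented constant.
#' @param label optional display label; defaults to the family plus its
#'   distinguishing hyperparameter.
#' @return An object of class `regressor_spec`.
#' @examples
#' regressor_spec("knn", k = 2, weighting = "uniform")
#' regressor_spec("ann", restarts = 50)
#' @export
regressor_spec <- function(family = c("knn", "svr", "rf", "gbm", "ann"), ...,
                           seed = 20190929L, label = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    knn = list(k = 2L, weighting = "inverse"),
    svr = list(kernel = "radial", cost = 1, epsilon = 0.1, degree = 3,
               coef0 = 0, gamma = NULL),
    rf  = list(mtry = 1L, ntree = 30L),
    gbm = list(nrounds = 100L, eta = 0.1, gamma = 0.5, max_depth = 3L,
               subsample = 0.5, colsample_bytree = 1, min_child_weight = 1),
    ann = list(size = 5L, decay = 1e-8, maxit = 10000L, tol = 1e-8,
               restarts = 50L))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s hyperparameter(s): %s", family,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  pars <- utils::modifyList(defaults, override)
  if (family == "knn" && !pars$weighting %in% c("uniform", "inverse"))
    stop("knn weighting must be 'uniform' or 'inverse'", call. = FALSE)
  if (family == "svr" &&
      !pars$kernel %in% c("linear", "polynomial", "radial", "sigmoid"))
    stop("unknown svr kernel: ", pars$kernel, call. = FALSE)
  if (is.null(label))
    label <- switch(family,
      knn = sprintf("knn (k=%d, %s)", pars$k, pars$weighting),
      svr = sprintf("svr (%s)", pars$kernel),
      rf  = "rf", gbm = "gbm", ann = "ann")
  structure(list(family = family, params = pars, seed = as.integer(seed),
                 label = label),
            class = "regressor_spec")
}

#' @export
print.regressor_spec <- function(x, ...) {
  shown <- x$params[!vapply(x$params, is.null, logical(1))]
  cat(sprintf("Regressor spec %s: %s\n", x$label,
              paste(sprintf("%s=%s", names(shown), unlist(shown)),
                    collapse = ", ")))
  invisible(x)
}

#' The nine reference hybrid configurations
#'
#' The standard comparison set: conventional and inverse-distance weighted
#' k-nearest neighbours, the four support-vector kernels, random forest,
#' gradient boosting and the neural network, each with its default
#' hyperparameters.
#'
#' @param seed seed passed to every spec (stochastic families consume it).
#' @return A list of [regressor_spec()] objects.
#' @export
default_regressor_specs <- function(seed = 20190929L) {
  c(list(regressor_spec("knn", weighting = "uniform", seed = seed),
         regressor_spec("knn", weighting = "inverse", seed = seed)),
    lapply(c("linear", "polynomial", "radial", "sigmoid"),
           function(k) regressor_spec("svr", kernel = k, seed = seed)),
    list(regressor_spec("rf", seed = seed),
         regressor_spec("gbm", seed = seed),
         regressor_spec("ann", seed = seed)))
}

#' Train a second-stage regressor and predict
#'
#' Fits the specified regressor on the training rows of a hybrid dataset
#' (grey features to actual counts) and produces predictions for both the
#' training rows (in-sample: the query point takes part in its own
#' neighbourhood or ensemble) and the testing rows. Accuracy is computed with
#' [accuracy()] on the unrounded predictions. Stochastic families (rf, gbm,
#' ann) are deterministic given the spec's seed; the caller's RNG state is
#' preserved.
#'
#' @param spec a [regressor_spec()].
#' @param data a [build_features()] dataset with at least 3 training rows.
#' @return An object of class `hybrid_result`: the spec, per-year train and
#'   test predictions, `train_accuracy` and `test_accuracy` reports, the
#'   feature subset used, and for the ann family a `converged` flag.
#' @examples
#' sp <- split_series(china_occupational())
#' hd <- build_features(fit_all_grey(sp$train), sp)
#' train_predict(regressor_spec("knn"), hd)
#' @export
train_predict <- function(spec, data) {
  stopifnot(inherits(spec, "regressor_spec"), inherits(data, "hybrid_dataset"))
  tr <- data$group == "training"
  if (sum(tr) < 3L)
    stop("need at least 3 training rows", call. = FALSE)
  if (any(!is.finite(data$features)))
    stop("non-finite feature values", call. = FALSE)
  Xtr <- data$features[tr, , drop = FALSE]
  ytr <- data$labels[tr]
  backend <- switch(spec$family, knn = .fit_knn, svr = .fit_svr, rf = .fit_rf,
                    gbm = .fit_gbm, ann = .fit_ann)
  pred <- with_preserved_rng(spec$seed,
                             backend(spec$params, Xtr, ytr, data$features))
  p_tr <- pred$values[tr]
  p_te <- pred$values[!tr]
  structure(list(spec = spec,
                 years = data$years,
                 train_predictions = structure(p_tr, names = data$years[tr]),
                 test_predictions = structure(p_te, names = data$years[!tr]),
                 train_accuracy = accuracy(ytr, p_tr),
                 test_accuracy = accuracy(data$labels[!tr], p_te),
                 feature_subset = colnames(data$features),
                 converged = pred$converged),
            class = "hybrid_result")
}

#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf("Hybrid result %s on features {%s}\n", x$spec$label,
              paste(x$feature_subset, collapse = ", ")))
  cat(sprintf("  training MAPE %.2f%%, RMSE %.2f | testing MAPE %.2f%%, RMSE %.2f\n",
              x$train_accuracy$MAPE, x$train_accuracy$RMSE,
              x$test_accuracy$MAPE, x$test_accuracy$RMSE))
  if (isFALSE(x$converged))
    cat("  note: optimiser did not report convergence\n")
  invisible(x)
}

# --- family backends ------------------------------------------------------
# Each backend returns list(values = predictions for every row of X,
# converged = TRUE/NA). Query points are scored against the full training
# set, self-matches included.

.fit_knn <- function(p, Xtr, ytr, X) {
  k <- min(p$k, nrow(Xtr))
  vals <- apply(X, 1L, function(q) {
    d <- sqrt(colSums((t(Xtr) - q)^2))
    nb <- order(d)[seq_len(k)]
    if (p$weighting == "uniform") return(mean(ytr[nb]))
    exact <- nb[d[nb] < 1e-12]
    if (length(exact)) return(mean(ytr[exact]))  # zero distance dominates
    w <- 1 / d[nb]
    sum(w * ytr[nb]) / sum(w)
  })
  list(values = vals, converged = TRUE)
}

.fit_svr <- function(p, Xtr, ytr, X) {
  gamma <- if (is.null(p$gamma)) 1 / ncol(Xtr) else p$gamma
  fit <- e1071::svm(Xtr, ytr, type = "eps-regression", kernel = p$kernel,
                    cost = p$cost, epsilon = p$epsilon, degree = p$degree,
                    coef0 = p$coef0, gamma = gamma)
  list(values = as.numeric(stats::predict(fit, X)), converged = TRUE)
}

.fit_rf <- function(p, Xtr, ytr, X) {
  fit <- randomForest::randomForest(Xtr, ytr, mtry = min(p$mtry, ncol(Xtr)),
                                    ntree = p$ntree)
  list(values = as.numeric(stats::predict(fit, X)), converged = TRUE)
}

.fit_gbm <- function(p, Xtr, ytr, X) {
  fit <- xgboost::xgboost(Xtr, ytr,
                          nrounds = p$nrounds,
                          learning_rate = p$eta,
                          min_split_loss = p$gamma,
                          max_depth = p$max_depth,
                          subsample = p$subsample,
                          colsample_bytree = p$colsample_bytree,
                          min_child_weight = p$min_child_weight,
                          nthreads = 1L, verbosity = 0L)
  list(values = as.numeric(stats::predict(fit, X)), converged = TRUE)
}

# Single-hidden-layer network with logistic output on min-max scaled inputs
# and labels. Features are scaled per column over all rows (the grey
# forecasts for the test years are known at training time); labels over the
# training rows only. Multiple random restarts; keep the lowest training
# RMSE.
.fit_ann <- function(p, Xtr, ytr, X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  span <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2L, lo), 2L, span, "/")
  trn <- rownames(X) %in% rownames(Xtr)
  ylo <- min(ytr); yhi <- max(ytr)
  yspan <- if (yhi > ylo) yhi - ylo else 1
  ys <- (ytr - ylo) / yspan
  best <- NULL
  best_rmse <- Inf
  for (r in seq_len(max(1L, p$restarts))) {
    nn <- nnet::nnet(Xs[trn, , drop = FALSE], ys, size = p$size,
                     decay = p$decay, maxit = p$maxit, linout = FALSE,
                     abstol = p$tol, reltol = p$tol, trace = FALSE)
    rmse <- sqrt(mean((ys - as.numeric(stats::predict(nn, Xs[trn, , drop = FALSE])))^2))
    if (rmse < best_rmse) { best_rmse <- rmse; best <- nn }
  }
  vals <- as.numeric(stats::predict(best, Xs)) * yspan + ylo
  conv <- if (is.null(best$convergence)) NA else best$convergence == 0L
  list(values = vals, converged = conv)
}

# --- model selection ------------------------------------------------------

#' Select the best hybrid result
#'
#' Minimum testing MAPE; ties broken by testing RMSE, remaining ties by the
#' stable order of the input list.
#'
#' @param results a non-empty list of `hybrid_result` objects.
#' @return The winning `hybrid_result`.
#' @export
select_best <- function(results) {
  if (length(results) == 0L) stop("no results to select from", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "hybrid_result")))
  mape <- vapply(results, function(r) r$test_accuracy$MAPE, numeric(1))
  rmse <- vapply(results, function(r) r$test_accuracy$RMSE, numeric(1))
  results[[order(mape, rmse, seq_along(results))[1L]]]
}

#' Exhaustive grey-feature subset search
#'
#' Trains the given regressor on every non-empty subset of the available grey
#' feature columns (31 subsets for the full set of five) and ranks the
#' results by testing MAPE, ties broken by testing RMSE, then by larger
#' subsets first, then lexicographically. Per-subset failures are recorded,
#' not fatal.
#'
#' @param fits a `grey_fit_list` trained on `split$train`.
#' @param split a `dataset_split`.
#' @param spec the [regressor_spec()] to train on every subset.
#' @return A list with `ranking` (data frame: subset, size, test_MAPE,
#'   test_RMSE, train_MAPE), `results` (the `hybrid_result` per subset, in
#'   ranking order) and `failures` (named character vector).
#' @export
subset_search <- function(fits, split, spec) {
  models <- intersect(grey_models(), names(fits))
  if (length(models) == 0L) stop("no grey fits available", call. = FALSE)
  subsets <- unlist(lapply(seq_along(models), function(sz)
    utils::combn(models, sz, simplify = FALSE)), recursive = FALSE)
  keys <- vapply(subsets, paste, character(1), collapse = "+")
  results <- list()
  failures <- character()
  for (i in seq_along(subsets)) {
    res <- tryCatch(
      train_predict(spec, build_features(fits, split, subset = subsets[[i]])),
      error = function(e) e)
    if (inherits(res, "error")) failures[[keys[i]]] <- conditionMessage(res)
    else results[[keys[i]]] <- res
  }
  if (length(results) == 0L)
    stop("every subset failed; first error: ", failures[[1L]], call. = FALSE)
  mape <- vapply(results, function(r) r$test_accuracy$MAPE, numeric(1))
  rmse <- vapply(results, function(r) r$test_accuracy$RMSE, numeric(1))
  size <- lengths(strsplit(names(results), "+", fixed = TRUE))
  ord <- order(mape, rmse, -size, names(results))
  ranking <- data.frame(subset = names(results)[ord], size = size[ord],
                        test_MAPE = mape[ord], test_RMSE = rmse[ord],
                        train_MAPE = vapply(results[ord], function(r)
                          r$train_accuracy$MAPE, numeric(1)),
                        row.names = NULL)
  list(ranking = ranking, results = results[ord], failures = failures)
}

#' Accuracy table for hybrid results
#'
#' One training and one testing row per hybrid result, in the standard
#' reporting shape.
#'
#' @param results a list of `hybrid_result` objects.
#' @param digits reporting rounding (default 2 decimals, half up); `NULL`
#'   for unrounded.
#' @return A data frame with columns `model`, `group`, the five accuracy
#'   statistics and `n`.
#' @export
hybrid_accuracy_table <- function(results, digits = 2) {
  stopifnot(all(vapply(results, inherits, logical(1), "hybrid_result")))
  rows <- lapply(results, function(r)
    rbind(cbind(model = r$spec$label, group = "training", r$train_accuracy),
          cbind(model = r$spec$label, group = "testing", r$test_accuracy)))
  out <- do.call(rbind, rows)
  stat_cols <- c("ME", "RMSE", "MAE", "MPE", "MAPE")
  if (!is.null(digits))
    out[stat_cols] <- lapply(out[stat_cols], round_half_up, digits = digits)
  rownames(out) <- NULL
  out
}

#' Run the full hybrid experiment
#'
#' Convenience wrapper for the whole two-stage pipeline on one series:
#' chronological split, all five grey fits, feature construction, training
#' of every supplied regressor spec, and selection of the best by testing
#' MAPE/RMSE.
#'
#' @param series an [annual_series()].
#' @param specs list of [regressor_spec()] objects (default: the ten
#'   reference configurations).
#' @param train_fraction passed to [split_series()].
#' @param subset grey feature subset (default all five).
#' @return A list with `split`, `fits`, `dataset`, `results`,
#'   `table` (from [hybrid_accuracy_table()]) and `best`.
#' @examples
#' \donttest{
#' ex <- run_hybrid_experiment(china_occupational(),
#'                             specs = list(regressor_spec("knn")))
#' ex$table
#' }
#' @export
run_hybrid_experiment <- function(series, specs = default_regressor_specs(),
                                  train_fraction = 0.75,
                                  subset = grey_models()) {
  split <- split_series(series, train_fraction)
  fits <- fit_all_grey(split$train)
  data <- build_features(fits, split, subset = subset)
  results <- lapply(specs, train_predict, data = data)
  list(split = split, fits = fits, dataset = data, results = results,
       table = hybrid_accuracy_table(results), best = select_best(results))
}
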