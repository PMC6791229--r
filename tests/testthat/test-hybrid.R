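make_china_data <- function(subset = grey_models()) {
  sp <- china_split()
  build_features(fit_all_grey(sp$train), sp, subset = subset)
}

test_that("the feature matrix anchors the first row and covers the split", {
  hd <- make_china_data()
  expect_identical(dim(hd$features), c(13L, 5L))
  expect_identical(colnames(hd$features), grey_models())
  expect_identical(sum(hd$group == "training"), 10L)
  expect_identical(sum(hd$group == "testing"), 3L)
  # first training row: every grey model reproduces the first observation
  expect_equal(unname(hd$features[1, ]), rep(hd$labels[1], 5))
  expect_equal(hd$labels[1], 12212)
  # 2006 row against the reference fitted values (integer rounding)
  expect_equal(round_half_up(unname(hd$features[2, ])),
               c(14255, 14268, 14136, 14415, 14677))

  # subsets keep canonical column order regardless of request order
  hd2 <- make_china_data(subset = c("DGM", "EGM"))
  expect_identical(colnames(hd2$features), c("EGM", "DGM"))

  sp <- china_split()
  fits <- fit_all_grey(sp$train)
  expect_error(build_features(fits, sp, subset = character(0)), "at least one")
  expect_error(build_features(fits, sp, subset = c("EGM", "XGM")), "XGM")
})

test_that("inverse-distance knn interpolates distinct training rows exactly", {
  hd <- make_china_data()
  res <- train_predict(regressor_spec("knn", weighting = "inverse"), hd)
  expect_equal(unname(res$train_predictions),
               hd$labels[hd$group == "training"], tolerance = 1e-12)
  expect_equal(res$train_accuracy$MAPE, 0)
  expect_equal(res$train_accuracy$RMSE, 0)

  # property: holds for any dataset with pairwise-distinct feature rows
  for (seed in 1:3) {
    s <- generate_series("oscillating", n = 9, start = 500, slope = 30,
                         amplitude = 80, noise_sd = 0.2, seed = seed)
    sp <- split_series(s, 0.75)
    hd2 <- build_features(fit_all_grey(sp$train), sp)
    r2 <- train_predict(regressor_spec("knn", weighting = "inverse"), hd2)
    expect_equal(r2$train_accuracy$MAPE, 0)
  }
})

test_that("deterministic families ignore training-row order", {
  hd <- make_china_data()
  perm <- c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)
  hd_perm <- hd
  hd_perm$years <- c(hd$years[perm], hd$years[11:13])
  hd_perm$features <- rbind(hd$features[perm, ], hd$features[11:13, ])
  hd_perm$labels <- c(hd$labels[perm], hd$labels[11:13])
  for (spec in list(regressor_spec("knn"),
                    regressor_spec("svr", kernel = "radial"))) {
    a <- train_predict(spec, hd)
    b <- train_predict(spec, hd_perm)
    expect_equal(unname(a$test_predictions), unname(b$test_predictions),
                 tolerance = 1e-8)
  }
})

test_that("stochastic families are reproducible under a fixed seed", {
  hd <- make_china_data()
  for (fam in c("rf", "gbm")) {
    a <- train_predict(regressor_spec(fam, seed = 7L), hd)
    b <- train_predict(regressor_spec(fam, seed = 7L), hd)
    expect_identical(a$test_predictions, b$test_predictions)
  }
  a <- train_predict(regressor_spec("ann", restarts = 3L, seed = 7L), hd)
  b <- train_predict(regressor_spec("ann", restarts = 3L, seed = 7L), hd)
  expect_identical(a$test_predictions, b$test_predictions)
})

test_that("tree ensembles cannot extrapolate beyond the training labels", {
  hd <- make_china_data()
  ytr <- hd$labels[hd$group == "training"]
  for (fam in c("rf", "gbm")) {
    res <- train_predict(regressor_spec(fam, seed = 3L), hd)
    preds <- c(res$train_predictions, res$test_predictions)
    expect_true(all(preds >= min(ytr) - 1e-6))
    expect_true(all(preds <= max(ytr) + 1e-6))
  }
})

test_that("heavier weight decay shrinks the network towards the label mean", {
  hd <- make_china_data()
  spread <- vapply(c(1e-8, 1, 100), function(d) {
    res <- train_predict(regressor_spec("ann", decay = d, restarts = 5L,
                                        seed = 21L), hd)
    stats::var(c(res$train_predictions, res$test_predictions))
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("subset search enumerates all 31 subsets and ranks deterministically", {
  sp <- china_split()
  fits <- fit_all_grey(sp$train)
  spec <- regressor_spec("knn")
  search <- subset_search(fits, sp, spec)
  expect_identical(nrow(search$ranking), 31L)
  expect_length(search$failures, 0L)
  expect_true(all(diff(search$ranking$test_MAPE) >= 0))
  search2 <- subset_search(fits, sp, spec)
  expect_identical(search$ranking, search2$ranking)

  single <- subset_search(fits["DGM"], sp, spec)
  expect_identical(nrow(single$ranking), 1L)
  expect_identical(single$ranking$subset, "DGM")
})

test_that("select_best minimises testing MAPE with RMSE tie-break", {
  fake <- function(mape, rmse, label) {
    structure(list(spec = regressor_spec("knn", label = label),
                   test_accuracy = data.frame(MAPE = mape, RMSE = rmse)),
              class = "hybrid_result")
  }
  a <- fake(5, 100, "a"); b <- fake(5, 50, "b"); c_ <- fake(6, 1, "c")
  expect_identical(select_best(list(a, b, c_))$spec$label, "b")
  expect_identical(select_best(list(a))$spec$label, "a")
  # equal MAPE and RMSE: stable order keeps the first
  expect_identical(select_best(list(fake(5, 50, "x"), fake(5, 50, "y")))$spec$label,
                   "x")
  expect_error(select_best(list()), "no results")
})

test_that("regressor specs validate their hyperparameters", {
  expect_error(regressor_spec("knn", neighbours = 3), "unknown")
  expect_error(regressor_spec("svr", kernel = "laplace"), "kernel")
  expect_error(regressor_spec("knn", weighting = "gaussian"), "weighting")
  spec <- regressor_spec("gbm")
  expect_equal(spec$params[c("nrounds", "eta", "gamma", "max_depth")],
               list(nrounds = 100L, eta = 0.1, gamma = 0.5, max_depth = 3L))
  expect_length(default_regressor_specs(), 9L)
})
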