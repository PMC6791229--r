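test_that("accumulation, restoration and background values are exact", {
  expect_equal(ago(c(1, 1, 1)), c(1, 2, 3))
  expect_equal(ago(china_train_counts)[2], 12212 + 11805)
  expect_equal(ago(5), 5)
  expect_error(ago(c(1, -2, 3)), "positive")

  expect_equal(iago(c(2, 6, 14, 30, 62)), c(2, 4, 8, 16, 32))
  expect_equal(iago(ago(c(3, 1, 4))), c(3, 1, 4))
  expect_equal(iago(7), 7)
  for (seed in 1:5) {
    v <- generate_series("oscillating", n = 12, start = 50, amplitude = 10,
                         noise_sd = 0.2, seed = seed)$values
    expect_equal(iago(ago(v)), v)
  }

  expect_equal(background(c(2, 4)), 3)
  expect_equal(background(ago(china_train_counts))[1], 18114.5)
  expect_equal(background(rep(4.2, 6)), rep(4.2, 5))
  expect_error(background(3), "at least 2")
})

test_that("difference-form models recover the exact parameters of 2,4,8,16,32", {
  s <- geom_series(2, 2, 5)

  dgm <- fit_grey(s, "DGM")
  expect_equal(unname(coef(dgm)), c(2, 2), tolerance = 1e-10)
  expect_equal(dgm$fitted, s$values, tolerance = 1e-10)

  odgm <- fit_grey(s, "ODGM")
  expect_equal(unname(coef(odgm)), c(-0.5, 1), tolerance = 1e-10)
  expect_equal(odgm$fitted, s$values, tolerance = 1e-10)

  edgm <- fit_grey(s, "EDGM")
  expect_equal(unname(coef(edgm)), c(-2 / 3, 4 / 3), tolerance = 1e-10)
  expect_equal(edgm$fitted, s$values, tolerance = 1e-10)

  # the even model's exponential response is not in this model class
  egm <- fit_grey(s, "EGM")
  expect_gt(max(abs(egm$fitted - s$values)), 1e-6)
})

test_that("ODGM, EDGM and DGM reproduce homogeneous exponentials exactly", {
  cases <- expand.grid(q = c(0.5, 3, 120), r = c(0.6, 1.05, 1.8),
                       n = c(5, 9, 14))
  for (i in seq_len(nrow(cases))) {
    s <- geom_series(cases$q[i], cases$r[i], cases$n[i])
    truth <- cases$q[i] * cases$r[i]^(seq_len(cases$n[i] + 3) - 1)
    for (m in c("ODGM", "EDGM", "DGM")) {
      fit <- fit_grey(s, m)
      got <- c(fit$fitted, unname(forecast(fit, 3)))
      expect_equal(got, truth, tolerance = 1e-8)
    }
  }
})

test_that("the even-model development coefficient matches an independent OLS oracle", {
  x0 <- china_train_counts
  x1 <- cumsum(x0)
  z <- (x1[-1] + x1[-10]) / 2
  oracle <- stats::lm(x0[-1] ~ z)       # x0(k) = b + (-a) z(k)
  a_oracle <- -unname(coef(oracle)[2])
  b_oracle <- unname(coef(oracle)[1])
  fit <- fit_grey(annual_series(2005:2014, x0), "EGM")
  expect_equal(fit$a, a_oracle, tolerance = 1e-10)
  expect_equal(fit$b, b_oracle, tolerance = 1e-10)
  expect_equal(fit$a, -0.1032, tolerance = 1e-3)
})

test_that("every grey model preserves the first observation exactly", {
  series_set <- list(
    china_split()$train,
    generate_series("logistic", n = 12, start = 20, capacity = 500, rate = 0.4),
    generate_series("oscillating", n = 10, start = 300, slope = 12,
                    amplitude = 40, noise_sd = 0.1, seed = 4))
  for (s in series_set) {
    fits <- fit_all_grey(s)
    for (m in names(fits))
      expect_identical(fits[[m]]$fitted[1], s$values[1])
  }
})

test_that("restored values obey the models' growth-ratio identities", {
  s <- generate_series("oscillating", n = 11, start = 400, slope = 25,
                       amplitude = 60, noise_sd = 0.15, seed = 11)
  ratio_of <- function(v) unname(v[-(1:2)] / v[2:(length(v) - 1)])  # k >= 2
  egm <- fit_grey(s, "EGM")
  expect_equal(ratio_of(c(egm$fitted, forecast(egm, 2))),
               rep(exp(-egm$a), 11), tolerance = 1e-9)
  edgm <- fit_grey(s, "EDGM")
  expect_equal(ratio_of(c(edgm$fitted, forecast(edgm, 2))),
               rep((1 - edgm$a / 2) / (1 + edgm$a / 2), 11), tolerance = 1e-9)
  odgm <- fit_grey(s, "ODGM")
  expect_equal(ratio_of(c(odgm$fitted, forecast(odgm, 2))),
               rep(1 / (1 + odgm$a), 11), tolerance = 1e-9)
  dgm <- fit_grey(s, "DGM")
  expect_equal(ratio_of(c(dgm$fitted, forecast(dgm, 2))),
               rep(dgm$beta1, 11), tolerance = 1e-9)
})

test_that("constant series hit the analytic zero-coefficient limit", {
  s <- annual_series(2001:2008, rep(250, 8))
  egm <- fit_grey(s, "EGM")
  expect_lt(abs(egm$a), 1e-10)
  expect_equal(egm$fitted, s$values, tolerance = 1e-8)

  fits <- fit_all_grey(s)
  errs <- attr(fits, "errors")
  expect_named(errs, "Verhulst")  # collinear z and z^2 regressors
  expect_match(errs[["Verhulst"]], "singular")
  for (m in c("EGM", "EDGM", "ODGM", "DGM"))
    expect_equal(fits[[m]]$fitted, s$values, tolerance = 1e-8)
})

test_that("forecasts extend the fit deterministically and consistently", {
  fit <- fit_grey(china_split()$train, "DGM")
  expect_equal(unname(forecast(fit, 1)), unname(forecast(fit, 3))[1])
  expect_named(forecast(fit, 3), c("2015", "2016", "2017"))
  expect_error(forecast(fit, 0), "at least 1")
  expect_error(fit_grey(annual_series(2001:2003, 1:3), "EGM"), "at least 4")
})

test_that("the Verhulst fit on the Chinese series saturates monotonically", {
  fit <- fit_grey(china_split()$train, "Verhulst")
  expect_equal(round_half_up(fit$fitted[2]), 14677)
  vals <- c(fit$fitted, unname(forecast(fit, 10)))
  capacity <- fit$a / fit$b
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < capacity))
  expect_lt(fit$a, 0)
})

test_that("DGM recovers the growth ratio of geometric data", {
  # noise-free: exact recovery
  fit <- fit_grey(geom_series(7, 1.3, 12), "DGM")
  expect_equal(fit$beta1, 1.3, tolerance = 1e-10)

  # multiplicative noise sd 0.05, n = 20: median relative error under 5%
  rel_err <- vapply(1:100, function(seed) {
    s <- generate_series("geometric", n = 20, start = 10, ratio = 1.15,
                         noise_sd = 0.05, seed = seed)
    abs(fit_grey(s, "DGM")$beta1 - 1.15) / 1.15
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.05)
})

test_that("fit_all_grey collects per-model diagnostics without aborting", {
  fits <- fit_all_grey(china_split()$train)
  expect_s3_class(fits, "grey_fit_list")
  expect_identical(names(fits), grey_models())
  expect_length(attr(fits, "errors"), 0L)
  for (m in names(fits)) expect_equal(fits[[m]]$fitted[1], 12212)

  # geometric input: difference models exact, EGM not
  g <- geom_series(2, 2, 5)
  gf <- fit_all_grey(g)
  for (m in c("ODGM", "EDGM", "DGM"))
    expect_lt(max(abs(gf[[m]]$fitted - g$values)), 1e-8)
  expect_gt(max(abs(gf[["EGM"]]$fitted - g$values)), 1e-6)
})
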