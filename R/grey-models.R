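#' First-order accumulated generating operation (AGO)
#'
#' The cumulative sum that turns the raw sequence x0 into the accumulated
#' series x1, smoothing randomness so that (near-)exponential structure
#' emerges. Every grey model in this package is estimated on, or through, the
#' accumulated series.
#'
#' @param x0 numeric vector of positive values.
#' @return The accumulated series, same length as `x0`, strictly increasing.
#' @examples
#' ago(c(1, 1, 1))  # 1 2 3
#' @export
ago <- function(x0) {
  if (any(!is.finite(x0)) || any(x0 <= 0))
    stop("AGO requires strictly positive finite input", call. = FALSE)
  cumsum(x0)
}

#' Inverse accumulated generating operation (IAGO)
#'
#' First differencing that restores the raw sequence from the accumulated
#' one: the first element is kept as is, every later element is the
#' difference of consecutive accumulated values. `iago(ago(x))` equals `x`
#' exactly.
#'
#' @param x1 numeric vector (an accumulated series).
#' @return The restored series, same length as `x1`.
#' @examples
#' iago(c(2, 6, 14, 30, 62))  # 2 4 8 16 32
#' @export
iago <- function(x1) {
  if (length(x1) == 0L) stop("empty input", call. = FALSE)
  if (length(x1) == 1L) return(x1)
  c(x1[1L], diff(x1))
}

#' Mean-generated background values
#'
#' The even (mean-generated) background value of the GM(1,1) family:
#' `z(k) = (x1(k) + x1(k-1)) / 2` for `k = 2..n`. It is the regressor of the
#' even-form grey equations (EGM, EDGM) and, applied to the raw series, of
#' the grey Verhulst model.
#'
#' @param x1 numeric vector of length at least 2.
#' @return Numeric vector of length `length(x1) - 1`, indexed `k = 2..n`.
#' @export
background <- function(x1) {
  n <- length(x1)
  if (n < 2L) stop("background values need at least 2 points", call. = FALSE)
  (x1[-1L] + x1[-n]) / 2
}

#' The five grey model identifiers
#'
#' In canonical column order: even grey model (EGM), even difference grey
#' model (EDGM), original difference grey model (ODGM), discrete grey model
#' (DGM) and the grey Verhulst model.
#'
#' @return Character vector of the five model identifiers.
#' @export
grey_models <- function() c("EGM", "EDGM", "ODGM", "DGM", "Verhulst")

# tolerance below which a development coefficient is treated as zero and the
# analytic (linear) limit of the time response is used instead
.grey_tol <- 1e-12

# QR least squares with an explicit rank check; X spans several orders of
# magnitude for accumulated series, so no explicit normal equations.
.grey_ols <- function(X, y, model) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop(sprintf("%s: singular least-squares system (rank %d < %d); the series does not identify the model",
                 model, qrX$rank, ncol(X)), call. = FALSE)
  drop(qr.coef(qrX, y))
}

#' Fit a grey model
#'
#' Estimates one of the five GM(1,1)-family grey models on an annual series
#' by ordinary least squares on the model's defining difference form, and
#' restores fitted values to the original scale. All five models preserve the
#' first observation exactly (`fitted[1] == x0[1]`).
#'
#' The model forms (x0 the raw series, x1 its accumulation, z the
#' mean-generated background of x1):
#'
#' * **EGM** (even grey model): estimate `(a, b)` from
#'   `x0(k) = -a z(k) + b`, predict through the continuous whitening-equation
#'   solution `x1hat(k) = (x0(1) - b/a) exp(-a (k-1)) + b/a`, restore by
#'   differencing. When `|a|` is numerically zero the analytic limit
#'   `x1hat(k) = x0(1) + b (k-1)` is used.
#' * **EDGM** (even difference grey model): same `(a, b)` estimate as EGM,
#'   but prediction by the discrete recursion
#'   `x1hat(k) = ((1 - a/2) x1hat(k-1) + b) / (1 + a/2)`.
#' * **ODGM** (original difference grey model): estimate from
#'   `x0(k) = -a x1(k) + b`, recursion `x1hat(k) = (x1hat(k-1) + b) / (1 + a)`.
#' * **DGM** (discrete grey model): estimate `(beta1, beta2)` from
#'   `x1(k) = beta1 x1(k-1) + beta2`, run the recursion from `x1hat(1) = x0(1)`.
#' * **Verhulst**: the raw series itself is treated as the S-curve state
#'   variable (its first difference plays the role of x0); estimate `(a, b)`
#'   from `diff(x)(k) = -a z(k) + b z(k)^2` with z the background of the raw
#'   series, and evaluate the logistic time response
#'   `x1hat(k) = a x(1) / (b x(1) + (a - b x(1)) exp(a (k-1)))`, which is
#'   reported directly (no differencing). Its saturation level is `a / b`.
#'
#' @param series an [annual_series()] of length at least 4 (the training
#'   window).
#' @param model one of [grey_models()].
#' @return An object of class `grey_fit`: a list with the model identifier,
#'   estimated parameters (`a`, `b` or `beta1`, `beta2`), training years,
#'   the original values `x0`, the accumulated series `x1` (not for
#'   Verhulst), and the restored `fitted` values over the training years.
#' @examples
#' fit <- fit_grey(split_series(china_occupational())$train, "EGM")
#' fit
#' round(forecast(fit, 3))
#' @export
fit_grey <- function(series, model = grey_models()) {
  stopifnot(inherits(series, "annual_series"))
  model <- match.arg(model)
  x0 <- series$values
  n <- length(x0)
  if (n < 4L)
    stop("grey models need at least 4 observations", call. = FALSE)

  fit <- switch(model,
    EGM = , EDGM = {
      x1 <- ago(x0)
      z <- background(x1)
      ab <- .grey_ols(cbind(-z, 1), x0[-1L], model)
      list(a = ab[[1L]], b = ab[[2L]], x1 = x1)
    },
    ODGM = {
      x1 <- ago(x0)
      ab <- .grey_ols(cbind(-x1[-1L], 1), x0[-1L], model)
      if (abs(1 + ab[[1L]]) < .grey_tol)
        stop("ODGM: degenerate recursion (1 + a is numerically zero)",
             call. = FALSE)
      list(a = ab[[1L]], b = ab[[2L]], x1 = x1)
    },
    DGM = {
      x1 <- ago(x0)
      bb <- .grey_ols(cbind(x1[-n], 1), x1[-1L], model)
      list(beta1 = bb[[1L]], beta2 = bb[[2L]], x1 = x1)
    },
    Verhulst = {
      z <- background(x0)
      ab <- .grey_ols(cbind(-z, z^2), diff(x0), model)
      list(a = ab[[1L]], b = ab[[2L]], x1 = NULL)
    })
  if (model == "EDGM" && abs(1 + fit$a / 2) < .grey_tol)
    stop("EDGM: degenerate recursion (1 + a/2 is numerically zero)",
         call. = FALSE)

  out <- structure(c(list(model = model, years = series$years, x0 = x0), fit),
                   class = "grey_fit")
  out$fitted <- .grey_restore(out, n)
  out
}

# Restored model values at positions 1..m of the training index (m may exceed
# the training length; positions beyond it are forecasts). The first value is
# pinned to x0(1): every model anchors there analytically, and pinning keeps
# the identity exact in floating point.
.grey_restore <- function(fit, m) {
  out <- .grey_restore_raw(fit, m)
  out[1L] <- fit$x0[1L]
  out
}

.grey_restore_raw <- function(fit, m) {
  x0 <- fit$x0
  k <- seq_len(m)
  switch(fit$model,
    EGM = {
      a <- fit$a; b <- fit$b
      x1hat <- if (abs(a) < .grey_tol) x0[1L] + b * (k - 1)
               else (x0[1L] - b / a) * exp(-a * (k - 1)) + b / a
      iago(x1hat)
    },
    EDGM = {
      x1hat <- .grey_recur(m, x0[1L],
                           function(prev) ((1 - fit$a / 2) * prev + fit$b) / (1 + fit$a / 2))
      iago(x1hat)
    },
    ODGM = {
      x1hat <- .grey_recur(m, x0[1L],
                           function(prev) (prev + fit$b) / (1 + fit$a))
      iago(x1hat)
    },
    DGM = {
      x1hat <- .grey_recur(m, x0[1L],
                           function(prev) fit$beta1 * prev + fit$beta2)
      iago(x1hat)
    },
    Verhulst = {
      a <- fit$a; b <- fit$b; x11 <- x0[1L]
      a * x11 / (b * x11 + (a - b * x11) * exp(a * (k - 1)))
    })
}

.grey_recur <- function(m, first, step) {
  out <- numeric(m)
  out[1L] <- first
  for (k in seq_len(m)[-1L]) out[k] <- step(out[k - 1L])
  out
}

#' Forecast from a fitted grey model
#'
#' Extends the fitted model's time response or recursion beyond the training
#' window and restores the forecasts to the original scale with the same rule
#' used for the fitted values. For the four accumulation-based models the
#' forecast for horizon `h` is the restored value at index `n + h`. For the
#' Verhulst model the logistic time response is advanced one extra index step
#' (horizon `h` reads index `n + h + 1`); this reproduces the published
#' convention of the reference analysis — see the methods vignette.
#'
#' @param fit a `grey_fit` from [fit_grey()].
#' @param h forecast horizon in years, at least 1.
#' @return Numeric vector of `h` forecasts on the original scale, named by
#'   year.
#' @export
forecast <- function(fit, h) UseMethod("forecast")

#' @rdname forecast
#' @export
forecast.grey_fit <- function(fit, h) {
  if (!is.numeric(h) || h < 1) stop("'h' must be at least 1", call. = FALSE)
  h <- as.integer(h)
  n <- length(fit$x0)
  shift <- if (fit$model == "Verhulst") 1L else 0L
  all_vals <- .grey_restore(fit, n + h + shift)
  out <- all_vals[n + shift + seq_len(h)]
  names(out) <- max(fit$years) + seq_len(h)
  out
}

#' @export
fitted.grey_fit <- function(object, ...) {
  structure(object$fitted, names = object$years)
}

#' @export
residuals.grey_fit <- function(object, ...) {
  structure(object$x0 - object$fitted, names = object$years)
}

#' @export
coef.grey_fit <- function(object, ...) {
  if (object$model == "DGM") c(beta1 = object$beta1, beta2 = object$beta2)
  else c(a = object$a, b = object$b)
}

#' @export
print.grey_fit <- function(x, ...) {
  cat(sprintf("Grey model %s fitted on %d years (%d-%d)\n", x$model,
              length(x$x0), min(x$years), max(x$years)))
  cat("  parameters:",
      paste(sprintf("%s = %.6g", names(coef(x)), coef(x)), collapse = ", "),
      "\n")
  if (x$model == "Verhulst" && x$b != 0)
    cat(sprintf("  saturation level a/b = %.1f\n", x$a / x$b))
  invisible(x)
}

#' Fit all five grey models
#'
#' Applies [fit_grey()] for each of the five model identifiers on the same
#' training series. A failure in one model (for example the Verhulst rank
#' error on a constant series) is recorded per model and does not abort the
#' others.
#'
#' @param series an [annual_series()] (the training window).
#' @param models character vector of model identifiers, default all five.
#' @return An object of class `grey_fit_list`: a named list of `grey_fit`
#'   objects with an `errors` attribute (named character vector of per-model
#'   failure messages, empty when all succeeded).
#' @examples
#' fits <- fit_all_grey(split_series(china_occupational())$train)
#' names(fits)
#' @export
fit_all_grey <- function(series, models = grey_models()) {
  models <- match.arg(models, grey_models(), several.ok = TRUE)
  fits <- list()
  errors <- character()
  for (m in models) {
    res <- tryCatch(fit_grey(series, m), error = function(e) e)
    if (inherits(res, "error")) errors[[m]] <- conditionMessage(res)
    else fits[[m]] <- res
  }
  structure(fits, errors = errors, class = "grey_fit_list")
}

#' @export
`[.grey_fit_list` <- function(x, i) {
  structure(NextMethod(), errors = attr(x, "errors"), class = "grey_fit_list")
}

#' @export
print.grey_fit_list <- function(x, ...) {
  cat(sprintf("Grey fits: %s\n", paste(names(x), collapse = ", ")))
  errs <- attr(x, "errors")
  if (length(errs))
    cat("failed:", paste(sprintf("%s (%s)", names(errs), errs),
                         collapse = "; "), "\n")
  invisible(x)
}

#' Fitted-and-forecast table for a set of grey fits
#'
#' Assembles the standard year-by-model table: one row per year of the full
#' series, the actual count, and each grey model's restored fitted value
#' (training years) or forecast (later years).
#'
#' @param fits a `grey_fit_list` from [fit_all_grey()].
#' @param series the full [annual_series()] (training years plus the years to
#'   forecast).
#' @param digits rounding applied to the model columns for reporting;
#'   `NULL` leaves them unrounded. Internal computations are never rounded.
#' @return A data frame with columns `year`, `actual` and one column per
#'   fitted model.
#' @export
grey_table <- function(fits, series, digits = 0) {
  stopifnot(inherits(fits, "grey_fit_list"), inherits(series, "annual_series"))
  if (length(fits) == 0L) stop("no successful grey fits", call. = FALSE)
  years <- series$years
  out <- data.frame(year = years, actual = series$values)
  for (m in names(fits)) {
    f <- fits[[m]]
    n <- length(f$x0)
    h <- length(years) - n
    vals <- c(f$fitted, if (h > 0) forecast(f, h))
    if (!identical(f$years, years[seq_len(n)]))
      stop("fits were not trained on the head of 'series'", call. = FALSE)
    out[[m]] <- if (is.null(digits)) vals else round_half_up(vals, digits)
  }
  out
}

#' @export
plot.grey_fit_list <- function(x, series, ...) {
  stopifnot(inherits(series, "annual_series"))
  tab <- grey_table(x, series, digits = NULL)
  ylim <- range(tab[, -1])
  graphics::plot(tab$year, tab$actual, type = "b", pch = 16, ylim = ylim,
                 xlab = "year", ylab = "count", ...)
  for (i in seq_along(x))
    graphics::lines(tab$year, tab[[names(x)[i]]], col = i + 1, lty = 2)
  graphics::legend("topleft", legend = c("actual", names(x)),
                   col = c(1, seq_along(x) + 1),
                   lty = c(1, rep(2, length(x))), pch = c(16, rep(NA, length(x))),
                   bty = "n")
  invisible(tab)
}
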