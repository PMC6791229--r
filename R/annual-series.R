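#' Annual incidence series
#'
#' An `annual_series` holds an ordered run of consecutive calendar years with a
#' strictly positive case count per year, and optionally the number of
#' reporting regions (provinces) behind each count. It is the raw modelling
#' substrate for the grey models: the sequence of counts plays the role of the
#' original series x0 before accumulation.
#'
#' Invariants enforced by the constructor:
#' * years are consecutive integers (grey models assume equally spaced
#'   observations);
#' * all counts are strictly positive (least-squares estimation on the
#'   accumulated series and percentage errors both require positivity);
#' * `regions`, when given, is a vector of positive integers of the same
#'   length as `years`.
#'
#' @param years integer vector of calendar years, consecutive and increasing.
#' @param values numeric vector of positive case counts, one per year.
#' @param regions optional integer vector of positive reporting-region counts.
#' @return An object of class `annual_series`: a list with elements `years`,
#'   `values`, `regions` (possibly `NULL`) and `normalized` (logical flag set
#'   by [normalize_per_region()]).
#' @examples
#' s <- annual_series(2005:2008, c(120, 140, 155, 170))
#' s
#' @seealso [read_annual_series()], [split_series()], [generate_series()]
#' @export
annual_series <- function(years, values, regions = NULL) {
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) == 0L)
    stop("an annual series needs at least one observation", call. = FALSE)
  if (length(years) != length(values))
    stop("'years' and 'values' must have the same length", call. = FALSE)
  if (anyNA(years) || anyNA(values))
    stop("years and values must not contain missing entries", call. = FALSE)
  dup <- years[duplicated(years)]
  if (length(dup))
    stop(sprintf("duplicate year(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  ord <- order(years)
  years <- years[ord]
  values <- values[ord]
  if (length(years) > 1L) {
    gaps <- which(diff(years) != 1L)
    if (length(gaps)) {
      missing_years <- unlist(lapply(gaps, function(i)
        seq(years[i] + 1L, years[i + 1L] - 1L)))
      stop(sprintf("year gap(s): missing %s",
                   paste(missing_years, collapse = ", ")), call. = FALSE)
    }
  }
  bad <- which(values <= 0)
  if (length(bad))
    stop(sprintf("non-positive count in year(s): %s",
                 paste(years[bad], collapse = ", ")), call. = FALSE)
  if (!is.null(regions)) {
    regions <- as.integer(regions[ord])
    if (length(regions) != length(years))
      stop("'regions' must have one entry per year", call. = FALSE)
    if (anyNA(regions) || any(regions <= 0L))
      stop("'regions' must be positive integers", call. = FALSE)
  }
  structure(list(years = years, values = values, regions = regions,
                 normalized = FALSE),
            class = "annual_series")
}

#' @export
length.annual_series <- function(x) length(x$years)

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("Annual series: %d year%s (%d-%d)%s%s\n",
              length(x), if (length(x) == 1L) "" else "s",
              min(x$years), max(x$years),
              if (is.null(x$regions)) "" else ", with region counts",
              if (isTRUE(x$normalized)) ", per-region normalized" else ""))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  d <- data.frame(year = x$years, count = x$values)
  if (!is.null(x$regions)) d$regions <- x$regions
  d
}

#' Read an annual series from CSV
#'
#' The expected schema is a header row followed by `year,count` and an
#' optional third `regions` column. Rows are sorted by year and the
#' `annual_series` invariants (consecutive years, positive counts) are
#' enforced, so malformed files fail loudly with the offending year named.
#'
#' @param path path to a CSV file.
#' @return An [annual_series()].
#' @examples
#' f <- system.file("extdata", "china_occupational_2005_2017.csv",
#'                  package = "greycast")
#' read_annual_series(f)
#' @export
read_annual_series <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "count")
  if (!all(need %in% names(d)))
    stop("CSV must have columns 'year,count' (optional 'regions')",
         call. = FALSE)
  annual_series(d$year, d$count,
                regions = if ("regions" %in% names(d)) d$regions else NULL)
}

#' Write an annual series to CSV
#'
#' Writes the `year,count[,regions]` schema read by [read_annual_series()].
#' Integer-valued counts are written without a decimal point so that a
#' read/write cycle round-trips exactly.
#'
#' @param x an [annual_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annual_series <- function(x, path) {
  stopifnot(inherits(x, "annual_series"))
  d <- as.data.frame(x)
  if (all(d$count == round(d$count))) d$count <- as.integer(round(d$count))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The Chinese occupational-disease series, 2005-2017
#'
#' Annual numbers of newly reported occupational-disease cases in China from
#' 2005 through 2017, together with the number of provinces reporting in each
#' year (29 in 2006, 31 from 2015 on, 30 otherwise). This 13-point series is
#' the canonical worked example for the package and the series all shipped
#' reference numbers refer to.
#'
#' @return An [annual_series()] of length 13 with region counts.
#' @examples
#' china_occupational()
#' @export
china_occupational <- function() {
  read_annual_series(system.file("extdata", "china_occupational_2005_2017.csv",
                                 package = "greycast", mustWork = TRUE))
}

#' Per-region normalization
#'
#' Divides each year's count by the number of reporting regions for that year,
#' making years with different reporting coverage comparable. The region
#' counts are retained so the transformation is invertible;
#' `denormalize_per_region()` undoes it exactly (to floating-point tolerance).
#'
#' Note that the grey models in this package are fitted on raw counts by
#' default: all shipped reference values are on the raw-count scale, and the
#' first fitted value of every grey model equals the raw first observation.
#' Normalization is an optional preprocessing step, never applied silently.
#'
#' @param x an [annual_series()] with `regions` present.
#' @return The normalized (resp. denormalized) `annual_series`.
#' @export
normalize_per_region <- function(x) {
  stopifnot(inherits(x, "annual_series"))
  if (is.null(x$regions))
    stop("cannot normalize: no region counts in this series", call. = FALSE)
  if (isTRUE(x$normalized))
    stop("series is already per-region normalized", call. = FALSE)
  out <- annual_series(x$years, x$values / x$regions, regions = x$regions)
  out$normalized <- TRUE
  out
}

#' @rdname normalize_per_region
#' @export
denormalize_per_region <- function(x) {
  stopifnot(inherits(x, "annual_series"))
  if (!isTRUE(x$normalized))
    stop("series is not per-region normalized", call. = FALSE)
  annual_series(x$years, x$values * x$regions, regions = x$regions)
}

#' Chronological train/test split
#'
#' Splits a series into a training head and a testing tail, never shuffling:
#' the training years immediately precede the testing years. The training size
#' is `floor(n * train_fraction + 0.5)` (round half up). The default fraction
#' of 0.75 reproduces the canonical 10-train / 3-test split of the 13-year
#' Chinese series (training 2005-2014, testing 2015-2017); see the methods
#' vignette for why this, and not a literal two-thirds, is the anchor.
#'
#' @param x an [annual_series()] of length at least 4.
#' @param train_fraction fraction of observations assigned to training,
#'   strictly between 0 and 1.
#' @return An object of class `dataset_split`: a list with `annual_series`
#'   elements `train` and `test`.
#' @examples
#' split_series(china_occupational())
#' @export
split_series <- function(x, train_fraction = 0.75) {
  stopifnot(inherits(x, "annual_series"))
  n <- length(x)
  if (n < 4L)
    stop("series too short to split: need at least 4 observations",
         call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie strictly between 0 and 1", call. = FALSE)
  n_train <- floor(n * train_fraction + 0.5)
  n_train <- max(3L, min(n - 1L, as.integer(n_train)))
  take <- function(idx) {
    annual_series(x$years[idx], x$values[idx],
                  regions = if (is.null(x$regions)) NULL else x$regions[idx])
  }
  structure(list(train = take(seq_len(n_train)),
                 test = take(seq.int(n_train + 1L, n))),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Chronological split: %d training years (%d-%d), %d testing years (%d-%d)\n",
              length(x$train), min(x$train$years), max(x$train$years),
              length(x$test), min(x$test$years), max(x$test$years)))
  invisible(x)
}

#' @export
plot.annual_series <- function(x, ...) {
  graphics::plot(x$years, x$values, type = "b", pch = 16,
                 xlab = "year", ylab = "count", ...)
  invisible(x)
}
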