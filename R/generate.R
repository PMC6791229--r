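#' Generate synthetic annual series
#'
#' Produces positive annual series of three qualitative shapes, with optional
#' multiplicative log-normal noise, for property testing and simulation:
#'
#' * `"geometric"`: the homogeneous exponential sequence
#'   `start * ratio^(k-1)` — the sequence class that the difference-form grey
#'   models (ODGM, EDGM, DGM) reproduce exactly;
#' * `"logistic"`: a discrete logistic (S-curve) approach to a carrying
#'   capacity, `capacity / (1 + (capacity/start - 1) * exp(-rate*(k-1)))` —
#'   the regime the grey Verhulst model is built for;
#' * `"oscillating"`: a linear trend plus a bounded sinusoid, a stand-in for
#'   noisy surveillance counts with no clean exponential structure.
#'
#' Noise is multiplicative log-normal: each value is multiplied by
#' `exp(rnorm(1, 0, noise_sd))`, so the series stays positive for any
#' `noise_sd` and `noise_sd = 0` returns the exact deterministic sequence.
#' With a fixed `seed` the output is reproducible; the caller's RNG state is
#' left untouched.
#'
#' @param kind one of `"geometric"`, `"logistic"`, `"oscillating"`.
#' @param n series length, at least 4.
#' @param start first value (all kinds); must be positive.
#' @param ratio per-step growth ratio (geometric), positive.
#' @param capacity carrying capacity (logistic), greater than `start`.
#' @param rate logistic growth rate, positive.
#' @param slope per-year trend increment (oscillating).
#' @param amplitude,period sinusoid amplitude and period (oscillating); the
#'   deterministic sequence must stay strictly positive.
#' @param noise_sd standard deviation of the log-normal multiplicative noise.
#' @param seed optional integer seed for the noise.
#' @param start_year first calendar year of the series.
#' @return An [annual_series()] of length `n`.
#' @examples
#' generate_series("geometric", n = 5, start = 2, ratio = 2)  # 2 4 8 16 32
#' generate_series("logistic", n = 20, start = 5, capacity = 100, rate = 0.6)
#' @export
generate_series <- function(kind = c("geometric", "logistic", "oscillating"),
                            n, start = 100, ratio = 1.1, capacity = 1000,
                            rate = 0.5, slope = 10, amplitude = 20,
                            period = 6, noise_sd = 0, seed = NULL,
                            start_year = 2001L) {
  kind <- match.arg(kind)
  if (n < 4L) stop("'n' must be at least 4", call. = FALSE)
  if (start <= 0) stop("'start' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  k <- seq_len(n)
  base <- switch(kind,
    geometric = {
      if (ratio <= 0) stop("'ratio' must be positive", call. = FALSE)
      start * ratio^(k - 1)
    },
    logistic = {
      if (capacity <= start)
        stop("'capacity' must exceed 'start'", call. = FALSE)
      if (rate <= 0) stop("'rate' must be positive", call. = FALSE)
      capacity / (1 + (capacity / start - 1) * exp(-rate * (k - 1)))
    },
    oscillating = {
      start + slope * (k - 1) + amplitude * sin(2 * pi * k / period)
    })
  if (any(base <= 0))
    stop("parameters produce non-positive values; increase 'start' or shrink 'amplitude'",
         call. = FALSE)
  if (noise_sd > 0) {
    noise <- with_preserved_rng(seed, stats::rnorm(n, 0, noise_sd))
    base <- base * exp(noise)
  }
  annual_series(start_year + k - 1L, base)
}

# Run `expr` under `set.seed(seed)` (when non-NULL) without disturbing the
# caller's RNG stream.
with_preserved_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
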