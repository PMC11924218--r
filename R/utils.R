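# Unit conventions: temperatures are kelvin everywhere inside the package;
# Celsius is accepted/emitted only at I/O boundaries and in *_C columns.

#' Temperature unit conversion
#'
#' Kelvin is the single internal temperature unit; these helpers convert at
#' I/O boundaries.
#'
#' @param x numeric vector of temperatures.
#' @return numeric vector.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

#' Default descending temperature grid for freezing spectra
#'
#' 0.5 K bins from 272.15 K (-1 C) down to 238.15 K (-35 C), resolving the
#' -8 to -25 C window where marine microbial INMs are active while leaving
#' room for the colder dust-dominated regime.
#'
#' @param t_warm warm end \[K\].
#' @param t_cold cold end \[K\].
#' @param step bin width \[K\], positive.
#' @return strictly descending numeric vector of grid temperatures \[K\].
#' @export
default_temperature_grid <- function(t_warm = 272.15, t_cold = 238.15,
                                     step = 0.5) {
  stopifnot(is.numeric(t_warm), is.numeric(t_cold), t_warm > t_cold, step > 0)
  seq(t_warm, t_cold, by = -step)
}

#' Clopper-Pearson binomial confidence interval
#'
#' Exact (beta-quantile) two-sided interval for a binomial proportion; used
#' for per-bin frozen fractions, where droplet counts are small (~100).
#'
#' @param k successes (vector).
#' @param n trials (vector or scalar).
#' @param level confidence level.
#' @return two-column matrix `lower`, `upper`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(all(k >= 0), all(n > 0), all(k <= n), level > 0, level < 1)
  a <- (1 - level) / 2
  n <- rep_len(n, length(k))
  lo <- ifelse(k == 0, 0, qbeta(a, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  cbind(lower = lo, upper = hi)
}

# strictly descending grid check shared by spectrum/model code
.check_grid <- function(temperature_grid) {
  if (length(temperature_grid) == 0) stop("temperature grid is empty")
  if (any(!is.finite(temperature_grid))) stop("temperature grid must be finite")
  if (length(temperature_grid) > 1 && any(diff(temperature_grid) >= 0))
    stop("temperature grid must be strictly descending")
  invisible(temperature_grid)
}

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

.scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name))
  x
}
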