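#' MSD series: an ordered time/MSD table
#'
#' The package's tabular exchange type for mean-square-displacement data:
#' a tibble with columns `time` and `msd` (strictly increasing positive
#' times, positive MSDs) and a dimensionality tag (1, 2 or 3) saying in how
#' many spatial dimensions the displacements were measured. All fitting
#' functions accept any data frame with these two columns;
#' `as_msd_series()` validates and tags one.
#'
#' @param data A data frame with numeric columns `time` and `msd`.
#' @param dimensionality 1, 2 or 3; defaults to an existing tag on `data`,
#'   else 2.
#' @return A tibble of class `msd_series` with attribute `dimensionality`.
#' @examples
#' as_msd_series(data.frame(time = c(0.035, 0.07), msd = c(0.3, 0.5)))
#' @export
as_msd_series <- function(data, dimensionality = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame.", call. = FALSE)
  if (!all(c("time", "msd") %in% names(data))) {
    stop("`data` needs columns `time` and `msd`.", call. = FALSE)
  }
  if (is.null(dimensionality)) {
    dimensionality <- attr(data, "dimensionality") %||% 2
  }
  dim_factor(dimensionality)  # validates
  time <- as.numeric(data$time); m <- as.numeric(data$msd)
  if (length(time) < 1L) stop("MSD series must have at least one row.", call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(m))) {
    stop("MSD series must be finite.", call. = FALSE)
  }
  if (any(time <= 0) || any(m <= 0)) {
    stop("MSD series times and values must be positive.", call. = FALSE)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop("MSD series times must be strictly increasing.", call. = FALSE)
  }
  out <- tibble::tibble(time = time, msd = m)
  attr(out, "dimensionality") <- as.integer(dimensionality)
  class(out) <- c("msd_series", class(out))
  out
}

#' @rdname as_msd_series
#' @param x Object to test.
#' @export
is_msd_series <- function(x) inherits(x, "msd_series")

# 2D-equivalent MSD values: the model core works in the canonical plane
msd_series_2d <- function(series) {
  series <- as_msd_series(series)
  series$msd / dim_factor(attr(series, "dimensionality"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
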