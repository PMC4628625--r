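#' Read and write MSD series as CSV
#'
#' Plain comma-separated files with a required header: columns `time,msd`
#' and optionally `dim` (a constant 1, 2 or 3; default 2 when absent).
#' Values use `.` as the decimal mark, UTF-8 encoding. Writing preserves
#' full double precision, so a write/read round trip is lossless well past
#' 12 significant digits.
#'
#' @param path File path.
#' @param series For writing: anything [as_msd_series()] accepts.
#' @return `read_msd_csv()`: an [as_msd_series()] tibble. `write_msd_csv()`:
#'   `path`, invisibly.
#' @export
read_msd_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "msd") %in% names(df))) {
    stop("MSD CSV must have header columns time,msd[,dim]; got: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  dimensionality <- 2
  if ("dim" %in% names(df)) {
    d <- unique(df$dim)
    if (length(d) != 1L) {
      stop("`dim` column must be constant within one MSD series.", call. = FALSE)
    }
    dimensionality <- d
  }
  as_msd_series(df[c("time", "msd")], dimensionality = dimensionality)
}

#' @rdname read_msd_csv
#' @export
write_msd_csv <- function(series, path) {
  series <- as_msd_series(series)
  out <- tibble::tibble(
    time = series$time, msd = series$msd,
    dim = attr(series, "dimensionality")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write 2D trajectories as CSV
#'
#' Header columns `time,x,y`, same CSV dialect as [read_msd_csv()].
#'
#' @param path File path.
#' @param traj A data frame with columns `time`, `x`, `y`.
#' @return `read_trajectory_csv()`: a `trajectory_table` tibble.
#'   `write_trajectory_csv()`: `path`, invisibly.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "x", "y") %in% names(df))) {
    stop("trajectory CSV must have header columns time,x,y; got: ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  if (is.unsorted(df$time, strictly = TRUE)) {
    stop("trajectory times must be strictly increasing.", call. = FALSE)
  }
  out <- tibble::as_tibble(df[c("time", "x", "y")])
  class(out) <- c("trajectory_table", class(out))
  out
}

#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!is.data.frame(traj) || !all(c("time", "x", "y") %in% names(traj))) {
    stop("`traj` must be a data frame with columns time, x, y.", call. = FALSE)
  }
  readr::write_csv(tibble::as_tibble(traj[c("time", "x", "y")]), path)
  invisible(path)
}

#' Write a fitted model as JSON and as a one-line TSV
#'
#' The JSON form carries every field of the fit (estimates, fixed
#' calibration, residual, provenance); the TSV form is a flat single data
#' row under a header, convenient for shell pipelines that accumulate fits
#' across files.
#'
#' @param fit An `msd_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "msd_fit"))
  x <- unclass(fit)
  x$data <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_fit_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "msd_fit"))
  readr::write_tsv(glance(fit), path)
  invisible(path)
}
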