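# Internal helpers shared across modules. Times are carried as POSIXct (UTC) at
# the interfaces and as numeric minutes internally.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
.time_min <- function(t) {
  if (inherits(t, "POSIXt")) as.numeric(t) / 60 else as.numeric(t)
}

#' @keywords internal
.as_time <- function(min) {
  as.POSIXct(min * 60, origin = "1970-01-01", tz = "UTC")
}

# Index of the reading nearest to t0 (minutes), or NA if none within tol.
# Ties (equidistant readings) resolve to the earlier reading.
#' @keywords internal
.nearest_idx <- function(times_min, t0, tol = 2.5) {
  n <- length(times_min)
  if (n == 0L) return(NA_integer_)
  i <- findInterval(t0, times_min)
  lo <- max(i, 1L)
  hi <- min(i + 1L, n)
  d_lo <- abs(times_min[lo] - t0)
  d_hi <- abs(times_min[hi] - t0)
  idx <- if (d_lo <= d_hi) lo else hi
  if (abs(times_min[idx] - t0) <= tol) idx else NA_integer_
}

# TRUE when a trace sits on a complete regular grid at `interval` minutes.
#' @keywords internal
.is_regular_grid <- function(times_min, interval) {
  n <- length(times_min)
  if (n < 2L) return(TRUE)
  d <- diff(times_min)
  all(abs(d - interval) < 1e-6)
}

#' @keywords internal
.assert_one_participant <- function(df) {
  if ("participant_id" %in% names(df) &&
      length(unique(df$participant_id)) > 1L) {
    stop("expected data for a single participant", call. = FALSE)
  }
  invisible(df)
}

#' Convert glucose quantities between mmol/L and mg/dL
#'
#' The molar-mass-based factor 18.016 mg/dL per mmol/L is used throughout the
#' package; all internal computation is in mmol/L.
#'
#' @param x numeric glucose values.
#' @return numeric vector in the other unit.
#' @examples
#' mmol_to_mgdl(10)   # 180.16
#' mgdl_to_mmol(70.3) # ~3.9
#' @export
mmol_to_mgdl <- function(x) x * 18.016

#' @rdname mmol_to_mgdl
#' @export
mgdl_to_mmol <- function(x) x / 18.016
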