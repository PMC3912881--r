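#' RR-interval series
#'
#' An `rr_series` is a tibble with one row per heartbeat interval:
#' `t_s`, the cumulative time (seconds from recording start) of the beat that
#' *terminates* the interval, and `rr_ms`, the interval length in
#' milliseconds. The time of the very first beat is `t_s[1] - rr_ms[1]/1000`,
#' so the full beat sequence is recoverable from the table alone. Optional
#' `participant_id` and `segment` labels may be carried as extra columns.
#'
#' Intervals outside the physiologically plausible 200–3000 ms range are
#' flagged with a warning on construction but are never deleted here;
#' removing artifacts is [median_filter_rr()]'s job.
#'
#' @param t_s Numeric vector of cumulative beat times (s), strictly
#'   increasing.
#' @param rr_ms Numeric vector of intervals (ms), same length as `t_s`; each
#'   must equal the successive difference of beat times (1e-6 s tolerance).
#' @param participant_id,segment Optional labels attached as columns.
#'
#' @return A tibble of class `rr_series`.
#' @seealso [generate_rr()], [read_rr_csv()], [write_rr_csv()]
#' @export
rr_series <- function(t_s, rr_ms, participant_id = NULL, segment = NULL) {
  if (length(t_s) != length(rr_ms)) {
    abort("`t_s` and `rr_ms` must have the same length.")
  }
  if (length(t_s) < 1) abort("an rr_series needs at least one interval.")
  if (any(rr_ms <= 0)) {
    abort(sprintf(
      "nonpositive RR interval at position %d (%.3f ms).",
      which(rr_ms <= 0)[1], rr_ms[which(rr_ms <= 0)[1]]
    ))
  }
  if (any(diff(t_s) <= 0)) abort("beat times must be strictly increasing.")
  implied <- diff(c(t_s[1] - rr_ms[1] / 1000, t_s)) * 1000
  if (any(abs(implied - rr_ms) > 1e-3 + 1e-9)) { # 1e-6 s
    abort("`rr_ms` must match successive beat-time differences.")
  }
  n_flag <- sum(rr_ms < 200 | rr_ms > 3000)
  if (n_flag > 0) {
    warn(sprintf(
      "%d interval(s) outside the plausible 200-3000 ms range (not removed).",
      n_flag
    ))
  }
  out <- tibble(t_s = as.numeric(t_s), rr_ms = as.numeric(rr_ms))
  if (!is.null(participant_id)) out$participant_id <- participant_id
  if (!is.null(segment)) out$segment <- segment
  new_rr_series(out)
}

new_rr_series <- function(x, ...) {
  structure(x, class = c("rr_series", class(tibble())), ...)
}

#' Read / write the RR CSV dialect
#'
#' Plain CSV with one header line and columns `t_s` (cumulative seconds,
#' written with 6 decimals) and `rr_ms`; one interval per row.
#'
#' @param path File path.
#' @return `read_rr_csv()` returns an [rr_series()] tibble.
#' @export
read_rr_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    t_s = readr::col_double(), rr_ms = readr::col_double(),
    .default = readr::col_guess()
  ))
  rr_series(x$t_s, x$rr_ms)
}

#' @rdname read_rr_csv
#' @param rr An [rr_series()].
#' @export
write_rr_csv <- function(rr, path) {
  out <- tibble(t_s = sprintf("%.6f", rr$t_s), rr_ms = rr$rr_ms)
  readr::write_csv(out, path)
  invisible(path)
}

# time of the first beat (origin of the series)
rr_origin <- function(rr) rr$t_s[1] - rr$rr_ms[1] / 1000
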