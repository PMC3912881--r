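#' Detect R peaks in a single-lead ECG trace
#'
#' Simple amplitude-threshold detector for clean (synthetic or
#' device-quality) traces: local maxima above an adaptive threshold (half
#' the 99th amplitude percentile above the median), enforced to be at least
#' `refractory` seconds apart; when two candidates fall inside the
#' refractory window the larger survives.
#'
#' @param ecg A tibble with columns `t_s`, `amplitude` (e.g. from
#'   [synthesize_ecg()]); sampling must be uniform to within 1%.
#' @param refractory Minimum beat separation, s (>= 0.2).
#' @return Numeric vector of beat times, s. A flat trace yields an empty
#'   result with a warning.
#' @export
detect_r_peaks <- function(ecg, refractory = 0.25) {
  if (refractory < 0.2) abort("`refractory` must be at least 0.2 s.")
  dt <- diff(ecg$t_s)
  if (max(dt) > 1.01 * min(dt)) abort("ECG sampling must be uniform within 1%.")
  x <- ecg$amplitude
  if (sd(x) == 0) {
    warn("flat ECG trace: no peaks detected.")
    return(numeric(0))
  }
  thresh <- median(x) + 0.5 * (stats::quantile(x, 0.99, names = FALSE) - median(x))
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE) &
    x > thresh
  cand <- which(is_peak)
  # keep largest peak inside each refractory window
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || ecg$t_s[i] - ecg$t_s[keep[length(keep)]] >= refractory) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  ecg$t_s[keep]
}

#' Median-filter an RR series in the beat domain
#'
#' Replaces each interval by the median of its `kernel`-wide neighbourhood
#' (replicate padding at the edges), then rebuilds beat times by cumulative
#' summation from the original first beat time. Run *before* spline
#' resampling: an ectopic couplet is a one-or-two-beat excursion here, but
#' smears across many samples once interpolated.
#'
#' @param rr An [rr_series()].
#' @param kernel Odd window width in beats, >= 3.
#' @return A repaired [rr_series()].
#' @export
median_filter_rr <- function(rr, kernel = 5L) {
  if (kernel %% 2 == 0) abort("`kernel` must be odd.")
  if (kernel < 3) abort("`kernel` must be at least 3.")
  n <- nrow(rr)
  if (n < kernel) abort("series shorter than the filter kernel.")
  h <- (kernel - 1L) %/% 2L
  padded <- c(rep(rr$rr_ms[1], h), rr$rr_ms, rep(rr$rr_ms[n], h))
  filtered <- vapply(
    seq_len(n),
    function(i) median(padded[i:(i + kernel - 1L)]),
    numeric(1)
  )
  suppressWarnings(
    rr_series(rr_origin(rr) + cumsum(filtered) / 1000, filtered)
  )
}

#' Resample an RR series to a uniform tachogram
#'
#' Fits a natural cubic spline through the (beat time, interval) knots and
#' evaluates it on a uniform grid spanning the first to last beat time —
#' the standard transformation of an irregular tachogram into an evenly
#' sampled series ready for frequency-domain analysis. The interpolant
#' passes through every knot exactly.
#'
#' @param rr An [rr_series()] with at least 4 beats.
#' @param rate Target sampling rate, Hz (default 4).
#' @return A `uniform_series`: tibble with `t_s`, `value` (ms) and
#'   attribute `rate`.
#' @export
resample_rr <- function(rr, rate = 4) {
  if (nrow(rr) < 4) abort("resampling needs at least 4 beats.")
  if (anyDuplicated(rr$t_s)) abort("duplicate beat times.")
  grid <- seq(rr$t_s[1], rr$t_s[nrow(rr)], by = 1 / rate)
  sp <- spline(rr$t_s, rr$rr_ms, xout = grid, method = "natural")
  uniform_series(grid, sp$y, rate)
}

#' @rdname resample_rr
#' @param t_s,values Time grid (s) and sample values.
#' @export
uniform_series <- function(t_s, values, rate) {
  if (rate <= 0) abort("`rate` must be positive.")
  if (length(values) < 2) abort("a uniform series needs at least 2 samples.")
  structure(
    tibble(t_s = t_s, value = values),
    class = c("uniform_series", class(tibble())),
    rate = rate
  )
}

#' Zero-phase Butterworth bandpass filtering
#'
#' Designs a Butterworth bandpass of the given order (MATLAB/Octave design
#' convention: an order-4 bandpass has 4 pole pairs) and applies it
#' forward-backward (`signal::filtfilt`) by default, so windowed band
#' powers stay time-aligned with segment boundaries; a causal single pass
#' is available with `zero_phase = FALSE`.
#'
#' @param series A `uniform_series`.
#' @param low,high Band edges, Hz; must satisfy `0 < low < high < rate/2`.
#' @param order Filter order (default 4).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return A `uniform_series` on the same grid.
#' @export
butterworth_filter <- function(series, low, high, order = 4L,
                               zero_phase = TRUE) {
  rate <- attr(series, "rate")
  if (!(low > 0 && low < high && high < rate / 2)) {
    abort("band edges must satisfy 0 < low < high < Nyquist (rate/2).")
  }
  if (order < 1) abort("`order` must be at least 1.")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  y <- if (zero_phase) {
    signal::filtfilt(bf, series$value)
  } else {
    as.numeric(signal::filter(bf, series$value))
  }
  uniform_series(series$t_s, y, rate)
}

#' Windowed LF/HF band-power track
#'
#' Band-filters a uniform tachogram into LF (0.04–0.15 Hz) and HF
#' (0.15–0.4 Hz) components with zero-phase Butterworth filters of the
#' given order, then computes per-window powers (mean squared component
#' sample) over overlapping windows and their LF/HF ratio. The series mean
#' is removed before filtering. Windows whose span intersects the first or
#' last `1.5/low_edge` seconds are dropped by default, because filter edge
#' transients inflate power there.
#'
#' @param series A `uniform_series` tachogram (ms).
#' @param window Window length, s (>= 25 s, one full cycle of 0.04 Hz).
#' @param hop Hop between window centers, s (<= window).
#' @param lf_band,hf_band Band edges, Hz.
#' @param order Butterworth order for both band filters.
#' @param trim_transients Drop edge-transient windows (default `TRUE`).
#' @return A tibble of class `band_power_track`: `window_center_s`,
#'   `lf_ms2`, `hf_ms2`, `ratio`, with attributes `window` and `hop`.
#'   `ratio` is `NA` (flagged undefined) where the HF power is zero.
#' @export
band_power_track <- function(series, window = 60, hop = 30,
                             lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                             order = 4L, trim_transients = TRUE) {
  if (window < 25) abort("`window` must be at least 25 s (one 0.04 Hz cycle).")
  if (hop > window) abort("`hop` must not exceed `window`.")
  t0 <- series$t_s[1]
  t1 <- series$t_s[nrow(series)]
  if (t1 - t0 < window) abort("series shorter than one window.")
  centered <- uniform_series(series$t_s, series$value - mean(series$value),
    rate = attr(series, "rate")
  )
  lf <- butterworth_filter(centered, lf_band[1], lf_band[2], order)
  hf <- butterworth_filter(centered, hf_band[1], hf_band[2], order)
  centers <- seq(t0 + window / 2, t1 - window / 2, by = hop)
  if (trim_transients) {
    guard <- 1.5 / lf_band[1]
    ok <- (centers - window / 2) >= (t0 + guard) &
      (centers + window / 2) <= (t1 - guard)
    if (any(ok)) centers <- centers[ok] # keep all if trimming would empty
  }
  pow <- function(comp, ctr) {
    idx <- comp$t_s >= ctr - window / 2 & comp$t_s < ctr + window / 2
    mean(comp$value[idx]^2)
  }
  lf_p <- vapply(centers, function(ctr) pow(lf, ctr), numeric(1))
  hf_p <- vapply(centers, function(ctr) pow(hf, ctr), numeric(1))
  structure(
    tibble(
      window_center_s = centers, lf_ms2 = lf_p, hf_ms2 = hf_p,
      ratio = ifelse(hf_p > 0, lf_p / hf_p, NA_real_)
    ),
    class = c("band_power_track", class(tibble())),
    window = window, hop = hop
  )
}

#' Mean and SD of the LF/HF ratio within a segment
#'
#' Averages the window ratios whose centers fall inside the half-open
#' interval `[start, end)` — the half-open convention means no window is
#' double-counted where segments join.
#'
#' @param track A [band_power_track()].
#' @param start,end Segment bounds, s.
#' @param segment Label used in error messages.
#' @return A one-row tibble: `segment`, `mean_ratio`, `sd_ratio`,
#'   `n_windows` (`sd_ratio` is `NA` for a single window).
#' @export
segment_mean_ratio <- function(track, start, end, segment = "segment") {
  inside <- track$window_center_s >= start & track$window_center_s < end
  if (!any(inside)) {
    abort(sprintf(
      "no band-power windows with centers inside %s [%.1f, %.1f).",
      segment, start, end
    ))
  }
  r <- track$ratio[inside]
  tibble(
    segment = segment,
    mean_ratio = mean(r),
    sd_ratio = if (length(r) > 1) sd(r) else NA_real_,
    n_windows = length(r)
  )
}

#' Write a band-power track to CSV
#'
#' Columns `window_center_s, lf_ms2, hf_ms2, ratio`.
#' @param track A [band_power_track()].
#' @param path File path.
#' @export
write_band_power_csv <- function(track, path) {
  readr::write_csv(as_tibble(track), path)
  invisible(path)
}
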